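#' Signed weighted graph for community analysis
#'
#' Wraps a symmetric signed connectivity matrix (typically a condition-wise
#' time-averaged coupling matrix) with a resolution parameter.
#'
#' @param weights Symmetric numeric matrix; the diagonal is zeroed.
#' @param gamma Resolution parameter multiplying the null-model term.
#' @return An object of class `cc_graph`.
#' @export
signed_graph <- function(weights, gamma = 1) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop_invalid("weights must be square")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)))
    stop_invalid("weights must be symmetric")
  check_scalar_number(gamma, "gamma", positive = TRUE)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (all(weights == 0)) stop_degenerate("graph has no non-zero weights")
  structure(list(weights = weights, gamma = gamma, n = nrow(weights)),
            class = "cc_graph")
}

#' @export
print.cc_graph <- function(x, ...) {
  cat(sprintf("<cc_graph> %d nodes, gamma = %g, %.0f%% negative edges\n",
              x$n, x$gamma,
              100 * mean(x$weights[upper.tri(x$weights)] < 0)))
  invisible(x)
}

# Signed modularity gain matrix: Q(M) = sum_{ij same module} B_ij, with
# asymmetric positive/negative weighting:
#   B = (W+ - g*s+ s+'/v+)/v+  -  (W- - g*s- s-'/v-)/(v+ + v-)
# where W+/W- are the positive/negative parts, s their strengths, v their
# total weights (summed over all ordered pairs). The diagonal carries the
# null-model self terms, as in the reference toolbox convention.
modularity_matrix <- function(graph) {
  W <- graph$weights
  g <- graph$gamma
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  vp <- sum(sp)
  vn <- sum(sn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- B + (Wp - g * outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - g * outer(sn, sn) / vn) / (vp + vn)
  B
}

#' Signed modularity Q of a partition
#'
#' Modularity with asymmetric signed weighting: the positive term is
#' normalised by the total positive weight, the negative term down-weighted by
#' the negative fraction of total weight; the degree-based null strength
#' products are scaled by the resolution `gamma` of the graph.
#'
#' @param graph A [signed_graph()].
#' @param membership Integer module label per node.
#' @return Scalar Q.
#' @examples
#' W <- matrix(1, 4, 4); diag(W) <- 0
#' modularity_q(signed_graph(W), rep(1, 4))  # 0: one module of everything
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "cc_graph"))
  if (length(membership) != graph$n)
    stop_invalid("membership must label every node")
  B <- modularity_matrix(graph)
  same <- outer(membership, membership, `==`)
  sum(B[same])
}

#' Consensus community detection by repeated Louvain runs
#'
#' Runs the Louvain algorithm `n_runs` times on the signed modularity matrix
#' with random node orders, builds the module co-assignment agreement matrix,
#' and re-clusters the agreement matrix iteratively until all runs coincide
#' (the consensus). A deterministic single-node fine-tuning pass on the
#' original graph then refines the consensus partition.
#'
#' @param graph A [signed_graph()].
#' @param gamma Optional override of the graph's resolution.
#' @param n_runs Number of Louvain restarts (default 500).
#' @param seed Integer seed controlling the restarts.
#' @param tau Agreement threshold below which co-assignment evidence is
#'   discarded when building the consensus graph (default 0.5).
#' @return A list of class `cc_partition`: `membership` (contiguous labels
#'   from 1), `q`, `n_modules`, `n_runs`, `seed`, `gamma`.
#' @export
louvain_consensus <- function(graph, gamma = NULL, n_runs = 500, seed = 1,
                              tau = 0.5) {
  stopifnot(inherits(graph, "cc_graph"))
  if (!is.null(gamma)) graph <- signed_graph(graph$weights, gamma)
  if (n_runs < 1) stop_invalid("n_runs must be >= 1")
  B <- modularity_matrix(graph)
  set.seed(seed)
  # each restart is run to convergence by the move sweeps; restarts
  # alternate between agglomerative (singleton) starts and random-partition
  # starts, which escape the agglomeration bias of pure Louvain on small
  # frustrated signed graphs
  n <- graph$n
  runs <- lapply(seq_len(n_runs), function(r) {
    if (r %% 2 == 1) {
      .finetune_gain(B, .louvain_gain(B, TRUE))
    } else {
      k <- sample(2:max(2, min(n, 8)), 1)
      .finetune_gain(B, sample.int(k, n, replace = TRUE))
    }
  })
  membership <- consensus_from_runs(runs, B, n_runs)
  membership <- refine_partition(B, membership)
  q <- sum(B[outer(membership, membership, `==`)])
  # the refined consensus must not score below the best individual restart;
  # if the agreement compromise does, refine from that restart instead
  qs <- vapply(runs, function(r) sum(B[outer(r, r, `==`)]), 0)
  if (max(qs) > q + 1e-12) {
    membership <- refine_partition(B, runs[[which.max(qs)]])
    q <- sum(B[outer(membership, membership, `==`)])
  }
  structure(list(membership = membership, q = q,
                 n_modules = max(membership), n_runs = n_runs, seed = seed,
                 gamma = graph$gamma),
            class = "cc_partition")
}

# Iteratively cluster the agreement matrix until all runs return the same
# partition (fine-tuning consensus).
consensus_from_runs <- function(runs, B, n_runs, tau = 0.5, max_iter = 20) {
  identical_runs <- function(rs) all(vapply(rs[-1], function(r)
    same_partition(r, rs[[1]]), TRUE))
  if (identical_runs(runs)) return(runs[[1]])
  for (iter in seq_len(max_iter)) {
    A <- Reduce(`+`, lapply(runs, function(r) outer(r, r, `==`) * 1)) / length(runs)
    A[A < tau] <- 0
    diag(A) <- 0
    if (all(A == 0)) return(seq_along(runs[[1]]))  # no agreement: singletons
    # uniform null on the agreement graph, resolution 1
    s <- rowSums(A)
    v <- sum(s)
    BA <- (A - outer(s, s) / v) / v
    diag(BA) <- diag(BA)  # keep null self-terms
    runs <- replicate(length(runs), .louvain_gain(BA, TRUE), simplify = FALSE)
    if (identical_runs(runs)) return(runs[[1]])
  }
  # fall back to the highest-Q run among the last batch
  qs <- vapply(runs, function(r) sum(B[outer(r, r, `==`)]), 0)
  runs[[which.max(qs)]]
}

# Kernighan-Lin style refinement: alternate single-node best-move sweeps
# (compiled) with pairwise cross-community swaps and community merges until
# no move of any kind improves the quality sum.
refine_partition <- function(B, memb, max_iter = 200) {
  n <- nrow(B)
  for (iter in seq_len(max_iter)) {
    memb <- .finetune_gain(B, memb)
    mods <- sort(unique(memb))
    ind <- outer(memb, mods, `==`) * 1
    acc <- B %*% ind
    acc[cbind(seq_len(n), match(memb, mods))] <-
      acc[cbind(seq_len(n), match(memb, mods))] - diag(B)
    ci <- match(memb, mods)
    own <- acc[cbind(seq_len(n), ci)]
    improved <- FALSE
    # best pairwise swap: gain = 2(acc_i[cj] + acc_j[ci] - own_i - own_j - 2B_ij)
    if (length(mods) > 1) {
      gain <- acc[, ci, drop = FALSE]           # gain[i, j] = acc_i[c_j]
      swap <- gain + t(gain) - outer(own, own, `+`) - 2 * B
      swap[outer(ci, ci, `==`)] <- -Inf
      diag(swap) <- -Inf
      k <- arrayInd(which.max(swap), dim(swap))
      if (swap[k] > 1e-12) {
        tmp <- memb[k[1]]
        memb[k[1]] <- memb[k[2]]
        memb[k[2]] <- tmp
        improved <- TRUE
      }
    }
    if (!improved && length(mods) > 1) {
      agg <- crossprod(ind, B %*% ind)
      diag(agg) <- -Inf
      k <- arrayInd(which.max(agg), dim(agg))
      if (agg[k] > 1e-12) {   # merge gain = 2 * between-community weight
        memb[memb == mods[k[2]]] <- mods[k[1]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  m <- match(memb, sort(unique(memb)))
  as.integer(m)
}

same_partition <- function(a, b) {
  # label-permutation-invariant equality
  length(unique(a)) == length(unique(b)) &&
    !anyDuplicated(unique(cbind(a, b))[, 1]) &&
    !anyDuplicated(unique(cbind(a, b))[, 2])
}

#' @export
print.cc_partition <- function(x, ...) {
  cat(sprintf("<cc_partition> %d modules, Q = %.4f (gamma = %g, %d runs)\n",
              x$n_modules, x$q, x$gamma, x$n_runs))
  invisible(x)
}

#' Partition stability across the resolution parameter
#'
#' For each `gamma`, runs the Louvain algorithm `n_runs` times and reports the
#' mean pairwise Pearson correlation between the runs' co-assignment vectors
#' (upper-triangle of the co-assignment matrix); higher means the resolution
#' yields more reproducible partitions.
#'
#' @param graph A [signed_graph()].
#' @param gammas Resolutions to scan (default 0.5 to 2.5 in steps of 0.1).
#' @param n_runs Runs per resolution (default 20).
#' @param seed Integer seed.
#' @return Data frame with `gamma`, `stability`, `n_modules` (median across
#'   runs); the most stable gamma in attribute `"best_gamma"` (ties resolved
#'   toward the smallest gamma).
#' @export
gamma_stability <- function(graph, gammas = seq(0.5, 2.5, by = 0.1),
                            n_runs = 20, seed = 1) {
  stopifnot(inherits(graph, "cc_graph"))
  if (length(gammas) < 2) stop_invalid("at least 2 gamma values are required")
  res <- lapply(seq_along(gammas), function(k) {
    g <- signed_graph(graph$weights, gammas[k])
    B <- modularity_matrix(g)
    set.seed(derive_seed(seed, k))
    runs <- replicate(n_runs, .louvain_gain(B, TRUE), simplify = FALSE)
    co <- vapply(runs, function(r) {
      m <- outer(r, r, `==`) * 1
      m[upper.tri(m)]
    }, numeric(graph$n * (graph$n - 1) / 2))
    cors <- stats::cor(co)
    # runs with a single module have zero-variance co-assignment: treat a
    # pair of such runs as perfectly similar
    cors[is.na(cors)] <- ifelse(outer(apply(co, 2, stats::sd) == 0,
                                      apply(co, 2, stats::sd) == 0,
                                      `&`)[is.na(cors)], 1, 0)
    data.frame(gamma = gammas[k],
               stability = mean(cors[upper.tri(cors)]),
               n_modules = stats::median(vapply(runs, max, 0L)))
  })
  out <- do.call(rbind, res)
  attr(out, "best_gamma") <- out$gamma[which.max(out$stability)]
  out
}

#' Participation coefficient of each node
#'
#' PC_i = 1 - sum_s (k_is / k_i)^2 over modules s, computed on positive
#' weights only (negative connections are discarded first). Nodes with zero
#' positive strength are assigned PC = 0.
#'
#' @param graph A [signed_graph()] (or plain symmetric matrix).
#' @param membership Module label per node (e.g. from [louvain_consensus()]).
#' @return Numeric vector of PC in `[0, 1]`, named by the weight matrix's
#'   row names when present.
#' @examples
#' W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
#' participation_coefficient(signed_graph(W), c(1, 1, 2, 2))  # all 0
#' @export
participation_coefficient <- function(graph, membership) {
  W <- if (inherits(graph, "cc_graph")) graph$weights else as.matrix(graph)
  if (length(membership) != nrow(W))
    stop_invalid("membership must label every node")
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  k <- rowSums(Wp)
  mods <- sort(unique(membership))
  ind <- outer(membership, mods, `==`) * 1
  kis <- Wp %*% ind
  pc <- 1 - rowSums((kis / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  names(pc) <- rownames(W)
  pc
}

#' Compare participation coefficients across task conditions
#'
#' Runs a one-way ANOVA on subject-by-condition mean PC (and a
#' repeated-measures variant with subject as error stratum), parcel-wise
#' paired t tests between all condition pairs with Benjamini-Hochberg control,
#' and the correlation of the group-mean dual-task PC map with the average of
#' the two single-task maps.
#'
#' @param mean_pc Subjects x conditions matrix of mean PC (columns named
#'   balance, calculation, dual).
#' @param parcel_pc Optional 3-D array, parcels x subjects x conditions, for
#'   the parcel-wise paired tests.
#' @param q FDR level (default 0.05).
#' @return List with `anova` (F, df1, df2, p), `anova_rm` (repeated-measures
#'   F, p), `pairwise` (per condition pair: parcel-level p's, BH-adjusted,
#'   n_significant; or mean-PC paired t when no parcel data), and
#'   `dual_vs_single_r`.
#' @export
compare_pc_across_tasks <- function(mean_pc, parcel_pc = NULL, q = 0.05) {
  mean_pc <- as.matrix(mean_pc)
  if (!all(CC_CONDITIONS %in% colnames(mean_pc)))
    stop_invalid("mean_pc must have columns ",
                 paste(CC_CONDITIONS, collapse = ", "))
  mean_pc <- mean_pc[, CC_CONDITIONS]
  n <- nrow(mean_pc)
  if (n < 2) stop_invalid("at least 2 subjects are required")
  long <- data.frame(
    pc = as.vector(mean_pc),
    condition = factor(rep(CC_CONDITIONS, each = n), levels = CC_CONDITIONS),
    subject = factor(rep(seq_len(n), times = 3))
  )
  if (stats::sd(long$pc) == 0) {
    # identical PC everywhere: no association, F defined as 0
    return(list(anova = list(F = 0, df1 = 2, df2 = 3 * n - 3, p = 1),
                anova_rm = list(F = 0, p = 1),
                group_means = colMeans(mean_pc),
                pairwise = NULL, dual_vs_single_r = NA_real_))
  }
  av <- stats::anova(stats::aov(pc ~ condition, data = long))
  rm_fit <- summary(stats::aov(pc ~ condition + Error(subject), data = long))
  rm_tab <- rm_fit[["Error: Within"]][[1]]
  pairs <- utils::combn(CC_CONDITIONS, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr) {
    if (!is.null(parcel_pc)) {
      d <- parcel_pc[, , pr[1]] - parcel_pc[, , pr[2]]
      pvals <- apply(d, 1, function(x) {
        if (stats::sd(x) == 0) return(1)
        stats::t.test(x)$p.value
      })
      padj <- stats::p.adjust(pvals, method = "BH")
      list(pair = pr, p = pvals, p_adj = padj,
           n_significant = sum(padj < q),
           mean_diff = mean(d))
    } else {
      tt <- stats::t.test(mean_pc[, pr[1]], mean_pc[, pr[2]], paired = TRUE)
      list(pair = pr, t = unname(tt$statistic), p = tt$p.value,
           mean_diff = unname(tt$estimate))
    }
  })
  names(pairwise) <- vapply(pairs, paste, "", collapse = "_vs_")
  dual_r <- if (!is.null(parcel_pc)) {
    dual_map <- rowMeans(parcel_pc[, , "dual"])
    single_map <- (rowMeans(parcel_pc[, , "balance"]) +
                     rowMeans(parcel_pc[, , "calculation"])) / 2
    stats::cor(dual_map, single_map)
  } else {
    NA_real_
  }
  list(
    anova = list(F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
                 p = av$`Pr(>F)`[1]),
    anova_rm = list(F = rm_tab$`F value`[1], p = rm_tab$`Pr(>F)`[1]),
    group_means = colMeans(mean_pc),
    pairwise = pairwise,
    dual_vs_single_r = dual_r
  )
}
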