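#' Multiplication of temporal derivatives (MTD) coupling
#'
#' For each parcel the first temporal derivative is divided by its
#' whole-series standard deviation; the pairwise products of these normalised
#' derivatives are then smoothed with a simple moving average of length
#' `window`. With the default `align = "forward"` the value at time t averages
#' derivative samples t .. t+window-1 (the convention of the printed formula);
#' `"trailing"` averages t-window+1 .. t. Either way the valid series has
#' `frames - window` samples.
#'
#' @param bold A [parcellated_bold()].
#' @param window Moving-average length in frames (default 20).
#' @param edge_subset `"cortico-cerebellar"` (default: the 400 x 28 system)
#'   or `"all"` (every unordered pair; memory-hungry at full atlas size).
#' @param align Window convention, `"forward"` or `"trailing"`.
#' @return A list of class `cc_edges`: `values` (time x edge matrix),
#'   `edge_index` (data.frame `i`, `j`, `name_i`, `name_j`), `window`,
#'   `align`, `tr`.
#' @export
mtd <- function(bold, window = 20,
                edge_subset = c("cortico-cerebellar", "all"),
                align = c("forward", "trailing")) {
  stopifnot(inherits(bold, "cc_bold"))
  edge_subset <- match.arg(edge_subset)
  align <- match.arg(align)
  Tn <- nrow(bold$data)
  if (window < 2 || window >= Tn)
    stop_invalid("window must be in [2, frames): got ", window,
                 " with ", Tn, " frames")
  dtz <- normalized_derivatives(bold)
  atlas <- bold$atlas
  if (edge_subset == "cortico-cerebellar") {
    ci <- cortex_idx(atlas)
    cj <- cerebellum_idx(atlas)
    if (!length(ci) || !length(cj))
      stop_invalid("atlas lacks cortical or cerebellar parcels")
    ii <- rep(ci, times = length(cj))
    jj <- rep(cj, each = length(ci))
  } else {
    pr <- which(upper.tri(matrix(0, ncol(dtz), ncol(dtz))), arr.ind = TRUE)
    ii <- pr[, 1]
    jj <- pr[, 2]
  }
  prod <- dtz[, ii, drop = FALSE] * dtz[, jj, drop = FALSE]
  values <- moving_average(prod, window)
  structure(list(
    values = values,
    edge_index = data.frame(i = ii, j = jj,
                            name_i = atlas$name[ii], name_j = atlas$name[jj],
                            stringsAsFactors = FALSE),
    window = window, align = align, tr = bold$tr, n_frames = Tn
  ), class = "cc_edges")
}

#' @export
print.cc_edges <- function(x, ...) {
  cat(sprintf("<cc_edges> %d x %d (time x edges), window %d (%s)\n",
              nrow(x$values), ncol(x$values), x$window, x$align))
  invisible(x)
}

normalized_derivatives <- function(bold) {
  dt <- diff(bold$data)
  sds <- apply(dt, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop_degenerate("constant signal in parcel(s): ",
                    paste(colnames(bold$data)[bad[seq_len(min(3, length(bad)))]],
                          collapse = ", "))
  sweep(dt, 2, sds, "/")
}

# Columnwise moving average of length w; output has nrow - w + 1 rows, row t
# averaging input rows t .. t+w-1.
moving_average <- function(x, w) {
  cs <- rbind(0, apply(x, 2, cumsum))
  (cs[(w + 1):nrow(cs), , drop = FALSE] -
      cs[1:(nrow(cs) - w), , drop = FALSE]) / w
}

#' Condition-wise time-averaged MTD matrices
#'
#' Returns, per condition, the full parcels x parcels MTD coupling matrix
#' averaged over the MTD samples falling inside that condition's trials
#' (trial windows shifted by a fixed haemodynamic lag). Computed through the
#' identity mean_t MTD(t) = t(D) (D * m) where D holds the normalised
#' derivatives and m the per-sample window-overlap weights, so the full edge
#' tensor is never materialised.
#'
#' @param bold A [parcellated_bold()].
#' @param events Event table (`onset`, `duration`, `trial_type`).
#' @param window Moving-average length (default 20).
#' @param lag Haemodynamic lag (seconds) applied to trial windows when
#'   assigning MTD samples to conditions (default 5).
#' @param align Window convention as in [mtd()].
#' @param censor Optional logical vector over frames (e.g. `flagged` from
#'   [qc_flags()]); MTD samples whose window overlaps a censored frame are
#'   dropped from the averages. Off (`NULL`) by default.
#' @return Named list (by condition) of symmetric matrices with zero diagonal.
#' @export
mtd_condition_matrices <- function(bold, events, window = 20, lag = 5,
                                   align = c("forward", "trailing"),
                                   censor = NULL) {
  stopifnot(inherits(bold, "cc_bold"))
  align <- match.arg(align)
  Tn <- nrow(bold$data)
  if (window < 2 || window >= Tn) stop_invalid("window out of range")
  dtz <- normalized_derivatives(bold)
  nd <- nrow(dtz)              # derivative samples
  nv <- nd - window + 1        # valid MTD samples
  # derivative sample k sits between frames k and k+1: time (k - 0.5) * tr
  dtimes <- (seq_len(nd) - 0.5) * bold$tr
  censored_sample <- rep(FALSE, nv)
  if (!is.null(censor)) {
    if (length(censor) != Tn)
      stop_invalid("censor must flag every frame (", Tn, ")")
    bad_dt <- censor[-Tn] | censor[-1]  # derivative touches a flagged frame
    censored_sample <- vapply(seq_len(nv), function(t)
      any(bad_dt[t:(t + window - 1)]), TRUE)
  }
  out <- list()
  for (cond in CC_CONDITIONS) {
    ev <- events[events$trial_type == cond, , drop = FALSE]
    if (!nrow(ev)) next
    # valid MTD sample t covers derivative samples t..t+w-1 under either
    # alignment (only the nominal timestamp differs); assign by window centre
    centre <- (dtimes[seq_len(nv)] + dtimes[seq_len(nv) + window - 1]) / 2
    inside <- rep(FALSE, nv)
    for (r in seq_len(nrow(ev)))
      inside <- inside | (centre >= ev$onset[r] + lag &
                            centre < ev$onset[r] + ev$duration[r] + lag)
    inside <- inside & !censored_sample
    if (!any(inside)) next
    sel <- which(inside)
    # weight on derivative sample k = (# selected MTD samples covering k)/(|S| w)
    m <- numeric(nd)
    for (t in sel) m[t:(t + window - 1)] <- m[t:(t + window - 1)] + 1
    m <- m / (length(sel) * window)
    M <- crossprod(dtz, dtz * m)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    dimnames(M) <- list(bold$atlas$name, bold$atlas$name)
    out[[cond]] <- M
  }
  out
}

#' Least-squares GLM on edge coupling series
#'
#' Fits the design matrix (cropped to the MTD-valid samples) to every edge's
#' coupling series by ordinary least squares.
#'
#' @param edges A [mtd()] result.
#' @param dm A [build_design_matrix()] built at the BOLD frame count.
#' @return Matrix of betas, regressors (minus intercept) x edges.
#' @export
edge_glm <- function(edges, dm) {
  stopifnot(inherits(edges, "cc_edges"), inherits(dm, "cc_design_matrix"))
  X <- dm$matrix
  nv <- nrow(edges$values)
  if (nrow(X) == edges$n_frames) {
    # crop to valid MTD samples: forward windows start at frame t
    offset <- if (edges$align == "forward") 0L else edges$window - 1L
    X <- X[seq_len(nv) + offset, , drop = FALSE]
  } else if (nrow(X) != nv) {
    stop_invalid("design matrix rows (", nrow(X), ") match neither the BOLD ",
                 "frame count (", edges$n_frames, ") nor the MTD samples (",
                 nv, ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_singular("edge design matrix is rank deficient")
  coefs <- qr.coef(qrX, edges$values)
  coefs[-1, , drop = FALSE]
}

#' Split dual-task trials into correct and incorrect
#'
#' A dual-task trial counts as correct when the calculation answer was
#' accurate AND its balance RMS error lies strictly below the population
#' median; otherwise (inaccurate calculation, large RMS error, or both) it is
#' incorrect. Ties at the median are incorrect (strict below-50% reading).
#'
#' @param outcomes Data frame of dual-task trials with `calc_correct` and
#'   `rms_error` columns.
#' @param rms_median Optional externally supplied population median.
#' @return Logical vector, `TRUE` for correct trials.
#' @export
split_trials <- function(outcomes, rms_median = NULL) {
  if (anyNA(outcomes$calc_correct) || anyNA(outcomes$rms_error))
    stop_invalid("every dual-task trial needs calc_correct and rms_error")
  if (is.null(rms_median)) rms_median <- stats::median(outcomes$rms_error)
  outcomes$calc_correct & outcomes$rms_error < rms_median
}

#' Permutation contrast of edge betas between two groups
#'
#' Two-sample t statistic per edge with a permutation null from label
#' shuffles; p = (b + 1) / (n_perm + 1) where b counts permuted |t| >=
#' observed |t| (add-one estimator, so p is never 0).
#'
#' @param betas Observations x edges matrix (e.g. trial-level edge betas).
#' @param labels Logical or two-level factor of group membership per row.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Significance level for the `significant` flags (default
#'   0.001).
#' @param seed Integer seed.
#' @return A list of class `cc_edge_contrast`: `effect` (group mean
#'   difference per edge), `tstat`, `p_perm`, `significant`, `alpha`,
#'   `n_perm`.
#' @export
contrast_edges_permutation <- function(betas, labels, n_perm = 5000,
                                       alpha = 0.001, seed = 1) {
  betas <- as.matrix(betas)
  labels <- as.logical(labels)
  if (anyNA(labels)) stop_invalid("labels must be TRUE/FALSE")
  n1 <- sum(labels)
  n2 <- sum(!labels)
  if (n1 < 2 || n2 < 2)
    stop_invalid("both groups need at least 2 observations (got ", n1, ", ",
                 n2, ")")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  tobs <- two_sample_t(betas, labels)
  set.seed(seed)
  n <- length(labels)
  exceed <- integer(ncol(betas))
  for (b in seq_len(n_perm)) {
    perm <- labels[sample.int(n)]
    exceed <- exceed + (abs(two_sample_t(betas, perm)) >= abs(tobs) - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  structure(list(
    effect = colMeans(betas[labels, , drop = FALSE]) -
      colMeans(betas[!labels, , drop = FALSE]),
    tstat = tobs, p_perm = p, significant = p < alpha,
    alpha = alpha, n_perm = n_perm
  ), class = "cc_edge_contrast")
}

# pooled-variance two-sample t per column
two_sample_t <- function(x, g) {
  n1 <- sum(g); n2 <- sum(!g)
  m1 <- colMeans(x[g, , drop = FALSE])
  m2 <- colMeans(x[!g, , drop = FALSE])
  v1 <- colSums(sweep(x[g, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(x[!g, , drop = FALSE], 2, m2)^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  d <- m1 - m2
  out <- ifelse(se > 0, d / se, 0)
  out
}

#' Summarise an edge contrast on the network x lobule grid
#'
#' Collapses significant cortico-cerebellar edge effects into a 10-lobule by
#' 7-network grid: each cell is the mean effect over significant edges whose
#' cortical end lies in the network and whose cerebellar end lies in the
#' lobule (left/right hemispheres pooled); vermal edges are excluded. Cells
#' with no significant edge are `NA`.
#'
#' @param contrast A [contrast_edges_permutation()] result.
#' @param edge_index The `edge_index` of the [mtd()] object the betas came
#'   from.
#' @param atlas The parcel atlas.
#' @return 10 x 7 matrix (lobules x networks).
#' @export
summarize_network_lobule <- function(contrast, edge_index, atlas) {
  validate_atlas(atlas)
  networks <- cc_networks()
  lobules <- cc_lobules()
  grid <- matrix(NA_real_, nrow = length(lobules), ncol = length(networks),
                 dimnames = list(lobules, networks))
  eff <- contrast$effect[contrast$significant]
  if (!length(eff)) return(grid)
  idx <- edge_index[contrast$significant, , drop = FALSE]
  net <- atlas$network[idx$i]
  lob <- atlas$lobule[idx$j]
  hemi <- atlas$hemisphere[idx$j]
  keep <- hemi != "vermis"
  if (!any(keep)) return(grid)
  agg <- tapply(eff[keep], list(factor(lob[keep], levels = lobules),
                                factor(net[keep], levels = networks)),
                mean)
  grid[] <- agg
  grid
}

#' Instantaneous MTD coupling matrix at one window
#'
#' Returns the full parcels x parcels MTD matrix for a single valid window
#' position (the w-sample average of normalised-derivative outer products
#' starting at sample `t`), supporting time-resolved topology such as
#' windowed participation coefficients.
#'
#' @param bold A [parcellated_bold()].
#' @param t Valid MTD sample index (1 .. frames - window).
#' @param window Moving-average length (default 20).
#' @return Symmetric matrix with zero diagonal.
#' @export
mtd_window_matrix <- function(bold, t, window = 20) {
  stopifnot(inherits(bold, "cc_bold"))
  Tn <- nrow(bold$data)
  if (window < 2 || window >= Tn) stop_invalid("window out of range")
  nv <- Tn - window
  if (t < 1 || t > nv)
    stop_invalid("t must lie in [1, ", nv, "], got ", t)
  dtz <- normalized_derivatives(bold)
  rows <- dtz[t:(t + window - 1), , drop = FALSE]
  M <- crossprod(rows) / window
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(bold$atlas$name, bold$atlas$name)
  M
}
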