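#' Directed cortico-cerebellar structural connectome
#'
#' Holds the two directed tract weight matrices: CPC (cortex -> cerebellum,
#' cortical x cerebellar) and CTC (cerebellum -> cortex, cerebellar x
#' cortical). Weights are non-negative; when built from streamline counts use
#' `from_counts = TRUE` to apply the log10(count + 1) transform (zero
#' streamlines map to weight 0).
#'
#' @param cpc Cortical x cerebellar weight matrix.
#' @param ctc Cerebellar x cortical weight matrix.
#' @param atlas Atlas the dimensions must match.
#' @param from_counts If `TRUE`, `cpc`/`ctc` are raw streamline counts and are
#'   transformed to log10(count + 1).
#' @return A list of class `cc_connectome` with `cpc`, `ctc`.
#' @export
structural_connectome <- function(cpc, ctc, atlas, from_counts = FALSE) {
  validate_atlas(atlas)
  cpc <- as.matrix(cpc)
  ctc <- as.matrix(ctc)
  nc <- length(cortex_idx(atlas))
  nb <- length(cerebellum_idx(atlas))
  if (!all(dim(cpc) == c(nc, nb)))
    stop_invalid("cpc must be ", nc, " x ", nb, ", got ",
                 paste(dim(cpc), collapse = " x "))
  if (!all(dim(ctc) == c(nb, nc)))
    stop_invalid("ctc must be ", nb, " x ", nc, ", got ",
                 paste(dim(ctc), collapse = " x "))
  if (any(cpc < 0) || any(ctc < 0))
    stop_invalid("connectome weights must be non-negative")
  if (from_counts) {
    cpc <- log10(cpc + 1)
    ctc <- log10(ctc + 1)
  }
  ctx_names <- atlas$name[cortex_idx(atlas)]
  cbm_names <- atlas$name[cerebellum_idx(atlas)]
  dimnames(cpc) <- list(ctx_names, cbm_names)
  dimnames(ctc) <- list(cbm_names, ctx_names)
  structure(list(cpc = cpc, ctc = ctc), class = "cc_connectome")
}

#' Predict a target activation pattern through structural weights
#'
#' Activity-flow prediction: the predicted activity of target parcel j is the
#' weight-mixed sum of source activity, `sum_i weights[i, j] * source[i]`.
#' Cerebellar patterns are predicted from cortical betas through the CPC
#' matrix; cortical patterns from cerebellar betas through the CTC matrix.
#'
#' @param source_beta Activation vector over the source parcels.
#' @param weights Directed weight matrix, source x target.
#' @return Predicted activation vector over the target parcels.
#' @export
predict_activity <- function(source_beta, weights) {
  weights <- as.matrix(weights)
  if (length(source_beta) != nrow(weights))
    stop_invalid("source length (", length(source_beta),
                 ") does not match weight source axis (", nrow(weights), ")")
  drop(crossprod(weights, as.numeric(source_beta)))
}

#' Pearson evaluation of a flow prediction
#'
#' @param predicted Predicted activation vector.
#' @param observed Observed activation vector of equal length.
#' @return Pearson r.
#' @export
evaluate_flow <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_invalid("predicted and observed must have equal length")
  if (stats::sd(predicted) == 0)
    stop_degenerate("predicted pattern is constant; correlation undefined")
  if (stats::sd(observed) == 0)
    stop_degenerate("observed pattern is constant; correlation undefined")
  stats::cor(predicted, observed)
}

#' Permutation null for an activity-flow prediction
#'
#' Builds the null by randomly permuting the rows (source assignment) of the
#' weight matrix each iteration, preserving each source's weight profile, and
#' recomputing the prediction correlation; p = (b + 1) / (n_perm + 1) with b
#' the number of null r >= observed r.
#'
#' @param source_beta Source activation vector.
#' @param observed Observed target activation vector.
#' @param weights Directed weight matrix, source x target.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `r` (observed), `p`, `null_r` (vector of null
#'   correlations).
#' @export
flow_permutation_null <- function(source_beta, observed, weights,
                                  n_perm = 5000, seed = 1) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  weights <- as.matrix(weights)
  robs <- evaluate_flow(predict_activity(source_beta, weights), observed)
  set.seed(seed)
  ns <- nrow(weights)
  # permuting rows of W with fixed source s equals fixing W and permuting s
  perms <- vapply(seq_len(n_perm),
                  function(k) as.numeric(source_beta)[sample.int(ns)],
                  numeric(ns))
  preds <- crossprod(weights, perms)       # targets x n_perm
  sdp <- apply(preds, 2, stats::sd)
  null_r <- rep(NA_real_, n_perm)
  ok <- sdp > 0
  if (any(ok))
    null_r[ok] <- suppressWarnings(stats::cor(preds[, ok, drop = FALSE],
                                              observed))[, 1]
  b <- sum(null_r >= robs - 1e-12, na.rm = TRUE)
  list(r = robs, p = (b + 1) / (n_perm + 1), null_r = null_r)
}

#' Compare flow prediction accuracy between correct and incorrect trials
#'
#' Fisher-z transforms the per-trial prediction correlations and runs a
#' two-sided two-sample Welch t test (correct minus incorrect).
#'
#' @param r_values Per-trial prediction correlations.
#' @param correct Logical label per trial.
#' @return List with `t`, `df`, `p`, `mean_correct`, `mean_incorrect`.
#' @export
compare_flow_by_accuracy <- function(r_values, correct) {
  correct <- as.logical(correct)
  if (length(r_values) != length(correct))
    stop_invalid("r_values and labels must have equal length")
  if (sum(correct) < 2 || sum(!correct) < 2)
    stop_invalid("both accuracy groups need at least 2 trials")
  z <- atanh(pmin(pmax(r_values, -1 + 1e-12), 1 - 1e-12))
  if (stats::sd(z[correct]) == 0 && stats::sd(z[!correct]) == 0 &&
      mean(z[correct]) == mean(z[!correct]))
    return(list(t = 0, df = length(z) - 2, p = 1,
                mean_correct = mean(r_values[correct]),
                mean_incorrect = mean(r_values[!correct])))
  tt <- stats::t.test(z[correct], z[!correct])
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_correct = mean(r_values[correct]),
       mean_incorrect = mean(r_values[!correct]))
}

#' Run the full activity-flow analysis for a set of beta maps
#'
#' For each condition (and optionally each dual-task trial) predicts the
#' cerebellar pattern from the cortical betas through CPC and the cortical
#' pattern from the cerebellar betas through CTC, evaluates both against the
#' observed patterns, and attaches permutation p values.
#'
#' @param betamap A `cc_betamap` (condition- or trial-level).
#' @param connectome A [structural_connectome()].
#' @param atlas The parcel atlas.
#' @param n_perm Permutations per test (default 5000).
#' @param seed Integer seed.
#' @return Data frame with one row per (regressor, direction): `regressor`,
#'   `direction` ("ctx_to_cbm" or "cbm_to_ctx"), `r`, `p`.
#' @export
flow_analysis <- function(betamap, connectome, atlas, n_perm = 5000, seed = 1) {
  stopifnot(inherits(betamap, "cc_betamap"),
            inherits(connectome, "cc_connectome"))
  ci <- cortex_idx(atlas)
  cb <- cerebellum_idx(atlas)
  regs <- rownames(betamap$beta)
  out <- lapply(seq_along(regs), function(k) {
    w_ctx <- betamap$beta[k, ci]
    w_cbm <- betamap$beta[k, cb]
    fwd <- flow_permutation_null(w_ctx, w_cbm, connectome$cpc, n_perm,
                                 seed = derive_seed(seed, 2L * k))
    bwd <- flow_permutation_null(w_cbm, w_ctx, connectome$ctc, n_perm,
                                 seed = derive_seed(seed, 2L * k + 1L))
    data.frame(regressor = regs[k],
               direction = c("ctx_to_cbm", "cbm_to_ctx"),
               r = c(fwd$r, bwd$r), p = c(fwd$p, bwd$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
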