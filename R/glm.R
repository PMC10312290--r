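#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style double-gamma kernel: a gamma density peaking at 6 s minus a 16-s
#' undershoot scaled by 1/6, sampled at the repetition time and rescaled to
#' unit peak. The kernel is exactly 0 at onset.
#'
#' @param tr Sampling interval in seconds.
#' @param length Kernel support in seconds (default 32).
#' @return Numeric vector sampled at `0, tr, 2*tr, ...` up to `length`.
#' @examples
#' h <- canonical_hrf(0.7)
#' plot(seq_along(h) * 0.7 - 0.7, h, type = "l", xlab = "s")
#' @export
canonical_hrf <- function(tr, length = 32) {
  check_scalar_number(tr, "tr", positive = TRUE)
  check_scalar_number(length, "length", positive = TRUE)
  t <- seq(0, length, by = tr)
  # shape/rate parameterisation: peak delay 6 s, undershoot delay 16 s,
  # dispersions 1 s, undershoot ratio 1/6
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a block-design matrix with HRF-convolved regressors
#'
#' One regressor per condition (or per trial with `granularity = "trial"`),
#' formed by convolving the event boxcar sampled at frame times with the
#' canonical HRF, plus a leading intercept column.
#'
#' @param design Event table with columns `onset`, `duration`, `trial_type`
#'   (from [generate_design()] or [read_events()]).
#' @param tr Repetition time in seconds.
#' @param n_frames Number of frames in the run.
#' @param granularity `"condition"` (default) or `"trial"` (one regressor per
#'   event, named `<condition>_<k>`).
#' @return A list of class `cc_design_matrix`: `matrix` (frames x regressors,
#'   intercept first), `hrf`, `frame_times`, `tr`, `granularity`.
#' @export
build_design_matrix <- function(design, tr, n_frames,
                                granularity = c("condition", "trial")) {
  granularity <- match.arg(granularity)
  check_scalar_number(tr, "tr", positive = TRUE)
  check_scalar_number(n_frames, "n_frames", positive = TRUE)
  ev <- as.data.frame(design)
  frame_times <- (seq_len(n_frames) - 1) * tr
  scan_end <- n_frames * tr
  if (nrow(ev)) {
    if (!all(ev$trial_type %in% CC_CONDITIONS))
      stop_invalid("unknown trial_type: ",
                   paste(setdiff(ev$trial_type, CC_CONDITIONS), collapse = ", "))
    over <- ev$onset + ev$duration > scan_end + 1e-9
    if (any(over))
      stop_invalid("event ", which(over)[1], " extends past scan end (",
                   ev$onset[which(over)[1]] + ev$duration[which(over)[1]],
                   " s > ", scan_end, " s)")
  }
  hrf <- canonical_hrf(tr)
  boxcar <- function(onset, duration)
    as.numeric(frame_times >= onset & frame_times < onset + duration)
  convolved <- function(box) {
    full <- stats::convolve(box, rev(hrf), type = "open")
    full[seq_len(n_frames)]
  }
  if (granularity == "condition") {
    present <- CC_CONDITIONS[CC_CONDITIONS %in% ev$trial_type]
    cols <- lapply(present, function(cond) {
      rows <- ev$trial_type == cond
      box <- Reduce(`+`, Map(boxcar, ev$onset[rows], ev$duration[rows]),
                    accumulate = FALSE)
      convolved(box)
    })
    names(cols) <- present
  } else {
    k <- stats::ave(seq_len(nrow(ev)), ev$trial_type, FUN = seq_along)
    cols <- Map(function(onset, duration, cond, i)
      convolved(boxcar(onset, duration)),
      ev$onset, ev$duration, ev$trial_type, k)
    names(cols) <- sprintf("%s_%02d", ev$trial_type, k)
  }
  X <- cbind(`(Intercept)` = rep(1, n_frames),
             if (length(cols)) do.call(cbind, cols))
  structure(list(matrix = X, hrf = hrf, frame_times = frame_times, tr = tr,
                 granularity = granularity, events = ev),
            class = "cc_design_matrix")
}

#' Fit the block-design GLM to parcellated BOLD data
#'
#' Ordinary least squares per parcel; returns the task betas (the intercept is
#' estimated but dropped from the map).
#'
#' @param bold A [parcellated_bold()].
#' @param dm A [build_design_matrix()] result with matching frame count.
#' @param subject_id Optional identifier stored on the result.
#' @return A list of class `cc_betamap`: `beta` (regressor x parcel matrix),
#'   `intercept` (per-parcel), `subject_id`, `granularity`.
#' @export
fit_glm <- function(bold, dm, subject_id = NA) {
  stopifnot(inherits(bold, "cc_bold"), inherits(dm, "cc_design_matrix"))
  X <- dm$matrix
  if (nrow(X) != nrow(bold$data))
    stop_invalid("design matrix frames (", nrow(X),
                 ") do not match BOLD frames (", nrow(bold$data), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_singular("design matrix is rank deficient (rank ", qrX$rank,
                  " < ", ncol(X), " columns)")
  coefs <- qr.coef(qrX, bold$data)
  structure(list(
    beta = coefs[-1, , drop = FALSE],
    intercept = coefs[1, ],
    subject_id = subject_id,
    granularity = dm$granularity
  ), class = "cc_betamap")
}

#' Fit the principal-component task decoder
#'
#' Stacks the per-subject balance and calculation beta maps, demeans each
#' parcel across the stacked observations, and takes the leading principal
#' component as a linear decoder between the two tasks. The sign is fixed so
#' that the loading correlates positively with the group-mean
#' (calculation - balance) contrast.
#'
#' @param balance_betas Subjects x parcels matrix of balance betas.
#' @param calculation_betas Subjects x parcels matrix of calculation betas.
#' @return A list of class `cc_decoder`: `loading` (unit-norm parcel vector),
#'   `center` (per-parcel training mean), `sign_flipped`, `sdev` (singular
#'   values of the demeaned stack).
#' @export
fit_decoder <- function(balance_betas, calculation_betas) {
  balance_betas <- as.matrix(balance_betas)
  calculation_betas <- as.matrix(calculation_betas)
  if (nrow(balance_betas) < 2 || nrow(calculation_betas) < 2)
    stop_invalid("at least 2 subjects per condition are required")
  if (ncol(balance_betas) != ncol(calculation_betas))
    stop_invalid("balance and calculation betas must share the parcel axis")
  stacked <- rbind(balance_betas, calculation_betas)
  center <- colMeans(stacked)
  demeaned <- sweep(stacked, 2, center)
  if (all(abs(demeaned) < .Machine$double.eps * 100))
    stop_degenerate("beta maps have zero variance; decoder undefined")
  sv <- svd(demeaned)
  loading <- sv$v[, 1]
  contrast <- colMeans(calculation_betas) - colMeans(balance_betas)
  flip <- FALSE
  cr <- suppressWarnings(stats::cor(loading, contrast))
  if (is.finite(cr) && cr < 0) {
    loading <- -loading
    flip <- TRUE
  }
  names(loading) <- colnames(balance_betas)
  structure(list(loading = loading, center = center, sign_flipped = flip,
                 sdev = sv$d), class = "cc_decoder")
}

#' Project dual-task beta maps onto the decoder
#'
#' Computes the dot product between each subject's (demeaned) dual-task beta
#' map and the decoder loading, then a two-sided one-sample t test against 0:
#' positive loadings indicate calculation-like, negative balance-like
#' activation patterns.
#'
#' @param dual_betas Subjects x parcels matrix of dual-task betas.
#' @param decoder A [fit_decoder()] result on the same parcel axis.
#' @return List with `loadings` (per subject), `t`, `df`, `p`, `mean`.
#' @export
project_dual <- function(dual_betas, decoder) {
  dual_betas <- as.matrix(dual_betas)
  stopifnot(inherits(decoder, "cc_decoder"))
  if (ncol(dual_betas) != length(decoder$loading))
    stop_invalid("parcel axes of dual betas and decoder differ")
  if (nrow(dual_betas) < 2)
    stop_invalid("at least 2 subjects are required for the t test")
  loadings <- drop(sweep(dual_betas, 2, decoder$center) %*% decoder$loading)
  if (stats::sd(loadings) < .Machine$double.eps * 100)
    stop_degenerate("projection loadings have zero variance; t undefined")
  tt <- stats::t.test(loadings, mu = 0)
  list(loadings = loadings, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, mean = mean(loadings))
}

#' Positive-beta contingency table and chi-square test
#'
#' `positive_beta_counts` tabulates, per condition, how many cerebellar
#' parcel-by-subject observations have positive beta; `positive_beta_test`
#' runs the Pearson chi-square (no continuity correction) on a conditions x
#' {positive, non-positive} table.
#'
#' @param betamaps List of per-subject `cc_betamap`s (condition-level).
#' @param atlas The atlas identifying cerebellar parcels.
#' @param table Integer matrix, conditions x 2 (positive, non-positive).
#' @return `positive_beta_counts`: the contingency table with a `proportion`
#'   attribute. `positive_beta_test`: list with `proportions`, `statistic`,
#'   `df`, `p`, `table`.
#' @export
positive_beta_counts <- function(betamaps, atlas) {
  validate_atlas(atlas)
  cb <- cerebellum_idx(atlas)
  if (!length(cb)) stop_invalid("atlas contains no cerebellar parcels")
  conds <- rownames(betamaps[[1]]$beta)
  counts <- t(vapply(conds, function(cond) {
    obs <- unlist(lapply(betamaps, function(b) b$beta[cond, cb]))
    c(positive = sum(obs > 0), nonpositive = sum(obs <= 0))
  }, c(positive = 0, nonpositive = 0)))
  attr(counts, "proportion") <- counts[, 1] / rowSums(counts)
  counts
}

#' @rdname positive_beta_counts
#' @export
positive_beta_test <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != 2) stop_invalid("table must have 2 columns")
  if (any(table < 0)) stop_invalid("counts must be non-negative")
  props <- table[, 1] / rowSums(table)
  if (any(colSums(table) == 0)) {
    # every observation falls in one column: proportions are identical across
    # conditions, hence no association (Pearson statistic degenerates to 0/0)
    return(list(proportions = props, statistic = 0,
                df = (nrow(table) - 1) * (ncol(table) - 1), p = 1,
                table = table))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(proportions = props, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, table = table)
}

#' Kolmogorov-Smirnov comparison of balance RMS errors
#'
#' Two-sample two-sided KS test between the balance-trial and dual-trial RMS
#' error distributions.
#'
#' @param balance_rms Numeric vector of balance-trial RMS errors (degrees).
#' @param dual_rms Numeric vector of dual-trial RMS errors (degrees).
#' @return List with `D`, `p`.
#' @export
ks_compare_rms <- function(balance_rms, dual_rms) {
  balance_rms <- balance_rms[!is.na(balance_rms)]
  dual_rms <- dual_rms[!is.na(dual_rms)]
  if (!length(balance_rms) || !length(dual_rms))
    stop_invalid("both RMS samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(balance_rms, dual_rms,
                                        alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}
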