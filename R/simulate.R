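#' Simulation configuration for a synthetic dual-task cohort
#'
#' Defines the study conditions of the generated cohorts: a block design with
#' `n_blocks` blocks each containing one balance, one calculation and one
#' dual-task trial in random order followed by a rest period, sampled at
#' repetition time `tr` over a combined cortical + cerebellar atlas.
#' Condition-specific activation maps, condition-dependent modular noise
#' correlation, structure-function coupling of strength `coupling_strength`
#' through the directed CPC/CTC connectomes, and per-trial behavioural
#' outcomes tied to the trial's coupling are planted as recoverable ground
#' truth.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param n_cortical,n_cerebellar Atlas sizes (defaults 400 and 28).
#' @param tr Repetition time in seconds (default 0.7).
#' @param n_blocks Blocks per run (default 12).
#' @param trial_duration Trial length in seconds (default 15).
#' @param rest_duration Rest after each block in seconds (default 15).
#' @param activation_amplitude Per-condition named lists `network = c(...)`,
#'   `lobule = c(...)` of activation amplitudes (signal units); `NULL` for the
#'   built-in defaults.
#' @param cbm_baseline Per-condition baseline shift added to every cerebellar
#'   parcel's activation (controls the positive-beta proportions).
#' @param coupling_strength Structure-function coupling kappa in `[0, 1]`.
#' @param structure_align Strength (in units of pattern SD) of the
#'   CPC-projected cortical map inherited by the cerebellar intrinsic maps,
#'   emulating mossy-fibre drive of cerebellar BOLD (default 0.5; makes
#'   matching-condition flow predictions outperform non-matching controls).
#' @param coupling_jitter SD of the per-trial jitter on kappa (disabled at the
#'   degenerate kappa = 0 or 1 so noiseless closure is exact).
#' @param modular_structure List with `labels` (module label per parcel, or
#'   per-condition list of such), `rho_within` (within-module noise
#'   correlation) and `rho_between` (named per-condition between-module
#'   correlation); `NULL` for defaults (0.35 within; 0.05 / 0.15 / 0.25
#'   between for balance / dual / calculation, planting the participation
#'   ordering balance < dual < calculation).
#' @param noise_sd Noise standard deviation in signal units (default 1).
#' @param behaviour_link Slope of trial correctness (logistic in the trial's
#'   coupling) and of the lognormal RMS error on coupling (default 8).
#' @param baseline Mean BOLD signal level (arbitrary units, default 200:
#'   with unit noise SD this yields a group-mean DVARS near 0.8% of mean
#'   signal, typical of a low-motion cohort).
#' @param avatar_target Upright avatar target angle in degrees (default 90).
#' @param lag Haemodynamic lag (s) used when planting condition-dependent
#'   noise structure (default 5, matching the analysis-side window
#'   assignment).
#' @param seed Master seed.
#' @return A validated list of class `cc_sim_config`.
#' @export
sim_config <- function(n_subjects = 20, n_cortical = 400, n_cerebellar = 28,
                       tr = 0.7, n_blocks = 12, trial_duration = 15,
                       rest_duration = 15, activation_amplitude = NULL,
                       cbm_baseline = c(balance = 0.3, calculation = 0.1,
                                        dual = 0.2),
                       coupling_strength = 0.5, structure_align = 0.5,
                       coupling_jitter = 0.1,
                       modular_structure = NULL, noise_sd = 1,
                       behaviour_link = 8, baseline = 200,
                       avatar_target = 90, lag = 5, seed = 1) {
  check_scalar_number(tr, "tr", positive = TRUE)
  check_scalar_number(trial_duration, "trial_duration", positive = TRUE)
  check_scalar_number(rest_duration, "rest_duration", positive = TRUE)
  check_scalar_number(n_blocks, "n_blocks", positive = TRUE)
  check_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  check_scalar_number(coupling_strength, "coupling_strength")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop_invalid("coupling_strength must lie in [0, 1]")
  atlas <- parcel_atlas(n_cortical, n_cerebellar)
  if (is.null(activation_amplitude))
    activation_amplitude <- default_activation_amplitude()
  if (is.null(modular_structure))
    modular_structure <- default_modular_structure(atlas)
  labs <- modular_structure$labels
  lab_list <- if (is.list(labs)) labs else list(labs)
  for (l in lab_list)
    if (length(l) != nrow(atlas) || anyNA(l))
      stop_invalid("module labels must cover every parcel exactly once")
  cfg <- list(
    n_subjects = n_subjects, n_cortical = n_cortical,
    n_cerebellar = n_cerebellar, tr = tr, n_blocks = n_blocks,
    trial_duration = trial_duration, rest_duration = rest_duration,
    activation_amplitude = activation_amplitude, cbm_baseline = cbm_baseline,
    coupling_strength = coupling_strength, structure_align = structure_align,
    coupling_jitter = coupling_jitter,
    modular_structure = modular_structure, noise_sd = noise_sd,
    behaviour_link = behaviour_link, baseline = baseline,
    avatar_target = avatar_target, lag = lag, seed = seed, atlas = atlas
  )
  class(cfg) <- "cc_sim_config"
  cfg
}

# Built-in activation maps: balance loads sensorimotor cortex and the motor
# cerebellum (anterior lobe + VIII), calculation loads frontoparietal /
# default cortex and Crus I/II, dual task is an attenuated superposition.
default_activation_amplitude <- function() {
  bal <- list(network = c(SomMot = 1, Vis = 0.3),
              lobule = c(I_IV = 1, V = 1, VI = 0.8, VIIIa = 0.5, VIIIb = 0.5))
  calc <- list(network = c(Cont = 1, Default = 0.6, DorsAttn = 0.5),
               lobule = c(CrusI = 1, CrusII = 1, VIIb = 0.5))
  comb <- function(a, b) {
    nm <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(nm)), nm)
    out[names(a)] <- a
    out[names(b)] <- out[names(b)] + b
    0.9 * out
  }
  list(balance = bal, calculation = calc,
       dual = list(network = comb(bal$network, calc$network),
                   lobule = comb(bal$lobule, calc$lobule)))
}

# Four planted noise modules spanning cortex and cerebellum.
default_modular_structure <- function(atlas) {
  net_mod <- c(Vis = 1, SomMot = 1, DorsAttn = 2, SalVentAttn = 2,
               Limbic = 3, Cont = 3, Default = 4)
  lob_mod <- c(I_IV = 1, V = 1, VI = 1, VIIIa = 1, VIIIb = 1,
               VIIb = 2, X = 2, CrusI = 3, IX = 3, CrusII = 4)
  labels <- ifelse(atlas$structure == "cortex",
                   net_mod[atlas$network], lob_mod[atlas$lobule])
  list(labels = unname(labels), rho_within = 0.35,
       rho_between = c(balance = 0.05, dual = 0.15, calculation = 0.25))
}

#' Balance-task disturbance signal
#'
#' Sum of 15 sinusoids with log-uniform random frequencies in 0.025-1 Hz,
#' uniform random phases and pink-weighted (1/sqrt(f)) amplitudes, rescaled
#' so the peak absolute excursion is exactly 30 degrees.
#'
#' @param seed Integer seed.
#' @param duration Trace length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param freq_range Frequency band (Hz).
#' @param max_amplitude Peak absolute amplitude after rescaling (degrees).
#' @return Numeric vector of the disturbance angle over time, with attribute
#'   `"frequencies"`.
#' @examples
#' d <- generate_disturbance(1, duration = 60, sample_rate = 100)
#' max(abs(d))  # 30
#' @export
generate_disturbance <- function(seed, duration, sample_rate,
                                 freq_range = c(0.025, 1),
                                 max_amplitude = 30) {
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  set.seed(seed)
  freqs <- exp(stats::runif(15, log(freq_range[1]), log(freq_range[2])))
  phases <- stats::runif(15, 0, 2 * pi)
  amps <- 1 / sqrt(freqs)
  t <- seq(0, duration, by = 1 / sample_rate)
  x <- rowSums(vapply(seq_len(15), function(k)
    amps[k] * sin(2 * pi * freqs[k] * t + phases[k]), numeric(length(t))))
  x <- x / max(abs(x)) * max_amplitude
  attr(x, "frequencies") <- freqs
  x
}

#' Generate a randomized block design
#'
#' `n_blocks` blocks, each containing one trial per condition in seeded
#' random order, each block followed by a rest period; onsets strictly
#' increasing and non-overlapping. Behavioural outcome columns are present
#' but `NA` (filled by [generate_cohort()]).
#'
#' @param config A [sim_config()].
#' @param seed Seed for the condition orderings (defaults to the config
#'   seed).
#' @return Event data.frame (`onset`, `duration`, `trial_type`, `block`,
#'   `rms_error`, `calc_correct`) with attributes `"total_duration"` and
#'   `"n_frames"`.
#' @export
generate_design <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cc_sim_config"))
  set.seed(seed)
  onset <- 0
  rows <- vector("list", config$n_blocks * 3)
  k <- 0
  for (b in seq_len(config$n_blocks)) {
    for (cond in sample(CC_CONDITIONS)) {
      k <- k + 1
      rows[[k]] <- data.frame(onset = onset,
                              duration = config$trial_duration,
                              trial_type = cond, block = b,
                              stringsAsFactors = FALSE)
      onset <- onset + config$trial_duration
    }
    onset <- onset + config$rest_duration
  }
  ev <- do.call(rbind, rows)
  ev$rms_error <- NA_real_
  ev$calc_correct <- NA
  attr(ev, "total_duration") <- onset
  attr(ev, "n_frames") <- ceiling(onset / config$tr)
  ev
}

# Leading structure-consistent activation pair: the Perron mode of the
# cortex -> cerebellum -> cortex weight composition, scaled (never centred:
# shifts break the exact flow closure) to unit SD across parcels. The
# connectome's hub heterogeneity keeps this mode's profile well away from
# flat, so the unit-SD scaling leaves amplitudes O(1).
perron_pair <- function(connectome) {
  cpc <- connectome$cpc
  ctc <- connectome$ctc
  v <- rep(1, nrow(cpc))
  for (i in 1:200) {
    b <- drop(crossprod(cpc, v))
    v2 <- drop(crossprod(ctc, b))
    v <- v2 / sqrt(sum(v2^2))
  }
  b <- drop(crossprod(cpc, v))
  list(ctx = v / stats::sd(v), cbm = b / stats::sd(b))
}

# Per-condition intrinsic (uncoupled) activation patterns over all parcels.
intrinsic_patterns <- function(config) {
  atlas <- config$atlas
  out <- sapply(CC_CONDITIONS, function(cond) {
    amp <- config$activation_amplitude[[cond]]
    u <- numeric(nrow(atlas))
    ctx <- atlas$structure == "cortex"
    u[ctx] <- ifelse(atlas$network[ctx] %in% names(amp$network),
                     amp$network[atlas$network[ctx]], 0)
    cbm <- !ctx
    u[cbm] <- ifelse(atlas$lobule[cbm] %in% names(amp$lobule),
                     amp$lobule[atlas$lobule[cbm]], 0) +
      config$cbm_baseline[[cond]]
    u
  })
  rownames(out) <- atlas$name
  out  # parcels x conditions
}

# Blend intrinsic pattern with the structure-consistent pair at coupling k.
coupled_pattern <- function(u, k, pair, atlas) {
  ctx <- atlas$structure == "cortex"
  out <- (1 - k) * u
  out[ctx] <- out[ctx] + k * pair$ctx
  out[!ctx] <- out[!ctx] + k * pair$cbm
  out
}

#' Generate a random cortico-cerebellar structural connectome
#'
#' Lognormal streamline counts with multiplicative source- and target-parcel
#' strength factors (tractography counts are strongly hub-dominated) and a
#' sparsity mask, log10(count + 1) weighted. The strength heterogeneity also
#' gives the leading mode of the weight composition a well-varying profile
#' across parcels.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [structural_connectome()].
#' @export
generate_connectome <- function(config, seed = derive_seed(config$seed, 1L)) {
  set.seed(seed)
  nc <- config$n_cortical
  nb <- config$n_cerebellar
  counts <- function(n, m) {
    src <- stats::rnorm(n, 0, 0.8)   # per-parcel log-strength factors
    tgt <- stats::rnorm(m, 0, 0.8)
    ml <- 2.5 + outer(src, tgt, `+`)
    x <- matrix(stats::rlnorm(n * m, meanlog = ml, sdlog = 0.8), n, m)
    x * (matrix(stats::runif(n * m), n, m) > 0.3)  # ~30% absent connections
  }
  structural_connectome(counts(nc, nb), counts(nb, nc),
                        config$atlas, from_counts = TRUE)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Forward model: per-trial activation patterns (intrinsic condition maps
#' blended with the structure-consistent coupling mode at the trial's
#' coupling strength) enter a trial-level design matrix convolved with the
#' canonical HRF; Gaussian noise with condition-dependent modular correlation
#' structure is added on top of a constant baseline. Trial correctness is
#' logistic in the trial's coupling; balance RMS error is lognormal,
#' decreasing with coupling. Motion traces are small random walks.
#'
#' @param config A [sim_config()].
#' @return A list of class `cc_cohort`: `subjects` (list with `bold`,
#'   `events`, `motion`, `betamap_true`), `connectome`, `atlas`, `config`,
#'   and `ground_truth` (`true_beta`, `true_modules`, `true_kappa`,
#'   `trial_outcomes`, `planted_pc_order`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cc_sim_config"))
  atlas <- config$atlas
  connectome <- generate_connectome(config)
  pair <- perron_pair(connectome)
  U <- intrinsic_patterns(config)
  # cerebellar intrinsic maps partially inherit the CPC projection of the
  # cortical map (mossy-fibre drive): plants condition-specific
  # structure-function alignment beyond the shared coupling mode. The hub
  # profile (total input strength, shared by every condition's projection)
  # is residualised out so the inherited component is condition-specific.
  if (config$structure_align > 0) {
    ctx <- atlas$structure == "cortex"
    hub <- colSums(connectome$cpc)
    for (cond in CC_CONDITIONS) {
      proj <- drop(crossprod(connectome$cpc, U[ctx, cond]))
      proj <- proj - hub * sum(proj * hub) / sum(hub * hub)
      if (stats::sd(proj) > 0)
        U[!ctx, cond] <- U[!ctx, cond] +
          config$structure_align * proj / stats::sd(proj)
    }
  }
  kap <- config$coupling_strength
  true_beta <- t(vapply(CC_CONDITIONS, function(cond)
    coupled_pattern(U[, cond], kap, pair, atlas), numeric(nrow(atlas))))
  colnames(true_beta) <- atlas$name

  subjects <- vector("list", config$n_subjects)
  outcomes_all <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sseed <- derive_seed(config$seed, 100L + s)
    ev <- generate_design(config, seed = sseed)
    n_frames <- attr(ev, "n_frames")
    set.seed(derive_seed(config$seed, 500L + s))
    n_trials <- nrow(ev)
    # coupling fluctuates trial-to-trial only in the dual task (where
    # performance is coupling-limited); single-task trials run at nominal
    # kappa, and the degenerate kappa = 0 / 1 configurations are exact
    jitter <- if (kap %in% c(0, 1)) rep(0, n_trials) else
      stats::rnorm(n_trials, 0, config$coupling_jitter) *
        (ev$trial_type == "dual")
    kappa_t <- clip01(kap + jitter)
    p_correct <- stats::plogis(stats::qlogis(0.65) +
                                 config$behaviour_link * (kappa_t - kap))
    correct <- stats::runif(n_trials) < p_correct
    rms <- stats::rlnorm(n_trials,
                         meanlog = log(20) -
                           (config$behaviour_link / 2) * (kappa_t - kap),
                         sdlog = 0.3)
    ev$calc_correct <- ifelse(ev$trial_type %in% c("calculation", "dual"),
                              correct, NA)
    ev$rms_error <- ifelse(ev$trial_type %in% c("balance", "dual"), rms,
                           NA_real_)
    # per-trial activation patterns
    Bt <- t(vapply(seq_len(n_trials), function(t)
      coupled_pattern(U[, ev$trial_type[t]], kappa_t[t], pair, atlas),
      numeric(nrow(atlas))))
    dm <- build_design_matrix(ev, config$tr, n_frames, granularity = "trial")
    Y <- config$baseline + dm$matrix[, -1, drop = FALSE] %*% Bt
    if (config$noise_sd > 0)
      Y <- Y + modular_noise(config, ev, n_frames)
    bold <- parcellated_bold(Y, config$tr, atlas)
    motion <- random_motion(n_frames)
    subjects[[s]] <- list(bold = bold, events = ev, motion = motion,
                          kappa_t = kappa_t, subject_id = s)
    oc <- ev[, c("block", "trial_type", "rms_error", "calc_correct")]
    oc$subject <- s
    oc$kappa_t <- kappa_t
    outcomes_all[[s]] <- oc
  }
  labs <- config$modular_structure$labels
  true_modules <- if (is.list(labs)) labs else
    stats::setNames(rep(list(labs), 3), CC_CONDITIONS)
  structure(list(
    subjects = subjects, connectome = connectome, atlas = atlas,
    config = config,
    ground_truth = list(
      true_beta = true_beta,
      true_modules = true_modules,
      true_kappa = kap,
      coupling_pair = pair,
      trial_outcomes = do.call(rbind, outcomes_all),
      planted_pc_order = c("balance", "dual", "calculation")
    )
  ), class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("<cc_cohort> %d subjects, %d parcels, kappa = %g\n",
              length(x$subjects), nrow(x$atlas),
              x$ground_truth$true_kappa))
  invisible(x)
}

# Gaussian noise with planted modular correlation: within-module correlation
# rho_within everywhere, between-module correlation depending on the
# condition active at each (lag-shifted) frame.
modular_noise <- function(config, events, n_frames) {
  ms <- config$modular_structure
  labs <- ms$labels
  if (is.list(labs)) labs <- labs[[1]]
  rw <- ms$rho_within
  P <- length(labs)
  times <- (seq_len(n_frames) - 1) * config$tr
  cond_at <- rep("rest", n_frames)
  for (r in seq_len(nrow(events))) {
    inside <- times >= events$onset[r] + config$lag &
      times < events$onset[r] + events$duration[r] + config$lag
    cond_at[inside] <- events$trial_type[r]
  }
  rb_map <- ms$rho_between
  rb <- ifelse(cond_at == "rest", mean(rb_map), rb_map[cond_at])
  mods <- sort(unique(labs))
  mod_col <- match(labs, mods)
  G <- matrix(stats::rnorm(n_frames * length(mods)), n_frames)  # module factors
  H <- stats::rnorm(n_frames)                                   # global factor
  E <- matrix(stats::rnorm(n_frames * P), n_frames)
  noise <- sqrt(1 - rw) * E +
    sqrt(pmax(rw - rb, 0)) * G[, mod_col, drop = FALSE] +
    sqrt(rb) * H
  config$noise_sd * noise
}

# Small random-walk head motion: mean FD ~0.13 mm with a sub-threshold tail,
# emulating a compliant cohort in which no subject trips the exclusion rule.
random_motion <- function(n_frames) {
  steps_t <- matrix(stats::rnorm(n_frames * 3, 0, 0.035), n_frames)
  steps_r <- matrix(stats::rnorm(n_frames * 3, 0, 3.5e-4), n_frames)
  motion_trace(apply(steps_t, 2, cumsum), apply(steps_r, 2, cumsum))
}

#' Write a generated cohort to disk in the package's text formats
#'
#' One directory per subject (`sub-XX`) with `bold.tsv`, `events.tsv`,
#' `motion.tsv`; connectome matrices `cpc.tsv` / `ctc.tsv`; ground truth as a
#' JSON sidecar `ground_truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects)) {
    sd <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sd, showWarnings = FALSE)
    sub <- cohort$subjects[[s]]
    write_timeseries(sub$bold, file.path(sd, "bold.tsv"))
    write_events(sub$events, file.path(sd, "events.tsv"))
    write_motion(sub$motion, file.path(sd, "motion.tsv"))
  }
  write_matrix(cohort$connectome$cpc, file.path(dir, "cpc.tsv"))
  write_matrix(cohort$connectome$ctc, file.path(dir, "ctc.tsv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    true_kappa = gt$true_kappa,
    planted_pc_order = gt$planted_pc_order,
    true_modules = gt$true_modules,
    true_beta = as.data.frame(t(gt$true_beta)),
    trial_outcomes = gt$trial_outcomes
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
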