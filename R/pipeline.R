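#' Default pipeline configuration
#'
#' Flat key-value configuration controlling the full analysis: simulation (or
#' input paths), stage toggles, MTD window, topology settings, permutation
#' counts and seeds. All randomness is routed through per-stage seeds derived
#' from the single master `seed`.
#'
#' @param ... Overrides of the defaults, e.g. `sim.n_subjects = 5`,
#'   `topo.n_runs = 50`.
#' @return A named list of class `cc_pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    input_dir = "",
    out_dir = "ccflow-out",
    seed = 1,
    sim.n_subjects = 20,
    sim.n_cortical = 400,
    sim.n_cerebellar = 28,
    sim.tr = 0.7,
    sim.n_blocks = 12,
    sim.coupling_strength = 0.5,
    sim.noise_sd = 1,
    stage.qc = TRUE,
    stage.glm = TRUE,
    stage.tvfc = TRUE,
    stage.topology = TRUE,
    stage.actflow = TRUE,
    mtd.window = 20,
    mtd.lag = 5,
    mtd.align = "forward",
    qc.censor = FALSE,
    topo.gamma = 1.0,
    topo.n_runs = 100,
    topo.gamma_sweep = FALSE,
    perm.n_edge = 1000,
    perm.n_flow = 1000,
    perm.alpha = 0.05,
    write_data = FALSE,
    log_level = "info"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "cc_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration file
#'
#' Plain-text `key = value` lines; `#` starts a comment. Unknown keys are
#' rejected. Values are parsed as logical, numeric or string.
#'
#' @param path File path.
#' @param config A `cc_pipeline_config`.
#' @return `read_pipeline_config` returns a `cc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  bad <- which(eq < 0 | eq == 1)
  if (length(bad))
    stop_format("malformed config line ", bad[1], ": '", lines[bad[1]], "'")
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substring(lines, eq + 1))
  parsed <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && nzchar(v)) return(num)
    v
  })
  names(parsed) <- keys
  do.call(default_pipeline_config, parsed)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste(k, "=", if (is.numeric(v)) fmt_num(v) else as.character(v))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full cortico-cerebellar analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (or load) ->
#' QC -> GLM + decoder -> MTD connectivity and edge contrasts -> modularity /
#' participation topology -> activity flow -> report. Identical configuration
#' and seed yield identical outputs.
#'
#' @param config A [default_pipeline_config()] (or path handled by the CLI).
#' @param cohort Optionally, a pre-built [generate_cohort()] to analyse
#'   (overrides the simulate stage).
#' @return A list of class `cc_report` with per-stage summaries, the planted
#'   ground-truth recovery flags (when ground truth is available), a file
#'   manifest, the package version and a config echo.
#' @export
run_pipeline <- function(config = default_pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "cc_pipeline_config"))
  t0 <- Sys.time()
  log_msg <- function(...) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf("[ccflow] %s", paste0(...)))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  report <- list(config = unclass(config),
                 version = as.character(utils::packageVersion("ccflow")))

  # ---- simulate / load ------------------------------------------------------
  if (is.null(cohort)) {
    if (isTRUE(config$simulate)) {
      log_msg("simulate: generating ", config$sim.n_subjects, "-subject cohort")
      sc <- sim_config(n_subjects = config$sim.n_subjects,
                       n_cortical = config$sim.n_cortical,
                       n_cerebellar = config$sim.n_cerebellar,
                       tr = config$sim.tr, n_blocks = config$sim.n_blocks,
                       coupling_strength = config$sim.coupling_strength,
                       noise_sd = config$sim.noise_sd,
                       seed = derive_seed(config$seed, 11L))
      cohort <- generate_cohort(sc)
      if (isTRUE(config$write_data)) {
        write_cohort(cohort, file.path(out_dir, "data"))
        manifest <- c(manifest, file.path(out_dir, "data"))
      }
    } else {
      if (!nzchar(config$input_dir) || !dir.exists(config$input_dir))
        stop_dependency("stage 'load': simulation disabled and input_dir ('",
                        config$input_dir, "') does not exist")
      cohort <- read_cohort(config$input_dir, tr = config$sim.tr,
                            n_cortical = config$sim.n_cortical,
                            n_cerebellar = config$sim.n_cerebellar)
    }
  }
  atlas <- cohort$atlas
  nsub <- length(cohort$subjects)
  gt <- cohort$ground_truth

  # ---- QC -------------------------------------------------------------------
  qc <- NULL
  if (isTRUE(config$stage.qc) || isTRUE(config$qc.censor)) {
    log_msg("qc: FD / DVARS flags")
    qc <- lapply(cohort$subjects, function(sub) {
      fd <- compute_fd(sub$motion)
      dv <- compute_dvars(sub$bold)
      qc_flags(fd, dv)
    })
    qc_tab <- data.frame(
      subject = seq_len(nsub),
      mean_fd = vapply(qc, function(q) mean(q$fd), 0),
      mean_dvars = vapply(qc, function(q) mean(q$dvars), 0),
      n_flagged = vapply(qc, function(q) q$n_flagged, 0L),
      exclude = vapply(qc, function(q) q$exclude_subject, TRUE)
    )
    f <- file.path(out_dir, "qc.tsv")
    utils::write.table(qc_tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, f)
    report$qc <- list(mean_fd = mean(qc_tab$mean_fd),
                      n_excluded = sum(qc_tab$exclude))
  }

  # ---- GLM + decoder --------------------------------------------------------
  betamaps <- betamaps_trial <- NULL
  if (isTRUE(config$stage.glm) || isTRUE(config$stage.tvfc) ||
      isTRUE(config$stage.actflow)) {
    log_msg("glm: condition- and trial-level fits")
    betamaps <- lapply(seq_len(nsub), function(s) {
      sub <- cohort$subjects[[s]]
      dm <- build_design_matrix(sub$events, sub$bold$tr, nrow(sub$bold$data))
      fit_glm(sub$bold, dm, subject_id = s)
    })
    betamaps_trial <- lapply(seq_len(nsub), function(s) {
      sub <- cohort$subjects[[s]]
      dm <- build_design_matrix(sub$events, sub$bold$tr, nrow(sub$bold$data),
                                granularity = "trial")
      fit_glm(sub$bold, dm, subject_id = s)
    })
  }
  if (isTRUE(config$stage.glm)) {
    bal <- t(vapply(betamaps, function(b) b$beta["balance", ],
                    numeric(nrow(atlas))))
    calc <- t(vapply(betamaps, function(b) b$beta["calculation", ],
                     numeric(nrow(atlas))))
    dual <- t(vapply(betamaps, function(b) b$beta["dual", ],
                     numeric(nrow(atlas))))
    decoder <- fit_decoder(bal, calc)
    proj <- project_dual(dual, decoder)
    delta <- colMeans(bal) - colMeans(calc)
    counts <- positive_beta_counts(betamaps, atlas)
    chi2 <- positive_beta_test(counts)
    ev_all <- do.call(rbind, lapply(cohort$subjects, `[[`, "events"))
    ks <- ks_compare_rms(ev_all$rms_error[ev_all$trial_type == "balance"],
                         ev_all$rms_error[ev_all$trial_type == "dual"])
    grp_beta <- rbind(balance = colMeans(bal), calculation = colMeans(calc),
                      dual = colMeans(dual))
    f <- file.path(out_dir, "group_beta.tsv")
    write_matrix(grp_beta, f)
    manifest <- c(manifest, f)
    report$glm <- list(
      decoder_projection = list(t = proj$t, df = proj$df, p = proj$p,
                                mean_loading = proj$mean),
      dual_delta_r = stats::cor(colMeans(dual), delta),
      positive_beta = list(proportions = unname(chi2$proportions),
                           chi2 = chi2$statistic, df = chi2$df, p = chi2$p),
      ks_rms = ks
    )
    report$decoder_loading <- decoder$loading
    if (!is.null(gt)) {
      planted <- gt$true_beta["calculation", ] - gt$true_beta["balance", ]
      report$recovery$beta_contrast_r <- stats::cor(decoder$loading, planted)
      report$recovery$beta_contrast_recovered <-
        report$recovery$beta_contrast_r > 0.9
    }
  }

  # ---- dual-trial accuracy labels (shared by tvfc and actflow) --------------
  dual_info <- NULL
  if (isTRUE(config$stage.tvfc) || isTRUE(config$stage.actflow)) {
    ev_all <- do.call(rbind, lapply(seq_len(nsub), function(s) {
      e <- cohort$subjects[[s]]$events
      e$subject <- s
      e$trial_row <- seq_len(nrow(e))
      e
    }))
    duals <- ev_all[ev_all$trial_type == "dual", ]
    duals$correct <- split_trials(duals)
    dual_info <- duals
  }

  # ---- TVFC -----------------------------------------------------------------
  if (isTRUE(config$stage.tvfc)) {
    log_msg("tvfc: MTD edge series and correct/incorrect contrast")
    edge_betas <- vector("list", nsub)
    for (s in seq_len(nsub)) {
      sub <- cohort$subjects[[s]]
      edges <- mtd(sub$bold, window = config$mtd.window,
                   align = config$mtd.align)
      dm_tr <- build_design_matrix(sub$events, sub$bold$tr,
                                   nrow(sub$bold$data), granularity = "trial")
      eb <- edge_glm(edges, dm_tr)
      dual_rows <- which(sub$events$trial_type == "dual")
      rn <- sprintf("dual_%02d",
                    seq_along(dual_rows))
      edge_betas[[s]] <- eb[rn, , drop = FALSE]
      if (s == 1) edge_index <- edges$edge_index
    }
    eb_all <- do.call(rbind, edge_betas)
    labels <- dual_info$correct[order(dual_info$subject, dual_info$trial_row)]
    # rows of eb_all are (subject, dual trial in order); align labels likewise
    di <- dual_info[order(dual_info$subject, dual_info$trial_row), ]
    contrast <- contrast_edges_permutation(eb_all, di$correct,
                                           n_perm = config$perm.n_edge,
                                           alpha = config$perm.alpha,
                                           seed = derive_seed(config$seed, 21L))
    grid <- summarize_network_lobule(contrast, edge_index, atlas)
    f <- file.path(out_dir, "network_lobule_grid.tsv")
    write_matrix(grid, f)
    manifest <- c(manifest, f)
    report$tvfc <- list(
      n_edges = length(contrast$effect),
      n_significant = sum(contrast$significant),
      mean_effect_significant =
        if (any(contrast$significant))
          mean(contrast$effect[contrast$significant]) else NA_real_
    )
  }

  # ---- topology -------------------------------------------------------------
  if (isTRUE(config$stage.topology)) {
    log_msg("topology: consensus modularity and participation")
    pc_mean <- matrix(NA_real_, nsub, 3,
                      dimnames = list(NULL, CC_CONDITIONS))
    pc_parcel <- array(NA_real_, c(nrow(atlas), nsub, 3),
                       dimnames = list(atlas$name, NULL, CC_CONDITIONS))
    q_mean <- matrix(NA_real_, nsub, 3, dimnames = list(NULL, CC_CONDITIONS))
    for (s in seq_len(nsub)) {
      sub <- cohort$subjects[[s]]
      mats <- mtd_condition_matrices(
        sub$bold, sub$events, window = config$mtd.window,
        lag = config$mtd.lag, align = config$mtd.align,
        censor = if (isTRUE(config$qc.censor)) qc[[s]]$flagged)
      for (cond in CC_CONDITIONS) {
        g <- signed_graph(mats[[cond]], gamma = config$topo.gamma)
        part <- louvain_consensus(g, n_runs = config$topo.n_runs,
                                  seed = derive_seed(config$seed,
                                                     31L + s * 3L +
                                                       match(cond, CC_CONDITIONS)))
        pc <- participation_coefficient(g, part$membership)
        pc_mean[s, cond] <- mean(pc)
        pc_parcel[, s, cond] <- pc
        q_mean[s, cond] <- part$q
      }
    }
    pc_cmp <- compare_pc_across_tasks(pc_mean, pc_parcel)
    if (isTRUE(config$topo.gamma_sweep)) {
      sub <- cohort$subjects[[1]]
      mats <- mtd_condition_matrices(sub$bold, sub$events,
                                     window = config$mtd.window,
                                     lag = config$mtd.lag)
      M <- Reduce(`+`, mats) / length(mats)
      gs <- gamma_stability(signed_graph(M),
                            seed = derive_seed(config$seed, 41L))
      report$topology_gamma <- list(best_gamma = attr(gs, "best_gamma"),
                                    mean_stability = mean(gs$stability))
    }
    f <- file.path(out_dir, "pc_mean.tsv")
    utils::write.table(cbind(subject = seq_len(nsub), pc_mean), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, f)
    report$topology <- list(
      group_mean_pc = colMeans(pc_mean),
      mean_q = colMeans(q_mean),
      anova = pc_cmp$anova, anova_rm = pc_cmp$anova_rm,
      dual_vs_single_r = pc_cmp$dual_vs_single_r
    )
    if (!is.null(gt)) {
      gm <- colMeans(pc_mean)
      report$recovery$pc_order_observed <-
        names(sort(gm))
      report$recovery$pc_order_recovered <-
        identical(names(sort(gm)), gt$planted_pc_order)
    }
  }

  # ---- activity flow --------------------------------------------------------
  if (isTRUE(config$stage.actflow)) {
    log_msg("actflow: structure-informed predictions")
    # condition-level flow with permutation nulls, group-mean betas
    grp <- Reduce(`+`, lapply(betamaps, function(b) b$beta)) / nsub
    grp_map <- structure(list(beta = grp, granularity = "condition"),
                         class = "cc_betamap")
    cond_flow <- flow_analysis(grp_map, cohort$connectome, atlas,
                               n_perm = config$perm.n_flow,
                               seed = derive_seed(config$seed, 51L))
    # per-dual-trial flow correlations (both directions)
    ci <- cortex_idx(atlas)
    cb <- cerebellum_idx(atlas)
    di <- dual_info[order(dual_info$subject, dual_info$trial_row), ]
    r_fwd <- r_bwd <- numeric(nrow(di))
    k <- 0
    for (s in seq_len(nsub)) {
      bt <- betamaps_trial[[s]]$beta
      rows <- grep("^dual_", rownames(bt))
      for (r in rows) {
        k <- k + 1
        r_fwd[k] <- evaluate_flow(
          predict_activity(bt[r, ci], cohort$connectome$cpc), bt[r, cb])
        r_bwd[k] <- evaluate_flow(
          predict_activity(bt[r, cb], cohort$connectome$ctc), bt[r, ci])
      }
    }
    acc_fwd <- compare_flow_by_accuracy(r_fwd, di$correct)
    acc_bwd <- compare_flow_by_accuracy(r_bwd, di$correct)
    trial_tab <- data.frame(subject = di$subject, trial = di$trial_row,
                            correct = di$correct, r_ctx_to_cbm = r_fwd,
                            r_cbm_to_ctx = r_bwd)
    f <- file.path(out_dir, "flow_trials.tsv")
    utils::write.table(trial_tab, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest <- c(manifest, f)
    report$actflow <- list(
      condition = cond_flow,
      accuracy_ctx = acc_fwd,
      accuracy_cbm = acc_bwd
    )
    if (!is.null(gt)) {
      report$recovery$flow_accuracy_t_cbm <- acc_fwd$t
      report$recovery$flow_accuracy_t_ctx <- acc_bwd$t
      report$recovery$kappa_effect_recovered <- acc_fwd$t > 0 && acc_bwd$t > 0
    }
  }

  report$manifest <- manifest
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_body(report), f, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  report$manifest <- c(manifest, f)
  class(report) <- "cc_report"
  report
}

# report without volatile fields (for byte-identical reruns)
report_body <- function(report) {
  report$elapsed_s <- NULL
  report$manifest <- NULL
  report
}

#' @export
print.cc_report <- function(x, ...) {
  cat("<cc_report>\n")
  if (!is.null(x$qc))
    cat(sprintf("  qc: mean FD %.3f mm, %d excluded\n", x$qc$mean_fd,
                x$qc$n_excluded))
  if (!is.null(x$glm))
    cat(sprintf("  glm: decoder projection t = %.2f (p = %.3g)\n",
                x$glm$decoder_projection$t, x$glm$decoder_projection$p))
  if (!is.null(x$topology))
    cat(sprintf("  topology: mean PC %s\n",
                paste(sprintf("%s %.3f", CC_CONDITIONS,
                              x$topology$group_mean_pc), collapse = ", ")))
  if (!is.null(x$actflow))
    cat(sprintf("  actflow: accuracy effect t (cbm) = %.2f, t (ctx) = %.2f\n",
                x$actflow$accuracy_ctx$t, x$actflow$accuracy_cbm$t))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery: beta %s, PC order %s, kappa effect %s\n",
                x$recovery$beta_contrast_recovered,
                x$recovery$pc_order_recovered,
                x$recovery$kappa_effect_recovered))
  invisible(x)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param tr Repetition time of the stored series.
#' @param n_cortical,n_cerebellar Atlas sizes.
#' @return A `cc_cohort` (without ground truth unless the JSON sidecar is
#'   present).
#' @export
read_cohort <- function(dir, tr = 0.7, n_cortical = 400, n_cerebellar = 28) {
  atlas <- parcel_atlas(n_cortical, n_cerebellar)
  sub_dirs <- sort(list.dirs(dir, recursive = FALSE))
  sub_dirs <- sub_dirs[grepl("sub-", basename(sub_dirs))]
  if (!length(sub_dirs)) stop_dependency("no subject directories under ", dir)
  subjects <- lapply(seq_along(sub_dirs), function(s) {
    sd <- sub_dirs[s]
    list(bold = read_timeseries(file.path(sd, "bold.tsv"), tr, atlas),
         events = read_events(file.path(sd, "events.tsv")),
         motion = read_motion(file.path(sd, "motion.tsv")),
         subject_id = s)
  })
  cpc <- read_matrix(file.path(dir, "cpc.tsv"))
  ctc <- read_matrix(file.path(dir, "ctc.tsv"))
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- list(true_kappa = raw$true_kappa,
               planted_pc_order = raw$planted_pc_order,
               true_modules = raw$true_modules,
               true_beta = t(as.matrix(raw$true_beta)),
               trial_outcomes = raw$trial_outcomes)
  }
  structure(list(subjects = subjects,
                 connectome = structural_connectome(cpc, ctc, atlas),
                 atlas = atlas, config = NULL, ground_truth = gt),
            class = "cc_cohort")
}
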