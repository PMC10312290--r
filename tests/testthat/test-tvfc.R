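test_that("MTD matches the direct formula evaluation on a toy series", {
  set.seed(11)
  atl <- parcel_atlas(2, 1)
  x <- matrix(rnorm(7 * 3, 100, 3), 7, 3)
  b <- parcellated_bold(x, 0.7, atl)
  e <- mtd(b, window = 2, edge_subset = "all")
  for (k in seq_len(nrow(e$edge_index))) {
    expect_equal(e$values[, k],
                 mtd_oracle(x, e$edge_index$i[k], e$edge_index$j[k], 2),
                 tolerance = 1e-12)
  }
  # valid length: frames - 1 - (window - 1)
  expect_equal(nrow(e$values), 7 - 2)
})

test_that("MTD is symmetric, scale invariant and counts 11,200 edges", {
  set.seed(12)
  atl <- parcel_atlas(6, 3)
  x <- matrix(rnorm(60 * 9), 60, 9)
  b <- parcellated_bold(x, 0.7, atl)
  e_all <- mtd(b, window = 5, edge_subset = "all")
  # symmetry: MTD(i, j) must equal MTD(j, i); recompute with swapped columns
  x_sw <- x
  x_sw[, c(1, 2)] <- x[, c(2, 1)]
  e_sw <- mtd(parcellated_bold(x_sw, 0.7, atl), window = 5,
              edge_subset = "all")
  k12 <- which(e_all$edge_index$i == 1 & e_all$edge_index$j == 2)
  expect_equal(e_sw$values[, k12], e_all$values[, k12], tolerance = 1e-12)

  # linear rescaling of inputs leaves MTD unchanged
  x_sc <- sweep(x, 2, c(3, rep(1, 8)), "*") + 40
  e_sc <- mtd(parcellated_bold(x_sc, 0.7, atl), window = 5,
              edge_subset = "all")
  expect_equal(e_sc$values, e_all$values, tolerance = 1e-10)

  # default cortico-cerebellar subset at full atlas scale
  atl_full <- parcel_atlas(400, 28)
  bf <- parcellated_bold(matrix(rnorm(30 * 428), 30, 428), 0.7, atl_full)
  ef <- mtd(bf, window = 5)
  expect_equal(ncol(ef$values), 11200)

  const <- x
  const[, 4] <- 7
  err <- tryCatch(mtd(parcellated_bold(const, 0.7, atl), window = 5),
                  error = identity)
  expect_s3_class(err, "ccflow_degenerate_input")
  expect_match(conditionMessage(err), atl$name[4], fixed = TRUE)
})

test_that("self- and negated-pair MTD approach +1 and -1 on white noise", {
  set.seed(13)
  atl <- parcel_atlas(2, 2)
  Tn <- 10000
  base <- rnorm(Tn)
  x <- cbind(base, rnorm(Tn), base, -base)
  b <- parcellated_bold(x + 100, 0.7, atl)
  e <- mtd(b, window = 20)
  m <- colMeans(e$values)
  self_edge <- which(e$edge_index$i == 1 & e$edge_index$j == 3)
  neg_edge <- which(e$edge_index$i == 1 & e$edge_index$j == 4)
  expect_lt(abs(m[self_edge] - 1), 0.05)
  expect_lt(abs(m[neg_edge] + 1), 0.05)
})

test_that("edge GLM recovers planted coupling regressors", {
  set.seed(14)
  atl <- parcel_atlas(4, 2)
  tr <- 1
  n <- 80
  ev <- data.frame(onset = c(5, 40), duration = 10,
                   trial_type = c("balance", "calculation"))
  dm <- build_design_matrix(ev, tr, n)
  # synthetic edge series equal to a regressor: beta 1 there, 0 elsewhere
  edges <- structure(list(
    values = cbind(dm$matrix[1:70, "balance"], rep(0, 70)),
    edge_index = data.frame(i = c(1, 1), j = c(5, 6)),
    window = 11, align = "forward", tr = tr, n_frames = n
  ), class = "cc_edges")
  eb <- edge_glm(edges, dm)
  expect_equal(unname(eb["balance", 1]), 1, tolerance = 1e-9)
  expect_equal(unname(eb["calculation", 1]), 0, tolerance = 1e-9)
  expect_equal(unname(eb[, 2]), c(0, 0), tolerance = 1e-12)

  bad <- edges
  bad$values <- bad$values[1:50, , drop = FALSE]
  bad$n_frames <- 90
  expect_error(edge_glm(bad, dm), class = "ccflow_invalid_argument")
})

test_that("trial splitting follows the strict median / accuracy rule", {
  oc <- data.frame(calc_correct = c(TRUE, TRUE, TRUE, FALSE),
                   rms_error = c(1, 2, 10, 1))
  lab <- split_trials(oc)  # median rms = 1.5
  expect_identical(lab, c(TRUE, FALSE, FALSE, FALSE))

  # value exactly at the median is incorrect
  oc2 <- data.frame(calc_correct = rep(TRUE, 3), rms_error = c(1, 2, 3))
  expect_identical(split_trials(oc2), c(TRUE, FALSE, FALSE))

  # all accurate and below an external median: all correct
  expect_true(all(split_trials(oc2, rms_median = 10)))
  expect_error(split_trials(data.frame(calc_correct = NA, rms_error = 1)),
               class = "ccflow_invalid_argument")
})

test_that("permutation contrast attains its extreme p values correctly", {
  set.seed(15)
  x <- matrix(rnorm(20 * 4), 20, 4)
  g <- rep(c(TRUE, FALSE), each = 10)
  # identical groups sample-for-sample: p = 1
  xx <- rbind(x[1:10, ], x[1:10, ])
  r <- contrast_edges_permutation(xx, g, n_perm = 200, seed = 1)
  expect_true(all(r$p_perm == 1))

  # one hugely separated edge reaches the minimum attainable p
  x2 <- x
  x2[g, 1] <- x2[g, 1] + 50
  r2 <- contrast_edges_permutation(x2, g, n_perm = 200, seed = 2)
  expect_equal(r2$p_perm[1], 1 / 201)
  expect_gt(r2$effect[1], 40)

  expect_error(contrast_edges_permutation(x, rep(TRUE, 20)),
               class = "ccflow_invalid_argument")
})

test_that("network x lobule grid places effects in the right cells", {
  atl <- parcel_atlas(28, 28)  # 2 parcels per network per hemisphere
  ei <- expand.grid(i = which(atl$structure == "cortex"),
                    j = which(atl$structure == "cerebellum"))
  eff <- rep(2.5, nrow(ei))
  ctr <- structure(list(effect = eff, significant = rep(TRUE, nrow(ei))),
                   class = "cc_edge_contrast")
  grid <- summarize_network_lobule(ctr, ei, atl)
  expect_equal(dim(grid), c(10, 7))
  expect_true(all(grid == 2.5))  # uniform effect fills every cell

  # a single significant edge yields exactly one non-missing cell
  ctr2 <- ctr
  ctr2$significant <- rep(FALSE, nrow(ei))
  k <- which(atl$network[ei$i] == "Cont" & atl$lobule[ei$j] == "CrusI" &
               atl$hemisphere[ei$j] == "L")[1]
  ctr2$significant[k] <- TRUE
  g2 <- summarize_network_lobule(ctr2, ei, atl)
  expect_equal(sum(!is.na(g2)), 1)
  expect_equal(g2["CrusI", "Cont"], 2.5)

  # vermis edges are excluded
  ctr3 <- ctr
  ctr3$significant <- atl$hemisphere[ei$j] == "vermis"
  g3 <- summarize_network_lobule(ctr3, ei, atl)
  expect_true(all(is.na(g3)))
})

test_that("edge-mean maps are stable across window sizes on synthetic data", {
  cfg <- tiny_config(seed = 21)
  coh <- generate_cohort(cfg)
  s <- coh$subjects[[1]]
  means <- sapply(c(10, 20, 50), function(w)
    colMeans(mtd(s$bold, window = w)$values))
  expect_gt(cor(means[, 1], means[, 2], method = "spearman"), 0.8)
  expect_gt(cor(means[, 2], means[, 3], method = "spearman"), 0.8)
})

test_that("frame censoring removes flagged windows from condition averages", {
  cfg <- tiny_config(seed = 22)
  coh <- generate_cohort(cfg)
  s <- coh$subjects[[1]]
  Tn <- nrow(s$bold$data)
  none <- rep(FALSE, Tn)
  m0 <- mtd_condition_matrices(s$bold, s$events, censor = none)
  m_plain <- mtd_condition_matrices(s$bold, s$events)
  expect_equal(m0, m_plain)

  # censoring a mid-trial stretch changes the averages
  cen <- none
  first_bal <- s$events[s$events$trial_type == "balance", ][1, ]
  idx <- which((seq_len(Tn) - 1) * cfg$tr >= first_bal$onset + cfg$lag &
                 (seq_len(Tn) - 1) * cfg$tr < first_bal$onset + 10 + cfg$lag)
  cen[idx] <- TRUE
  m1 <- mtd_condition_matrices(s$bold, s$events, censor = cen)
  expect_false(isTRUE(all.equal(m1$balance, m0$balance)))
  # other conditions only lose windows that overlap the censored frames
  expect_equal(dim(m1$calculation), dim(m0$calculation))
  expect_error(mtd_condition_matrices(s$bold, s$events, censor = cen[-1]),
               class = "ccflow_invalid_argument")
})

test_that("windowed coupling matrix equals the average of outer products", {
  set.seed(23)
  atl <- parcel_atlas(4, 2)
  x <- matrix(rnorm(40 * 6), 40, 6)
  b <- parcellated_bold(x + 100, 0.7, atl)
  M <- mtd_window_matrix(b, t = 5, window = 4)
  # direct evaluation
  dt <- apply(x, 2, diff)
  dz <- sweep(dt, 2, apply(dt, 2, sd), "/")
  Mo <- matrix(0, 6, 6)
  for (k in 5:8) Mo <- Mo + outer(dz[k, ], dz[k, ]) / 4
  diag(Mo) <- 0
  expect_equal(unname(M), Mo, tolerance = 1e-12)
  # windowed participation from it is well defined
  pc <- participation_coefficient(signed_graph(M), rep(1:2, 3))
  expect_true(all(pc >= 0 & pc <= 1))
  expect_error(mtd_window_matrix(b, t = 40, window = 4),
               class = "ccflow_invalid_argument")
})
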