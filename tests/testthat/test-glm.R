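test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)                      # vanishes at onset
  expect_equal(max(h), 1)                    # unit peak
  expect_lt(abs(t[which.max(h)] - 5), 0.1 + 1e-9)  # peak near 5 s
  # exactly one sign change: positive lobe then undershoot
  signs <- sign(h[h != 0])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_error(canonical_hrf(0), class = "ccflow_invalid_argument")
})

test_that("design matrix construction follows convolution linearity", {
  tr <- 0.5
  n <- 100
  empty <- build_design_matrix(data.frame(onset = numeric(0),
                                          duration = numeric(0),
                                          trial_type = character(0)),
                               tr, n)
  expect_equal(colnames(empty$matrix), "(Intercept)")
  expect_equal(empty$matrix[, 1], rep(1, n))

  # one 1-frame event: regressor equals the shifted kernel
  ev1 <- data.frame(onset = 10 * tr, duration = tr, trial_type = "balance")
  dm1 <- build_design_matrix(ev1, tr, n)
  h <- canonical_hrf(tr)
  reg <- dm1$matrix[, "balance"]
  k <- min(length(h), n - 10)
  expect_lt(max(abs(reg[11:(10 + k)] - h[seq_len(k)])), 1e-9)

  # two non-overlapping events of one condition: sum of shifted kernels
  ev2 <- data.frame(onset = c(5, 60) * tr, duration = tr,
                    trial_type = "balance")
  dm2 <- build_design_matrix(ev2, tr, n)
  single <- function(on) build_design_matrix(
    data.frame(onset = on, duration = tr, trial_type = "balance"),
    tr, n)$matrix[, "balance"]
  expect_equal(dm2$matrix[, "balance"], single(5 * tr) + single(60 * tr),
               tolerance = 1e-9)

  expect_error(build_design_matrix(
    data.frame(onset = 49, duration = 5, trial_type = "dual"), tr, n),
    "past scan end", class = "ccflow_invalid_argument")
})

test_that("OLS fit inverts a noiseless forward model and handles rank issues", {
  atl <- parcel_atlas(4, 2)
  tr <- 0.7
  n <- 120
  ev <- data.frame(onset = c(5, 30, 55), duration = 10,
                   trial_type = c("balance", "calculation", "dual"))
  dm <- build_design_matrix(ev, tr, n)
  B <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(c("balance", "calculation", "dual"), atl$name))
  Y <- 50 + dm$matrix[, -1] %*% B
  bm <- fit_glm(parcellated_bold(Y, tr, atl), dm)
  expect_equal(bm$beta, B, tolerance = 1e-10)

  # shift invariance: a constant added to the signal lands in the intercept
  bm2 <- fit_glm(parcellated_bold(Y + 17, tr, atl), dm)
  expect_equal(bm2$beta, bm$beta, tolerance = 1e-9)

  # noise orthogonal to all regressors gives zero betas
  set.seed(2)
  E <- matrix(rnorm(n * 6), n, 6)
  E <- E - dm$matrix %*% qr.coef(qr(dm$matrix), E)  # residualise
  bm3 <- fit_glm(parcellated_bold(E + 100, tr, atl), dm)
  expect_lt(max(abs(bm3$beta)), 1e-9)

  # 2-frame toy system (intercept + slope) against the closed-form solution:
  # x = (1, 2), y = (3, 5) has exact fit y = 1 + 2 x
  x <- c(1, 2)
  y <- c(3, 5)
  atl1 <- parcel_atlas(2, 2)
  dm_toy <- structure(list(matrix = cbind(`(Intercept)` = c(1, 1),
                                          balance = x),
                           granularity = "condition"),
                      class = "cc_design_matrix")
  bm4 <- fit_glm(parcellated_bold(matrix(y, 2, 4), 1, atl1), dm_toy)
  expect_equal(unname(bm4$beta["balance", 1]), 2, tolerance = 1e-12)
  expect_equal(unname(bm4$intercept[1]), 1, tolerance = 1e-12)

  dup <- dm
  dup$matrix <- cbind(dm$matrix, dm$matrix[, 2])
  expect_error(fit_glm(parcellated_bold(Y, tr, atl), dup),
               class = "ccflow_singular_design")
})

test_that("decoder is the leading PC with the documented sign convention", {
  # two observations: loading parallel to their difference
  b <- rbind(c(1, 0, 0, 2), c(0, 1, 1, 0))
  ca <- rbind(c(3, 0, 0, 2), c(2, 1, 1, 0))
  dec <- fit_decoder(b, ca)
  expect_equal(sqrt(sum(dec$loading^2)), 1, tolerance = 1e-12)

  set.seed(7)
  n_sub <- 10
  contrast <- c(rep(1, 5), rep(-1, 5))
  bal <- matrix(rnorm(n_sub * 10, 0, 0.3), n_sub, 10)
  calc <- sweep(matrix(rnorm(n_sub * 10, 0, 0.3), n_sub, 10), 2, contrast, "+")
  dec2 <- fit_decoder(bal, calc)
  expect_gt(cor(dec2$loading, contrast), 0.9)

  # subject order invariance (up to sign convention, which fixes it exactly)
  perm <- sample(n_sub)
  dec3 <- fit_decoder(bal[perm, ], calc[perm, ])
  expect_equal(dec3$loading, dec2$loading, tolerance = 1e-9)

  expect_error(fit_decoder(bal[1, , drop = FALSE], calc[1, , drop = FALSE]),
               class = "ccflow_invalid_argument")
  expect_error(fit_decoder(matrix(1, 3, 4), matrix(1, 3, 4)),
               class = "ccflow_degenerate_input")
})

test_that("dual projection behaves under orthogonality and degeneracy", {
  set.seed(3)
  bal <- matrix(rnorm(40), 4, 10)
  calc <- sweep(matrix(rnorm(40), 4, 10), 2, rep(c(1, -1), 5), "+")
  dec <- fit_decoder(bal, calc)

  # dual betas at the calculation group mean project positively
  dual_calc <- matrix(rep(colMeans(calc), 3), 3, byrow = TRUE) +
    matrix(rnorm(30, 0, 1e-6), 3)
  pr <- project_dual(dual_calc, dec)
  expect_true(all(pr$loadings > 0))

  # dual betas orthogonal to the loading project to ~0 (third row anchors
  # the variance so the t test stays defined)
  orth <- matrix(rnorm(30), 3, 10)
  orth <- orth - outer(drop(orth %*% dec$loading), dec$loading)
  mix <- rbind(orth[1:2, ], colMeans(calc) - dec$center)
  pr2 <- project_dual(sweep(mix, 2, dec$center, "+"), dec)
  expect_lt(max(abs(pr2$loadings[1:2])), 1e-9)

  # identical loadings: zero variance, t undefined
  same <- matrix(rep(colMeans(calc), 4), 4, byrow = TRUE)
  expect_error(project_dual(same, dec), class = "ccflow_degenerate_input")
})

test_that("positive-beta chi-square matches the Pearson formula", {
  tab0 <- rbind(balance = c(30, 70), calculation = c(30, 70),
                dual = c(30, 70))
  r0 <- positive_beta_test(tab0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  expect_equal(r0$df, 2)

  # hand evaluation: [[10, 0], [0, 10]] has X^2 = 20
  r1 <- positive_beta_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(r1$statistic, 20, tolerance = 1e-12)

  # counts agree with a direct tally on a tiny cohort
  cfg <- tiny_config(noise_sd = 0.5, seed = 9)
  coh <- generate_cohort(cfg)
  bms <- lapply(coh$subjects, function(s) {
    dm <- build_design_matrix(s$events, cfg$tr, nrow(s$bold$data))
    fit_glm(s$bold, dm)
  })
  counts <- positive_beta_counts(bms, coh$atlas)
  cb <- which(coh$atlas$structure == "cerebellum")
  manual <- sum(sapply(bms, function(b) sum(b$beta["dual", cb] > 0)))
  expect_equal(unname(counts["dual", "positive"]), manual)
  expect_equal(rowSums(counts),
               c(balance = 12, calculation = 12, dual = 12))  # 2 subj x 6 parcels
})

test_that("KS statistic equals the exhaustive ECDF-difference scan", {
  expect_equal(ks_compare_rms(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_compare_rms(c(1, 2), c(10, 11))$D, 1)
  x <- c(1, 2, 3)
  y <- c(1.5, 2.5, 3.5)
  expect_equal(ks_compare_rms(x, y)$D, ks_oracle(x, y), tolerance = 1e-12)
  set.seed(5)
  for (k in 1:5) {
    a <- rlnorm(7 + k)
    b <- rlnorm(9)
    expect_equal(ks_compare_rms(a, b)$D, ks_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ks_compare_rms(numeric(0), 1),
               class = "ccflow_invalid_argument")
})
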