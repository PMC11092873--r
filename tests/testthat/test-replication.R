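test_that("restrict_columns intersects by column identity", {
  arm <- toy_arm(matrix(rbinom(40, 2, .4), 4), matrix(rbinom(40, 2, .4), 4))
  all_cols <- colnames(arm$D$values)
  expect_setequal(restrict_columns(all_cols[1:6], arm), all_cols[1:6])
  # superset of the arm's columns collapses to the arm's columns
  got <- restrict_columns(c(all_cols, "rs999:het"), arm)
  expect_setequal(got, all_cols)
  expect_error(restrict_columns(c("zz:het"), arm), "shared")
})

test_that("bicluster axis matches a dense SVD oracle and fixes the sign", {
  set.seed(5)
  arm <- toy_arm(matrix(rbinom(10 * 8, 2, .45), 10),
                 matrix(rbinom(6 * 8, 2, .45), 6))
  J <- arm$D$subject_ids[1:5]
  K <- colnames(arm$D$values)[1:7]
  ax <- bicluster_axis(arm, J, K)
  sub <- arm$D$values[1:5, K]
  Ac <- sweep(sub, 2, colMeans(sub))
  v_svd <- svd(Ac)$v[, 1]
  # equal up to sign
  expect_lt(min(sum((ax$v - v_svd)^2), sum((ax$v + v_svd)^2)), 1e-20)
  expect_equal(sum(ax$v^2), 1, tolerance = 1e-12)
  expect_gte(ax$train_auc, 0.5)
  # reproducible and unique after orientation
  ax_again <- bicluster_axis(arm, J, K)
  expect_identical(ax$v, ax_again$v)
  expect_error(bicluster_axis(arm, J, character(0)), "length")
})

test_that("a rank-1 block yields an axis supported on the block columns", {
  # cases: 3 carriers of the hom_minor pattern at SNPs 1-2, 3 non-carriers
  geno <- rbind(matrix(c(2L, 2L, 0L, 0L), 3, 4, byrow = TRUE),
                matrix(0L, 3, 4))
  arm <- toy_arm(geno, matrix(0L, 4, 4))
  K <- colnames(arm$D$values)
  ax <- bicluster_axis(arm, arm$D$subject_ids, K)
  on_block <- arm$D$column_map$snp_id %in% c("rs001", "rs002")
  expect_gt(sum(ax$v[on_block]^2), 0.999)
})

test_that("bicluster scores centre correctly and respect missing cells", {
  set.seed(6)
  arm <- toy_arm(matrix(rbinom(8 * 6, 2, .45), 8),
                 matrix(rbinom(5 * 6, 2, .45), 5))
  J <- arm$D$subject_ids[1:4]
  K <- colnames(arm$D$values)[1:9]
  ax <- bicluster_axis(arm, J, K)
  # a row equal to the centring means scores 0
  fake <- matrix(ax$centers, 1, dimnames = list("x", K))
  expect_equal(unname(bicluster_scores(fake, ax))[1], 0, tolerance = 1e-12)
  # missing cells contribute 0 (treated as the centring mean)
  r <- arm$D$values[1, K, drop = FALSE]
  r_na <- r; r_na[1, 3] <- NA
  diff_expected <- (r[1, 3] - ax$centers[3]) * ax$v[3]
  expect_equal(unname(bicluster_scores(r, ax) - bicluster_scores(r_na, ax))[1],
               unname(diff_expected), tolerance = 1e-12)
})

test_that("covariate-adjusted AUC: enumeration, saturation, residualisation", {
  expect_equal(as.numeric(covariate_adjusted_auc(c(0.9, 0.4), c(0.5, 0.1))),
               3 / 4)
  expect_equal(as.numeric(covariate_adjusted_auc(c(5, 6), c(1, 2))), 1)
  # ties counted one half: pairs (1,1) tie; (1,0), (2,1), (2,0) wins
  expect_equal(as.numeric(covariate_adjusted_auc(c(1, 2), c(1, 0))), 0.875)
  # scores explained by an included covariate -> AUC ~ 0.5
  set.seed(7)
  cv <- c(rnorm(50, 2), rnorm(50, 0))
  sc <- cv * 2 + 1 + rnorm(100, 0, 0.05)
  auc <- covariate_adjusted_auc(sc[1:50], sc[51:100], covariates = cbind(cv))
  expect_lt(abs(auc - 0.5), 0.15)
  # constant residuals flagged
  auc0 <- covariate_adjusted_auc(rep(1, 5), rep(1, 4))
  expect_equal(as.numeric(auc0), 0.5)
  expect_true(attr(auc0, "degenerate"))
  # unadjusted AUC invariant to monotone transforms
  a <- rexp(30); b <- rexp(20) * 1.5
  expect_equal(as.numeric(covariate_adjusted_auc(a, b)),
               as.numeric(covariate_adjusted_auc(log(a), log(b))))
})

test_that("replication on an identical arm reproduces the training AUC", {
  cfg <- synth_config(n_cases = 60, n_controls = 90, n_snps = 120, seed = 31,
                      planted = list(case_fraction = 0.3, snp_fraction = 0.2,
                                     shift = 0.35))
  arm <- simulate_arm(cfg)
  tr <- halfloop_run(arm)
  usable <- tr$iterations$iteration[tr$iterations$M >= 5]
  interval <- range(usable[seq(10, length(usable) - 5)])
  rc <- replication_curve(tr, arm, arm, interval, n_trials = 20,
                          max_points = 10, seed = 2)
  expect_equal(rc$curve$A, rc$curve$A_rep, tolerance = 1e-12)
  expect_true(all(rc$curve$A >= 0.5))
})

test_that("planted two-arm replication beats its shuffled null", {
  cfg <- synth_config(n_cases = 150, n_controls = 250, n_snps = 200,
                      seed = 13,
                      planted = list(case_fraction = 0.3, snp_fraction = 0.2,
                                     shift = 0.4),
                      arms = list(list(snp_overlap = 0.8)))
  arms <- simulate_multi_arm(cfg)
  ens <- null_ensemble(arms[[1]], n_trials = 8, seed = 13,
                       keep_members = FALSE)
  interval <- halfmax_interval(ens)
  rc <- replication_curve(ens$observed, arms[[1]], arms[[2]], interval,
                          n_trials = 60, max_points = 25, seed = 3)
  expect_gt(rc$Abar, 0.5)
  expect_lte(rc$p_Abar, 0.1)
  sh <- shuffle_labels_within_bins(arms[[2]], n_bins = 1, seed = 99)
  rc0 <- replication_curve(ens$observed, arms[[1]], sh, interval,
                           n_trials = 60, max_points = 25, seed = 3)
  expect_lt(abs(rc0$Abar - 0.5), 0.06)
})

test_that("SNP dropout degrades the interval-averaged replication AUC", {
  cfg <- synth_config(n_cases = 150, n_controls = 250, n_snps = 200,
                      seed = 17,
                      planted = list(case_fraction = 0.3, snp_fraction = 0.2,
                                     shift = 0.4),
                      arms = list(list(snp_overlap = 1)))
  arms <- simulate_multi_arm(cfg)
  ens <- null_ensemble(arms[[1]], n_trials = 8, seed = 17,
                       keep_members = FALSE)
  interval <- halfmax_interval(ens)
  base <- replication_curve(ens$observed, arms[[1]], arms[[2]], interval,
                            n_trials = 8, max_points = 15, seed = 1)
  od <- overlap_degradation(ens$observed, arms[[1]], arms[[2]],
                            c(1, 0.6, 0.25), interval, seed = 4,
                            n_trials = 8, max_points = 15)
  expect_equal(od$Abar[1], base$Abar, tolerance = 1e-12)
  # strong dropout loses most of the replication signal
  expect_lt(od$Abar[3] - 0.5, 0.8 * (od$Abar[1] - 0.5) + 0.02)
  expect_error(overlap_degradation(ens$observed, arms[[1]], arms[[2]],
                                   0, interval, seed = 1),
               "keep_fractions")
})
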