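test_that("compute_q reproduces the hand-worked sharing fractions", {
  D <- rbind(c(1, 0), c(1, 1), c(0, 1))
  X <- rbind(c(0, 0), c(1, 0))
  qs <- compute_q(D, X)
  expect_equal(unname(qs$q), rbind(c(0, -1), c(0, 0.5), c(-0.5, 0.5)))
  expect_equal(unname(qs$row_scores), c(-1, 0.5, 0))
  expect_equal(unname(qs$col_scores), c(-0.5, 0))
  expect_equal(qs$trace, -0.5)
})

test_that("compute_q degenerate columns score zero", {
  # every case and control shares the value -> Q = 0
  D <- cbind(rep(1, 4), c(1, 1, 0, 0))
  X <- cbind(rep(1, 3), c(0, 0, 0))
  qs <- compute_q(D, X)
  expect_equal(unname(qs$q[, 1]), rep(0, 4))
  # perfect separation -> Q = 1 for every case
  D <- cbind(rep(1, 4))
  X <- cbind(rep(0, 3))
  expect_equal(unname(compute_q(D, X)$q[, 1]), rep(1, 4))
  # a column missing in all controls scores 0 with a warning
  D <- cbind(c(1, 0, 1))
  X <- cbind(c(NA, NA))
  expect_warning(qs <- compute_q(D, X), "controls")
  expect_equal(unname(qs$q[, 1]), rep(0, 3))
})

test_that("compute_q matches the brute-force oracle on random instances", {
  set.seed(20)
  for (rep in 1:20) {
    M <- sample(5:30, 1); N <- sample(5:40, 1); MX <- sample(4:25, 1)
    D <- matrix(rbinom(M * N, 1, 0.4), M)
    X <- matrix(rbinom(MX * N, 1, 0.4), MX)
    D[runif(M * N) < 0.05] <- NA
    X[runif(MX * N) < 0.05] <- NA
    qs <- suppressWarnings(compute_q(D, X))
    expect_lt(max(abs(qs$q - oracle_q(D, X))), 1e-12)
    # conservation
    expect_equal(sum(qs$row_scores), qs$trace, tolerance = 1e-12)
    expect_equal(sum(qs$col_scores), qs$trace, tolerance = 1e-12)
    expect_true(all(qs$q >= -1 - 1e-12 & qs$q <= 1 + 1e-12))
  }
})

test_that("kernel weights: normalisation, degenerate and clustered cases", {
  arm <- toy_arm(matrix(rbinom(60, 2, .4), 6), matrix(rbinom(80, 2, .4), 8))
  w <- covariate_weights(arm, c("U1", "U2"), bandwidth = 1)
  expect_equal(unname(rowSums(w$WDD)), rep(1, 6))
  expect_equal(unname(rowSums(w$WDX)), rep(1, 6))
  expect_true(all(diag(w$WDD) == 0))
  # identical covariate values -> uniform weights
  covs <- tibble::tibble(U1 = rep(1, 14), U2 = rep(2, 14))
  arm2 <- toy_arm(matrix(rbinom(60, 2, .4), 6), matrix(rbinom(80, 2, .4), 8),
                  covs = covs)
  w2 <- covariate_weights(arm2, c("U1", "U2"))
  expect_equal(unname(w2$WDX), matrix(1 / 8, 6, 8))
  # two well-separated clusters: within-cluster mass > 0.99 at small bandwidth
  covs <- tibble::tibble(U1 = c(rep(0, 7), rep(50, 7)), U2 = 0)
  arm3 <- toy_arm(matrix(rbinom(120, 2, .4), 6),
                  matrix(rbinom(160, 2, .4), 8), covs = covs)
  w3 <- covariate_weights(arm3, "U1", bandwidth = 0.2)
  # cases 1-6 in cluster 1 except case 7.. (cases are subjects 1-6: all cluster 1)
  ctrl_cluster <- c(rep(1, 1), rep(2, 7))  # subjects 7..14 -> ctrl 1 is cluster 1
  mass_within <- rowSums(w3$WDX[, ctrl_cluster == 1, drop = FALSE])
  expect_true(all(mass_within > 0.99))
  # empty correction set falls back to uniform
  wu <- covariate_weights(arm, character(0))
  expect_equal(unname(wu$WDX), matrix(1 / 8, 6, 8))
})

test_that("compute_q with uniform weight matrices equals the unweighted path", {
  set.seed(9)
  M <- 12; N <- 15; MX <- 9
  D <- matrix(rbinom(M * N, 1, .4), M)
  X <- matrix(rbinom(MX * N, 1, .4), MX)
  WDD <- matrix(1 / (M - 1), M, M); diag(WDD) <- 0
  WDX <- matrix(1 / MX, M, MX)
  q_u <- compute_q(D, X)
  q_w <- compute_q(D, X, list(WDD = WDD, WDX = WDX))
  expect_lt(max(abs(q_u$q - q_w$q)), 1e-12)
})

test_that("nested-logistic covariate selection behaves at the extremes", {
  set.seed(4)
  n <- 400
  y <- rep(0:1, each = n / 2)
  covs <- tibble::tibble(
    U1 = y + rnorm(n, 0, 0.1),       # near-perfect predictor
    U2 = rnorm(n),                    # independent
    U3 = rep(1, n)                    # zero variance
  )
  expect_warning(sel <- select_correction_covariates(covs, y), "zero variance")
  expect_true("U1" %in% sel)
  expect_false("U3" %in% sel)
})

test_that("independent covariates are selected at about the nominal rate", {
  set.seed(11)
  hits <- 0
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    n <- 300
    y <- rep(0:1, each = n / 2)
    covs <- tibble::tibble(U1 = rnorm(n))
    hits <- hits + ("U1" %in% select_correction_covariates(covs, y))
  }
  # binomial(120, 0.05): generous band
  expect_gt(hits / n_rep, 0.005)
  expect_lt(hits / n_rep, 0.14)
})

test_that("halfloop_run is deterministic, conserves scores and respects gamma", {
  set.seed(30)
  arm <- toy_arm(matrix(rbinom(100 * 30, 2, .4), 100),
                 matrix(rbinom(60 * 30, 2, .4), 60))
  tr1 <- halfloop_run(arm, gamma = 0.5^8)
  tr2 <- halfloop_run(arm, gamma = 0.5^8)
  expect_identical(tr1$iterations, tr2$iterations)
  expect_identical(tr1$row_elim, tr2$row_elim)
  # gamma = 0.5^8 with M = 100 removes exactly 1 row and 1 column per
  # iteration (max(1, round(gamma * remaining)))
  expect_equal(tr1$iterations$M[1:3], c(100, 99, 98))
  expect_equal(tr1$iterations$N[1:3], c(90, 89, 88))
  # conservation at every iteration
  live <- tr1$iterations$M >= 2
  rel <- abs(tr1$iterations$trace - tr1$iterations$trace_col) /
    pmax(1, abs(tr1$iterations$trace))
  expect_lt(max(rel[live]), 1e-9)
  # monotone shrinkage and nested membership
  expect_true(all(diff(tr1$iterations$M) < 0))
  expect_true(all(diff(tr1$iterations$N) < 0))
  m10 <- trace_members(tr1, 10)
  m40 <- trace_members(tr1, 40)
  expect_true(all(m40$J %in% m10$J))
  expect_true(all(m40$K %in% m10$K))
  # terminal record is exhausted
  last <- nrow(tr1$iterations)
  expect_true(tr1$iterations$M[last] == 0 || tr1$iterations$N[last] == 0)
  expect_error(halfloop_run(arm, gamma = 0), "gamma")
  expect_error(halfloop_run(arm, gamma = 0.7), "gamma")
})

test_that("the C++ elimination core agrees with compute_q at iteration 1", {
  cfg <- synth_config(n_cases = 60, n_controls = 80, n_snps = 50, seed = 8,
                      planted = list(case_fraction = 0.3, snp_fraction = 0.2,
                                     shift = 0.3))
  arm <- simulate_arm(cfg)
  tr <- halfloop_run(arm)
  qs <- compute_q(arm$D, arm$X)
  expect_equal(tr$iterations$trace[1], qs$trace, tolerance = 1e-10)
  # and with kernel weights
  trw <- halfloop_run(arm, correction = c("U1", "U2"), bandwidth = 1)
  w <- covariate_weights(arm, c("U1", "U2"), bandwidth = 1)
  qsw <- compute_q(arm$D, arm$X, w)
  expect_equal(trw$iterations$trace[1], qsw$trace, tolerance = 1e-8)
})

test_that("halfloop recovers a strongly planted block", {
  cfg <- synth_config(n_cases = 60, n_controls = 90, n_snps = 30, seed = 21,
                      planted = list(case_fraction = 1 / 3, snp_fraction = 0.5,
                                     shift = 0.4))
  arm <- simulate_arm(cfg)
  truth <- attr(arm, "truth")
  tr <- halfloop_run(arm)
  # the last surviving cases are the planted rows
  it <- tr$iterations
  i_at <- max(it$iteration[it$M >= length(truth$rows)])
  J <- trace_members(tr, i_at)$J
  expect_gte(length(intersect(J, truth$rows)) / length(truth$rows), 0.9)
})

test_that("reverse_labels is an involution that swaps counts", {
  arm <- toy_arm(matrix(rbinom(50, 2, .4), 5), matrix(rbinom(70, 2, .4), 7))
  rv <- reverse_labels(arm)
  expect_equal(unname(arm_counts(rv)), unname(rev(arm_counts(arm))))
  back <- reverse_labels(rv)
  expect_identical(back$D$values, arm$D$values)
  expect_identical(back$X$values, arm$X$values)
  expect_null(rv$subtype)
})

test_that("scramble_submatrix preserves block column margins and is seeded", {
  G <- toy_geno(20, 10, seed = 2)
  A <- encode_allele_combinations(G)
  rows <- A$subject_ids[3:12]
  cols <- colnames(A$values)[5:20]
  S1 <- scramble_submatrix(A, rows, cols, seed = 7)
  S2 <- scramble_submatrix(A, rows, cols, seed = 7)
  S3 <- scramble_submatrix(A, rows, cols, seed = 8)
  expect_identical(S1$values, S2$values)
  expect_false(identical(S1$values, S3$values))
  ri <- match(rows, A$subject_ids)
  expect_equal(colSums(S1$values[ri, cols]), colSums(A$values[ri, cols]))
  # outside the block untouched
  expect_identical(S1$values[-ri, ], A$values[-ri, ])
  expect_identical(S1$values[, setdiff(colnames(A$values), cols)],
                   A$values[, setdiff(colnames(A$values), cols)])
  expect_warning(scramble_submatrix(A, character(0), cols), "empty")
})

test_that("membership composition: fractions and hypergeometric enrichment", {
  set.seed(40)
  arm <- toy_arm(matrix(rbinom(10 * 20, 2, .4), 10),
                 matrix(rbinom(8 * 20, 2, .4), 8))
  tr <- halfloop_run(arm, gamma = 0.1)
  # all-positive labels: fraction 1 and p = 1 at every live iteration
  labs <- stats::setNames(rep(TRUE, 10), arm$D$subject_ids)
  comp <- membership_composition(tr, labs)
  live <- comp$n_retained > 0
  expect_true(all(comp$fraction[live] == 1))
  expect_true(all(comp$p_enrichment[live] == 1))
  # full pool at iteration 1: fraction equals initial proportion, p >= 0.5
  labs2 <- stats::setNames(rep(c(TRUE, FALSE), 5), arm$D$subject_ids)
  comp2 <- membership_composition(tr, labs2)
  expect_equal(comp2$fraction[1], 0.5)
  expect_gte(comp2$p_enrichment[1], 0.5)
  # closed-form check: pool 10 (4 positive), retained 5 with 4 positive
  expect_equal(stats::phyper(3, 4, 6, 5, lower.tail = FALSE), 6 / 252,
               tolerance = 1e-12)
})

test_that("kernel weighting suppresses a covariate-driven spurious bicluster", {
  better <- 0
  for (seed in 1:3) {
    arm <- confounded_arm(seed)
    ens_u <- suppressWarnings(null_ensemble(arm, n_trials = 16, seed = seed,
                                            keep_members = FALSE))
    ens_w <- suppressWarnings(null_ensemble(arm, n_trials = 16, seed = seed,
                                            correction = "U1",
                                            keep_members = FALSE))
    better <- better + (max(ens_w$iterations$z) < max(ens_u$iterations$z))
  }
  expect_gte(better, 2)
})
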