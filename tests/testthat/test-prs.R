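test_that("gwas recovers the 2x2 log odds ratio without covariates", {
  # cases: 30 carriers (dosage 1), 10 non-carriers; controls: 10 / 30
  calls <- matrix(c(rep(1L, 30), rep(0L, 10), rep(1L, 10), rep(0L, 30)),
                  ncol = 1)
  arm <- toy_arm(calls[1:40, , drop = FALSE], calls[41:80, , drop = FALSE])
  st <- gwas(arm)
  expect_equal(st$beta, log(9), tolerance = 1e-6)
  expect_equal(st$maf, mean(calls[1:80]) / 2)
})

test_that("gwas drops monomorphic SNPs and absorbs confounds", {
  set.seed(8)
  calls <- cbind(rbinom(60, 2, .4), 1L)
  arm <- toy_arm(calls[1:25, , drop = FALSE], calls[26:60, , drop = FALSE])
  st <- gwas(arm)
  expect_equal(nrow(st), 1)
  expect_equal(attr(st, "n_dropped"), 1)
  # covariate fully explaining the label difference -> SNP non-significant
  n <- 400
  u <- c(rnorm(n / 2, 2), rnorm(n / 2, -2))
  dose <- rbinom(n, 2, plogis(u))  # SNP correlated with U only
  ids <- sprintf("s%03d", 1:n)
  G <- genotype_matrix(matrix(dose, ncol = 1),
                       tibble::tibble(snp_id = "rs1", chr = "1", pos = 1L,
                                      allele1 = "A", allele2 = "B"), ids)
  cov <- tibble::tibble(subject_id = ids, U1 = u)
  arm2 <- cohort_arm(G, rep(c(TRUE, FALSE), each = n / 2), cov)
  p_raw <- gwas(arm2)$p
  p_adj <- gwas(arm2, correction = "U1")$p
  expect_lt(p_raw, 0.05)
  expect_gt(p_adj, 0.05)
})

test_that("gwas p-values are uniform under permuted labels", {
  cfg <- synth_config(n_cases = 100, n_controls = 120, n_snps = 300,
                      seed = 55)
  arm <- null_dataset(cfg)
  st <- gwas(arm)
  ks <- stats::ks.test(st$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("greedy clumping follows the p-order and LD rule", {
  # three SNPs at 100/300/900 kb with p 1e-8/1e-6/1e-4; r2(1,2) high
  set.seed(10)
  n <- 200
  g1 <- rbinom(n, 2, 0.3)
  g2 <- ifelse(runif(n) < 0.9, g1, rbinom(n, 2, 0.3))  # strong LD with g1
  g3 <- rbinom(n, 2, 0.3)
  ref <- genotype_matrix(
    cbind(g1, g2, g3),
    tibble::tibble(snp_id = c("s1", "s2", "s3"), chr = "1",
                   pos = c(100000L, 300000L, 900000L),
                   allele1 = "A", allele2 = "B")
  )
  stats_tab <- tibble::tibble(
    snp_id = c("s1", "s2", "s3"), chr = "1",
    pos = c(100000L, 300000L, 900000L), a1 = "A",
    beta = c(1, 1, 1), se = 1, p = c(1e-8, 1e-6, 1e-4),
    maf = c(0.3, 0.3, 0.3)
  )
  model <- clump(stats_tab, ref, r2_max = 0.1, window_bp = 5e5)
  expect_setequal(model$snps$snp_id, c("s1", "s3"))
  # all pairwise r2 below threshold -> everything kept regardless of distance
  model2 <- clump(stats_tab, ref, r2_max = 0.999, window_bp = 5e5)
  expect_setequal(model2$snps$snp_id, c("s1", "s2", "s3"))
  # one SNP -> kept
  model3 <- clump(stats_tab[1, ], ref)
  expect_equal(model3$snps$snp_id, "s1")
  # maf filter applied first
  low_maf <- stats_tab
  low_maf$maf[3] <- 0.01
  expect_setequal(clump(low_maf, ref)$snps$snp_id, c("s1"))
  # SNP absent from the reference dropped with warning
  off_ref <- stats_tab
  off_ref$snp_id[3] <- "s9"
  expect_warning(clump(off_ref, ref), "absent")
})

test_that("build_prs weights dosages and imputes missing by 2*maf", {
  model <- structure(list(
    snps = tibble::tibble(snp_id = c("a", "b"), chr = "1",
                          pos = c(1L, 2L), a1 = "A",
                          beta = c(0.5, -0.2), se = 1,
                          p = c(1e-4, 1e-2), maf = c(0.25, 0.4)),
    params = list()
  ), class = "prs_model")
  G <- genotype_matrix(rbind(c(2L, 1L), c(NA, 0L)),
                       tibble::tibble(snp_id = c("a", "b"), chr = "1",
                                      pos = c(1L, 2L),
                                      allele1 = "A", allele2 = "B"),
                       c("s1", "s2"))
  sc <- build_prs(model, G, p_tilde = 1)
  expect_equal(unname(sc["s1"]), 0.5 * 2 - 0.2 * 1)
  expect_equal(unname(sc["s2"]), 0.5 * (2 * 0.25) - 0.2 * 0)
  expect_equal(attr(sc, "n_snp"), 2L)
  # thresholding
  sc2 <- build_prs(model, G, p_tilde = 1e-3)
  expect_equal(attr(sc2, "n_snp"), 1L)
  expect_error(build_prs(model, G, p_tilde = 1e-9), "p_tilde")
  # all betas zero -> all scores zero
  model$snps$beta <- c(0, 0)
  expect_equal(as.numeric(build_prs(model, G, 1)), c(0, 0))
})

test_that("evaluate_prs restricts cases by subtype", {
  cfg <- synth_config(n_cases = 60, n_controls = 60, n_snps = 40, seed = 3,
                      planted = list(case_fraction = 0.5, snp_fraction = 0.3,
                                     shift = 0.3))
  arm <- simulate_arm(cfg)
  sc <- stats::setNames(rnorm(120), arm$geno$subject_ids)
  r_all <- evaluate_prs(sc, arm)
  r_bdi <- evaluate_prs(sc, arm, subtype_filter = "BDI")
  expect_equal(r_all$n_cases, 60)
  expect_lt(r_bdi$n_cases, 60)
  expect_true(all(c(r_all$auc, r_bdi$auc) >= 0 &
                    c(r_all$auc, r_bdi$auc) <= 1))
  # every case above every control -> AUC 1 for any filter
  sc2 <- sc
  sc2[arm$D$subject_ids] <- 10 + abs(sc2[arm$D$subject_ids])
  sc2[arm$X$subject_ids] <- -10 - abs(sc2[arm$X$subject_ids])
  expect_equal(evaluate_prs(sc2, arm)$auc, 1)
  expect_equal(evaluate_prs(sc2, arm, subtype_filter = "BDII")$auc, 1)
})

test_that("liability conversion: boundary, monotonicity, symmetry", {
  expect_equal(auc_to_liability_r2(0.5, 0.01, 0.5), 0)
  grid <- seq(0.52, 0.95, by = 0.01)
  r2 <- vapply(grid, auc_to_liability_r2, 1, K = 0.02, P = 0.4)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
  expect_warning(low <- auc_to_liability_r2(0.4, 0.02, 0.4), "symmetrised")
  expect_equal(low, auc_to_liability_r2(0.6, 0.02, 0.4))
  expect_error(auc_to_liability_r2(1, 0.02, 0.4), "undefined")
})

test_that("PRS is invariant to SNP and subject ordering", {
  cfg <- synth_config(n_cases = 40, n_controls = 40, n_snps = 60, seed = 9,
                      planted = list(case_fraction = 0.4, snp_fraction = 0.3,
                                     shift = 0.3))
  arm <- simulate_arm(cfg)
  st <- gwas(arm)
  model <- clump(st, arm$geno)
  sc <- build_prs(model, arm$geno, 1)
  G2 <- arm$geno
  perm_s <- sample(nrow(G2$calls))
  perm_k <- sample(ncol(G2$calls))
  G2 <- genotype_matrix(G2$calls[perm_s, perm_k],
                        G2$snp_table[perm_k, ], G2$subject_ids[perm_s])
  sc2 <- build_prs(model, G2, 1)
  expect_equal(sc2[names(sc)], sc, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bicluster-informed summary statistics at iteration 1 equal the wide ones", {
  cfg <- synth_config(n_cases = 50, n_controls = 60, n_snps = 50, seed = 19,
                      planted = list(case_fraction = 0.3, snp_fraction = 0.2,
                                     shift = 0.3))
  arm <- simulate_arm(cfg)
  tr <- halfloop_run(arm)
  J1 <- trace_members(tr, 1)$J
  st_wide <- gwas(arm, "all", c("U1", "U2"))
  st_bicl <- gwas(arm, J1, c("U1", "U2"))
  expect_equal(st_bicl$beta, st_wide$beta, tolerance = 1e-12)
  expect_equal(st_bicl$p, st_wide$p, tolerance = 1e-12)
})
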