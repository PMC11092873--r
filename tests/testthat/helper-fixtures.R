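# small deterministic fixtures used across test files

# plain genotype_matrix with given dimensions
toy_geno <- function(n_sub = 10, n_snp = 5, seed = 1, maf = 0.4,
                     missing_rate = 0) {
  set.seed(seed)
  calls <- matrix(rbinom(n_sub * n_snp, 2, maf), n_sub, n_snp)
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  }
  snp_table <- tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(n_snp)), chr = "1",
    pos = 100000L * seq_len(n_snp), allele1 = "A", allele2 = "B"
  )
  genotype_matrix(calls, snp_table, sprintf("s%03d", seq_len(n_sub)))
}

# cohort arm from raw call matrices (cases then controls)
toy_arm <- function(case_calls, ctrl_calls, seed = 1, covs = NULL) {
  n_ca <- nrow(case_calls)
  n_ct <- nrow(ctrl_calls)
  calls <- rbind(case_calls, ctrl_calls)
  n_snp <- ncol(calls)
  ids <- sprintf("s%03d", seq_len(n_ca + n_ct))
  snp_table <- tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(n_snp)), chr = "1",
    pos = 100000L * seq_len(n_snp), allele1 = "A", allele2 = "B"
  )
  G <- genotype_matrix(calls, snp_table, ids)
  set.seed(seed)
  if (is.null(covs)) {
    covs <- tibble::tibble(subject_id = ids,
                           U1 = rnorm(n_ca + n_ct),
                           U2 = rnorm(n_ca + n_ct))
  } else {
    covs$subject_id <- ids
  }
  cohort_arm(G, c(rep(TRUE, n_ca), rep(FALSE, n_ct)), covs)
}

# brute-force double-loop sharing-score oracle (uniform weights)
oracle_q <- function(D, X) {
  M <- nrow(D); N <- ncol(D)
  q <- matrix(0, M, N)
  for (j in seq_len(M)) {
    for (k in seq_len(N)) {
      v <- D[j, k]
      if (is.na(v)) next
      oth <- D[-j, k]; oth <- oth[!is.na(oth)]
      xx <- X[, k]; xx <- xx[!is.na(xx)]
      if (!length(oth) || !length(xx)) next
      q[j, k] <- mean(oth == v) - mean(xx == v)
    }
  }
  q
}

# confounded null arm: ancestry clusters with allele-frequency tilt and
# imbalanced case/control cluster membership, no disease signal
confounded_arm <- function(seed, n_ca = 120, n_ct = 180, n_snp = 300) {
  set.seed(seed)
  q <- runif(n_snp, 0.25, 0.5)
  cl_ca <- rbinom(n_ca, 1, 0.6)
  cl_ct <- rbinom(n_ct, 1, 0.3)
  tilt <- numeric(n_snp)
  sel <- sample(n_snp, round(n_snp / 3))
  tilt[sel] <- runif(length(sel), 0.1, 0.25)
  draw <- function(n, cl) {
    qq <- outer(rep(1, n), q) + outer(cl, tilt)
    matrix(rbinom(n * n_snp, 2, pmin(pmax(qq, 0.02), 0.98)), n, n_snp)
  }
  calls <- rbind(draw(n_ca, cl_ca), draw(n_ct, cl_ct))
  ids <- sprintf("s%03d", seq_len(n_ca + n_ct))
  st <- tibble::tibble(snp_id = sprintf("rs%04d", seq_len(n_snp)), chr = "1",
                       pos = 100000L * seq_len(n_snp),
                       allele1 = "A", allele2 = "B")
  G <- genotype_matrix(calls, st, ids)
  cov <- tibble::tibble(subject_id = ids,
                        U1 = c(cl_ca, cl_ct) + rnorm(n_ca + n_ct, 0, 0.15),
                        U2 = rnorm(n_ca + n_ct))
  cohort_arm(G, c(rep(TRUE, n_ca), rep(FALSE, n_ct)), cov)
}

# gene-aligned annotation: one synthetic gene per SNP
per_snp_annotation <- function(geno) {
  simulate_annotation(geno$snp_table$snp_id, snps_per_gene = 1)
}

# half-max excess interval of an ensemble (near-peak plateau of the trace)
halfmax_interval <- function(ens) {
  it <- ens$iterations
  ex <- it$trace - it$null_mean
  range(it$iteration[ex >= 0.5 * max(ex)])
}
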