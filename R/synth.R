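#' Synthetic cohort configuration
#'
#' Describes a multi-arm case/control genotype cohort with an optionally
#' planted case-only bicluster. Genotypes are drawn under Hardy-Weinberg
#' equilibrium at common SNPs; the planted cases carry an allele-frequency
#' displacement `shift` at a fraction of the SNPs, so the planted signal is
#' expressed on genotype frequencies and respects the one-hot encoding.
#' Ancestry-like covariates come from a Gaussian mixture; case subtype
#' labels are assigned with the planted subgroup enriched for BDI.
#'
#' @param n_cases,n_controls,n_snps Cohort dimensions.
#' @param maf_range Minor-allele-frequency interval for the simulated SNPs
#'   (default `c(0.25, 0.5)`, matching a common-variant analysis).
#' @param planted List: `case_fraction` (f), `snp_fraction` (g), `shift`
#'   (allele-frequency displacement delta for planted cases at planted
#'   SNPs).
#' @param covariates List: `n_dims`, `cluster_count`, `confound_strength`
#'   (how strongly cluster membership differs between cases and controls).
#' @param subtype List: `bdi_fraction`, `bdii_fraction`,
#'   `bicluster_bdi_enrichment` (added BDI probability for planted cases).
#' @param arms List of per-replication-arm settings, each a list with
#'   `snp_overlap` (target Szymkiewicz-Simpson coefficient with arm 1) and
#'   optional `n_cases`, `n_controls`.
#' @param ld List: `block_size` (SNPs per correlated block; 1 = independent
#'   SNPs) and `rho` (probability that a block member copies the block's
#'   anchor genotype).
#' @param seed Integer seed; the seed fully determines the cohorts.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 200, n_controls = 300, n_snps = 500,
                         maf_range = c(0.25, 0.5),
                         planted = list(), covariates = list(),
                         subtype = list(), arms = list(), ld = list(),
                         seed = 1) {
  planted <- utils::modifyList(
    list(case_fraction = 0, snp_fraction = 0.1, shift = 0.3,
         combo_mode = "frequency", coherence = c(0.5, 0.95)), planted)
  covariates <- utils::modifyList(
    list(n_dims = 2, cluster_count = 3, confound_strength = 0), covariates)
  subtype <- utils::modifyList(
    list(bdi_fraction = 0.65, bdii_fraction = 0.31,
         bicluster_bdi_enrichment = 0.2), subtype)
  ld <- utils::modifyList(list(block_size = 1, rho = 0), ld)
  stopifnot(
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    planted$case_fraction >= 0, planted$case_fraction <= 1,
    planted$snp_fraction > 0, planted$snp_fraction <= 1
  )
  if (planted$case_fraction > 0 &&
      maf_range[2] + planted$shift >= 1) {
    stop("infeasible shift: maximum planted allele frequency reaches 1",
         call. = FALSE)
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
         maf_range = maf_range, planted = planted, covariates = covariates,
         subtype = subtype, arms = arms, ld = ld, seed = seed),
    class = "synth_config"
  )
}

# HWE genotype draws, with optional per-subject frequency overrides and
# block-LD copying
draw_genotypes <- function(n, q, ld) {
  n_snp <- length(q)
  g <- matrix(stats::rbinom(n * n_snp, 2, rep(q, each = n)), n, n_snp)
  if (ld$block_size > 1 && ld$rho > 0) {
    anchors <- seq(1, n_snp, by = ld$block_size)
    for (a in anchors) {
      members <- seq(a + 1, min(a + ld$block_size - 1, n_snp))
      if (!length(members) || members[1] > n_snp) next
      for (k in members) {
        copy <- stats::runif(n) < ld$rho
        g[copy, k] <- g[copy, a]
      }
    }
  }
  g
}

simulate_arm_impl <- function(config, snp_table, q, planted_snps, arm_id,
                              n_cases, n_controls, seed) {
  pl <- config$planted
  cv <- config$covariates
  st <- config$subtype
  with_rng_seed(seed, {
    n <- n_cases + n_controls
    subject_ids <- sprintf("%s_s%04d", arm_id, seq_len(n))
    status <- c(rep(TRUE, n_cases), rep(FALSE, n_controls))
    calls <- draw_genotypes(n, q, config$ld)
    planted_cases <- character(0)
    planted_idx <- integer(0)
    if (pl$case_fraction > 0 && length(planted_snps)) {
      n_planted <- round(pl$case_fraction * n_cases)
      planted_idx <- sort(sample.int(n_cases, n_planted))
      cols <- match(planted_snps, snp_table$snp_id)
      cols <- cols[!is.na(cols)]
      if (length(cols)) {
        nb <- length(planted_idx)
        if (identical(pl$combo_mode, "signature")) {
          # shared signature genotype per planted SNP; each planted case
          # copies it with a row-specific coherence, yielding the core /
          # adjacent structure of a realistic bicluster (rows differ in how
          # strongly they carry the pattern)
          g_star <- stats::rbinom(length(cols), 2,
                                  pmin(q[cols] + pl$shift, 0.999))
          rho <- if (!is.null(pl$core_fraction)) {
            # two-tier core/adjacent structure: a core at the upper
            # coherence, adjacent rows at the lower
            ifelse(stats::runif(nb) < pl$core_fraction,
                   pl$coherence[2], pl$coherence[1])
          } else {
            stats::runif(nb, pl$coherence[1], pl$coherence[2])
          }
          bg <- matrix(stats::rbinom(nb * length(cols), 2,
                                     rep(q[cols], each = nb)),
                       nb, length(cols))
          take <- matrix(stats::runif(nb * length(cols)), nb,
                         length(cols)) < rho
          block <- ifelse(take, matrix(g_star, nb, length(cols),
                                       byrow = TRUE), bg)
          calls[planted_idx, cols] <- block
        } else {
          q_shift <- pmin(q[cols] + pl$shift, 0.999)
          calls[planted_idx, cols] <- matrix(
            stats::rbinom(nb * length(cols), 2,
                          rep(q_shift, each = nb)),
            nb, length(cols)
          )
        }
      }
      planted_cases <- subject_ids[planted_idx]
    }
    # covariates: Gaussian mixture, cluster probabilities tilted for cases
    K <- cv$cluster_count
    centers <- matrix(stats::rnorm(K * cv$n_dims, sd = 2), K, cv$n_dims)
    tilt <- exp(cv$confound_strength * seq(-1, 1, length.out = K))
    p_case <- tilt / sum(tilt)
    clus <- integer(n)
    clus[status] <- sample.int(K, n_cases, replace = TRUE, prob = p_case)
    clus[!status] <- sample.int(K, n_controls, replace = TRUE)
    covs <- centers[clus, , drop = FALSE] +
      matrix(stats::rnorm(n * cv$n_dims), n, cv$n_dims)
    colnames(covs) <- paste0("U", seq_len(cv$n_dims))
    sex <- stats::rbinom(n, 1, 0.5)
    # subtype labels (cases only); planted cases enriched for BDI
    p_bdi <- rep(st$bdi_fraction, n_cases)
    p_bdi[planted_idx] <- pmin(0.97, st$bdi_fraction +
                                 st$bicluster_bdi_enrichment)
    subtype <- rep(NA_character_, n)
    is_bdi <- stats::runif(n_cases) < p_bdi
    rest <- st$bdii_fraction / max(1e-9, 1 - st$bdi_fraction)
    is_bdii <- !is_bdi & (stats::runif(n_cases) < min(1, rest))
    subtype[status] <- ifelse(is_bdi, "BDI", ifelse(is_bdii, "BDII", "other"))
    covariates <- tibble::as_tibble(covs)
    covariates$subject_id <- subject_ids
    covariates$sex <- sex
    G <- genotype_matrix(calls, snp_table, subject_ids)
    arm <- cohort_arm(G, status, covariates, subtype, arm_id)
    truth <- list(
      rows = planted_cases,
      snps = if (length(planted_cases)) planted_snps else character(0),
      cols = if (length(planted_cases))
        arm$D$column_map$column[arm$D$column_map$snp_id %in% planted_snps]
      else character(0)
    )
    attr(arm, "truth") <- truth
    arm
  })
}

#' Simulate a single cohort arm
#'
#' Draws a case/control arm under the configuration: HWE genotypes at
#' common SNPs, an optionally planted case-only bicluster (an f-fraction of
#' cases whose allele frequency at a g-fraction of SNPs is displaced by
#' `shift`), Gaussian-mixture covariates and BDI/BDII subtype labels with
#' the planted subgroup enriched for BDI.
#'
#' @param config A [synth_config()].
#' @return A [cohort_arm()]; the planted truth (case ids, SNP ids, allele
#'   columns) is attached as `attr(arm, "truth")`.
#' @export
simulate_arm <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_rng_seed(config$seed, {
    q <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    snp_table <- make_snp_table(config$n_snps)
    n_planted_snps <- max(1, round(config$planted$snp_fraction *
                                     config$n_snps))
    planted_snps <- if (config$planted$case_fraction > 0)
      sort(sample(snp_table$snp_id, n_planted_snps)) else character(0)
    arm_seed <- sample.int(.Machine$integer.max - 1, 1)
  })
  simulate_arm_impl(config, snp_table, q, planted_snps, "arm1",
                    config$n_cases, config$n_controls, arm_seed)
}

# deterministic global panel layout: 1000 SNPs per chromosome, 100 kb apart,
# so consecutive indices are neighbours (relevant for LD blocks and clumping)
make_snp_table <- function(n_snps, start_index = 1) {
  idx <- seq.int(start_index, length.out = n_snps)
  chr <- as.character(((idx - 1) %/% 1000) + 1)
  pos <- 100000L * (((idx - 1L) %% 1000L) + 1L)
  tibble::tibble(
    snp_id = sprintf("rs%06d", idx), chr = chr, pos = pos,
    allele1 = "A", allele2 = "B"
  )
}

#' Simulate multiple arms sharing a planted signal
#'
#' Generates a master SNP panel containing arm 1's SNPs (and the planted
#' SNPs); each replication arm observes a random subset of arm 1's panel
#' achieving its target overlap coefficient, topped up with private SNPs,
#' so replication strength degrades naturally with overlap. All arms share
#' per-SNP allele frequencies, the planted SNP set and the displacement;
#' each arm plants its own f-fraction of its cases.
#'
#' @param config A [synth_config()] with a non-empty `arms` list.
#' @return List of [cohort_arm()]s (first element is the training arm);
#'   each carries its planted truth attribute.
#' @export
simulate_multi_arm <- function(config) {
  stopifnot(inherits(config, "synth_config"), length(config$arms) >= 1)
  for (a in config$arms) {
    if (is.null(a$snp_overlap) || a$snp_overlap <= 0) {
      stop("every replication arm needs snp_overlap > 0", call. = FALSE)
    }
  }
  n1 <- config$n_snps
  with_rng_seed(config$seed, {
    snp_table1 <- make_snp_table(n1)
    q1 <- stats::runif(n1, config$maf_range[1], config$maf_range[2])
    n_planted_snps <- max(1, round(config$planted$snp_fraction * n1))
    planted_snps <- if (config$planted$case_fraction > 0)
      sort(sample(snp_table1$snp_id, n_planted_snps)) else character(0)
    seeds <- sample.int(.Machine$integer.max - 1, 1 + length(config$arms))
    arm_specs <- vector("list", length(config$arms))
    next_idx <- n1 + 1
    for (r in seq_along(config$arms)) {
      spec <- config$arms[[r]]
      nr <- spec$n_snps %||% n1
      n_shared <- round(spec$snp_overlap * min(n1, nr))
      shared <- sort(sample.int(n1, n_shared))
      n_private <- nr - n_shared
      priv_table <- make_snp_table(n_private, start_index = next_idx)
      next_idx <- next_idx + n_private
      q_priv <- stats::runif(n_private, config$maf_range[1],
                             config$maf_range[2])
      arm_specs[[r]] <- list(
        snp_table = dplyr::bind_rows(snp_table1[shared, ], priv_table),
        q = c(q1[shared], q_priv),
        n_cases = spec$n_cases %||% config$n_cases,
        n_controls = spec$n_controls %||% config$n_controls
      )
    }
  })
  arms <- vector("list", 1 + length(config$arms))
  arms[[1]] <- simulate_arm_impl(config, snp_table1, q1, planted_snps,
                                 "arm1", config$n_cases, config$n_controls,
                                 seeds[1])
  for (r in seq_along(config$arms)) {
    sp <- arm_specs[[r]]
    arms[[r + 1]] <- simulate_arm_impl(
      config, sp$snp_table, sp$q, planted_snps,
      sprintf("arm%d", r + 1), sp$n_cases, sp$n_controls, seeds[r + 1]
    )
  }
  arms
}

#' Simulate a null arm (no planted structure)
#'
#' @param config A [synth_config()]; its planted `case_fraction` is forced
#'   to zero.
#' @return A [cohort_arm()] with an empty truth record.
#' @export
null_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  config$planted$case_fraction <- 0
  simulate_arm(config)
}

#' Toy SNP-to-gene annotation for simulated panels
#'
#' Assigns consecutive SNPs to synthetic genes (`snps_per_gene` SNPs per
#' gene), giving a deterministic many-to-one SNP-to-gene map for
#' enrichment analyses of simulated cohorts.
#'
#' @param snp_ids Character vector of SNP ids (panel order).
#' @param snps_per_gene SNPs assigned to each synthetic gene.
#' @return Tibble with `snp_id` and `gene`.
#' @export
simulate_annotation <- function(snp_ids, snps_per_gene = 4) {
  gene_idx <- ((seq_along(snp_ids) - 1) %/% snps_per_gene) + 1
  tibble::tibble(
    snp_id = snp_ids,
    gene = sprintf("GENE%04d", gene_idx)
  )
}

#' Toy gene-set collection over synthetic genes
#'
#' Random pathways of the given sizes over a gene universe; optionally one
#' pathway is forced to concentrate on a supplied gene set (e.g. the genes
#' of planted SNPs) to create a known enrichment target.
#'
#' @param genes Gene universe.
#' @param n_pathways Number of pathways.
#' @param size_range Pathway size interval.
#' @param focus Optional gene vector: the first pathway is built around it.
#' @param seed Integer seed.
#' @return Named list of gene vectors.
#' @export
simulate_gene_sets <- function(genes, n_pathways = 10,
                               size_range = c(5, 25), focus = NULL,
                               seed = 1) {
  with_rng_seed(seed, {
    sets <- lapply(seq_len(n_pathways), function(i) {
      sz <- sample(seq(size_range[1], size_range[2]), 1)
      sort(sample(genes, min(sz, length(genes))))
    })
    names(sets) <- sprintf("pathway_%02d", seq_len(n_pathways))
    if (!is.null(focus) && length(focus)) {
      extra <- sample(setdiff(genes, focus),
                      min(3, length(setdiff(genes, focus))))
      sets[[1]] <- sort(unique(c(focus, extra)))
      names(sets)[1] <- "pathway_focus"
    }
    sets
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
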