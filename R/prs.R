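#' Per-SNP logistic GWAS summary statistics
#'
#' For each SNP, logistic regression of case/control status on the additive
#' minor-allele dosage plus the correction covariates; Wald beta, standard
#' error and p-value. Restricting `case_subset` to a bicluster's retained
#' cases yields bicluster-informed summary statistics; `"all"` contrasts
#' every case against the controls (population-wide).
#'
#' @param arm A [cohort_arm()] carrying genotypes.
#' @param case_subset `"all"` or a character vector of case ids.
#' @param correction Covariate columns to include in every model.
#' @return Object of class `summary_stats`: tibble with `snp_id`, `chr`,
#'   `pos`, `a1` (effect/minor allele), `beta` (log-odds per allele copy),
#'   `se`, `p`, `maf`, plus attributes `provenance` and `n_dropped`
#'   (monomorphic or non-converged SNPs).
#' @export
gwas <- function(arm, case_subset = "all", correction = NULL) {
  stopifnot(inherits(arm, "cohort_arm"))
  case_ids <- arm$D$subject_ids
  if (identical(case_subset, "all")) {
    cases <- case_ids
  } else {
    cases <- intersect(case_subset, case_ids)
    if (!length(cases)) stop("empty case subset", call. = FALSE)
  }
  ctrl <- arm$X$subject_ids
  ids <- c(cases, ctrl)
  y <- c(rep(1, length(cases)), rep(0, length(ctrl)))
  G <- arm$geno
  dose <- G$calls[match(ids, G$subject_ids), , drop = FALSE]
  covm <- NULL
  if (!is.null(correction) && length(correction)) {
    cm <- covariate_matrix(arm, correction)
    covm <- cm[match(ids, rownames(cm)), , drop = FALSE]
  }
  n_snp <- ncol(dose)
  beta <- se <- p <- maf <- rep(NA_real_, n_snp)
  dropped <- logical(n_snp)
  base <- matrix(1, length(ids), 1,
                 dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covm)) base <- cbind(base, covm)
  for (k in seq_len(n_snp)) {
    d <- dose[, k]
    obs <- !is.na(d)
    if (sum(obs) < 4 || stats::var(d[obs]) == 0) {
      dropped[k] <- TRUE
      next
    }
    Xk <- cbind(base[obs, , drop = FALSE], dosage = d[obs])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Xk, y[obs], family = stats::binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      dropped[k] <- TRUE
      next
    }
    # Wald statistics: (X' W X)^-1 at the converged IRLS weights
    WX <- Xk * sqrt(fit$weights)
    cov_unscaled <- tryCatch(chol2inv(chol(crossprod(WX))),
                             error = function(e) NULL)
    if (is.null(cov_unscaled)) {
      dropped[k] <- TRUE
      next
    }
    j <- ncol(Xk)
    beta[k] <- fit$coefficients[j]
    se[k] <- sqrt(cov_unscaled[j, j])
    z <- beta[k] / se[k]
    p[k] <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    maf[k] <- mean(d[obs]) / 2
  }
  keep <- !dropped
  st <- G$snp_table
  out <- tibble::tibble(
    snp_id = st$snp_id[keep], chr = st$chr[keep], pos = st$pos[keep],
    a1 = if ("allele1" %in% names(st)) st$allele1[keep] else "A",
    beta = beta[keep], se = se[keep], p = p[keep], maf = maf[keep]
  )
  structure(out,
            provenance = if (identical(case_subset, "all")) "wide"
                         else sprintf("bicl(%d cases)", length(cases)),
            n_dropped = sum(dropped),
            class = c("summary_stats", class(out)))
}

#' Greedy LD clumping
#'
#' Visits SNPs by ascending p-value and keeps a SNP unless it lies within
#' `window_bp` of an already-kept SNP on the same chromosome with sample
#' `r^2` above `r2_max` in the reference panel. Minor-allele-frequency and
#' (when present) info-score filters are applied first.
#'
#' @param stats A `summary_stats` table (needs `snp_id`, `chr`, `pos`, `p`,
#'   `maf`; optional `info`).
#' @param ld_reference A [genotype_matrix()] covering the SNPs, used for
#'   sample `r^2`.
#' @param r2_max LD threshold (default 0.1).
#' @param window_bp Genomic window (default 500000).
#' @param maf_min Frequency filter (default 0.05).
#' @param info_min Info-score filter (default 0.9; skipped when no `info`
#'   column is present).
#' @return Object of class `prs_model`: the retained rows of `stats` plus
#'   the clumping parameters.
#' @export
clump <- function(stats, ld_reference, r2_max = 0.1, window_bp = 5e5,
                  maf_min = 0.05, info_min = 0.9) {
  stopifnot(inherits(ld_reference, "genotype_matrix"))
  tab <- tibble::as_tibble(stats)
  tab <- tab[!is.na(tab$p) & tab$maf > maf_min & tab$maf < 1 - maf_min, ]
  if ("info" %in% names(tab)) tab <- tab[tab$info >= info_min, ]
  in_ref <- tab$snp_id %in% ld_reference$snp_table$snp_id
  if (any(!in_ref)) {
    warning(sum(!in_ref), " SNP(s) absent from the LD reference; dropped",
            call. = FALSE)
    tab <- tab[in_ref, ]
  }
  tab <- tab[order(tab$p, tab$snp_id), ]
  ref <- ld_reference$calls[, tab$snp_id, drop = FALSE]
  storage.mode(ref) <- "double"
  keep <- logical(nrow(tab))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(tab))) {
    ok <- TRUE
    if (length(kept_idx)) {
      near <- kept_idx[tab$chr[kept_idx] == tab$chr[i] &
                         abs(tab$pos[kept_idx] - tab$pos[i]) <= window_bp]
      if (length(near)) {
        r2 <- suppressWarnings(
          stats::cor(ref[, i], ref[, near, drop = FALSE],
                     use = "pairwise.complete.obs")
        )^2
        if (any(r2 > r2_max, na.rm = TRUE)) ok <- FALSE
      }
    }
    keep[i] <- ok
    if (ok) kept_idx <- c(kept_idx, i)
  }
  structure(
    list(
      snps = tab[keep, , drop = FALSE],
      params = list(r2_max = r2_max, window_bp = window_bp,
                    maf_min = maf_min, info_min = info_min)
    ),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d SNPs retained (r2 <= %.2g within %g kb)\n",
              nrow(x$snps), x$params$r2_max, x$params$window_bp / 1000))
  invisible(x)
}

#' Polygenic score at a p-value threshold
#'
#' Weighted sum of minor-allele dosages over the retained SNPs whose GWAS
#' p-value is at most `p_tilde`. Missing dosages are imputed as twice the
#' summary-statistic allele frequency (mean imputation).
#'
#' @param model A `prs_model`.
#' @param G A [genotype_matrix()] for the subjects to score.
#' @param p_tilde Inclusion threshold on the per-SNP p-value.
#' @return Named numeric vector of scores with attribute `n_snp`.
#' @export
build_prs <- function(model, G, p_tilde = 1) {
  stopifnot(inherits(model, "prs_model"), inherits(G, "genotype_matrix"))
  snps <- model$snps[model$snps$p <= p_tilde, , drop = FALSE]
  if (!nrow(snps)) {
    stop(sprintf("no retained SNP passes the threshold p_tilde = %g", p_tilde),
         call. = FALSE)
  }
  present <- snps$snp_id %in% G$snp_table$snp_id
  if (any(!present)) {
    warning(sum(!present), " scored SNP(s) absent from the genotypes; skipped",
            call. = FALSE)
    snps <- snps[present, , drop = FALSE]
    if (!nrow(snps)) stop("no scoreable SNPs", call. = FALSE)
  }
  dose <- G$calls[, snps$snp_id, drop = FALSE]
  storage.mode(dose) <- "double"
  for (k in seq_len(ncol(dose))) {
    nas <- is.na(dose[, k])
    if (any(nas)) dose[nas, k] <- 2 * snps$maf[k]
  }
  score <- as.numeric(dose %*% snps$beta)
  structure(stats::setNames(score, G$subject_ids), n_snp = nrow(snps))
}

#' Evaluate a polygenic score on an arm
#'
#' Covariate-adjusted AUC between the (optionally subtype-restricted) cases
#' and all controls of the arm.
#'
#' @param scores Named score vector covering the arm's subjects.
#' @param arm A [cohort_arm()].
#' @param correction Covariate columns for adjustment.
#' @param subtype_filter `"all"`, `"BDI"` or `"BDII"`.
#' @return One-row tibble with `subtype`, `n_cases`, `n_controls`, `auc`.
#' @export
evaluate_prs <- function(scores, arm, correction = NULL,
                         subtype_filter = c("all", "BDI", "BDII")) {
  subtype_filter <- match.arg(subtype_filter)
  case_ids <- arm$D$subject_ids
  if (subtype_filter != "all") {
    if (is.null(arm$subtype)) {
      stop("arm has no subtype labels", call. = FALSE)
    }
    case_ids <- case_ids[arm$subtype[case_ids] == subtype_filter]
    if (!length(case_ids)) {
      stop("no cases with subtype ", subtype_filter, call. = FALSE)
    }
  }
  ctrl_ids <- arm$X$subject_ids
  sc <- scores[case_ids]
  sx <- scores[ctrl_ids]
  if (anyNA(sc) || anyNA(sx)) stop("scores missing for some subjects",
                                   call. = FALSE)
  cov <- arm_case_control_covariates(arm, correction, case_ids, ctrl_ids)
  auc <- covariate_adjusted_auc(sc, sx, cov)
  tibble::tibble(subtype = subtype_filter, n_cases = length(case_ids),
                 n_controls = length(ctrl_ids), auc = as.numeric(auc))
}

#' AUC to liability-scale R-squared
#'
#' Threshold-liability conversion: the AUC is mapped to the case-control
#' difference of the score in within-group standard-deviation units,
#' `d = sqrt(2) * qnorm(AUC)`; `d` gives the observed-scale (0/1) variance
#' explained via the point-biserial correlation at case fraction `P`; the
#' observed-scale R2 is then transformed to the liability scale for a
#' population prevalence `K` (correcting for case-control ascertainment
#' when `P != K`).
#'
#' @param auc AUC in `[0.5, 1)`. Values below 0.5 are symmetrised
#'   (`1 - auc`) with a warning.
#' @param K Population prevalence in `(0, 1)`.
#' @param P Case fraction of the evaluated sample in `(0, 1)`.
#' @return Liability-scale R-squared in `[0, 1)`; 0 exactly at `auc = 0.5`.
#' @export
auc_to_liability_r2 <- function(auc, K, P) {
  stopifnot(length(auc) == 1, is.finite(auc), K > 0, K < 1, P > 0, P < 1)
  if (auc < 0.5) {
    warning("AUC below 0.5 symmetrised", call. = FALSE)
    auc <- 1 - auc
  }
  if (auc >= 1) stop("liability R2 undefined at AUC = 1", call. = FALSE)
  if (auc == 0.5) return(0)
  d <- sqrt(2) * stats::qnorm(auc)
  r2_obs <- d^2 * P * (1 - P) / (1 + d^2 * P * (1 - P))
  thresh <- stats::qnorm(1 - K)
  z <- stats::dnorm(thresh)
  mean_case <- z / K
  cc <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  shrink <- mean_case * ((P - K) / (1 - K)) *
    (mean_case * ((P - K) / (1 - K)) - thresh)
  cc * r2_obs / (1 + cc * shrink * r2_obs)
}

#' Population-wide versus bicluster-informed PRS comparison
#'
#' Builds population-wide summary statistics (all training cases versus
#' controls) and bicluster-informed statistics (retained cases at each
#' requested iteration versus controls), clumps both against an LD
#' reference, and evaluates p-value-thresholded scores on each replication
#' arm and on the arms pooled (per-arm residualisation, pooled ranks), for
#' all subjects and restricted to each subtype, with liability-scale R2
#' conversions.
#'
#' @param trace A `bicluster_trace` from the training arm.
#' @param train_arm Training [cohort_arm()].
#' @param rep_arms List of replication [cohort_arm()]s.
#' @param iterations Trace iterations for the bicluster-informed models
#'   (iteration 1 reproduces the population-wide model exactly).
#' @param thresholds Numeric p-value thresholds, or `"auto"`: a geometric
#'   grid spanning the population-wide p-values.
#' @param correction Covariates for both the GWAS and the AUC adjustment.
#' @param ld_reference Genotype panel for clumping (default: the training
#'   arm's genotypes).
#' @param prevalences Named list of prevalences for the liability
#'   conversion (`all`, `BDI`, `BDII`).
#' @param clump_args List of [clump()] parameter overrides.
#' @return Object of class `prs_evaluation`: tibble with `arm`, `model`,
#'   `iteration`, `p_tilde`, `n_snp`, `subtype`, `auc`, `r2_liab`.
#' @export
prs_comparison <- function(trace, train_arm, rep_arms, iterations,
                           thresholds = "auto", correction = NULL,
                           ld_reference = NULL,
                           prevalences = list(all = 0.02, BDI = 0.01,
                                              BDII = 0.01),
                           clump_args = list()) {
  stopifnot(inherits(trace, "bicluster_trace"))
  if (inherits(rep_arms, "cohort_arm")) rep_arms <- list(rep_arms)
  if (is.null(ld_reference)) ld_reference <- train_arm$geno
  models <- list()
  wide_stats <- gwas(train_arm, "all", correction)
  models[["wide"]] <- do.call(clump, c(list(wide_stats, ld_reference),
                                       clump_args))
  for (i in iterations) {
    J <- trace_members(trace, i)$J
    st <- gwas(train_arm, J, correction)
    models[[sprintf("bicl_%d", i)]] <- do.call(
      clump, c(list(st, ld_reference), clump_args))
  }
  # "auto": per-model thresholds matched on the number of SNPs used, so the
  # models are compared at equal N_SNP (AUC as a function of #SNPs used)
  auto <- identical(thresholds, "auto")
  n_grid <- NULL
  if (auto) {
    n_max <- max(vapply(models, function(m) nrow(m$snps), 1L))
    n_grid <- unique(pmin(c(25, 50, 100, 200, 400, 800, 1600, n_max), n_max))
    n_grid <- n_grid[n_grid >= 1]
  }
  model_thresholds <- lapply(models, function(m) {
    if (!auto) return(thresholds)
    pv <- sort(m$snps$p)
    unique(pv[pmin(n_grid, length(pv))])
  })
  subtypes <- c("all", "BDI", "BDII")
  arm_names <- vapply(rep_arms, function(a) a$arm_id, "")
  rows <- list()
  pooled_cache <- list()
  for (mi in seq_along(models)) {
    mname <- names(models)[mi]
    model <- models[[mi]]
    is_wide <- mname == "wide"
    iter_i <- if (is_wide) NA_integer_ else
      as.integer(sub("bicl_", "", mname))
    for (pt in model_thresholds[[mi]]) {
      n_pass <- sum(model$snps$p <= pt)
      if (n_pass == 0) next
      per_arm <- lapply(rep_arms, function(a) {
        sc <- build_prs(model, a$geno, pt)
        cov <- arm_case_control_covariates(a, intersect(correction,
                                                        names(a$covariates)))
        s_all <- c(sc[a$D$subject_ids], sc[a$X$subject_ids])
        resid <- if (is.null(cov)) s_all else
          stats::lm.fit(cbind(1, cov), s_all)$residuals
        list(arm = a, scores = sc,
             resid = stats::setNames(resid,
                                     c(a$D$subject_ids, a$X$subject_ids)))
      })
      for (ai in seq_along(per_arm)) {
        a <- per_arm[[ai]]$arm
        for (stp in subtypes) {
          if (stp != "all" && (is.null(a$subtype) ||
                               !any(a$subtype == stp))) next
          case_ids <- a$D$subject_ids
          if (stp != "all") case_ids <- case_ids[a$subtype[case_ids] == stp]
          r <- per_arm[[ai]]$resid
          auc <- rank_auc(c(r[case_ids], r[a$X$subject_ids]),
                          seq_along(case_ids))
          Pfrac <- length(case_ids) / (length(case_ids) +
                                         length(a$X$subject_ids))
          rows[[length(rows) + 1]] <- tibble::tibble(
            arm = a$arm_id, model = if (is_wide) "wide" else "bicl",
            iteration = iter_i, p_tilde = pt, n_snp = n_pass, subtype = stp,
            auc = auc,
            r2_liab = auc_to_liability_r2(max(auc, 0.5), prevalences[[stp]],
                                          Pfrac)
          )
        }
      }
      # pooled across arms: per-arm residuals, pooled ranks
      for (stp in subtypes) {
        case_r <- ctrl_r <- numeric(0)
        for (pa in per_arm) {
          a <- pa$arm
          if (stp != "all" && (is.null(a$subtype) ||
                               !any(a$subtype == stp))) next
          case_ids <- a$D$subject_ids
          if (stp != "all") case_ids <- case_ids[a$subtype[case_ids] == stp]
          case_r <- c(case_r, pa$resid[case_ids])
          ctrl_r <- c(ctrl_r, pa$resid[a$X$subject_ids])
        }
        if (!length(case_r) || !length(ctrl_r)) next
        auc <- rank_auc(c(case_r, ctrl_r), seq_along(case_r))
        Pfrac <- length(case_r) / (length(case_r) + length(ctrl_r))
        rows[[length(rows) + 1]] <- tibble::tibble(
          arm = "pooled", model = if (is_wide) "wide" else "bicl",
          iteration = iter_i, p_tilde = pt, n_snp = n_pass, subtype = stp,
          auc = auc,
          r2_liab = auc_to_liability_r2(max(auc, 0.5), prevalences[[stp]],
                                        Pfrac)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, models = names(models), arms = arm_names,
            class = c("prs_evaluation", class(out)))
}
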