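#' Construct a genotype matrix
#'
#' Container for diploid genotype calls at biallelic SNPs. Calls count copies
#' of the designated minor allele (0, 1 or 2); missing genotypes are `NA`.
#'
#' @param calls Integer matrix, subjects x SNPs, values in `{0, 1, 2, NA}`.
#' @param snp_table Data frame with one row per SNP and columns `snp_id`,
#'   `chr`, `pos` (1-based bp), `allele1` (designated minor), `allele2`.
#' @param subject_ids Character vector of unique subject identifiers.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_table, subject_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snp_table <- tibble::as_tibble(snp_table)
  if (is.null(subject_ids)) {
    subject_ids <- paste0("s", seq_len(nrow(calls)))
  }
  subject_ids <- as.character(subject_ids)
  stopifnot(
    nrow(calls) == length(subject_ids),
    ncol(calls) == nrow(snp_table),
    all(c("snp_id", "chr", "pos") %in% names(snp_table))
  )
  if (anyDuplicated(snp_table$snp_id)) {
    stop("snp ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls must lie in {0, 1, 2, NA}", call. = FALSE)
  }
  dimnames(calls) <- list(subject_ids, snp_table$snp_id)
  structure(
    list(calls = calls, snp_table = snp_table, subject_ids = subject_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d subjects x %d SNPs (%.2f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-SNP minor-allele frequency
#'
#' Frequency of the designated minor allele over all non-missing calls.
#' Missing calls are excluded from the denominator.
#'
#' @param G A [genotype_matrix()].
#' @return Named numeric vector, one frequency per SNP.
#' @export
snp_maf <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_obs <- colSums(!is.na(G$calls))
  counts <- colSums(G$calls, na.rm = TRUE)
  maf <- counts / (2 * n_obs)
  maf[n_obs == 0] <- NA_real_
  stats::setNames(maf, G$snp_table$snp_id)
}

#' Construct an allele-combination matrix
#'
#' Binary subjects x allele-combination matrix: each SNP contributes three
#' one-hot columns (heterozygous, homozygous-minor, homozygous-major). A
#' missing genotype yields `NA` in all three of its columns.
#'
#' @param values Integer matrix, subjects x (3 * n_snp), values `{0, 1, NA}`.
#' @param column_map Data frame with columns `column`, `snp_id`, `combo`
#'   (one of `"het"`, `"hom_minor"`, `"hom_major"`).
#' @param subject_ids Character vector of subject identifiers.
#' @return An object of class `allele_matrix`.
#' @export
allele_matrix <- function(values, column_map, subject_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  column_map <- tibble::as_tibble(column_map)
  subject_ids <- as.character(subject_ids)
  stopifnot(
    ncol(values) == nrow(column_map),
    nrow(values) == length(subject_ids),
    all(c("column", "snp_id", "combo") %in% names(column_map)),
    all(column_map$combo %in% c("het", "hom_minor", "hom_major"))
  )
  dimnames(values) <- list(subject_ids, column_map$column)
  structure(
    list(values = values, column_map = column_map, subject_ids = subject_ids),
    class = "allele_matrix"
  )
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf(
    "<allele_matrix> %d subjects x %d allele-combination columns (%d SNPs)\n",
    nrow(x$values), ncol(x$values), length(unique(x$column_map$snp_id))
  ))
  invisible(x)
}

#' @export
dim.allele_matrix <- function(x) dim(x$values)

#' Construct a cohort arm
#'
#' A paired case array `D` and control array `X` over a shared set of
#' allele-combination columns, with per-subject covariates and optional
#' case subtype labels. This is the unit on which discovery and replication
#' operate.
#'
#' @param geno A [genotype_matrix()] covering all subjects of the arm.
#' @param status Logical or 0/1 vector: `TRUE`/1 for cases. Aligned with the
#'   subjects of `geno`.
#' @param covariates Data frame with `subject_id` plus numeric covariate
#'   columns (ancestry principal components `U1`, `U2`, ..., `sex`, ...).
#' @param subtype Optional character vector of case subtype labels
#'   (`"BDI"`, `"BDII"`, `"other"`), aligned with subjects; ignored entries
#'   for controls.
#' @param arm_id Identifier for the arm.
#'
#' @return An object of class `cohort_arm` with elements `D` and `X`
#'   ([allele_matrix()]s sharing one column map), `covariates`, `subtype`
#'   (named vector over case ids, or `NULL`), `geno` and `arm_id`.
#' @export
cohort_arm <- function(geno, status, covariates, subtype = NULL, arm_id = "arm") {
  stopifnot(inherits(geno, "genotype_matrix"))
  status <- as.logical(status)
  stopifnot(length(status) == length(geno$subject_ids), !anyNA(status))
  covariates <- tibble::as_tibble(covariates)
  stopifnot("subject_id" %in% names(covariates))
  missing_cov <- setdiff(geno$subject_ids, covariates$subject_id)
  if (length(missing_cov)) {
    stop("covariates missing for subjects: ", paste(utils::head(missing_cov, 5), collapse = ", "),
         call. = FALSE)
  }
  covariates <- covariates[match(geno$subject_ids, covariates$subject_id), ]
  am <- encode_allele_combinations(geno)
  case_ids <- geno$subject_ids[status]
  ctrl_ids <- geno$subject_ids[!status]
  if (!length(case_ids) || !length(ctrl_ids)) {
    stop("a cohort arm needs at least one case and one control", call. = FALSE)
  }
  D <- allele_matrix(am$values[status, , drop = FALSE], am$column_map, case_ids)
  X <- allele_matrix(am$values[!status, , drop = FALSE], am$column_map, ctrl_ids)
  st <- NULL
  if (!is.null(subtype)) {
    subtype <- as.character(subtype)
    stopifnot(length(subtype) == length(status))
    st <- stats::setNames(subtype[status], case_ids)
  }
  structure(
    list(
      D = D, X = X, covariates = covariates, subtype = st,
      geno = geno, status = status, arm_id = arm_id
    ),
    class = "cohort_arm"
  )
}

#' @export
print.cohort_arm <- function(x, ...) {
  cat(sprintf(
    "<cohort_arm '%s'> %d cases / %d controls, %d allele-combination columns\n",
    x$arm_id, nrow(x$D$values), nrow(x$X$values), ncol(x$D$values)
  ))
  invisible(x)
}

#' Number of cases / controls in an arm
#' @param arm A [cohort_arm()].
#' @return Named integer vector `c(cases = ..., controls = ...)`.
#' @export
arm_counts <- function(arm) {
  stopifnot(inherits(arm, "cohort_arm"))
  c(cases = nrow(arm$D$values), controls = nrow(arm$X$values))
}

# covariate matrix (subjects x selected covariates), aligned with arm subjects
covariate_matrix <- function(arm, correction) {
  if (is.null(correction) || !length(correction)) {
    return(NULL)
  }
  missing <- setdiff(correction, names(arm$covariates))
  if (length(missing)) {
    stop("correction covariates not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(arm$covariates[, correction, drop = FALSE])
  if (anyNA(m)) stop("correction covariates contain missing values", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- arm$covariates$subject_id
  m
}
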