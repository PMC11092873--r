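#' Read a PLINK 1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet (SNP-major PLINK 1 binary). Calls are
#' recoded so that they count copies of the minor allele as determined from
#' the sample itself: if the `.bim` A1 allele turns out to be the major
#' allele in this sample, the SNP's coding is flipped and `allele1`/`allele2`
#' swapped accordingly.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PLINK files: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bim) < 6) stop("malformed .bim file: expected 6 columns", call. = FALSE)
  names(bim)[1:6] <- c("chr", "snp_id", "cm", "pos", "a1", "a2")
  n_sub <- nrow(fam)
  n_snp <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed .bed magic bytes", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  bytes_per_snp <- ceiling(n_sub / 4)
  if (length(raw) - 3L != bytes_per_snp * n_snp) {
    stop("dimension mismatch between .bed payload and .fam/.bim", call. = FALSE)
  }
  body <- raw[-(1:3)]
  # decode 2-bit codes: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- integer(4)
  lut[1] <- 2L; lut[2] <- NA_integer_; lut[3] <- 1L; lut[4] <- 0L
  ints <- as.integer(body)
  codes <- rbind(
    bitwAnd(ints, 3L),
    bitwAnd(bitwShiftR(ints, 2L), 3L),
    bitwAnd(bitwShiftR(ints, 4L), 3L),
    bitwAnd(bitwShiftR(ints, 6L), 3L)
  )
  dim(codes) <- c(4L * bytes_per_snp, n_snp)
  calls <- matrix(lut[codes[seq_len(n_sub), , drop = FALSE] + 1L], n_sub, n_snp)
  subject_ids <- as.character(fam[[2]])
  # designate minor allele from the sample itself
  freq_a1 <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
  flip <- !is.na(freq_a1) & freq_a1 > 0.5
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    tmp <- bim$a1[flip]
    bim$a1[flip] <- bim$a2[flip]
    bim$a2[flip] <- tmp
  }
  snp_table <- tibble::tibble(
    snp_id = as.character(bim$snp_id), chr = as.character(bim$chr),
    pos = as.integer(bim$pos), allele1 = bim$a1, allele2 = bim$a2
  )
  genotype_matrix(calls, snp_table, subject_ids)
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]; writes SNP-major `.bed` plus `.bim`/`.fam`.
#' Calls are written with A1 = the designated minor allele, so a round trip
#' through [read_plink()] reproduces the calls exactly (up to per-SNP flips
#' when the stored minor allele has sample frequency exactly 0.5).
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_sub <- nrow(G$calls)
  n_snp <- ncol(G$calls)
  fam <- data.frame(
    fid = G$subject_ids, iid = G$subject_ids,
    pat = 0L, mat = 0L, sex = 0L, pheno = -9L
  )
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  st <- G$snp_table
  a1 <- if ("allele1" %in% names(st)) st$allele1 else rep("A", n_snp)
  a2 <- if ("allele2" %in% names(st)) st$allele2 else rep("B", n_snp)
  bim <- data.frame(chr = st$chr, snp_id = st$snp_id, cm = 0L, pos = st$pos,
                    a1 = a1, a2 = a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # encode calls (copies of A1) to 2-bit codes
  enc <- matrix(1L, nrow = 4L * ceiling(n_sub / 4), ncol = n_snp)  # 01 missing
  code_lut <- c(3L, 2L, 0L)  # genotype 0,1,2 -> code
  codes <- matrix(NA_integer_, n_sub, n_snp)
  obs <- !is.na(G$calls)
  codes[obs] <- code_lut[G$calls[obs] + 1L]
  codes[!obs] <- 1L
  enc[seq_len(n_sub), ] <- codes
  packed <- enc[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * enc[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * enc[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * enc[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(packed), con)
  invisible(prefix)
}

#' Read / write genotypes as plain TSV
#'
#' Text dialect: a subjects x SNPs table of `{0, 1, 2, NA}` with a
#' `subject_id` column and SNP ids as column names, plus an optional SNP
#' information table (`snp_id`, `chr`, `pos`, `allele1`, `allele2`). When no
#' SNP table is supplied, SNPs are placed on chromosome 1 at 100 kb spacing.
#'
#' @param path Path to the genotype TSV.
#' @param snp_path Optional path to the SNP information TSV.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, snp_path = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot("subject_id" %in% names(tab))
  subject_ids <- as.character(tab$subject_id)
  calls <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  storage.mode(calls) <- "integer"
  if (!is.null(snp_path)) {
    snp_table <- readr::read_tsv(snp_path, show_col_types = FALSE, progress = FALSE)
    snp_table <- snp_table[match(colnames(calls), snp_table$snp_id), ]
  } else {
    snp_table <- tibble::tibble(
      snp_id = colnames(calls), chr = "1",
      pos = 100000L * seq_len(ncol(calls)),
      allele1 = "A", allele2 = "B"
    )
  }
  genotype_matrix(calls, snp_table, subject_ids)
}

#' @rdname read_genotype_tsv
#' @param G A [genotype_matrix()] to write.
#' @export
write_genotype_tsv <- function(G, path, snp_path = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- tibble::as_tibble(G$calls)
  tab <- dplyr::bind_cols(tibble::tibble(subject_id = G$subject_ids), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(snp_path)) {
    readr::write_tsv(G$snp_table, snp_path, progress = FALSE)
  }
  invisible(path)
}

#' Filter SNPs by minor-allele frequency
#'
#' Retains exactly the SNPs whose minor-allele frequency, computed over all
#' non-missing calls of the supplied sample (cases and controls pooled), is
#' strictly greater than `threshold`. The subject set is unchanged.
#'
#' @param G A [genotype_matrix()].
#' @param threshold Frequency in `[0, 0.5]`.
#' @return A filtered [genotype_matrix()].
#' @export
maf_filter <- function(G, threshold = 0.25) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5) {
    stop("maf threshold must lie in [0, 0.5]", call. = FALSE)
  }
  maf <- snp_maf(G)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) {
    warning("maf_filter removed every SNP", call. = FALSE)
  }
  genotype_matrix(
    G$calls[, keep, drop = FALSE],
    G$snp_table[keep, , drop = FALSE],
    G$subject_ids
  )
}

#' One-hot allele-combination encoding
#'
#' Expands each SNP into three binary columns: heterozygous (`het`, genotype
#' 1), homozygous-minor (`hom_minor`, genotype 2) and homozygous-major
#' (`hom_major`, genotype 0). For a non-missing genotype exactly one of the
#' three columns is 1; a missing genotype propagates `NA` into all three.
#'
#' @param G A [genotype_matrix()].
#' @return An [allele_matrix()] with `3 * n_snp` columns.
#' @export
encode_allele_combinations <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  calls <- G$calls
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls outside {0, 1, 2, NA}", call. = FALSE)
  }
  n_snp <- ncol(calls)
  combos <- c("het", "hom_minor", "hom_major")
  genos <- c(het = 1L, hom_minor = 2L, hom_major = 0L)
  values <- matrix(NA_integer_, nrow(calls), 3L * n_snp)
  for (c_i in 1:3) {
    cols <- seq.int(c_i, by = 3L, length.out = n_snp)
    values[, cols] <- (calls == genos[[c_i]]) + 0L
  }
  column_map <- tibble::tibble(
    snp_id = rep(G$snp_table$snp_id, each = 3L),
    combo = rep(combos, n_snp)
  )
  column_map$column <- paste(column_map$snp_id, column_map$combo, sep = ":")
  allele_matrix(values, column_map[, c("column", "snp_id", "combo")],
                G$subject_ids)
}

#' Decode allele-combinations back to genotypes
#'
#' Inverse of [encode_allele_combinations()]: reconstructs the subjects x
#' SNPs call matrix from the one-hot columns. Cells whose three columns are
#' all `NA` decode to `NA`.
#'
#' @param A An [allele_matrix()].
#' @return A [genotype_matrix()] (with a minimal SNP table if `snp_table`
#'   is not supplied).
#' @param snp_table Optional SNP table to attach.
#' @export
decode_allele_combinations <- function(A, snp_table = NULL) {
  stopifnot(inherits(A, "allele_matrix"))
  snp_ids <- unique(A$column_map$snp_id)
  geno_of <- c(het = 1L, hom_minor = 2L, hom_major = 0L)
  calls <- matrix(NA_integer_, nrow(A$values), length(snp_ids),
                  dimnames = list(A$subject_ids, snp_ids))
  for (combo in names(geno_of)) {
    sel <- A$column_map$combo == combo
    v <- A$values[, sel, drop = FALSE]
    idx <- which(v == 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      snp_idx <- match(A$column_map$snp_id[sel][idx[, 2]], snp_ids)
      calls[cbind(idx[, 1], snp_idx)] <- geno_of[[combo]]
    }
  }
  if (is.null(snp_table)) {
    snp_table <- tibble::tibble(
      snp_id = snp_ids, chr = "1", pos = 100000L * seq_along(snp_ids),
      allele1 = "A", allele2 = "B"
    )
  }
  genotype_matrix(calls, snp_table, A$subject_ids)
}

#' SNP overlap between two arms
#'
#' Shared SNP set and Szymkiewicz-Simpson overlap coefficient
#' `|A ∩ B| / min(|A|, |B|)` over the SNP id sets of the two arms.
#'
#' @param arm_a,arm_b [cohort_arm()]s (or [genotype_matrix()]s).
#' @return A list with `shared` (character vector) and `coefficient`.
#' @export
snp_overlap <- function(arm_a, arm_b) {
  ids <- function(x) {
    if (inherits(x, "cohort_arm")) unique(x$D$column_map$snp_id)
    else if (inherits(x, "genotype_matrix")) x$snp_table$snp_id
    else as.character(x)
  }
  a <- ids(arm_a)
  b <- ids(arm_b)
  if (!length(a) || !length(b)) {
    stop("snp_overlap requires non-empty SNP sets", call. = FALSE)
  }
  shared <- intersect(a, b)
  list(shared = shared,
       coefficient = length(shared) / min(length(a), length(b)))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (pathway -> genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    stop("malformed GMT: every row needs name, description and >= 1 gene",
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP-to-gene annotation table
#'
#' Two-column TSV (`snp_id`, `gene`), possibly many SNPs per gene. A header
#' row is detected if the first line names the columns.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `snp_id` and `gene`.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("snp_id", first, fixed = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:2] <- c("snp_id", "gene")
  tibble::as_tibble(tab[, c("snp_id", "gene")])
}

#' Read / write a covariate table
#'
#' TSV with `subject_id` plus numeric covariates (`U1`..`U20`, `sex`, ...)
#' and optional `status` / `subtype` columns.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_covariates_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_covariates_tsv
#' @param covariates Data frame to write.
#' @export
write_covariates_tsv <- function(covariates, path) {
  readr::write_tsv(tibble::as_tibble(covariates), path, progress = FALSE)
  invisible(path)
}
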