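#' Select correction covariates by nested logistic regression
#'
#' Candidates are tested in index order; each is added to a logistic model of
#' case/control status containing the previously selected covariates, and
#' kept if the likelihood-ratio test for its addition is significant at
#' `alpha`.
#'
#' @param covariates Data frame with the candidate columns.
#' @param status Logical/0-1 case indicator aligned with the rows.
#' @param candidates Character vector of candidate column names, in test
#'   order (default: all `U<k>` columns present, in index order).
#' @param alpha Significance level for the likelihood-ratio test.
#' @return Character vector of selected covariate names (ordered as tested).
#' @export
select_correction_covariates <- function(covariates, status,
                                         candidates = NULL, alpha = 0.05) {
  covariates <- tibble::as_tibble(covariates)
  y <- as.numeric(as.logical(status))
  stopifnot(length(y) == nrow(covariates), length(unique(y)) == 2)
  if (is.null(candidates)) {
    u_cols <- grep("^U[0-9]+$", names(covariates), value = TRUE)
    candidates <- u_cols[order(as.integer(sub("^U", "", u_cols)))]
  }
  if (length(candidates) < 1) stop("no candidate covariates", call. = FALSE)
  selected <- character(0)
  dev0 <- suppressWarnings(
    stats::glm(y ~ 1, family = stats::binomial())$deviance
  )
  base_mat <- NULL
  for (cand in candidates) {
    v <- covariates[[cand]]
    if (is.null(v)) stop("candidate covariate not found: ", cand, call. = FALSE)
    if (stats::sd(v) == 0) {
      warning("covariate '", cand, "' has zero variance; excluded",
              call. = FALSE)
      next
    }
    xmat <- cbind(base_mat, v)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, xmat), y,
                                      family = stats::binomial())),
      error = function(e) {
        stop("logistic fit failed for covariate '", cand, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    p <- stats::pchisq(dev0 - fit$deviance, df = 1, lower.tail = FALSE)
    if (!is.na(p) && p < alpha) {
      selected <- c(selected, cand)
      base_mat <- xmat
      dev0 <- fit$deviance
    }
  }
  selected
}

#' Gaussian-kernel covariate weights
#'
#' For each case, nonnegative weights over the other cases and over the
#' controls, decaying with squared distance in (standardised)
#' covariate-space: `w(j, j') = exp(-||c_j - c_j'||^2 / (2 b^2))`. The
#' self-weight is zero. These weights replace the uniform sharing fractions
#' in [compute_q()], damping differential expression contributed by
#' structures that are unevenly distributed in covariate-space.
#'
#' @param arm A [cohort_arm()].
#' @param correction Character vector of covariate columns. Empty/`NULL`
#'   yields uniform weights (documented fallback).
#' @param bandwidth Positive kernel bandwidth, or `"auto"`: the median
#'   pairwise distance among a deterministic subsample of at most 500
#'   subjects.
#' @return List with `WDD` (cases x cases, zero diagonal, rows summing to 1)
#'   and `WDX` (cases x controls, rows summing to 1), plus the `bandwidth`
#'   used.
#' @export
covariate_weights <- function(arm, correction, bandwidth = "auto") {
  M <- nrow(arm$D$values)
  MX <- nrow(arm$X$values)
  uniform <- function() {
    WDD <- matrix(1 / max(1, M - 1), M, M)
    diag(WDD) <- 0
    WDX <- matrix(1 / MX, M, MX)
    list(WDD = WDD, WDX = WDX, bandwidth = Inf)
  }
  if (is.null(correction) || !length(correction)) {
    return(uniform())
  }
  cov_all <- covariate_matrix(arm, correction)
  cov_all <- scale(cov_all)
  cov_all[is.nan(cov_all)] <- 0  # zero-variance column
  case_ids <- arm$D$subject_ids
  ctrl_ids <- arm$X$subject_ids
  cd <- cov_all[match(case_ids, rownames(cov_all)), , drop = FALSE]
  cx <- cov_all[match(ctrl_ids, rownames(cov_all)), , drop = FALSE]
  if (identical(bandwidth, "auto")) {
    n <- nrow(cov_all)
    sub <- cov_all[unique(round(seq(1, n, length.out = min(500, n)))), ,
                   drop = FALSE]
    bandwidth <- stats::median(stats::dist(sub))
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      return(uniform())
    }
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  sqd <- function(A, B) {
    # squared Euclidean distances, rows of A x rows of B
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    outer(an, bn, "+") - 2 * tcrossprod(A, B)
  }
  WDD <- exp(-pmax(sqd(cd, cd), 0) / (2 * bandwidth^2))
  diag(WDD) <- 0
  WDX <- exp(-pmax(sqd(cd, cx), 0) / (2 * bandwidth^2))
  WDD <- WDD / pmax(rowSums(WDD), .Machine$double.eps)
  WDX <- WDX / pmax(rowSums(WDX), .Machine$double.eps)
  list(WDD = WDD, WDX = WDX, bandwidth = bandwidth)
}

#' Half-loop differential-sharing scores
#'
#' For each case `j` and allele-combination column `k`, the score
#' `Q[j, k]` is the (weighted) fraction of *other* cases sharing the cell's
#' binary value minus the (weighted) fraction of controls sharing it.
#' "Sharing" means equality of the binary value (both 1 or both 0), which
#' makes `Q` well defined for every cell. Missing cells contribute 0 and are
#' excluded from all denominators; a column with no observed controls (or
#' fewer than two observed cases) scores 0 with a warning.
#'
#' @param D Case [allele_matrix()] (or plain binary matrix).
#' @param X Control [allele_matrix()] (or matrix) over the same columns.
#' @param weights Optional list with `WDD`/`WDX` from [covariate_weights()];
#'   `NULL` means uniform weights.
#' @return An object of class `qscores`: list with the `q` matrix,
#'   `row_scores`, `col_scores` and the `trace` (sum over all cells).
#' @export
compute_q <- function(D, X, weights = NULL) {
  Dv <- if (inherits(D, "allele_matrix")) D$values else as.matrix(D)
  Xv <- if (inherits(X, "allele_matrix")) X$values else as.matrix(X)
  stopifnot(ncol(Dv) == ncol(Xv), nrow(Dv) >= 2)
  M <- nrow(Dv); N <- ncol(Dv)
  OD <- !is.na(Dv)
  OX <- !is.na(Xv)
  D0 <- ifelse(OD, Dv, 0)
  X0 <- ifelse(OX, Xv, 0)
  xo <- colSums(OX)
  x1 <- colSums(X0)
  if (any(xo == 0)) {
    warning("column(s) missing in all controls score 0", call. = FALSE)
  }
  if (is.null(weights)) {
    m <- colSums(OD)
    s1 <- colSums(D0)
    Mm <- matrix(m, M, N, byrow = TRUE)
    S1 <- matrix(s1, M, N, byrow = TRUE)
    fdd <- (Dv * (S1 - 1) + (1 - Dv) * (Mm - S1 - 1)) / (Mm - 1)
    XOm <- matrix(xo, M, N, byrow = TRUE)
    X1m <- matrix(x1, M, N, byrow = TRUE)
    fdx <- (Dv * X1m + (1 - Dv) * (XOm - X1m)) / XOm
    q <- fdd - fdx
    q[!OD] <- 0
    q[, m < 2] <- 0
    q[, xo == 0] <- 0
  } else {
    WDD <- weights$WDD
    WDX <- weights$WDX
    P1 <- WDD %*% D0
    PO <- WDD %*% OD
    PX1 <- WDX %*% X0
    PXO <- WDX %*% OX
    fdd <- (Dv * P1 + (1 - Dv) * (PO - P1)) / PO
    fdx <- (Dv * PX1 + (1 - Dv) * (PXO - PX1)) / PXO
    q <- fdd - fdx
    q[!OD] <- 0
    q[PO <= 1e-12 | PXO <= 1e-12] <- 0
  }
  dimnames(q) <- dimnames(Dv)
  structure(
    list(q = q, row_scores = rowSums(q), col_scores = colSums(q),
         trace = sum(q)),
    class = "qscores"
  )
}

#' @export
print.qscores <- function(x, ...) {
  cat(sprintf("<qscores> %d cases x %d columns, trace = %.4f\n",
              nrow(x$q), ncol(x$q), x$trace))
  invisible(x)
}

#' Run the half-loop biclustering algorithm
#'
#' Iteratively computes the differential-sharing scores of the retained case
#' submatrix against the full control array, then removes the
#' `max(1, round(gamma * remaining))` cases and columns with the lowest row-
#' and column-scores (ties broken by ascending original index), until cases
#' or columns are exhausted. Controls are never removed. With a non-empty
#' `correction` set, Gaussian-kernel covariate weights dampen structure that
#' is unevenly distributed in covariate-space.
#'
#' @param arm A [cohort_arm()].
#' @param gamma Elimination fraction per iteration, in `(0, 0.5]`. Default
#'   `0.5^8` (about 0.004).
#' @param correction Character vector of covariate columns to correct for
#'   (e.g. `c("U1", "U2")`), or `NULL` for no correction.
#' @param bandwidth Kernel bandwidth for [covariate_weights()].
#' @return An object of class `bicluster_trace`: per-iteration records
#'   (`iteration`, `M`, `N`, `trace`, `trace_col`), elimination iterations
#'   for every case and column, and the run parameters. Use
#'   [trace_members()] to reconstruct the retained sets at any iteration.
#' @export
halfloop_run <- function(arm, gamma = 0.5^8, correction = NULL,
                         bandwidth = "auto") {
  stopifnot(inherits(arm, "cohort_arm"))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0 || gamma > 0.5) {
    stop("gamma must lie in (0, 0.5]", call. = FALSE)
  }
  w <- NULL
  if (!is.null(correction) && length(correction)) {
    w <- covariate_weights(arm, correction, bandwidth)
  }
  res <- halfloop_core(
    arm$D$values, arm$X$values, gamma,
    if (is.null(w)) NULL else w$WDD,
    if (is.null(w)) NULL else w$WDX
  )
  structure(
    list(
      iterations = tibble::tibble(
        iteration = res$iteration, M = res$M, N = res$N,
        trace = res$trace, trace_col = res$trace_col
      ),
      row_elim = stats::setNames(res$row_elim, arm$D$subject_ids),
      col_elim = stats::setNames(res$col_elim, colnames(arm$D$values)),
      case_ids = arm$D$subject_ids,
      col_ids = colnames(arm$D$values),
      column_map = arm$D$column_map,
      gamma = gamma,
      correction = correction,
      arm_id = arm$arm_id
    ),
    class = "bicluster_trace"
  )
}

#' @export
print.bicluster_trace <- function(x, ...) {
  n_it <- nrow(x$iterations)
  cat(sprintf(
    "<bicluster_trace '%s'> %d iterations, %d cases x %d columns at start, gamma = %.4g\n",
    x$arm_id, n_it, x$iterations$M[1], x$iterations$N[1], x$gamma
  ))
  invisible(x)
}

#' Retained case and column sets at an iteration
#'
#' @param trace A `bicluster_trace` from [halfloop_run()].
#' @param i Iteration index (1-based; members are those present while the
#'   iteration's scores were computed).
#' @return List with `J` (retained case ids) and `K` (retained column
#'   names).
#' @export
trace_members <- function(trace, i) {
  stopifnot(inherits(trace, "bicluster_trace"), i >= 1)
  re <- trace$row_elim
  ce <- trace$col_elim
  list(
    J = names(re)[is.na(re) | re >= i],
    K = names(ce)[is.na(ce) | ce >= i]
  )
}

#' Swap case and control roles
#'
#' Returns a new arm in which the controls play the role of cases and vice
#' versa, so that [halfloop_run()] searches for control-specific biclusters.
#' Subtype labels (a case-side concept) are dropped; covariates are
#' preserved.
#'
#' @param arm A [cohort_arm()].
#' @return A [cohort_arm()] with `D` and `X` swapped.
#' @export
reverse_labels <- function(arm) {
  stopifnot(inherits(arm, "cohort_arm"))
  out <- arm
  out$D <- arm$X
  out$X <- arm$D
  out$subtype <- NULL
  out$status <- !arm$status
  out$arm_id <- paste0(arm$arm_id, "_reversed")
  out
}

#' Scramble a submatrix of the case array
#'
#' Within each selected column, the entries restricted to the selected rows
#' are randomly permuted, preserving the column margins within the block and
#' leaving everything outside the block untouched. Used to erase a recovered
#' bicluster before searching for secondary structure.
#'
#' @param D An [allele_matrix()].
#' @param rows Subject ids (or indices) of the block rows.
#' @param cols Column names (or indices) of the block columns.
#' @param seed Integer seed; the scramble is deterministic given the seed.
#' @return A new [allele_matrix()].
#' @export
scramble_submatrix <- function(D, rows, cols, seed = 1) {
  stopifnot(inherits(D, "allele_matrix"))
  ri <- if (is.character(rows)) match(rows, D$subject_ids) else as.integer(rows)
  ci <- if (is.character(cols)) match(cols, colnames(D$values)) else as.integer(cols)
  if (anyNA(ri) || anyNA(ci)) stop("unknown rows or cols", call. = FALSE)
  if (!length(ri) || !length(ci)) {
    warning("empty block: nothing scrambled", call. = FALSE)
    return(D)
  }
  vals <- D$values
  with_rng_seed(seed, {
    for (k in ci) {
      vals[ri, k] <- vals[ri[sample.int(length(ri))], k]
    }
  })
  allele_matrix(vals, D$column_map, D$subject_ids)
}

#' Subtype composition along the trace
#'
#' Fraction of label-positive cases among the retained case set at each
#' iteration, with a one-sided hypergeometric enrichment p-value relative to
#' the iteration-1 proportion (drawing `M(i)` cases from the initial pool).
#'
#' @param trace A `bicluster_trace`.
#' @param labels Named logical vector over the initial cases (`TRUE` =
#'   positive, e.g. BDI).
#' @return Tibble with `iteration`, `n_retained`, `n_positive`, `fraction`,
#'   `p_enrichment`.
#' @export
membership_composition <- function(trace, labels) {
  stopifnot(inherits(trace, "bicluster_trace"))
  labels <- labels[!is.na(labels)]
  pool <- intersect(trace$case_ids, names(labels))
  if (length(pool) < length(trace$case_ids)) {
    warning("label missing for ", length(trace$case_ids) - length(pool),
            " case(s); excluded", call. = FALSE)
  }
  K1 <- sum(labels[pool])
  M1 <- length(pool)
  re <- trace$row_elim[pool]
  its <- trace$iterations$iteration
  out <- lapply(its, function(i) {
    retained <- pool[is.na(re) | re >= i]
    n <- length(retained)
    x <- sum(labels[retained])
    p <- if (n == 0) NA_real_ else
      stats::phyper(x - 1, K1, M1 - K1, n, lower.tail = FALSE)
    tibble::tibble(iteration = i, n_retained = n, n_positive = x,
                   fraction = if (n) x / n else NA_real_, p_enrichment = p)
  })
  dplyr::bind_rows(out)
}

# evaluate expr with a local RNG seed, restoring global state afterwards
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
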