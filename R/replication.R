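#' Restrict a retained column set to a replication arm
#'
#' Intersection of the training-arm column set with the columns available in
#' the replication arm, matched by (SNP id, combination) identity.
#'
#' @param K_i Character vector of retained column names (from
#'   [trace_members()]).
#' @param rep_arm A [cohort_arm()] (the replication arm).
#' @return Character vector of the shared columns, with attribute
#'   `retention` = `N'(i) / N(i)`.
#' @export
restrict_columns <- function(K_i, rep_arm) {
  stopifnot(inherits(rep_arm, "cohort_arm"))
  shared <- intersect(K_i, colnames(rep_arm$D$values))
  if (!length(shared)) {
    stop("no columns shared with the replication arm; replication impossible",
         call. = FALSE)
  }
  attr(shared, "retention") <- length(shared) / length(K_i)
  shared
}

#' Dominant principal component of a bicluster submatrix
#'
#' The leading right-singular vector of the column-centred `M(i) x N'(i)`
#' submatrix of the training cases (centring by the training-case column
#' means over the retained rows). The sign is oriented so that the
#' covariate-adjusted training AUC of the resulting scores is at least 0.5.
#'
#' @param train_arm A [cohort_arm()] (the training arm).
#' @param J_i Retained case ids.
#' @param Kp_i Restricted column names (see [restrict_columns()]).
#' @param correction Covariate columns used when orienting the sign.
#' @return An object of class `bicluster_axis`: unit vector `v` over
#'   `columns`, the centring `centers`, the training AUC after orientation,
#'   and whether the sign was flipped.
#' @export
bicluster_axis <- function(train_arm, J_i, Kp_i, correction = NULL) {
  stopifnot(inherits(train_arm, "cohort_arm"), length(J_i) >= 2,
            length(Kp_i) >= 1)
  sub <- train_arm$D$values[match(J_i, train_arm$D$subject_ids), Kp_i,
                            drop = FALSE]
  if (anyNA(match(J_i, train_arm$D$subject_ids))) {
    stop("unknown case ids in J_i", call. = FALSE)
  }
  centers <- colMeans(sub, na.rm = TRUE)
  centers[is.nan(centers)] <- 0
  Ac <- sweep(sub, 2, centers)
  Ac[is.na(Ac)] <- 0
  if (all(Ac == 0)) stop("zero matrix after centring", call. = FALSE)
  v <- leading_right_singular(Ac)
  axis <- structure(
    list(columns = Kp_i, v = v, centers = centers, flipped = FALSE,
         train_auc = NA_real_),
    class = "bicluster_axis"
  )
  # orient: training covariate-adjusted AUC >= 0.5
  uD <- bicluster_scores(train_arm$D, axis)
  uX <- bicluster_scores(train_arm$X, axis)
  cov <- arm_case_control_covariates(train_arm, correction)
  a <- covariate_adjusted_auc(uD, uX, cov)
  if (a < 0.5) {
    axis$v <- -axis$v
    axis$flipped <- TRUE
    a <- 1 - a
  }
  axis$train_auc <- a
  axis
}

# leading right-singular vector; exact LAPACK SVD for small problems, power
# iteration with a deterministic start otherwise
leading_right_singular <- function(A, tol = 1e-12, max_iter = 1000) {
  if (length(A) <= 262144 || min(dim(A)) <= 3) {
    return(svd(A, nu = 0, nv = 1)$v[, 1])
  }
  v <- sqrt(colSums(A^2))
  nv <- sqrt(sum(v^2))
  if (nv == 0) v[1] <- 1 else v <- v / nv
  sigma_old <- 0
  for (i in seq_len(max_iter)) {
    w <- A %*% v
    v_new <- crossprod(A, w)
    sigma <- sqrt(sqrt(sum(v_new^2)))
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) break
    v_new <- as.numeric(v_new / nrm)
    if (sum((v_new - v)^2) < tol^2 || abs(sigma - sigma_old) < tol * sigma) {
      v <- v_new
      break
    }
    v <- v_new
    sigma_old <- sigma
  }
  v
}

#' Project subjects onto a bicluster axis
#'
#' Per-subject bicluster score: the inner product of the subject's row
#' (restricted to the axis columns, minus the stored centring means) with
#' the axis vector. Missing cells are treated as the centring mean and so
#' contribute 0.
#'
#' @param B An [allele_matrix()] containing all axis columns.
#' @param axis A [bicluster_axis()].
#' @return Named numeric vector of scores.
#' @export
bicluster_scores <- function(B, axis) {
  stopifnot(inherits(axis, "bicluster_axis"))
  vals <- if (inherits(B, "allele_matrix")) B$values else as.matrix(B)
  miss <- setdiff(axis$columns, colnames(vals))
  if (length(miss)) {
    stop("matrix lacks axis columns: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  sub <- vals[, axis$columns, drop = FALSE]
  centred <- sweep(sub, 2, axis$centers)
  centred[is.na(centred)] <- 0
  u <- as.numeric(centred %*% axis$v)
  stats::setNames(u, rownames(vals))
}

#' Covariate-adjusted AUC
#'
#' Scores of cases and controls are pooled and residualised on the
#' correction covariates by least squares; the AUC is then the Mann-Whitney
#' statistic of the residualised scores, with ties counted one half.
#'
#' @param scores_cases,scores_controls Numeric score vectors.
#' @param covariates Optional numeric matrix/data frame with
#'   `length(scores_cases) + length(scores_controls)` rows (cases first), or
#'   `NULL` for the unadjusted AUC.
#' @return AUC in `[0, 1]`; attribute `degenerate` is `TRUE` when the
#'   residual scores are constant (AUC reported as 0.5).
#' @export
covariate_adjusted_auc <- function(scores_cases, scores_controls,
                                   covariates = NULL) {
  n1 <- length(scores_cases)
  n0 <- length(scores_controls)
  stopifnot(n1 > 0, n0 > 0)
  s <- c(scores_cases, scores_controls)
  if (!is.null(covariates)) {
    X <- cbind(1, as.matrix(covariates))
    stopifnot(nrow(X) == n1 + n0)
    s <- stats::lm.fit(X, s)$residuals
  }
  if (max(s) - min(s) < .Machine$double.eps * max(1, abs(max(s)))) {
    return(structure(0.5, degenerate = TRUE))
  }
  r <- rank(s)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, degenerate = FALSE)
}

# stacked covariate matrix for (cases, controls) of an arm, or NULL
arm_case_control_covariates <- function(arm, correction,
                                        case_ids = arm$D$subject_ids,
                                        ctrl_ids = arm$X$subject_ids) {
  if (is.null(correction) || !length(correction)) return(NULL)
  cm <- covariate_matrix(arm, correction)
  rbind(cm[match(case_ids, rownames(cm)), , drop = FALSE],
        cm[match(ctrl_ids, rownames(cm)), , drop = FALSE])
}

#' Replication curve of bicluster AUCs
#'
#' For each evaluated iteration, builds the bicluster axis from the training
#' arm (restricted to the columns available in the replication arm), scores
#' both arms, and computes the covariate-adjusted training AUC `A(i)` and
#' replication AUC `A'(i)`. Per-iteration p-values and the overall p-value
#' of the interval average `Abar'` come from label shuffles of the
#' replication arm within covariate bins (one shuffle per trial, shared
#' across iterations). Because residualisation does not involve the labels,
#' shuffles only permute the group split of precomputed residual scores.
#'
#' @param trace A `bicluster_trace` from the training arm.
#' @param train_arm,rep_arm [cohort_arm()]s.
#' @param interval Iteration interval (integer vector or `c(lo, hi)`); the
#'   average `Abar'` is taken over the evaluated iterations inside it.
#' @param iterations Iterations at which to evaluate; default: up to
#'   `max_points` evenly spaced iterations spanning the interval.
#' @param n_trials Label-shuffle trials for the null.
#' @param correction_train,correction_rep Covariate columns for adjusting
#'   the training and replication AUCs.
#' @param n_bins,seed Shuffling bins and seed.
#' @param max_points Cap on the number of evaluated iterations.
#' @return Object of class `replication_curve`: tibble `curve` with columns
#'   `iteration`, `M`, `N`, `n_cols`, `A`, `A_rep`, `p_A`, `p_A_rep`;
#'   `Abar`, `p_Abar`, `interval`, `n_trials`.
#' @export
replication_curve <- function(trace, train_arm, rep_arm, interval,
                              iterations = NULL, n_trials = 100,
                              correction_train = NULL,
                              correction_rep = NULL,
                              n_bins = 8, seed = 1, max_points = 120) {
  stopifnot(inherits(trace, "bicluster_trace"),
            inherits(train_arm, "cohort_arm"),
            inherits(rep_arm, "cohort_arm"))
  if (!length(interval)) stop("empty iteration interval", call. = FALSE)
  interval <- range(interval)
  it_tab <- trace$iterations
  usable <- it_tab$iteration[it_tab$M >= 2 & it_tab$N >= 1]
  if (is.null(iterations)) {
    cand <- usable[usable >= interval[1] & usable <= interval[2]]
    if (!length(cand)) stop("interval outside the trace range", call. = FALSE)
    iterations <- unique(round(seq(min(cand), max(cand),
                                   length.out = min(max_points, length(cand)))))
  }
  iterations <- sort(intersect(iterations, usable))
  if (!length(iterations)) stop("no usable iterations", call. = FALSE)

  cov_train <- arm_case_control_covariates(train_arm, correction_train)
  cov_rep <- arm_case_control_covariates(rep_arm, correction_rep)
  n1r <- nrow(rep_arm$D$values)
  n0r <- nrow(rep_arm$X$values)
  n1t <- nrow(train_arm$D$values)
  n0t <- nrow(train_arm$X$values)

  A <- A_rep <- numeric(length(iterations))
  rep_resid <- matrix(NA_real_, n1r + n0r, length(iterations))
  train_resid <- matrix(NA_real_, n1t + n0t, length(iterations))
  n_cols <- integer(length(iterations))
  for (ii in seq_along(iterations)) {
    mem <- trace_members(trace, iterations[ii])
    Kp <- restrict_columns(mem$K, rep_arm)
    n_cols[ii] <- length(Kp)
    axis <- bicluster_axis(train_arm, mem$J, Kp, correction_train)
    uD <- bicluster_scores(train_arm$D, axis)
    uX <- bicluster_scores(train_arm$X, axis)
    s_t <- c(uD, uX)
    if (!is.null(cov_train)) {
      s_t <- stats::lm.fit(cbind(1, cov_train), s_t)$residuals
    }
    train_resid[, ii] <- s_t
    A[ii] <- axis$train_auc
    uDr <- bicluster_scores(rep_arm$D, axis)
    uXr <- bicluster_scores(rep_arm$X, axis)
    s_r <- c(uDr, uXr)
    if (!is.null(cov_rep)) {
      s_r <- stats::lm.fit(cbind(1, cov_rep), s_r)$residuals
    }
    rep_resid[, ii] <- s_r
    A_rep[ii] <- rank_auc(s_r, seq_len(n1r))
  }
  Abar <- mean(A_rep)

  # label-shuffle null: permute the case/control split within covariate bins
  rep_bins <- label_bins(rep_arm, correction_rep, n_bins)
  train_bins <- label_bins(train_arm, correction_train, n_bins)
  trial_seeds <- with_rng_seed(seed, sample.int(.Machine$integer.max - 1,
                                                n_trials))
  rep_ranks <- apply(rep_resid, 2, rank)
  train_ranks <- apply(train_resid, 2, rank)
  null_A <- matrix(NA_real_, n_trials, length(iterations))
  null_Ar <- matrix(NA_real_, n_trials, length(iterations))
  for (t in seq_len(n_trials)) {
    idx_r <- with_rng_seed(trial_seeds[t],
                           permute_within_bins(n1r + n0r, rep_bins))
    case_r <- which(idx_r <= n1r)
    idx_t <- with_rng_seed(trial_seeds[t] + 1L,
                           permute_within_bins(n1t + n0t, train_bins))
    case_t <- which(idx_t <= n1t)
    null_Ar[t, ] <- (colSums(rep_ranks[case_r, , drop = FALSE]) -
                       n1r * (n1r + 1) / 2) / (n1r * n0r)
    null_A[t, ] <- (colSums(train_ranks[case_t, , drop = FALSE]) -
                      n1t * (n1t + 1) / 2) / (n1t * n0t)
  }
  p_A <- vapply(seq_along(iterations), function(ii) {
    (1 + sum(null_A[, ii] >= A[ii])) / (n_trials + 1)
  }, 1)
  p_Ar <- vapply(seq_along(iterations), function(ii) {
    (1 + sum(null_Ar[, ii] >= A_rep[ii])) / (n_trials + 1)
  }, 1)
  null_Abar <- rowMeans(null_Ar)
  p_Abar <- (1 + sum(null_Abar >= Abar)) / (n_trials + 1)

  it_rows <- match(iterations, it_tab$iteration)
  structure(
    list(
      curve = tibble::tibble(
        iteration = iterations,
        M = it_tab$M[it_rows], N = it_tab$N[it_rows],
        n_cols = n_cols, A = A, A_rep = A_rep, p_A = p_A, p_A_rep = p_Ar
      ),
      Abar = Abar, p_Abar = p_Abar, null_Abar = null_Abar,
      interval = interval, n_trials = n_trials,
      train_arm_id = train_arm$arm_id, rep_arm_id = rep_arm$arm_id
    ),
    class = "replication_curve"
  )
}

#' @export
print.replication_curve <- function(x, ...) {
  cat(sprintf(
    "<replication_curve %s -> %s> %d iterations in [%d, %d], Abar' = %.3f (p = %.4g)\n",
    x$train_arm_id, x$rep_arm_id, nrow(x$curve),
    x$interval[1], x$interval[2], x$Abar, x$p_Abar
  ))
  invisible(x)
}

# AUC from a residual score vector and the case index set
rank_auc <- function(scores, case_idx) {
  r <- rank(scores)
  n1 <- length(case_idx)
  n0 <- length(scores) - n1
  (sum(r[case_idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# covariate bins over the stacked (cases, controls) subjects of an arm
label_bins <- function(arm, correction, n_bins) {
  n <- nrow(arm$D$values) + nrow(arm$X$values)
  if (is.null(correction) || !length(correction) || n_bins <= 1) {
    return(rep(1L, n))
  }
  cm <- covariate_matrix(arm, correction)
  ids <- c(arm$D$subject_ids, arm$X$subject_ids)
  cov_all <- scale(cm[match(ids, rownames(cm)), , drop = FALSE])
  cov_all[is.nan(cov_all)] <- 0
  k <- min(n_bins, nrow(unique(cov_all)))
  if (k <= 1) return(rep(1L, n))
  km <- with_rng_seed(760013, tryCatch(
    stats::kmeans(cov_all, centers = k, nstart = 5, iter.max = 50),
    error = function(e) NULL
  ))
  if (is.null(km)) rep(1L, n) else km$cluster
}

# permutation of 1..n that permutes positions within bins
permute_within_bins <- function(n, bins) {
  idx <- seq_len(n)
  for (b in unique(bins)) {
    in_b <- which(bins == b)
    idx[in_b] <- idx[in_b][sample.int(length(in_b))]
  }
  # value at position i tells which original label position i inherits
  idx
}

#' Replication degradation under SNP dropout
#'
#' Randomly removes SNPs from the replication arm down to each keep
#' fraction and recomputes the interval-averaged replication AUC, emulating
#' the reduction of inter-arm SNP overlap.
#'
#' @param trace A `bicluster_trace` from the training arm.
#' @param train_arm,rep_arm [cohort_arm()]s.
#' @param keep_fractions Fractions of replication-arm SNPs to keep, each in
#'   `(0, 1]`.
#' @param interval Iteration interval for the average.
#' @param seed Integer seed (dropout is deterministic per seed).
#' @param ... Passed to [replication_curve()].
#' @return Tibble with `keep_fraction`, `n_snps`, `Abar`.
#' @export
overlap_degradation <- function(trace, train_arm, rep_arm, keep_fractions,
                                interval, seed = 1, ...) {
  stopifnot(all(keep_fractions > 0), all(keep_fractions <= 1))
  snps <- unique(rep_arm$D$column_map$snp_id)
  seeds <- with_rng_seed(seed, sample.int(.Machine$integer.max - 1,
                                          length(keep_fractions)))
  out <- lapply(seq_along(keep_fractions), function(fi) {
    f <- keep_fractions[fi]
    keep <- if (f >= 1) snps else
      with_rng_seed(seeds[fi], sample(snps, max(1, round(f * length(snps)))))
    arm_f <- arm_subset_snps(rep_arm, keep)
    rc <- replication_curve(trace, train_arm, arm_f, interval, ...)
    tibble::tibble(keep_fraction = f, n_snps = length(keep), Abar = rc$Abar)
  })
  dplyr::bind_rows(out)
}

#' Restrict an arm to a subset of SNPs
#'
#' @param arm A [cohort_arm()].
#' @param keep_snps SNP ids to keep.
#' @return A [cohort_arm()] over the restricted SNP panel.
#' @export
arm_subset_snps <- function(arm, keep_snps) {
  stopifnot(inherits(arm, "cohort_arm"))
  keep_cols <- arm$D$column_map$snp_id %in% keep_snps
  if (!any(keep_cols)) stop("no SNPs left after subsetting", call. = FALSE)
  cmap <- arm$D$column_map[keep_cols, , drop = FALSE]
  out <- arm
  out$D <- allele_matrix(arm$D$values[, keep_cols, drop = FALSE], cmap,
                         arm$D$subject_ids)
  out$X <- allele_matrix(arm$X$values[, keep_cols, drop = FALSE], cmap,
                         arm$X$subject_ids)
  keep_g <- arm$geno$snp_table$snp_id %in% keep_snps
  out$geno <- genotype_matrix(arm$geno$calls[, keep_g, drop = FALSE],
                              arm$geno$snp_table[keep_g, , drop = FALSE],
                              arm$geno$subject_ids)
  out
}
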