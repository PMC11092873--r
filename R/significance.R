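#' Permute case/control labels within covariate bins
#'
#' Subjects are partitioned into `n_bins` clusters on the correction
#' covariates (k-means with a fixed internal seed) and the case/control
#' labels are permuted uniformly within each cluster, preserving the case
#' and control counts per cluster and globally. This draws a sample from the
#' null hypothesis that the case/control structure is independent of the
#' labels while respecting proximity in covariate-space.
#'
#' @param arm A [cohort_arm()].
#' @param n_bins Number of covariate bins (`1` = a global permutation).
#' @param seed Integer seed for the permutation.
#' @param correction Covariate columns defining covariate-space; `NULL` or
#'   empty collapses to a single bin.
#' @return A [cohort_arm()] with permuted labels (subtype labels dropped).
#' @export
shuffle_labels_within_bins <- function(arm, n_bins = 8, seed = 1,
                                       correction = NULL) {
  stopifnot(inherits(arm, "cohort_arm"), n_bins >= 1)
  case_ids <- arm$D$subject_ids
  ctrl_ids <- arm$X$subject_ids
  ids <- c(case_ids, ctrl_ids)
  status <- c(rep(TRUE, length(case_ids)), rep(FALSE, length(ctrl_ids)))
  bins <- rep(1L, length(ids))
  if (!is.null(correction) && length(correction) && n_bins > 1) {
    cov_all <- covariate_matrix(arm, correction)
    cov_all <- scale(cov_all[match(ids, rownames(cov_all)), , drop = FALSE])
    cov_all[is.nan(cov_all)] <- 0
    k <- min(n_bins, nrow(unique(cov_all)))
    if (k > 1) {
      km <- with_rng_seed(760013, tryCatch(
        stats::kmeans(cov_all, centers = k, nstart = 5, iter.max = 50),
        error = function(e) NULL
      ))
      if (!is.null(km)) bins <- km$cluster
    }
  }
  new_status <- status
  with_rng_seed(seed, {
    for (b in unique(bins)) {
      in_b <- which(bins == b)
      if (length(unique(status[in_b])) < 2) {
        warning("covariate bin with a single label left unshuffled",
                call. = FALSE)
        next
      }
      new_status[in_b] <- status[in_b][sample.int(length(in_b))]
    }
  })
  vals <- rbind(arm$D$values, arm$X$values)
  cmap <- arm$D$column_map
  new_case <- ids[new_status]
  new_ctrl <- ids[!new_status]
  D <- allele_matrix(vals[match(new_case, ids), , drop = FALSE], cmap, new_case)
  X <- allele_matrix(vals[match(new_ctrl, ids), , drop = FALSE], cmap, new_ctrl)
  status_by_id <- stats::setNames(new_status, ids)
  out <- arm
  out$D <- D
  out$X <- X
  out$subtype <- NULL
  out$status <- unname(status_by_id[arm$geno$subject_ids])
  out$arm_id <- paste0(arm$arm_id, "_shuffled")
  out
}

#' Label-permutation null ensemble for the trace
#'
#' Runs the half-loop algorithm on `n_trials` independently label-shuffled
#' copies of the arm. Because the removal schedule depends only on the case
#' count, column count and `gamma` -- all preserved by shuffling -- every
#' trial shares the observed run's iteration schedule. Per iteration, the
#' observed trace is standardised against the null trials (z-score) and an
#' add-one empirical p-value is computed. The overall p-value is the
#' empirical tail probability of the observed `max_i z(i)` against the null
#' distribution of per-trial maxima, each trial standardised against the
#' other trials (leave-one-out).
#'
#' @param arm A [cohort_arm()].
#' @param n_trials Number of label-shuffled trials (at least 8).
#' @param gamma Elimination fraction, as in [halfloop_run()].
#' @param seed Integer seed controlling all shuffles.
#' @param correction Covariate columns used both for the kernel correction
#'   inside the half-loop runs and for the shuffling bins.
#' @param n_bins Covariate bins for [shuffle_labels_within_bins()].
#' @param bandwidth Kernel bandwidth (see [covariate_weights()]).
#' @param observed Optional precomputed observed `bicluster_trace` (must
#'   come from the same arm and `gamma`).
#' @param keep_members Keep the per-trial elimination orders (needed for
#'   enrichment null distributions).
#' @return An object of class `null_ensemble`: the observed trace, a
#'   `n_trials x n_iterations` null trace matrix, a per-iteration tibble
#'   (`iteration`, `M`, `N`, `trace`, `null_mean`, `null_sd`, `z`, `p`,
#'   `degenerate`), the `overall_p`, and (optionally) the per-trial traces.
#' @export
null_ensemble <- function(arm, n_trials = 64, gamma = 0.5^8, seed = 1,
                          correction = NULL, n_bins = 8, bandwidth = "auto",
                          observed = NULL, keep_members = TRUE) {
  stopifnot(inherits(arm, "cohort_arm"), n_trials >= 8)
  if (is.null(observed)) {
    observed <- halfloop_run(arm, gamma, correction, bandwidth)
  }
  trial_seeds <- with_rng_seed(seed, sample.int(.Machine$integer.max - 1,
                                                n_trials))
  trials <- vector("list", n_trials)
  n_it <- nrow(observed$iterations)
  null_traces <- matrix(NA_real_, n_trials, n_it)
  for (t in seq_len(n_trials)) {
    sh <- shuffle_labels_within_bins(arm, n_bins = n_bins,
                                     seed = trial_seeds[t],
                                     correction = correction)
    tr <- halfloop_run(sh, gamma, correction, bandwidth)
    if (nrow(tr$iterations) != n_it) {
      stop("shuffled trial has a different iteration schedule", call. = FALSE)
    }
    null_traces[t, ] <- tr$iterations$trace
    trials[[t]] <- if (keep_members) tr else NULL
  }
  obs <- observed$iterations$trace
  mu <- colMeans(null_traces)
  sd_ <- apply(null_traces, 2, stats::sd)
  degenerate <- !is.finite(sd_) | sd_ <= 0
  z <- (obs - mu) / sd_
  z[degenerate] <- 0
  p_iter <- vapply(seq_len(n_it), function(i) {
    (1 + sum(null_traces[, i] >= obs[i])) / (n_trials + 1)
  }, 1)
  # leave-one-out standardised per-trial maxima
  S <- colSums(null_traces)
  SS <- colSums(null_traces^2)
  max_null <- vapply(seq_len(n_trials), function(t) {
    x <- null_traces[t, ]
    mu_t <- (S - x) / (n_trials - 1)
    var_t <- pmax((SS - x^2 - (n_trials - 1) * mu_t^2) / (n_trials - 2), 0)
    sd_t <- sqrt(var_t)
    zt <- (x - mu_t) / sd_t
    zt[!is.finite(zt)] <- 0
    max(zt)
  }, 1)
  z_obs_max <- max(z)
  overall_p <- (1 + sum(max_null >= z_obs_max)) / (n_trials + 1)
  structure(
    list(
      observed = observed,
      null_traces = null_traces,
      iterations = dplyr::mutate(
        observed$iterations,
        null_mean = mu, null_sd = sd_, z = z, p = p_iter,
        degenerate = degenerate
      ),
      overall_p = overall_p,
      null_max_z = max_null,
      n_trials = n_trials,
      seed = seed,
      trials = trials
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d trials, peak z = %.2f at iteration %d, overall p = %.4g\n",
    x$n_trials, max(x$iterations$z),
    x$iterations$iteration[which.max(x$iterations$z)], x$overall_p
  ))
  invisible(x)
}

#' Peak iteration of a null ensemble
#'
#' The iteration best approximating the bicluster. Two statistics are
#' offered. `"excess"` (the default) maximises the excess trace, the
#' observed trace minus the null mean: the total differential expression
#' above the label-shuffled expectation, which is largest when the retained
#' submatrix matches the underlying structure (removing a signal-carrying
#' row loses more excess than removing a background row). `"z"` maximises
#' the per-iteration z-score; note that deep into the elimination the null
#' spread collapses, so the z-score can keep growing after the retained set
#' has shrunk to a strict subset of the structure, which makes `"z"` a
#' better detector of significance than of identity.
#'
#' @param ensemble A `null_ensemble`.
#' @param method `"excess"` or `"z"`.
#' @return The peak iteration index (integer scalar).
#' @export
peak_iteration <- function(ensemble, method = c("excess", "z")) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  method <- match.arg(method)
  it <- ensemble$iterations
  stat <- switch(method,
                 excess = it$trace - it$null_mean,
                 z = it$z)
  it$iteration[which.max(stat)]
}

#' Significant plateau of iterations
#'
#' The maximal contiguous interval of iterations with per-iteration
#' empirical `p <= alpha` that contains the iteration of maximal z. Empty if
#' the peak iteration is not itself significant.
#'
#' @param ensemble A `null_ensemble`.
#' @param alpha Per-iteration significance level.
#' @return Integer vector of iteration indices (possibly empty).
#' @export
plateau_interval <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  it <- ensemble$iterations
  sig <- it$p <= alpha
  if (!any(sig)) return(integer(0))
  peak <- which.max(it$z)
  if (!sig[peak]) return(integer(0))
  lo <- peak
  while (lo > 1 && sig[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < nrow(it) && sig[hi + 1]) hi <- hi + 1
  it$iteration[lo:hi]
}
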