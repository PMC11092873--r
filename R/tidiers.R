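#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bicluster trace
#'
#' @param x A `bicluster_trace`.
#' @param ... Unused.
#' @return Tibble with one row per iteration (`iteration`, `M`, `N`,
#'   `trace`, `trace_col`).
#' @export
tidy.bicluster_trace <- function(x, ...) x$iterations

#' @rdname tidy.bicluster_trace
#' @export
glance.bicluster_trace <- function(x, ...) {
  it <- x$iterations
  peak <- which.max(it$trace)
  tibble::tibble(
    n_iterations = nrow(it), M_start = it$M[1], N_start = it$N[1],
    peak_iteration = it$iteration[peak], peak_trace = it$trace[peak],
    gamma = x$gamma
  )
}

#' Tidy a permutation null ensemble
#'
#' @param x A `null_ensemble`.
#' @param ... Unused.
#' @return Per-iteration tibble with the observed trace, null mean/sd,
#'   z-score and empirical p-value.
#' @export
tidy.null_ensemble <- function(x, ...) x$iterations

#' @rdname tidy.null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  it <- x$iterations
  peak <- which.max(it$z)
  tibble::tibble(
    overall_p = x$overall_p, n_trials = x$n_trials,
    peak_z = it$z[peak], peak_iteration = it$iteration[peak]
  )
}

#' Tidy a replication curve
#'
#' @param x A `replication_curve`.
#' @param ... Unused.
#' @return Per-iteration tibble with training/replication AUCs and their
#'   shuffled-null p-values.
#' @export
tidy.replication_curve <- function(x, ...) x$curve

#' @rdname tidy.replication_curve
#' @export
glance.replication_curve <- function(x, ...) {
  tibble::tibble(
    Abar = x$Abar, p_Abar = x$p_Abar,
    interval_lo = x$interval[1], interval_hi = x$interval[2],
    n_trials = x$n_trials, rep_arm = x$rep_arm_id
  )
}

#' Plot the z-score trace against the permutation null
#'
#' @param object A `null_ensemble`.
#' @param alpha Per-iteration significance level drawn as a reference.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_ensemble <- function(object, alpha = 0.05, ...) {
  it <- object$iterations
  nt <- object$null_traces
  mu <- it$null_mean
  sd_ <- pmax(it$null_sd, .Machine$double.eps)
  null_z <- sweep(sweep(nt, 2, mu), 2, sd_, "/")
  long <- tibble::tibble(
    iteration = rep(it$iteration, each = nrow(nt)),
    trial = rep(seq_len(nrow(nt)), times = ncol(nt)),
    z = as.numeric(null_z)
  )
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = long,
      ggplot2::aes(x = .data$iteration, y = .data$z, group = .data$trial),
      colour = "grey40", alpha = 0.3, linewidth = 0.2
    ) +
    ggplot2::geom_line(
      data = it,
      ggplot2::aes(x = .data$iteration, y = .data$z),
      colour = "red", linewidth = 0.7
    ) +
    ggplot2::labs(
      x = "iteration", y = "trace z-score",
      title = "Observed trace vs label-shuffled null",
      subtitle = sprintf("overall p = %.4g (%d trials)",
                         object$overall_p, object$n_trials)
    ) +
    ggplot2::theme_minimal()
}

#' Plot training and replication AUC curves
#'
#' @param object A `replication_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replication_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("A", "A_rep"),
                              names_to = "which", values_to = "auc")
  long$which <- ifelse(long$which == "A", "training A(i)",
                       "replication A'(i)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$auc,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`training A(i)` = "red",
                                            `replication A'(i)` = "darkgreen")) +
    ggplot2::labs(x = "iteration", y = "covariate-adjusted AUC",
                  colour = NULL,
                  subtitle = sprintf("Abar' = %.3f, p = %.4g",
                                     object$Abar, object$p_Abar)) +
    ggplot2::theme_minimal()
}

#' Plot a PRS evaluation grid
#'
#' AUC against the number of SNPs used, population-wide versus
#' bicluster-informed, faceted by subtype restriction.
#'
#' @param object A `prs_evaluation` from [prs_comparison()].
#' @param arm Which arm to show (default `"pooled"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prs_evaluation <- function(object, arm = "pooled", ...) {
  tab <- dplyr::filter(tibble::as_tibble(object), .data$arm == !!arm)
  tab$model_lab <- ifelse(tab$model == "wide", "population-wide",
                          sprintf("bicluster i=%d", tab$iteration))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_snp, y = .data$auc,
                                    colour = .data$model_lab)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~subtype) +
    ggplot2::labs(x = "number of SNPs", y = "covariate-adjusted AUC",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
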