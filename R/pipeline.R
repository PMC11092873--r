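#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end with a single configuration (an R
#' list or a YAML file): simulate a multi-arm cohort (or read genotype
#' files), bicluster the training arm, calibrate the permutation null,
#' assess replication on each replication arm, compare population-wide and
#' bicluster-informed polygenic scores, and run the gene-set
#' over-representation analysis. Every output file records the seed and a
#' configuration hash; reruns with the same configuration and seed produce
#' identical artifacts.
#'
#' @param config Path to a YAML file or a named list. Recognised keys (all
#'   optional except where noted): `seed`; `synth` (passed to
#'   [synth_config()]); `paths` (per-arm genotype/covariate files read via
#'   [read_genotype_tsv()] when no `synth` block is given); `gamma`;
#'   `n_trials`; `n_bins`; `alpha`; `correction_discovery`;
#'   `correction_replication`; `iterations` (for the PRS stage; default:
#'   spread over the significant plateau); `thresholds`; `prevalences`;
#'   `maf_threshold`; `enrichment` (`snps_per_gene`, `n_pathways`).
#' @param out_dir Output directory for the TSV artifacts.
#' @param stages Character vector from `c("simulate", "bicluster",
#'   "permtest", "replicate", "prs", "enrich")` or `"all"`.
#' @param verbose Log per-stage progress to stderr.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = "halfloopr_run",
                         stages = "all", verbose = TRUE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1, gamma = 0.5^8, n_trials = 64, n_bins = 8, alpha = 0.05,
    maf_threshold = 0.25,
    correction_discovery = c("U1", "U2"),
    correction_replication = c(paste0("U", 1:6), "U19"),
    thresholds = "auto",
    prevalences = list(all = 0.02, BDI = 0.01, BDII = 0.01),
    enrichment = list(snps_per_gene = 4, n_pathways = 10)
  )
  cfg <- utils::modifyList(defaults, config)
  all_stages <- c("simulate", "bicluster", "permtest", "replicate", "prs",
                  "enrich")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(digest_config(cfg), 1, 12)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  stamp <- function(path, tab) {
    con <- file(path, "w")
    writeLines(sprintf("# seed: %d", cfg$seed), con)
    writeLines(sprintf("# config: %s", cfg_hash), con)
    close(con)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  res <- list(config = cfg)

  # ---- inputs ----
  t0 <- Sys.time()
  if (!is.null(cfg$synth)) {
    sc <- do.call(synth_config, utils::modifyList(cfg$synth,
                                                  list(seed = cfg$seed)))
    arms <- if (length(sc$arms)) simulate_multi_arm(sc) else
      list(simulate_arm(sc))
  } else if (!is.null(cfg$paths)) {
    arms <- lapply(cfg$paths$arms, function(p) {
      for (f in c(p$genotypes, p$covariates)) {
        if (!file.exists(f)) {
          stop("missing upstream artifact: ", f, call. = FALSE)
        }
      }
      G <- read_genotype_tsv(p$genotypes, p$snps)
      cov <- read_covariates_tsv(p$covariates)
      if (!"status" %in% names(cov)) {
        stop("covariate file needs a 'status' column: ", p$covariates,
             call. = FALSE)
      }
      cov <- cov[match(G$subject_ids, cov$subject_id), ]
      cohort_arm(G, cov$status,
                 cov[, setdiff(names(cov), c("status", "subtype"))],
                 if ("subtype" %in% names(cov)) cov$subtype else NULL,
                 p$arm_id %||% "arm")
    })
  } else {
    stop("config needs a 'synth' or a 'paths' block", call. = FALSE)
  }
  train_arm <- arms[[1]]
  rep_arms <- arms[-1]
  if ("simulate" %in% stages) {
    for (a in arms) {
      write_genotype_tsv(a$geno,
                         file.path(out_dir, paste0(a$arm_id, "_geno.tsv")),
                         file.path(out_dir, paste0(a$arm_id, "_snps.tsv")))
      cov <- a$covariates
      cov$status <- a$status
      write_covariates_tsv(cov, file.path(out_dir,
                                          paste0(a$arm_id, "_cov.tsv")))
      tr <- attr(a, "truth")
      if (!is.null(tr)) {
        jsonlite::write_json(tr, file.path(out_dir,
                                           paste0(a$arm_id, "_truth.json")))
      }
    }
    log_msg("simulate: %d arm(s) written [%.1fs]", length(arms),
            as.numeric(Sys.time() - t0, units = "secs"))
  }
  res$arms <- arms

  # ---- discovery ----
  corr_d <- intersect(cfg$correction_discovery, names(train_arm$covariates))
  ens <- NULL
  trace <- NULL
  if (any(c("bicluster", "permtest", "replicate", "prs", "enrich") %in%
          stages)) {
    t0 <- Sys.time()
    trace <- halfloop_run(train_arm, cfg$gamma, corr_d)
    if ("bicluster" %in% stages) {
      stamp(file.path(out_dir, "trace.tsv"), trace$iterations)
      log_msg("bicluster: %d iterations [%.1fs]", nrow(trace$iterations),
              as.numeric(Sys.time() - t0, units = "secs"))
    }
    res$trace <- trace
  }
  if (any(c("permtest", "replicate", "prs", "enrich") %in% stages)) {
    t0 <- Sys.time()
    ens <- null_ensemble(train_arm, n_trials = cfg$n_trials,
                         gamma = cfg$gamma, seed = cfg$seed,
                         correction = corr_d, n_bins = cfg$n_bins,
                         observed = trace)
    if ("permtest" %in% stages) {
      stamp(file.path(out_dir, "null_z.tsv"), ens$iterations)
      stamp(file.path(out_dir, "overall_p.tsv"),
            tibble::tibble(overall_p = ens$overall_p,
                           n_trials = ens$n_trials))
      pk <- peak_iteration(ens)
      mem <- trace_members(trace, pk)
      stamp(file.path(out_dir, "members_cases.tsv"),
            tibble::tibble(iteration = pk, case_id = mem$J))
      stamp(file.path(out_dir, "members_columns.tsv"),
            tibble::tibble(iteration = pk, column = mem$K))
      log_msg("permtest: overall p = %.4g [%.1fs]", ens$overall_p,
              as.numeric(Sys.time() - t0, units = "secs"))
    }
    res$ensemble <- ens
  }
  plateau <- if (!is.null(ens)) plateau_interval(ens, cfg$alpha) else integer(0)
  res$plateau <- plateau

  # ---- replication ----
  corr_r <- intersect(cfg$correction_replication, names(train_arm$covariates))
  if ("replicate" %in% stages && length(rep_arms)) {
    t0 <- Sys.time()
    interval <- if (length(plateau)) range(plateau) else
      c(1, max(trace$iterations$iteration) - 1)
    curves <- lapply(rep_arms, function(a) {
      replication_curve(trace, train_arm, a, interval,
                        n_trials = cfg$n_trials,
                        correction_train = corr_r,
                        correction_rep = intersect(corr_r,
                                                   names(a$covariates)),
                        n_bins = cfg$n_bins, seed = cfg$seed)
    })
    for (rc in curves) {
      stamp(file.path(out_dir, paste0("replication_", rc$rep_arm_id,
                                      ".tsv")),
            dplyr::mutate(rc$curve, Abar = rc$Abar, p_Abar = rc$p_Abar))
    }
    log_msg("replicate: %s [%.1fs]",
            paste(sprintf("%s Abar'=%.3f (p=%.3g)",
                          vapply(curves, function(x) x$rep_arm_id, ""),
                          vapply(curves, function(x) x$Abar, 1),
                          vapply(curves, function(x) x$p_Abar, 1)),
                  collapse = "; "),
            as.numeric(Sys.time() - t0, units = "secs"))
    res$replication <- curves
  }

  # ---- PRS ----
  if ("prs" %in% stages && length(rep_arms)) {
    t0 <- Sys.time()
    iters <- cfg$iterations
    if (is.null(iters)) {
      iters <- if (length(plateau)) {
        unique(round(stats::quantile(plateau, c(0.05, 0.5, 0.95),
                                     names = FALSE)))
      } else {
        mx <- max(trace$iterations$iteration)
        unique(round(c(mx * 0.3, mx * 0.6)))
      }
    }
    pe <- prs_comparison(trace, train_arm, rep_arms, iters,
                         thresholds = cfg$thresholds, correction = corr_r,
                         prevalences = cfg$prevalences)
    stamp(file.path(out_dir, "prs_evaluation.tsv"), tibble::as_tibble(pe))
    log_msg("prs: %d evaluation rows [%.1fs]", nrow(pe),
            as.numeric(Sys.time() - t0, units = "secs"))
    res$prs <- pe
  }

  # ---- enrichment ----
  if ("enrich" %in% stages) {
    t0 <- Sys.time()
    ann <- if (!is.null(cfg$annotation_file)) {
      read_annotation(cfg$annotation_file)
    } else {
      simulate_annotation(unique(train_arm$D$column_map$snp_id),
                          cfg$enrichment$snps_per_gene)
    }
    paths <- if (!is.null(cfg$gene_sets_file)) {
      read_gene_sets(cfg$gene_sets_file)
    } else {
      simulate_gene_sets(unique(ann$gene), cfg$enrichment$n_pathways,
                         seed = cfg$seed)
    }
    interval <- if (length(plateau)) range(plateau) else
      c(1, max(trace$iterations$iteration) - 1)
    ez <- enrichment_z(ens, ann, paths, interval)
    stamp(file.path(out_dir, "enrichment.tsv"), ez$z_table)
    grid <- tidyr::pivot_wider(
      dplyr::mutate(ez$z_table, neglog10_p = -log10(pmax(.data$p, 1e-300))),
      id_cols = "pathway", names_from = "iteration",
      values_from = "neglog10_p"
    )
    stamp(file.path(out_dir, "enrichment_grid.tsv"), grid)
    stamp(file.path(out_dir, "enrichment_summary.tsv"),
          tibble::tibble(zbar = ez$zbar, p = ez$p))
    log_msg("enrich: zbar = %.2f (p = %.3g) [%.1fs]", ez$zbar, ez$p,
            as.numeric(Sys.time() - t0, units = "secs"))
    res$enrichment <- ez
  }
  invisible(res)
}

# order-independent hash of the configuration (no external digest package)
digest_config <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg[order(names(cfg))])),
             collapse = "\n")
  # small rolling hash; stability across runs is all that is needed
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x%04x", h, length(v) %% 65536)
}
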