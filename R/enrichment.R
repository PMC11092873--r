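#' Genes retained by a column set
#'
#' A gene is retained at iteration `i` when strictly more than half of the
#' allele-combination columns originally associated with it (via the
#' SNP-to-gene annotation, at iteration 1) are still present in `K_i`.
#' Genes with zero originally annotated columns are excluded from the
#' universe and never retained.
#'
#' @param K_i Retained column names (from [trace_members()]).
#' @param annotation Tibble with `snp_id` and `gene` (see
#'   [read_annotation()]).
#' @param all_columns Column names at iteration 1; together with the
#'   annotation they define each gene's original column count and the gene
#'   universe.
#' @return Character vector of retained genes, with attribute `universe`.
#' @export
retained_genes <- function(K_i, annotation, all_columns) {
  annotation <- tibble::as_tibble(annotation)
  snp_of <- function(cols) sub(":(het|hom_minor|hom_major)$", "", cols)
  gene_by_snp <- split(annotation$gene, annotation$snp_id)
  count_genes <- function(cols) {
    snps <- snp_of(cols)
    genes <- unlist(gene_by_snp[snps], use.names = FALSE)
    if (is.null(genes)) return(table(character(0)))
    table(genes)
  }
  orig <- count_genes(all_columns)
  universe <- names(orig)[orig > 0]
  now <- count_genes(intersect(K_i, all_columns))
  frac <- stats::setNames(rep(0, length(universe)), universe)
  frac[names(now)] <- as.numeric(now[names(now)]) /
    as.numeric(orig[names(now)])
  retained <- universe[frac[universe] > 0.5]
  attr(retained, "universe") <- universe
  retained
}

#' Gene-set over-representation by the hypergeometric distribution
#'
#' For each pathway, the overlap count `kappa = |G_i ∩ H_l|` and the
#' upper-tail hypergeometric probability of observing at least `kappa`
#' successes when drawing `|G_i|` genes from the universe, of which
#' `|H_l ∩ universe|` are pathway members.
#'
#' @param G_i Retained gene set (subset of `universe`).
#' @param pathways Named list of gene vectors (see [read_gene_sets()]).
#' @param universe Character vector: the annotation gene universe.
#' @return Tibble with `pathway`, `kappa`, `pathway_size` (in-universe),
#'   `p`.
#' @export
pathway_overrepresentation <- function(G_i, pathways, universe) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  G_i <- intersect(G_i, universe)
  out <- lapply(names(pathways), function(nm) {
    H <- intersect(pathways[[nm]], universe)
    kappa <- length(intersect(G_i, H))
    p <- stats::phyper(kappa - 1, length(H), length(universe) - length(H),
                       length(G_i), lower.tail = FALSE)
    tibble::tibble(pathway = nm, kappa = kappa, pathway_size = length(H),
                   p = p)
  })
  dplyr::bind_rows(out)
}

#' Enrichment table along a trace
#'
#' Overlap counts and hypergeometric p-values for every (iteration,
#' pathway) pair over a set of evaluated iterations.
#'
#' @param trace A `bicluster_trace`.
#' @param annotation SNP-to-gene annotation.
#' @param pathways Named list of gene sets.
#' @param iterations Iterations at which to evaluate.
#' @return Object of class `enrichment_table`: tibble with `iteration`,
#'   `pathway`, `kappa`, `pathway_size`, `p`.
#' @export
enrichment_table <- function(trace, annotation, pathways, iterations) {
  stopifnot(inherits(trace, "bicluster_trace"))
  all_cols <- trace$col_ids
  rows <- lapply(iterations, function(i) {
    K <- trace_members(trace, i)$K
    G <- retained_genes(K, annotation, all_cols)
    tab <- pathway_overrepresentation(G, pathways, attr(G, "universe"))
    tab$iteration <- i
    tab$n_genes <- length(G)
    tab
  })
  out <- dplyr::bind_rows(rows)[, c("iteration", "pathway", "kappa",
                                    "pathway_size", "n_genes", "p")]
  structure(out, class = c("enrichment_table", class(out)))
}

#' Permutation z-scores for pathway gene-counts
#'
#' Standardises the observed `kappa(i, l)` against the distribution of
#' `kappa(i, l)` under the label-shuffled null (the trials of a
#' [null_ensemble()]), averages the z-scores over the iteration interval
#' and the pathway collection, and assigns the average an empirical
#' p-value from the per-trial averages (each standardised leave-one-out).
#'
#' @param ensemble A `null_ensemble` run with `keep_members = TRUE`.
#' @param annotation SNP-to-gene annotation.
#' @param pathways Named list of gene sets.
#' @param interval Iteration interval over which to average.
#' @param iterations Evaluated iterations (default: up to `max_points`
#'   evenly spaced inside the interval).
#' @param max_points Cap on evaluated iterations.
#' @return List with `zbar`, `p`, per-(iteration, pathway) tibble `z_table`
#'   and the per-trial `null_zbar`.
#' @export
enrichment_z <- function(ensemble, annotation, pathways, interval,
                         iterations = NULL, max_points = 25) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (is.null(ensemble$trials[[1]])) {
    stop("ensemble was run with keep_members = FALSE", call. = FALSE)
  }
  it_all <- ensemble$iterations$iteration
  if (is.null(iterations)) {
    lo <- max(min(interval), min(it_all))
    hi <- min(max(interval), max(it_all))
    iterations <- unique(round(seq(lo, hi,
                                   length.out = min(max_points, hi - lo + 1))))
  }
  obs_tab <- enrichment_table(ensemble$observed, annotation, pathways,
                              iterations)
  n_trials <- ensemble$n_trials
  n_cells <- nrow(obs_tab)
  null_k <- matrix(NA_real_, n_trials, n_cells)
  for (t in seq_len(n_trials)) {
    tab_t <- enrichment_table(ensemble$trials[[t]], annotation, pathways,
                              iterations)
    null_k[t, ] <- tab_t$kappa
  }
  mu <- colMeans(null_k)
  sd_ <- apply(null_k, 2, stats::sd)
  z <- (obs_tab$kappa - mu) / sd_
  z[!is.finite(z)] <- 0
  obs_tab$z <- z
  zbar <- mean(z)
  # per-trial zbar, standardised leave-one-out
  S <- colSums(null_k)
  SS <- colSums(null_k^2)
  null_zbar <- vapply(seq_len(n_trials), function(t) {
    x <- null_k[t, ]
    mu_t <- (S - x) / (n_trials - 1)
    var_t <- pmax((SS - x^2 - (n_trials - 1) * mu_t^2) / (n_trials - 2), 0)
    zt <- (x - mu_t) / sqrt(var_t)
    zt[!is.finite(zt)] <- 0
    mean(zt)
  }, 1)
  p <- (1 + sum(null_zbar >= zbar)) / (n_trials + 1)
  list(zbar = zbar, p = p, z_table = obs_tab, null_zbar = null_zbar,
       iterations = iterations)
}
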