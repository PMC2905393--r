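# Integration of the binding, expression and fitness layers: enrichment
# ranking, bound x responsive cross-tables with exact-test statistics, Sty1
# dependency ratios, and the final report tables.

#' Rank genes by mean enrichment of two factors
#'
#' Dense descending ranks of the per-gene mean of two (log2) enrichment
#' levels; tied means share a rank and the next distinct mean gets the
#' previous rank plus one.
#'
#' @param level_a,level_b per-gene enrichment levels (log2), equal length.
#' @return integer vector of dense ranks.
#' @export
rank_by_mean_enrichment <- function(level_a, level_b) {
  stopifnot(length(level_a) == length(level_b),
            all(is.finite(level_a)), all(is.finite(level_b)))
  dense_rank((level_a + level_b) / 2)
}

#' Fold enrichment of one gene set in another
#'
#' For a universe of `N` genes, a group of interest of size `K` with `k`
#' members in a reference set of size `n`: observed fraction k/K, expected
#' fraction n/N, fold = observed/expected, and the two-sided Fisher exact
#' p-value (minimum-likelihood summation over the hypergeometric
#' distribution of the 2x2 table with fixed margins).
#'
#' @param k members of the group also in the reference set.
#' @param K group size.
#' @param n reference set size.
#' @param N universe size.
#' @return list: observed, expected (fractions), fold, p_value.
#' @export
fold_enrichment <- function(k, K, n, N) {
  stopifnot(k <= min(K, n), N >= max(K, n), k >= 0)
  if (n == 0 || N == 0) stop("expected fraction undefined (empty reference)")
  observed <- k / K
  expected <- n / N
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
  list(observed = observed, expected = expected,
       fold = observed / expected,
       p_value = fisher.test(tab)$p.value)
}

#' Sty1 recruitment dependency ratio
#'
#' Enrichment levels are stored in log2; the ratio is taken on the linear
#' scale: mean linear Sty1 level across the deletion strains divided by the
#' mean linear level across wild-type repeats. Recruitment is
#' Atf1/Pcr1-dependent iff the ratio is strictly below the cutoff.
#'
#' @param wt_levels wild-type Sty1 levels (log2), one per repeat.
#' @param mut_levels per-mutant Sty1 levels (log2; e.g. the atf1-delete and
#'   pcr1-delete averages).
#' @param cutoff dependency cutoff on the linear ratio (default 0.6,
#'   strict `<`).
#' @return list: ratio (linear), dependent (logical), wt_mean and mut_mean
#'   (linear scale).
#' @export
sty1_dependency_ratio <- function(wt_levels, mut_levels, cutoff = 0.6) {
  wt_mean <- mean(2^wt_levels)
  mut_mean <- mean(2^mut_levels)
  if (wt_mean <= 0) stop("wild-type mean level must be positive")
  ratio <- mut_mean / wt_mean
  list(ratio = ratio, dependent = ratio < cutoff,
       wt_mean = wt_mean, mut_mean = mut_mean)
}

#' Cross-classify genes by binding, responsiveness and fitness
#'
#' Builds the per-gene report row combining binding class (bound-major /
#' bound-minor / unbound), response status (induced / repressed /
#' unresponsive) and, where measured, the sensitivity flag. Every gene of
#' the universe appears exactly once and marginal counts reproduce the
#' inputs.
#'
#' @param universe character vector of all gene ids.
#' @param bound_major,bound_minor gene ids bound at major / minor sites
#'   (major takes precedence if listed in both).
#' @param responsive_calls a [call_responsive()] result (gene_id, status).
#' @param fitness optional data.frame (strain = gene id, sensitive).
#' @return data.frame: gene_id, binding, status, sensitive (NA where not
#'   assayed).
#' @export
cross_classify <- function(universe, bound_major, bound_minor = character(),
                           responsive_calls, fitness = NULL) {
  bad <- setdiff(c(bound_major, bound_minor, responsive_calls$gene_id),
                 universe)
  if (length(bad))
    stop("genes outside the universe: ", paste(head(bad, 5), collapse = ", "))
  binding <- ifelse(universe %in% bound_major, "bound_major",
                    ifelse(universe %in% bound_minor, "bound_minor",
                           "unbound"))
  status <- responsive_calls$status[match(universe,
                                          responsive_calls$gene_id)]
  status[is.na(status)] <- "unresponsive"
  sensitive <- rep(NA, length(universe))
  if (!is.null(fitness))
    sensitive <- fitness$sensitive[match(universe, fitness$strain)]
  data.frame(gene_id = universe, binding = binding, status = status,
             sensitive = sensitive, stringsAsFactors = FALSE)
}

#' Write the integrated report
#'
#' Emits a deterministic file set: per-gene cross-classification TSV, the
#' binding sites as BED (0-based half-open, score = enrichment level), the
#' site-to-gene assignment TSV, and a plain-text summary whose every count
#' is recomputable from the tables. When ground-truth planted sites are
#' supplied, a planted-vs-recovered confusion table is included.
#'
#' @param outdir output directory (created if needed).
#' @param sites called site data.frame (chrom, apex_bp, level).
#' @param assignments an [assign_promoters()] result.
#' @param cross a [cross_classify()] result.
#' @param truth_sites optional ground-truth planted sites (chrom, apex_bp).
#' @param match_distance bp tolerance for the confusion table.
#' @return invisibly, the vector of files written.
#' @export
build_report <- function(outdir, sites, assignments, cross,
                         truth_sites = NULL, match_distance = 100L) {
  for (nm in c("sites", "assignments", "cross"))
    if (is.null(get(nm))) stop("pipeline stage missing: ", nm)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f_bed <- file.path(outdir, "binding_sites.bed")
  write_sites_bed(sites, f_bed)
  f_assign <- file.path(outdir, "site_gene_assignments.tsv")
  write.table(assignments, f_assign, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_cross <- file.path(outdir, "gene_report.tsv")
  write.table(cross, f_cross, sep = "\t", quote = FALSE, row.names = FALSE)

  lines <- c(
    sprintf("binding_sites\t%d", nrow(sites)),
    sprintf("assigned_genes\t%d", length(unique(assignments$gene_id))),
    sprintf("bound_major_genes\t%d", sum(cross$binding == "bound_major")),
    sprintf("bound_minor_genes\t%d", sum(cross$binding == "bound_minor")),
    sprintf("induced_genes\t%d", sum(cross$status == "induced")),
    sprintf("repressed_genes\t%d", sum(cross$status == "repressed")),
    sprintf("universe\t%d", nrow(cross)))
  if (!is.null(truth_sites)) {
    ov <- overlap_sites(truth_sites, sites, match_distance)
    lines <- c(lines,
               sprintf("planted_sites\t%d", nrow(truth_sites)),
               sprintf("recovered_planted\t%d", nrow(ov$pairs)),
               sprintf("missed_planted\t%d", length(ov$unmatched_a)),
               sprintf("spurious_calls\t%d", length(ov$unmatched_b)))
  }
  f_sum <- file.path(outdir, "summary.txt")
  writeLines(lines, f_sum)
  invisible(c(f_bed, f_assign, f_cross, f_sum))
}
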