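# Binding-site comparison and promoter-assignment logic: apex-to-apex
# overlap matching across conditions/factors, major vs minor classification,
# common-site merging, promoter windows (ORF- and TSS-anchored) and
# intergenic-class labels.

#' Site-comparison and promoter-window parameters
#'
#' @param max_overlap_distance bp; two sites overlap iff their apexes are on
#'   the same chromosome and at most this far apart (inclusive boundary).
#' @param promoter_upstream_orf,promoter_downstream_orf promoter window
#'   anchored at the start codon: up to 1 kb of upstream intergenic sequence
#'   and 200 bp into the coding sequence.
#' @param promoter_upstream_tss,promoter_downstream_tss promoter window
#'   anchored at the TSS: 150 bp either side.
#' @param overlap_inclusive if `FALSE`, use a strict `<` overlap boundary
#'   instead of the default `<=`.
#' @return list of class `site_params`.
#' @export
site_params <- function(max_overlap_distance = 200L,
                        promoter_upstream_orf = 1000L,
                        promoter_downstream_orf = 200L,
                        promoter_upstream_tss = 150L,
                        promoter_downstream_tss = 150L,
                        overlap_inclusive = TRUE) {
  stopifnot(max_overlap_distance >= 0, promoter_upstream_orf >= 0,
            promoter_downstream_orf >= 0, promoter_upstream_tss >= 0,
            promoter_downstream_tss >= 0)
  structure(as.list(environment()), class = "site_params")
}

#' Match binding sites between two lists by apex distance
#'
#' Greedy nearest-apex matching: candidate pairs on the same chromosome with
#' apex distance within `max_distance` are taken in order of increasing
#' distance (leftmost pair on ties), each site used at most once. The
#' matching is symmetric in its two arguments.
#'
#' @param list_a,list_b site data.frames with columns `chrom` and `apex_bp`.
#' @param max_distance bp (inclusive boundary by default).
#' @param inclusive logical; `FALSE` for a strict `<` boundary.
#' @return list with `pairs` (data.frame idx_a, idx_b, distance) and integer
#'   vectors `unmatched_a`, `unmatched_b`.
#' @export
overlap_sites <- function(list_a, list_b, max_distance = 200L,
                          inclusive = TRUE) {
  na <- nrow(list_a); nb <- nrow(list_b)
  pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                      distance = numeric())
  if (na > 0 && nb > 0) {
    cand <- list()
    for (ch in intersect(unique(list_a$chrom), unique(list_b$chrom))) {
      ia <- which(list_a$chrom == ch)
      ib <- which(list_b$chrom == ch)
      d <- abs(outer(list_a$apex_bp[ia], list_b$apex_bp[ib], "-"))
      ok <- if (inclusive) which(d <= max_distance, arr.ind = TRUE)
            else which(d < max_distance, arr.ind = TRUE)
      if (nrow(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          idx_a = ia[ok[, 1]], idx_b = ib[ok[, 2]],
          distance = d[ok])
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$distance, cand$idx_a, cand$idx_b), ]
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_a[cand$idx_a[i]] && !used_b[cand$idx_b[i]]) {
          keep[i] <- TRUE
          used_a[cand$idx_a[i]] <- TRUE
          used_b[cand$idx_b[i]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$idx_a),
       unmatched_b = setdiff(seq_len(nb), pairs$idx_b))
}

#' Classify sites as major or minor across two conditions
#'
#' Sites found (within the overlap distance) in both lists are major; the
#' rest are minor. Reports the median enrichment level of each class, which
#' for real data separates the constitutive high-level sites from the
#' low-level condition-specific ones.
#'
#' @param sites_pre,sites_post site data.frames (chrom, apex_bp, level) from
#'   comparably processed (quantile-normalized) tracks.
#' @param params a [site_params()].
#' @return list with `pre` and `post` (inputs plus a `class` column),
#'   `pairs`, and `median_level` (major/minor medians pooled over both
#'   lists).
#' @export
classify_major <- function(sites_pre, sites_post, params = site_params()) {
  ov <- overlap_sites(sites_pre, sites_post, params$max_overlap_distance,
                      params$overlap_inclusive)
  lab <- function(s, matched) {
    s$class <- ifelse(seq_len(nrow(s)) %in% matched, "major", "minor")
    s
  }
  pre <- lab(sites_pre, ov$pairs$idx_a)
  post <- lab(sites_post, ov$pairs$idx_b)
  lev <- c(pre$level, post$level)
  cls <- c(pre$class, post$class)
  med <- c(major = median(lev[cls == "major"]),
           minor = median(lev[cls == "minor"]))
  list(pre = pre, post = post, pairs = ov$pairs, median_level = med)
}

#' Common major sites of two factors
#'
#' Pairs of major sites (one per factor) within the overlap distance are
#' merged into one site at the midpoint of the two apexes, carrying each
#' factor's enrichment level and their mean.
#'
#' @param major_a,major_b major-site data.frames (chrom, apex_bp, level).
#' @param params a [site_params()].
#' @return data.frame: chrom, apex_bp (midpoint), level_a, level_b,
#'   level_mean.
#' @export
common_major_sites <- function(major_a, major_b, params = site_params()) {
  ov <- overlap_sites(major_a, major_b, params$max_overlap_distance,
                      params$overlap_inclusive)
  p <- ov$pairs
  if (!nrow(p))
    return(data.frame(chrom = character(), apex_bp = numeric(),
                      level_a = numeric(), level_b = numeric(),
                      level_mean = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(
    chrom = major_a$chrom[p$idx_a],
    apex_bp = (major_a$apex_bp[p$idx_a] + major_b$apex_bp[p$idx_b]) / 2,
    level_a = major_a$level[p$idx_a],
    level_b = major_b$level[p$idx_b],
    stringsAsFactors = FALSE)
  out$level_mean <- (out$level_a + out$level_b) / 2
  out[order(out$chrom, out$apex_bp), , drop = FALSE]
}

# per-gene promoter window under the ORF rule, truncated so the upstream
# span stays intergenic (clipped at the neighbouring gene body)
.orf_windows <- function(annotation, up, down) {
  n <- nrow(annotation)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    same <- annotation$chrom == annotation$chrom[i]
    if (annotation$strand[i] == "+") {
      atg <- annotation$start[i]
      nb <- annotation$end[same & annotation$end < atg]
      lim <- if (length(nb)) max(nb) + 1L else 1L
      lo[i] <- max(atg - up, lim)
      hi[i] <- atg + down
    } else {
      atg <- annotation$end[i]
      nb <- annotation$start[same & annotation$start > atg]
      lim <- if (length(nb)) min(nb) - 1L else Inf
      lo[i] <- atg - down
      hi[i] <- min(atg + up, lim)
    }
  }
  data.frame(lo = lo, hi = hi)
}

#' Assign binding sites to probable promoters
#'
#' Under `rule = "orf"` a site maps to a gene iff its apex lies within the
#' window from `promoter_upstream_orf` bp of upstream *intergenic* sequence
#' to `promoter_downstream_orf` bp into the coding sequence, in the gene's
#' reading orientation. Under `rule = "tss"` the window is
#' `promoter_upstream_tss`/`promoter_downstream_tss` bp around the annotated
#' TSS. `rule = "either"` is the union of the two. A site in a divergent
#' intergenic region may map to both flanking genes; non-coding genes are
#' never assigned (but their bodies still bound the intergenic space).
#'
#' @param sites site data.frame (site rows carry chrom, apex_bp; a `site_id`
#'   column is used if present, else row numbers).
#' @param annotation gene annotation (gene_id, chrom, start, end, strand,
#'   coding, tss).
#' @param params a [site_params()].
#' @param rule one of "orf", "tss", "either".
#' @return data.frame: site_id, gene_id, rule_hit ("orf"/"tss"/"orf+tss").
#' @export
assign_promoters <- function(sites, annotation, params = site_params(),
                             rule = c("orf", "tss", "either")) {
  rule <- match.arg(rule)
  empty <- data.frame(site_id = character(), gene_id = character(),
                      rule_hit = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0 || nrow(annotation) == 0) return(empty)
  site_id <- if ("site_id" %in% names(sites)) sites$site_id
             else as.character(seq_len(nrow(sites)))
  coding <- if ("coding" %in% names(annotation)) annotation$coding
            else rep(TRUE, nrow(annotation))

  hit_for <- function(win, genes_keep) {
    res <- list()
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      gi <- which(annotation$chrom == ch & genes_keep & is.finite(win$lo) &
                    is.finite(win$hi))
      if (!length(si) || !length(gi)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = as.integer(round(sites$apex_bp[si])), width = 1L),
        IRanges::IRanges(start = as.integer(pmax(1, round(win$lo[gi]))),
                         end = as.integer(round(win$hi[gi]))))
      if (length(ov))
        res[[length(res) + 1L]] <- data.frame(
          site = si[S4Vectors::queryHits(ov)],
          gene = gi[S4Vectors::subjectHits(ov)])
    }
    if (length(res)) do.call(rbind, res) else data.frame(site = integer(),
                                                         gene = integer())
  }

  hits_orf <- hits_tss <- data.frame(site = integer(), gene = integer())
  if (rule %in% c("orf", "either")) {
    win <- .orf_windows(annotation, params$promoter_upstream_orf,
                        params$promoter_downstream_orf)
    hits_orf <- hit_for(win, coding)
  }
  if (rule %in% c("tss", "either")) {
    has_tss <- !is.na(annotation$tss)
    if (any(!has_tss & coding) && rule == "tss")
      warning(sum(!has_tss & coding), " gene(s) without TSS skipped")
    win <- data.frame(lo = annotation$tss - ifelse(annotation$strand == "+",
                                                   params$promoter_upstream_tss,
                                                   params$promoter_downstream_tss),
                      hi = annotation$tss + ifelse(annotation$strand == "+",
                                                   params$promoter_downstream_tss,
                                                   params$promoter_upstream_tss))
    win$lo[!has_tss] <- NA_real_
    win$hi[!has_tss] <- NA_real_
    hits_tss <- hit_for(win, coding & has_tss)
  }
  key <- function(h) paste(h$site, h$gene)
  all_h <- unique(rbind(hits_orf, hits_tss))
  if (!nrow(all_h)) return(empty)
  rh <- ifelse(key(all_h) %in% key(hits_orf) & key(all_h) %in% key(hits_tss),
               "orf+tss",
               ifelse(key(all_h) %in% key(hits_orf), "orf", "tss"))
  out <- data.frame(site_id = site_id[all_h$site],
                    gene_id = annotation$gene_id[all_h$gene],
                    rule_hit = rh, stringsAsFactors = FALSE)
  out[order(out$site_id, out$gene_id), , drop = FALSE]
}

#' Classify a site's genomic context
#'
#' `intragenic` if the apex falls inside any gene body; otherwise
#' `divergent` if the flanking genes transcribe away from the site on both
#' sides (head-to-head promoters), else `tandem` (co-oriented and
#' tail-to-tail intergenic regions are folded into tandem).
#'
#' @param sites site data.frame (chrom, apex_bp).
#' @param annotation gene annotation.
#' @return character vector of classes, one per site.
#' @export
classify_intergenic <- function(sites, annotation) {
  vapply(seq_len(nrow(sites)), function(k) {
    ch <- sites$chrom[k]; x <- sites$apex_bp[k]
    g <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(g)) stop("annotation does not cover chromosome ", ch)
    if (any(x >= g$start & x <= g$end)) return("intragenic")
    left <- g[g$end < x, , drop = FALSE]
    right <- g[g$start > x, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) {
      warning("site beyond the outermost gene; classified by single flank")
      fl <- if (nrow(left)) left[which.max(left$end), ] else right[which.min(right$start), ]
      facing <- (nrow(left) && fl$strand == "-") ||
        (nrow(right) && fl$strand == "+")
      return(if (facing) "divergent" else "tandem")
    }
    lg <- left[which.max(left$end), ]
    rg <- right[which.min(right$start), ]
    if (lg$strand == "-" && rg$strand == "+") "divergent" else "tandem"
  }, character(1))
}
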