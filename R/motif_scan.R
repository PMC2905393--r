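# Motif discovery from apex-centred binding sequences (MDscan-style seeded
# search with information-content scoring and refinement), PSSM log-odds
# scanning, and genome-wide ROC evaluation against unbound promoters.

.BASES <- c("A", "C", "G", "T")

#' Construct a PSSM
#'
#' @param mat 4 x w matrix of per-position base probabilities, rows A,C,G,T;
#'   columns must sum to 1.
#' @param bg background base probabilities (named, sums to 1).
#' @param pseudocount pseudocount per base used when the matrix was
#'   estimated (kept for provenance).
#' @return object of class `pssm`.
#' @export
pssm <- function(mat, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = 0.5) {
  stopifnot(nrow(mat) == 4, ncol(mat) >= 1,
            abs(sum(bg) - 1) < 1e-8,
            all(abs(colSums(mat) - 1) < 1e-6))
  rownames(mat) <- .BASES
  structure(list(mat = mat, bg = bg[.BASES], pseudocount = pseudocount),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM (width %d), consensus %s, IC %.2f bits\n",
              ncol(x$mat), pssm_consensus(x), information_content(x)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Consensus string of a PSSM
#' @param x a `pssm`.
#' @return character consensus (argmax base per column).
#' @export
pssm_consensus <- function(x) {
  paste(.BASES[apply(x$mat, 2, which.max)], collapse = "")
}

#' Reverse complement of a PSSM
#'
#' Motif discovery is strand-symmetric, so a motif may be reported in either
#' orientation; comparisons against a reference matrix should consider both.
#'
#' @param x a `pssm`.
#' @return the reverse-complement `pssm`.
#' @export
pssm_revcomp <- function(x) {
  m <- x$mat[4:1, ncol(x$mat):1, drop = FALSE]
  rownames(m) <- .BASES
  bg <- x$bg[4:1]
  names(bg) <- .BASES
  pssm(m, bg = bg, pseudocount = x$pseudocount)
}

#' Mean per-column total-variation distance between two PSSMs
#'
#' The orientation (forward or reverse complement of `x`) with the smaller
#' distance is used.
#'
#' @param x,ref `pssm` objects or 4 x w probability matrices of equal width.
#' @return mean over columns of half the L1 distance.
#' @export
pssm_distance <- function(x, ref) {
  mat <- function(p) if (inherits(p, "pssm")) p$mat else p
  tv <- function(a, b) mean(colSums(abs(a - b)) / 2)
  xm <- mat(x)
  if (inherits(x, "pssm")) {
    min(tv(xm, mat(ref)), tv(pssm_revcomp(x)$mat, mat(ref)))
  } else {
    rc <- xm[4:1, ncol(xm):1, drop = FALSE]
    min(tv(xm, mat(ref)), tv(rc, mat(ref)))
  }
}

#' Motif-discovery parameters
#'
#' @param apex_window bp of sequence around each apex used for discovery.
#' @param n_seed_sequences top-ranked sequences used to seed candidates.
#' @param n_refine_sequences next-ranked sequences used to refine them.
#' @param widths motif widths scanned (candidates compared by per-column
#'   information content across widths).
#' @param max_mismatch mismatches allowed when collecting w-mers matching a
#'   seed.
#' @param n_candidates candidate seeds kept for refinement.
#' @param pseudocount per-base pseudocount in PSSM estimation.
#' @param random_promoter_count unbound promoters sampled for ROC.
#' @param seed integer seed.
#' @return list of class `motif_params`.
#' @export
motif_params <- function(apex_window = 150L, n_seed_sequences = 30L,
                         n_refine_sequences = 30L, widths = 7:8,
                         max_mismatch = 1L, n_candidates = 30L,
                         pseudocount = 0.5, random_promoter_count = 100L,
                         seed = 1L) {
  stopifnot(apex_window %% 2 == 0, n_seed_sequences >= 1,
            n_refine_sequences >= 0, all(widths >= 4))
  structure(as.list(environment()), class = "motif_params")
}

#' Extract apex-centred sequences
#'
#' Windows of `window` bp centred on each site apex, clipped at chromosome
#' ends, ordered by descending enrichment level (the same ranking used in
#' the report tables).
#'
#' @param sites site data.frame (chrom, apex_bp, level; or level_mean).
#' @param genome named DNAStringSet.
#' @param window window size in bp.
#' @return named character vector of sequences in rank order.
#' @export
extract_apex_sequences <- function(sites, genome, window = 150L) {
  lev <- if ("level_mean" %in% names(sites)) sites$level_mean else sites$level
  ord <- order(lev, decreasing = TRUE)
  sites <- sites[ord, , drop = FALSE]
  half <- window %/% 2
  out <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    len <- length(genome[[sites$chrom[k]]])
    apex <- round(sites$apex_bp[k])
    if (apex < 1 || apex > len) stop("apex outside the genome")
    lo <- max(1L, apex - half)
    hi <- min(len, lo + window - 1L)
    lo <- max(1L, hi - window + 1L)
    out[k] <- as.character(Biostrings::subseq(genome[[sites$chrom[k]]], lo, hi))
  }
  names(out) <- if ("site_id" %in% names(sites)) sites$site_id
                else as.character(seq_len(nrow(sites)))
  out
}

# integer w-mer codes (base 4, A=0 C=1 G=2 T=3) for all offsets of all
# sequences; non-ACGT w-mers dropped
.encode_wmers <- function(seqs, w) {
  codes <- integer(0)
  for (s in seqs) {
    v <- match(strsplit(s, "")[[1]], .BASES) - 1L
    n <- length(v)
    if (n < w) next
    ok <- !is.na(v)
    # rolling code
    pow <- 4L^(w - seq_len(w))
    for (i in seq_len(n - w + 1L)) {
      win <- v[i:(i + w - 1L)]
      if (all(ok[i:(i + w - 1L)]))
        codes <- c(codes, sum(win * pow))
    }
  }
  codes
}

.decode_wmer <- function(code, w) {
  b <- numeric(w)
  for (j in w:1) { b[j] <- code %% 4; code <- code %/% 4 }
  b + 1  # 1-based base indices
}

.revcomp_code <- function(code, w) {
  b <- .decode_wmer(code, w) - 1L
  rc <- rev(3L - b)
  sum(rc * 4L^(w - seq_len(w)))
}

# 1-mismatch neighbourhood (including the code itself) as integer codes
.neighbourhood <- function(code, w, d) {
  out <- code
  if (d >= 1) {
    b <- .decode_wmer(code, w) - 1L
    pow <- 4L^(w - seq_len(w))
    for (j in seq_len(w)) for (nb in 0:3) if (nb != b[j])
      out <- c(out, code + (nb - b[j]) * pow[j])
  }
  out
}

.counts_to_pssm <- function(base_counts, bg, alpha) {
  m <- sweep(base_counts + alpha, 2, colSums(base_counts) + 4 * alpha, "/")
  pssm(m, bg = bg, pseudocount = alpha)
}

# accumulate per-position base counts for a set of codes with weights
.codes_base_counts <- function(codes, weights, w) {
  bc <- matrix(0, 4, w, dimnames = list(.BASES, NULL))
  for (i in seq_along(codes)) {
    b <- .decode_wmer(codes[i], w)
    for (j in seq_len(w)) bc[b[j], j] <- bc[b[j], j] + weights[i]
  }
  bc
}

#' Discover the enriched motif (MDscan-style)
#'
#' Enumerates w-mers in the seed sequences as candidate seeds; for each seed
#' collects all w-mers within `max_mismatch` mismatches (both strands)
#' across the seed sequences into a candidate matrix; keeps the
#' `n_candidates` candidates with the highest per-column information
#' content weighted by abundance; refines each by scanning the refinement
#' sequences for their best positive-scoring match and re-estimating; and
#' returns the candidate with the highest information content per column.
#'
#' @param seed_seqs character vector of top-ranked binding sequences.
#' @param refine_seqs character vector of next-ranked sequences.
#' @param params a [motif_params()].
#' @param bg background base probabilities; by default the 0-order base
#'   frequencies of all supplied sequences.
#' @return the winning `pssm`, with attributes `score` (IC per column) and
#'   `n_support`.
#' @export
discover_pssm <- function(seed_seqs, refine_seqs = character(),
                          params = motif_params(), bg = NULL) {
  usable <- nchar(seed_seqs) >= min(params$widths)
  if (!any(usable)) stop("all seed sequences shorter than the motif width")
  seed_seqs <- seed_seqs[usable]
  if (is.null(bg)) {
    tab <- table(factor(unlist(strsplit(c(seed_seqs, refine_seqs), "")),
                        levels = .BASES))
    bg <- as.numeric(tab) / sum(tab)
    names(bg) <- .BASES
    bg[bg == 0] <- 1e-3
    bg <- bg / sum(bg)
  }
  best <- NULL
  best_score <- -Inf
  for (w in params$widths) {
    codes <- .encode_wmers(seed_seqs, w)
    if (!length(codes)) next
    codes_rc <- vapply(codes, .revcomp_code, numeric(1), w = w)
    cnt <- tabulate(c(codes, codes_rc) + 1L, nbins = 4L^w)
    seeds <- unique(codes)
    # candidate score: IC/column of the neighbourhood-count PSSM, weighted
    # by log support, computed cheaply for every seed
    cand_stats <- lapply(seeds, function(s) {
      nb <- .neighbourhood(s, w, params$max_mismatch)
      wt <- cnt[nb + 1L]
      keep <- wt > 0
      if (!any(keep)) return(NULL)
      bc <- .codes_base_counts(nb[keep], wt[keep], w)
      p <- .counts_to_pssm(bc, bg, params$pseudocount)
      list(pssm = p, support = sum(wt),
           score = information_content(p) / w * log1p(sum(wt)))
    })
    cand_stats <- Filter(Negate(is.null), cand_stats)
    if (!length(cand_stats)) next
    ord <- order(vapply(cand_stats, `[[`, numeric(1), "score"),
                 decreasing = TRUE)
    top <- cand_stats[head(ord, params$n_candidates)]
    for (cand in top) {
      p <- cand$pssm
      support <- cand$support
      if (length(refine_seqs)) {
        # refinement: add each refinement sequence's best positive match
        bc <- p$mat * support  # back to (soft) counts
        add <- 0L
        for (s in refine_seqs) {
          hit <- .best_match(p, s)
          if (!is.null(hit) && hit$score > 0) {
            for (j in seq_len(w)) bc[hit$bases[j], j] <- bc[hit$bases[j], j] + 1
            add <- add + 1L
          }
        }
        if (add > 0) p <- .counts_to_pssm(bc, bg, params$pseudocount)
        support <- support + add
      }
      sc <- information_content(p) / w
      if (sc > best_score) {
        best_score <- sc
        best <- p
        attr(best, "score") <- sc
        attr(best, "n_support") <- support
      }
    }
  }
  if (is.null(best)) stop("no motif candidate could be built")
  best
}

# best-scoring w-mer of `seq` against pssm (both strands); returns base
# indices in motif orientation, or NULL if the sequence is too short
.best_match <- function(p, seq) {
  w <- ncol(p$mat)
  v <- match(strsplit(seq, "")[[1]], .BASES)
  n <- length(v)
  if (n < w) return(NULL)
  lo <- log2(p$mat / p$bg)
  best <- list(score = -Inf, bases = NULL)
  for (i in seq_len(n - w + 1L)) {
    b <- v[i:(i + w - 1L)]
    if (anyNA(b)) next
    s_f <- sum(lo[cbind(b, seq_len(w))])
    b_rc <- rev(5L - b)
    s_r <- sum(lo[cbind(b_rc, seq_len(w))])
    if (s_f >= best$score) best <- list(score = s_f, bases = b)
    if (s_r > best$score) best <- list(score = s_r, bases = b_rc)
  }
  if (is.null(best$bases)) NULL else best
}

#' Information content of a PSSM
#'
#' IC = sum over positions j and bases b of p(b,j) log2(p(b,j)/q(b)) bits.
#' With a uniform background this is sum_j (2 - H_j).
#'
#' @param x a `pssm`.
#' @return bits.
#' @export
information_content <- function(x) {
  p <- x$mat
  q <- x$bg
  term <- p * log2(sweep(p, 1, q, "/"))
  term[p == 0] <- 0
  sum(term)
}

#' Best log-odds PSSM score of a sequence
#'
#' Maximum over all offsets and both strands of
#' sum_j log2(p(base_j, j) / q(base_j)). Ambiguous bases contribute 0
#' (scored at background).
#'
#' @param x a `pssm`.
#' @param sequence character DNA string (length >= motif width).
#' @return the best score (log2 odds).
#' @export
pssm_score <- function(x, sequence) {
  w <- ncol(x$mat)
  v <- match(strsplit(toupper(sequence), "")[[1]], .BASES)
  n <- length(v)
  if (n < w) stop("sequence shorter than the motif width")
  lo <- log2(x$mat / x$bg)
  lo5 <- rbind(lo, 0)          # row 5 = ambiguous base, background score 0
  v[is.na(v)] <- 5L
  best <- -Inf
  for (i in seq_len(n - w + 1L)) {
    b <- v[i:(i + w - 1L)]
    s_f <- sum(lo5[cbind(b, seq_len(w))])
    b_rc <- rev(ifelse(b == 5L, 5L, 5L - b))
    s_r <- sum(lo5[cbind(b_rc, seq_len(w))])
    best <- max(best, s_f, s_r)
  }
  best
}

#' ROC curve and AUC for motif scores
#'
#' Sweeps a score threshold over bound (true) and unbound (false) promoter
#' scores; AUC by the trapezoid rule, which equals the Mann-Whitney U
#' statistic divided by n1*n2.
#'
#' @param bound_scores scores of bound promoter sequences.
#' @param unbound_scores scores of unbound promoter sequences.
#' @return list with `roc` (data.frame threshold, tpr, fpr) and `auc`.
#' @export
roc_auc <- function(bound_scores, unbound_scores) {
  stopifnot(length(bound_scores) > 0, length(unbound_scores) > 0)
  thr <- sort(unique(c(bound_scores, unbound_scores, Inf)),
              decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(bound_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(unbound_scores >= t), numeric(1))
  roc <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  auc <- sum(diff(c(0, fpr)) * (head(c(0, tpr), -1) + tail(c(0, tpr), -1)) / 2)
  list(roc = roc, auc = auc)
}
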