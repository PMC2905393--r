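# H2O2-responsiveness and Atf1/Pcr1-dependency calling from replicated
# expression time courses: SAM-style moderated d statistic, label-permutation
# FDR, the >2-fold + FDR + >=2-consecutive-time-points rule, dependency
# classes, time-to-fold-crossing, and induction ranking.

#' Response-calling parameters
#'
#' @param fold_change_min linear fold-change cutoff (default 2; a gene must
#'   change more than this between the compared groups).
#' @param fdr_max permutation FDR cutoff (default 0.05; 0.03 is the stricter
#'   alternative used in some displays).
#' @param min_consecutive minimum run of consecutive qualifying
#'   post-treatment time points (default 2).
#' @param n_permutations label permutations for the FDR (all distinct
#'   permutations are used when fewer exist).
#' @param s0_percentile percentile of the per-gene standard errors used as
#'   the SAM fudge factor s0 (default 0.5, the median).
#' @param seed integer seed for sampled permutations.
#' @return list of class `response_params`.
#' @export
response_params <- function(fold_change_min = 2, fdr_max = 0.05,
                            min_consecutive = 2L, n_permutations = 100L,
                            s0_percentile = 0.5, seed = 1L) {
  stopifnot(fold_change_min > 1, fdr_max > 0, fdr_max < 1,
            min_consecutive >= 1)
  structure(as.list(environment()), class = "response_params")
}

#' SAM-style moderated d statistic
#'
#' d = (mean_a - mean_b) / (s + s0), with s the pooled standard error of the
#' mean difference and s0 a fudge factor that damps genes with tiny
#' variance. Note d is not scale-invariant unless s0 is rescaled with the
#' data.
#'
#' @param values_a,values_b replicate values: numeric vectors (one gene) or
#'   genes x replicates matrices.
#' @param s0 fudge factor (same units as s).
#' @return numeric vector of d statistics (one per gene).
#' @export
sam_d <- function(values_a, values_b, s0 = 0) {
  if (is.null(dim(values_a))) values_a <- matrix(values_a, nrow = 1)
  if (is.null(dim(values_b))) values_b <- matrix(values_b, nrow = 1)
  na <- ncol(values_a); nb <- ncol(values_b)
  if (na < 2 || nb < 2) stop("need at least 2 replicates per group")
  va <- apply(values_a, 1, var)
  vb <- apply(values_b, 1, var)
  sp <- sqrt((1 / na + 1 / nb) *
               ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (rowMeans(values_a) - rowMeans(values_b)) / (sp + s0)
}

#' Pooled standard errors for a two-group comparison
#' @param values_a,values_b genes x replicates matrices.
#' @return per-gene pooled standard error of the mean difference.
#' @export
sam_s <- function(values_a, values_b) {
  na <- ncol(values_a); nb <- ncol(values_b)
  va <- apply(values_a, 1, var)
  vb <- apply(values_b, 1, var)
  sqrt((1 / na + 1 / nb) * ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
}

#' Permutation FDR and per-gene q-values
#'
#' FDR(t) = median over permutations of #\{|d*| >= t\} divided by
#' #\{|d| >= t\}; each gene's q is the FDR at its own |d|, made monotone by
#' a running minimum from the largest |d| down. A threshold exceeded by no
#' observed gene has FDR 0 by convention.
#'
#' @param d observed per-gene d statistics.
#' @param d_perm genes x permutations matrix of null d statistics.
#' @param thresholds optional vector of |d| thresholds; if supplied, a
#'   data.frame of per-threshold FDRs is returned instead of per-gene
#'   q-values (a threshold exceeded by no observed gene gets FDR 0).
#' @return numeric vector of q-values (one per gene), or a data.frame
#'   `threshold`, `fdr` when `thresholds` is given.
#' @export
permutation_fdr <- function(d, d_perm, thresholds = NULL) {
  ad <- abs(d)
  ap <- abs(d_perm)
  n_perm <- ncol(d_perm)
  fdr_at <- function(t) {
    n_obs <- sum(ad >= t)
    if (n_obs == 0) return(0)
    cnt <- vapply(seq_len(n_perm),
                  function(j) sum(ap[, j] >= t), numeric(1))
    min(1, median(cnt) / n_obs)
  }
  if (!is.null(thresholds))
    return(data.frame(threshold = thresholds,
                      fdr = vapply(thresholds, fdr_at, numeric(1))))
  ord <- order(ad, decreasing = TRUE)
  q <- vapply(ad, fdr_at, numeric(1))
  # monotone: running minimum from the most extreme gene down
  q[ord] <- cummin(q[ord])
  q
}

# all (or sampled) two-group label permutations as index matrices
.label_perms <- function(na, nb, n_max, seed) {
  all_c <- utils::combn(na + nb, na)
  # drop the identity assignment
  keep <- !apply(all_c, 2, function(x) identical(x, seq_len(na)))
  all_c <- all_c[, keep, drop = FALSE]
  if (ncol(all_c) > n_max) {
    set.seed(seed)
    all_c <- all_c[, sample(ncol(all_c), n_max), drop = FALSE]
  }
  all_c
}

# per-timepoint two-group SAM test with permutation q-values;
# A, B: genes x replicates
.sam_test <- function(A, B, params) {
  s <- sam_s(A, B)
  s0 <- quantile(s, params$s0_percentile, names = FALSE)
  d <- sam_d(A, B, s0)
  X <- cbind(A, B)
  na <- ncol(A)
  perms <- .label_perms(na, ncol(B), params$n_permutations, params$seed)
  d_perm <- apply(perms, 2, function(ia) {
    sam_d(X[, ia, drop = FALSE], X[, -ia, drop = FALSE], s0)
  })
  if (is.null(dim(d_perm))) d_perm <- matrix(d_perm, nrow = 1)
  q <- permutation_fdr(d, d_perm)
  list(d = d, q = q, delta = rowMeans(A) - rowMeans(B))
}

.time_cols <- function(m, t) {
  grep(sprintf("^t%g_r", t), colnames(m))
}

# longest same-direction qualifying run over ordered post-treatment points;
# sig: genes x timepoints logical, dir: genes x timepoints sign
.consecutive_call <- function(sig_up, sig_dn, k) {
  up <- apply(sig_up, 1, .has_consecutive, k = k)
  dn <- apply(sig_dn, 1, .has_consecutive, k = k)
  list(up = up, dn = dn)
}

#' Call H2O2-responsive genes
#'
#' Per post-treatment time point, the replicate values are compared with the
#' time-0 replicates by [sam_d()] with permutation q-values; a gene is
#' induced (repressed) iff at least `min_consecutive` consecutive time
#' points each show fold change > `fold_change_min` (< 1/fold_change_min)
#' at q < `fdr_max`, in a consistent direction.
#'
#' @param tc an `expression_timecourse` (uses its `wt` matrix) or a gene x
#'   column matrix with columns named `t<min>_r<rep>` including time 0.
#' @param params a [response_params()].
#' @param strain strain matrix to use when `tc` is an
#'   `expression_timecourse` (default "wt").
#' @return data.frame of class `response_calls`: gene_id, status
#'   ("induced"/"repressed"/"unresponsive"), max_abs_fc (log2), plus
#'   attribute `per_timepoint` (list of per-timepoint fc and q matrices).
#' @export
call_responsive <- function(tc, params = response_params(), strain = "wt") {
  m <- if (inherits(tc, "expression_timecourse")) tc$data[[strain]] else tc
  tp <- .matrix_timepoints(m)
  if (!0 %in% tp) stop("time 0 reference missing from the matrix")
  post <- sort(tp[tp > 0])
  B <- m[, .time_cols(m, 0), drop = FALSE]
  fc <- q <- matrix(NA_real_, nrow(m), length(post),
                    dimnames = list(rownames(m), paste0("t", post)))
  for (j in seq_along(post)) {
    A <- m[, .time_cols(m, post[j]), drop = FALSE]
    if (ncol(A) == 0) stop("missing time point: ", post[j])
    r <- .sam_test(A, B, params)
    fc[, j] <- r$delta
    q[, j] <- r$q
  }
  lf <- log2(params$fold_change_min)
  sig_up <- fc > lf & q < params$fdr_max
  sig_dn <- fc < -lf & q < params$fdr_max
  cc <- .consecutive_call(sig_up, sig_dn, params$min_consecutive)
  status <- rep("unresponsive", nrow(m))
  status[cc$up] <- "induced"
  status[cc$dn] <- "repressed"
  both <- cc$up & cc$dn
  if (any(both)) {
    # ambiguous direction: take the larger absolute change
    mx_up <- apply(fc[both, , drop = FALSE], 1, max)
    mx_dn <- apply(-fc[both, , drop = FALSE], 1, max)
    status[both] <- ifelse(mx_up >= mx_dn, "induced", "repressed")
  }
  out <- data.frame(gene_id = rownames(m), status = status,
                    max_abs_fc = apply(abs(fc), 1, max),
                    stringsAsFactors = FALSE)
  attr(out, "per_timepoint") <- list(fc = fc, q = q)
  class(out) <- c("response_calls", "data.frame")
  out
}

.matrix_timepoints <- function(m) {
  sort(unique(as.numeric(sub("^t([0-9.]+)_r[0-9]+$", "\\1", colnames(m)))))
}

#' Call response-disrupted genes in a deletion strain
#'
#' Applies the same fold-change + FDR + consecutive-time-point rule to the
#' mutant-versus-wild-type contrast at each post-treatment time point, on
#' 0-min-normalized levels (each strain's matrix is centred on its own
#' time-0 replicate mean per gene).
#'
#' @param mut_matrix,wt_matrix gene x column matrices sharing genes and time
#'   points (columns `t<min>_r<rep>`).
#' @param params a [response_params()].
#' @return character vector of disrupted gene ids, with attribute
#'   `per_timepoint`.
#' @export
call_dependent <- function(mut_matrix, wt_matrix,
                           params = response_params()) {
  if (!identical(rownames(mut_matrix), rownames(wt_matrix)) ||
      !identical(.matrix_timepoints(mut_matrix),
                 .matrix_timepoints(wt_matrix)))
    stop("mutant and wild-type matrices must share genes and time points")
  norm0 <- function(m) m - rowMeans(m[, .time_cols(m, 0), drop = FALSE])
  mm <- norm0(mut_matrix)
  wm <- norm0(wt_matrix)
  tp <- .matrix_timepoints(mm)
  post <- sort(tp[tp > 0])
  fc <- q <- matrix(NA_real_, nrow(mm), length(post),
                    dimnames = list(rownames(mm), paste0("t", post)))
  for (j in seq_along(post)) {
    A <- mm[, .time_cols(mm, post[j]), drop = FALSE]
    B <- wm[, .time_cols(wm, post[j]), drop = FALSE]
    r <- .sam_test(A, B, params)
    fc[, j] <- r$delta
    q[, j] <- r$q
  }
  lf <- log2(params$fold_change_min)
  cc <- .consecutive_call(fc > lf & q < params$fdr_max,
                          fc < -lf & q < params$fdr_max,
                          params$min_consecutive)
  out <- rownames(mm)[cc$up | cc$dn]
  attr(out, "per_timepoint") <- list(fc = fc, q = q)
  out
}

#' Classify factor dependency of responsive genes
#'
#' @param atf1_set,pcr1_set disrupted gene ids per deletion strain.
#' @param responsive_set gene ids called responsive in wild type.
#' @return data.frame gene_id, dependency in
#'   c("both","atf1_specific","pcr1_specific","independent").
#' @export
classify_dependency <- function(atf1_set, pcr1_set, responsive_set) {
  in_a <- responsive_set %in% atf1_set
  in_p <- responsive_set %in% pcr1_set
  dep <- ifelse(in_a & in_p, "both",
                ifelse(in_a, "atf1_specific",
                       ifelse(in_p, "pcr1_specific", "independent")))
  data.frame(gene_id = responsive_set, dependency = dep,
             stringsAsFactors = FALSE)
}

#' Time to reach a fold-change level
#'
#' First crossing time of log2(fold) by a mean log2 profile that starts at 0
#' at time 0, by linear interpolation between sampled time points; +Inf if
#' the level is never reached.
#'
#' @param profile mean log2 ratios over time (relative to time 0).
#' @param times sampling times in minutes (same length, starting at 0).
#' @param fold linear fold level (default 4).
#' @return minutes (possibly Inf).
#' @export
time_to_fold <- function(profile, times, fold = 4) {
  stopifnot(length(profile) == length(times), times[1] == 0)
  target <- log2(fold)
  if (profile[1] >= target) return(times[1])
  for (i in seq_along(profile)[-1]) {
    if (profile[i] >= target) {
      return(times[i - 1] + (target - profile[i - 1]) *
               (times[i] - times[i - 1]) / (profile[i] - profile[i - 1]))
    }
  }
  Inf
}

#' Rank responsive genes by mean induction
#'
#' Dense descending ranks of the mean log2 induction at 30, 60 and 120 min
#' across replicates.
#'
#' @param genes gene ids to rank (e.g. the induced set).
#' @param m wild-type expression matrix (columns `t<min>_r<rep>`).
#' @param times time points averaged (default c(30, 60, 120)).
#' @return data.frame gene_id, mean_induction, rank (dense; ties share).
#' @export
response_rank <- function(genes, m, times = c(30, 60, 120)) {
  cols <- unlist(lapply(times, function(t) .time_cols(m, t)))
  if (!length(cols)) stop("ranking time points absent from the matrix")
  base <- rowMeans(m[genes, .time_cols(m, 0), drop = FALSE])
  lev <- rowMeans(m[genes, cols, drop = FALSE]) - base
  data.frame(gene_id = genes, mean_induction = lev,
             rank = dense_rank(lev), stringsAsFactors = FALSE)
}
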