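# Normalization and SER (significantly enriched region) calling on tiling
# probe tracks: robust MAD threshold, windowed binomial test, >=4-consecutive
# rule, 3x5-probe smoothing for apex/level, and a permutation FDR.

#' Construct a probe track
#'
#' An ordered per-chromosome table of probe positions with per-probe log2
#' enrichment ratios (ChIP/WCE). Probes of both strands are pooled into one
#' positional grid: ChIP enrichment is not strand-resolved.
#'
#' @param chrom chromosome id per probe.
#' @param start probe start (1-based bp), strictly increasing per chromosome.
#' @param strand probe strand ("+"/"-").
#' @param ratio log2 enrichment ratio per probe (finite).
#' @param probe_length probe length in bp (used for probe midpoints).
#' @return data.frame of class `probe_track`.
#' @export
probe_track <- function(chrom, start, strand, ratio, probe_length = 50L) {
  stopifnot(length(chrom) == length(start), length(start) == length(ratio),
            all(is.finite(ratio)))
  ord <- order(chrom, start)
  x <- data.frame(chrom = chrom[ord], start = start[ord],
                  strand = strand[ord], ratio = ratio[ord],
                  stringsAsFactors = FALSE)
  if (any(unlist(tapply(x$start, x$chrom, function(s) diff(s) <= 0))))
    stop("probe positions must be strictly increasing within a chromosome")
  attr(x, "probe_length") <- as.integer(probe_length)
  class(x) <- c("probe_track", "data.frame")
  x
}

.probe_mid <- function(track) {
  track$start + attr(track, "probe_length") / 2
}

#' SER-calling parameters
#'
#' @param mad_multiplier `n` in Median(R) + n * MAD(R); default 2.5.
#' @param window_probes binomial test window L (odd); default 9 probes
#'   (about 300 bp at 17-bp tiling).
#' @param min_consecutive minimum run of above-threshold probes; default 4.
#' @param p_threshold binomial p-value cutoff; default 0.001.
#' @param smoothing_window,smoothing_rounds moving-average smoothing used
#'   for apex position and enrichment level; defaults 5 probes, 3 rounds.
#' @param top_fraction optional extra rank filter: probes must also lie in
#'   the top `top_fraction` of the ratio distribution (e.g. 0.03); `NULL`
#'   disables it. Composable with the MAD threshold.
#' @return list of class `ser_params`.
#' @export
ser_params <- function(mad_multiplier = 2.5, window_probes = 9L,
                       min_consecutive = 4L, p_threshold = 0.001,
                       smoothing_window = 5L, smoothing_rounds = 3L,
                       top_fraction = NULL) {
  stopifnot(window_probes %% 2 == 1, min_consecutive <= window_probes,
            p_threshold > 0, p_threshold < 1,
            smoothing_window %% 2 == 1)
  structure(list(mad_multiplier = mad_multiplier,
                 window_probes = as.integer(window_probes),
                 min_consecutive = as.integer(min_consecutive),
                 p_threshold = p_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 smoothing_rounds = as.integer(smoothing_rounds),
                 top_fraction = top_fraction),
            class = "ser_params")
}

#' LOWESS normalization of two-channel intensities
#'
#' Removes the intensity-dependent dye trend by local regression of the log
#' ratio M = log2(chip/wce) on the mean log intensity A, then median-centres
#' the corrected ratios so the array median is 0 in log scale.
#'
#' @param chip_intensity,wce_intensity positive intensity vectors of equal
#'   length.
#' @param f lowess smoother span.
#' @param design optional [make_array_design()]; if given, a `probe_track`
#'   is returned instead of a numeric vector.
#' @return normalized log2 ratios (median 0), or a `probe_track`.
#' @export
lowess_normalize <- function(chip_intensity, wce_intensity, f = 0.3,
                             design = NULL) {
  if (length(chip_intensity) != length(wce_intensity))
    stop("intensity vectors must have equal length")
  if (any(chip_intensity <= 0) || any(wce_intensity <= 0))
    stop("intensities must be positive")
  m <- log2(chip_intensity / wce_intensity)
  a <- (log2(chip_intensity) + log2(wce_intensity)) / 2
  fit <- lowess(a, m, f = f)
  trend <- approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  out <- m - trend
  out <- out - median(out)
  if (!is.null(design))
    return(probe_track(design$chrom, design$start, design$strand, out,
                       probe_length = attr(design, "probe_length")))
  out
}

#' Quantile normalization across tracks
#'
#' Makes the value distributions of a set of probe tracks identical (each
#' sorted value vector becomes the mean of the input quantiles) while
#' preserving within-track rank order.
#'
#' @param tracks list of `probe_track`s over identical probe sets.
#' @return list of `probe_track`s.
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  for (t in tracks[-1])
    if (!identical(ref$chrom, t$chrom) || !identical(ref$start, t$start))
      stop("tracks must share an identical probe set")
  m <- vapply(tracks, function(t) t$ratio, numeric(nrow(ref)))
  q <- limma::normalizeQuantiles(m)
  out <- Map(function(t, j) { t$ratio <- q[, j]; t },
             tracks, seq_along(tracks))
  names(out) <- names(tracks)
  out
}

#' Robust enrichment threshold
#'
#' Median(R) + n * MAD(R), with MAD the unscaled median absolute deviation
#' median(|R_i - median(R)|).
#'
#' @param x numeric vector of probe ratios, or a `probe_track`.
#' @param n MAD multiplier (default 2.5).
#' @return the threshold value.
#' @export
mad_threshold <- function(x, n = 2.5) {
  if (inherits(x, "probe_track")) x <- x$ratio
  if (length(x) == 0) stop("empty track")
  med <- median(x)
  med + n * median(abs(x - med))
}

#' Windowed binomial exceedance probability
#'
#' Upper-tail probability P(X >= m) for X ~ Binomial(L, Pr): the chance of
#' seeing at least `m` above-threshold probes in a window of `L` probes when
#' the genome-wide exceedance fraction is `Pr`.
#'
#' @param m exceedance count in the window (0 <= m <= L).
#' @param L window size in probes.
#' @param Pr genome-wide fraction of probes above the threshold.
#' @return the p-value.
#' @export
window_binom_p <- function(m, L, Pr) {
  if (any(Pr <= 0) || any(Pr >= 1)) stop("Pr must lie in (0, 1)")
  stopifnot(all(m >= 0), all(m <= L))
  pbinom(m - 1, L, Pr, lower.tail = FALSE)
}

#' Moving-average smoothing of a probe track
#'
#' Each round replaces every probe value by the mean over a centred window
#' (the window shrinks at chromosome edges), applied `rounds` times.
#' Constant tracks are unchanged; maxima never increase.
#'
#' @param track a `probe_track`.
#' @param window odd window size in probes.
#' @param rounds number of smoothing passes.
#' @return a `probe_track` with smoothed ratios.
#' @export
smooth_track <- function(track, window = 5L, rounds = 3L) {
  stopifnot(window %% 2 == 1, rounds >= 0)
  h <- window %/% 2
  sm1 <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    x <- track$ratio[sel]
    for (i in seq_len(rounds)) x <- sm1(x)
    track$ratio[sel] <- x
  }
  track
}

# windowed above-threshold counts with shrinking edge windows;
# returns list(m = counts, L_eff = actual window sizes)
.window_counts <- function(above, L) {
  n <- length(above)
  h <- L %/% 2
  cs <- cumsum(c(0L, above))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  list(m = cs[hi + 1L] - cs[lo], L_eff = hi - lo + 1L)
}

#' Call significantly enriched regions (SERs)
#'
#' A maximal run of at least `min_consecutive` consecutive probes above the
#' MAD threshold is an SER iff at least one window of `window_probes` probes
#' centred on a probe of the run has binomial exceedance p <=
#' `p_threshold` (with `Pr` the array-wide above-threshold fraction).
#' Apex position and enrichment level are taken from the smoothed track
#' (leftmost maximum on ties).
#'
#' @param track a normalized `probe_track`.
#' @param params a [ser_params()].
#' @return data.frame of class `occupancy`: chrom, start_bp, end_bp,
#'   n_probes, apex_bp, level, p_min; attributes `threshold` and `Pr`.
#' @export
call_sers <- function(track, params = ser_params()) {
  stopifnot(inherits(track, "probe_track"))
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_probes = integer(),
                      apex_bp = numeric(), level = numeric(),
                      p_min = numeric(), stringsAsFactors = FALSE)
  if (nrow(track) < params$window_probes) {
    warning("track shorter than the binomial window; no SERs called")
    class(empty) <- c("occupancy", "data.frame")
    return(empty)
  }
  thr <- mad_threshold(track, params$mad_multiplier)
  if (!is.null(params$top_fraction))
    thr <- max(thr, quantile(track$ratio, 1 - params$top_fraction))
  above <- track$ratio > thr
  Pr <- mean(above)
  if (Pr <= 0 || Pr >= 1) {
    class(empty) <- c("occupancy", "data.frame")
    attr(empty, "threshold") <- thr
    attr(empty, "Pr") <- Pr
    return(empty)
  }
  sm <- smooth_track(track, params$smoothing_window, params$smoothing_rounds)
  mid <- .probe_mid(track)
  plen <- attr(track, "probe_length")
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    ab <- above[sel]
    wc <- .window_counts(ab, params$window_probes)
    pv <- window_binom_p(wc$m, wc$L_eff, Pr)
    r <- rle(ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= params$min_consecutive)
    for (k in keep) {
      idx <- starts[k]:ends[k]
      pmin_run <- min(pv[idx])
      if (pmin_run > params$p_threshold) next
      gsel <- sel[idx]
      apex_i <- gsel[which.max(sm$ratio[gsel])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = track$start[gsel[1]],
        end_bp = track$start[gsel[length(gsel)]] + plen - 1L,
        n_probes = length(gsel),
        apex_bp = mid[apex_i],
        level = sm$ratio[apex_i],
        p_min = pmin_run,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  class(res) <- c("occupancy", "data.frame")
  attr(res, "threshold") <- thr
  attr(res, "Pr") <- Pr
  res
}

#' Apex of an SER
#'
#' Position and level of the maximum smoothed value within an SER's probe
#' span; ties are broken by the leftmost position.
#'
#' @param ser one row of a [call_sers()] result (or a list with chrom,
#'   start_bp, end_bp).
#' @param smoothed a smoothed `probe_track` (see [smooth_track()]).
#' @return list with `apex_bp` and `level`.
#' @export
find_apex <- function(ser, smoothed) {
  sel <- which(smoothed$chrom == ser$chrom &
                 smoothed$start >= ser$start_bp &
                 smoothed$start <= ser$end_bp)
  if (!length(sel)) stop("SER span contains no probes")
  i <- sel[which.max(smoothed$ratio[sel])]
  list(apex_bp = .probe_mid(smoothed)[i], level = smoothed$ratio[i])
}

#' Permutation estimate of the SER false discovery rate
#'
#' Permutes probe values within each chromosome (destroying spatial runs
#' while preserving the value distribution), re-calls SERs, and reports the
#' mean null SER count divided by the observed count, clipped to [0, 1].
#'
#' @param track a normalized `probe_track`.
#' @param params a [ser_params()].
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @return list with `fdr`, `observed` count and `null_counts`.
#' @export
estimate_fdr <- function(track, params = ser_params(), n_perm = 100L,
                         seed = 1L) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  obs <- nrow(call_sers(track, params))
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    perm <- track
    for (ch in unique(track$chrom)) {
      sel <- track$chrom == ch
      perm$ratio[sel] <- sample(track$ratio[sel])
    }
    nrow(call_sers(perm, params))
  }, numeric(1))
  fdr <- if (obs == 0) NaN else min(1, max(0, mean(null_counts) / obs))
  list(fdr = fdr, observed = obs, null_counts = null_counts)
}
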