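# Growth-curve phenotyping: half-maximal time T50, the stress-minus-optimal
# delay delta-T50, and the deficient score (mutant delta-T50 normalized by
# the wild type; >= 2 means H2O2-sensitive).

#' Half-maximal time of a growth curve
#'
#' The curve is lightly smoothed (3-point moving average); the half-maximal
#' level is (max + baseline)/2 with baseline the smoothed minimum (robust to
#' blank offsets); T50 is the first crossing time by linear interpolation.
#'
#' @param time time points in minutes (strictly increasing).
#' @param od optical densities (same length, >= 5 samples).
#' @return minutes; `Inf` with a warning if the half-maximal level is never
#'   reached.
#' @export
t50 <- function(time, od) {
  stopifnot(length(time) == length(od), length(time) >= 5,
            all(diff(time) > 0), all(od >= 0))
  n <- length(od)
  sm <- (c(od[1], od[-n]) + od + c(od[-1], od[n])) / 3
  half <- (max(sm) + min(sm)) / 2
  i <- which(sm >= half)[1]
  if (is.na(i)) {
    warning("curve never reaches the half-maximal level")
    return(Inf)
  }
  if (i == 1) return(time[1])
  time[i - 1] + (half - sm[i - 1]) * (time[i] - time[i - 1]) /
    (sm[i] - sm[i - 1])
}

#' Stress-induced delay in half-maximal time
#'
#' delta-T50 = T50(stress) - T50(optimal) for the same strain/replicate.
#' Negative values (faster growth under stress) are passed through.
#'
#' @param stress_time,stress_od stress-condition curve.
#' @param optimal_time,optimal_od optimal-condition curve.
#' @return minutes (Inf if either T50 is infinite).
#' @export
delta_t50 <- function(stress_time, stress_od, optimal_time, optimal_od) {
  t50(stress_time, stress_od) - t50(optimal_time, optimal_od)
}

#' Deficient score and sensitivity call
#'
#' score = mean(mutant delta-T50) / mean(wild-type delta-T50) over >= 3
#' replicate pairs (ratio of means by default; `method = "mean_of_ratios"`
#' pairs replicates instead). A strain is H2O2-sensitive iff its score is 2
#' or greater (inclusive).
#'
#' @param mutant_deltas,wildtype_deltas replicate delta-T50 values (>= 3
#'   each).
#' @param method aggregation rule.
#' @param cutoff sensitivity cutoff (default 2, inclusive).
#' @return list with `score` and logical `sensitive`.
#' @export
deficient_score <- function(mutant_deltas, wildtype_deltas,
                            method = c("ratio_of_means", "mean_of_ratios"),
                            cutoff = 2) {
  method <- match.arg(method)
  if (length(mutant_deltas) < 3 || length(wildtype_deltas) < 3)
    stop("need at least 3 replicate delta-T50 values per strain")
  if (mean(wildtype_deltas) <= 0)
    stop("wild-type mean delta-T50 must be positive for a defined score")
  score <- if (method == "ratio_of_means") {
    mean(mutant_deltas) / mean(wildtype_deltas)
  } else {
    if (length(mutant_deltas) != length(wildtype_deltas))
      stop("mean_of_ratios requires paired replicates")
    mean(mutant_deltas / wildtype_deltas)
  }
  list(score = score, sensitive = score >= cutoff)
}

#' Growth-fitness analysis of a curve set
#'
#' Computes per-replicate delta-T50 for every strain in a `growth_curves`
#' table and the deficient score of each strain against the wild type.
#'
#' @param curves a `growth_curves` data.frame (well, strain, condition,
#'   replicate, time_min, od).
#' @param wildtype name of the reference strain (default "wt").
#' @param cutoff sensitivity cutoff.
#' @return data.frame: strain, mean_delta_t50, score, sensitive.
#' @export
analyze_growth <- function(curves, wildtype = "wt", cutoff = 2) {
  stopifnot(wildtype %in% curves$strain)
  deltas <- function(strain) {
    reps <- sort(unique(curves$replicate[curves$strain == strain]))
    vapply(reps, function(r) {
      s <- curves[curves$strain == strain & curves$replicate == r &
                    curves$condition == "stress", ]
      o <- curves[curves$strain == strain & curves$replicate == r &
                    curves$condition == "optimal", ]
      delta_t50(s$time_min, s$od, o$time_min, o$od)
    }, numeric(1))
  }
  wt_d <- deltas(wildtype)
  strains <- unique(curves$strain)
  rows <- lapply(strains, function(st) {
    d <- deltas(st)
    sc <- deficient_score(d, wt_d, cutoff = cutoff)
    data.frame(strain = st, mean_delta_t50 = mean(d), score = sc$score,
               sensitive = sc$sensitive, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
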