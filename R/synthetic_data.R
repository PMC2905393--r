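# Synthetic-data generator: genomes, annotations, tiling-array designs,
# ChIP tracks with planted binding sites, H2O2 expression time courses with
# Atf1/Pcr1 dependency structure, and logistic mini-culture growth curves.
# Every generator is seeded and records its ground truth so downstream
# callers can be tested for recovery.

#' Simulation configuration
#'
#' Builds the configuration object shared by all synthetic-data generators.
#' Defaults emulate the study design: ~50-mer probes tiled every 17 bp on
#' alternating strands, peak-shaped log2 enrichment planted at motif-bearing
#' intergenic promoters, H2O2 expression time courses at 0/10/30/60/120 min
#' in wild type, atf1-delete and pcr1-delete strains in triplicate, and
#' logistic growth with a stress-induced lag.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param n_genes total genes across the genome.
#' @param frac_divergent fraction of genes arranged in head-to-head
#'   (divergent-promoter) pairs.
#' @param frac_noncoding fraction of genes flagged non-coding (tRNA-like);
#'   they occupy annotation space but never receive promoter assignments.
#' @param probe_length probe length in bp.
#' @param probe_step tiling step in bp (probes alternate strand).
#' @param peak_width half-width in bp of the triangular enrichment kernel.
#' @param n_planted_sites number of planted binding sites.
#' @param site_enrichment_log2 planted peak height (log2 units).
#' @param noise_sd per-probe Gaussian noise sd on the log2 ratio.
#' @param true_pssm 4 x w probability matrix (rows A,C,G,T) used to sample
#'   the planted binding sequences; columns must each sum to 1.
#' @param base_freq genome background base frequencies (A,C,G,T).
#' @param time_points expression sampling times in minutes; must start at 0.
#' @param n_replicates expression replicates per strain and time point.
#' @param induced_fraction,repressed_fraction fractions of genes induced /
#'   repressed by the stress.
#' @param dependency_probs named probabilities over
#'   c("both","atf1_only","pcr1_only","independent") for responsive genes.
#' @param expr_noise_sd replicate noise sd (log2) in expression data.
#' @param attenuation residual fraction of the response amplitude left in a
#'   deletion strain for genes that depend on the deleted factor.
#' @param rise_direct,rise_indirect minutes for a directly bound / unbound
#'   (indirect) induced gene to reach its full response amplitude.
#' @param growth_K,growth_r logistic plateau OD and rate (per min).
#' @param lag_optimal logistic midpoint t0 (min) under optimal growth.
#' @param lag_stress extra midpoint delay (min) stress adds for a strain of
#'   sensitivity 1 (the wild type); a strain's delay is sensitivity times this.
#' @param growth_noise_sd OD measurement noise sd.
#' @param growth_times sampling grid (min) for growth curves.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 150000L,
                       n_chromosomes = 3L,
                       n_genes = 150L,
                       frac_divergent = 0.3,
                       frac_noncoding = 0.05,
                       probe_length = 50L,
                       probe_step = 17L,
                       peak_width = 250L,
                       n_planted_sites = 50L,
                       site_enrichment_log2 = 3,
                       noise_sd = 0.3,
                       true_pssm = default_true_pssm(),
                       base_freq = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
                       time_points = c(0, 10, 30, 60, 120),
                       n_replicates = 3L,
                       induced_fraction = 0.2,
                       repressed_fraction = 0.1,
                       dependency_probs = c(both = 0.4, atf1_only = 0.2,
                                            pcr1_only = 0.1, independent = 0.3),
                       expr_noise_sd = 0.25,
                       attenuation = 0.15,
                       rise_direct = 10,
                       rise_indirect = 30,
                       growth_K = 1.0,
                       growth_r = 0.05,
                       lag_optimal = 300,
                       lag_stress = 60,
                       growth_noise_sd = 0.005,
                       growth_times = seq(0, 900, by = 15),
                       seed = 1L) {
  stopifnot(probe_step < probe_length,
            frac_divergent >= 0, frac_divergent <= 1,
            induced_fraction >= 0, repressed_fraction >= 0,
            induced_fraction + repressed_fraction <= 1,
            n_replicates >= 1, time_points[1] == 0,
            abs(sum(base_freq) - 1) < 1e-8)
  if (any(abs(colSums(true_pssm) - 1) > 1e-8))
    stop("true_pssm columns must each sum to 1")
  if (!identical(rownames(true_pssm), c("A", "C", "G", "T")))
    stop("true_pssm rows must be named A, C, G, T")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted motif
#'
#' A strong ATF/CREB-family heptamer (consensus ATGACGT, the M26-class
#' cAMP-response element bound by Atf1-Pcr1), with 0.85 weight on the
#' consensus base at every position.
#'
#' @return 4 x 7 probability matrix with rows A,C,G,T.
#' @export
default_true_pssm <- function() {
  consensus <- c("A", "T", "G", "A", "C", "G", "T")
  bases <- c("A", "C", "G", "T")
  m <- matrix(0.05, nrow = 4, ncol = length(consensus),
              dimnames = list(bases, NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 0.85
  m
}

.sample_bases <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

.sample_motif <- function(pssm) {
  paste(vapply(seq_len(ncol(pssm)), function(j)
    sample(rownames(pssm), 1, prob = pssm[, j]), character(1)), collapse = "")
}

#' Generate a genome, gene annotation, and planted binding sites
#'
#' Lays out non-overlapping genes on each chromosome (a configured fraction
#' in head-to-head divergent pairs, the rest co-oriented), draws a random
#' background genome, plants `n_planted_sites` binding sites in intergenic
#' promoter regions (each carrying one sequence sampled from the true motif
#' matrix), and records which gene(s) each site should be assigned to under
#' the promoter rules.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (Biostrings::DNAStringSet),
#'   `annotation` (data.frame: gene_id, chrom, start, end, strand, coding,
#'   tss, arrangement, bound) and `sites` (data.frame: site_id, chrom,
#'   apex_bp, motif_start, motif_seq, target_genes, height). Coordinates are
#'   1-based inclusive; `tss` is the transcription start position;
#'   `target_genes` is a `;`-joined gene-id string.
#' @export
make_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chroms <- sprintf("chr%d", seq_len(n_chr))
  genes_per_chr <- rep(config$n_genes %/% n_chr, n_chr)
  extra <- config$n_genes %% n_chr
  if (extra > 0) genes_per_chr[seq_len(extra)] <- genes_per_chr[seq_len(extra)] + 1

  if (config$n_genes > 0 &&
      any(config$genome_length / pmax(genes_per_chr, 1) < 1200))
    stop("genome too short for the requested gene count (need >= 1200 bp per gene slot)")

  ann <- list()
  gid <- 0L
  for (ci in seq_len(n_chr)) {
    g <- genes_per_chr[ci]
    if (g == 0) next
    unit <- config$genome_length %/% g
    len <- round(unit * 0.55)
    off <- round(unit * 0.30)
    start <- (seq_len(g) - 1L) * unit + off
    end <- start + len - 1L
    ann[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", gid + seq_len(g)),
      chrom = chroms[ci], start = start, end = end,
      strand = "+", stringsAsFactors = FALSE)
    gid <- gid + g
  }
  annotation <- do.call(rbind, ann)
  if (is.null(annotation)) {
    annotation <- data.frame(gene_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character(), coding = logical(),
                             tss = integer(), arrangement = character(),
                             bound = logical(), stringsAsFactors = FALSE)
  }

  n <- nrow(annotation)
  annotation$arrangement <- rep("tandem", n)
  if (n >= 2 && config$frac_divergent > 0) {
    # consecutive same-chromosome index pairs (1,2), (3,4), ... become
    # head-to-head: first gene minus strand (5' end at its right edge)
    n_pairs <- round(config$frac_divergent * n / 2)
    cand <- which(seq_len(n) %% 2 == 1 & seq_len(n) < n &
                    annotation$chrom == c(annotation$chrom[-1], NA)[seq_len(n)])
    take <- head(sample(cand), n_pairs)
    for (i in take) {
      annotation$strand[i] <- "-"
      annotation$arrangement[c(i, i + 1L)] <- "divergent"
    }
  }
  if (n > 0) {
    annotation$coding <- TRUE
    n_nc <- round(config$frac_noncoding * n)
    if (n_nc > 0)
      annotation$coding[sample(which(annotation$arrangement == "tandem"),
                               min(n_nc, sum(annotation$arrangement == "tandem")))] <- FALSE
    # TSS a short distance upstream of the ATG
    tss_off <- round(runif(n, 30, 150))
    annotation$tss <- ifelse(annotation$strand == "+",
                             annotation$start - tss_off,
                             annotation$end + tss_off)
  }

  # background genome
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(.sample_bases(config$genome_length, config$base_freq), collapse = ""),
    character(1)))
  names(genome) <- chroms

  # plant binding sites in intergenic promoter space
  sites <- data.frame(site_id = character(), chrom = character(),
                      apex_bp = integer(), motif_start = integer(),
                      motif_seq = character(), target_genes = character(),
                      height = numeric(), stringsAsFactors = FALSE)
  annotation$bound <- rep(FALSE, n)
  if (config$n_planted_sites > 0 && n > 0) {
    coding_idx <- which(annotation$coding)
    if (length(coding_idx) < config$n_planted_sites)
      stop("not enough coding genes to host the requested planted sites")
    targets <- sample(coding_idx, config$n_planted_sites)
    w <- ncol(config$true_pssm)
    rows <- vector("list", length(targets))
    for (k in seq_along(targets)) {
      i <- targets[k]
      atg <- if (annotation$strand[i] == "+") annotation$start[i] else annotation$end[i]
      dir <- if (annotation$strand[i] == "+") -1L else 1L
      # stay intergenic: distance to the neighbouring gene on the upstream side
      same_chr <- annotation$chrom == annotation$chrom[i]
      if (dir < 0) {
        lim <- max(c(0L, annotation$end[same_chr & annotation$end < annotation$start[i]]))
        max_u <- min(800L, annotation$start[i] - lim - 60L)
      } else {
        lim_v <- annotation$start[same_chr & annotation$start > annotation$end[i]]
        lim <- if (length(lim_v)) min(lim_v) else config$genome_length + 1L
        max_u <- min(800L, lim - annotation$end[i] - 60L)
      }
      u <- round(runif(1, 100, max(101, max_u)))
      apex <- atg + dir * u
      # which genes does the promoter rule attach this apex to?
      tg <- annotation$gene_id[i]
      if (annotation$arrangement[i] == "divergent") {
        j <- if (annotation$strand[i] == "+") i - 1L else i + 1L
        if (j >= 1 && j <= n && annotation$chrom[j] == annotation$chrom[i] &&
            annotation$coding[j]) {
          atg_j <- if (annotation$strand[j] == "+") annotation$start[j] else annotation$end[j]
          if (abs(apex - atg_j) <= 1000) tg <- c(tg, annotation$gene_id[j])
        }
      }
      motif <- .sample_motif(config$true_pssm)
      ms <- apex - w %/% 2
      genome[[annotation$chrom[i]]] <-
        Biostrings::replaceLetterAt(genome[[annotation$chrom[i]]],
                                    ms:(ms + w - 1L),
                                    strsplit(motif, "")[[1]])
      rows[[k]] <- data.frame(site_id = sprintf("site%03d", k),
                              chrom = annotation$chrom[i],
                              apex_bp = as.integer(apex),
                              motif_start = as.integer(ms),
                              motif_seq = motif,
                              target_genes = paste(sort(tg), collapse = ";"),
                              height = config$site_enrichment_log2,
                              stringsAsFactors = FALSE)
      annotation$bound[match(tg, annotation$gene_id)] <- TRUE
    }
    sites <- do.call(rbind, rows)
  }
  list(genome = genome, annotation = annotation, sites = sites)
}

#' Tiling-array design
#'
#' Probe start positions on an arithmetic grid of `probe_step` bp, strand
#' alternating probe to probe, per chromosome.
#'
#' @param genome named DNAStringSet (or named vector of chromosome lengths).
#' @param probe_length probe length (bp).
#' @param probe_step tiling step (bp).
#' @return data.frame of class `probe_design`: chrom, start (1-based),
#'   strand.
#' @export
make_array_design <- function(genome, probe_length = 50L, probe_step = 17L) {
  lens <- if (is.numeric(genome)) genome else Biostrings::width(genome)
  if (is.null(names(lens)) && !is.null(names(genome))) names(lens) <- names(genome)
  if (length(lens) == 0) stop("genome is empty")
  if (any(probe_length > lens)) stop("probe_length exceeds a chromosome length")
  out <- lapply(names(lens), function(ch) {
    starts <- seq.int(1L, lens[[ch]] - probe_length + 1L, by = probe_step)
    data.frame(chrom = ch, start = starts,
               strand = rep_len(c("+", "-"), length(starts)),
               stringsAsFactors = FALSE)
  })
  design <- do.call(rbind, out)
  attr(design, "probe_length") <- as.integer(probe_length)
  class(design) <- c("probe_design", "data.frame")
  design
}

#' Simulate a ChIP-chip log-ratio track
#'
#' Gaussian per-probe noise plus, for each planted site, a triangular
#' enrichment kernel (half-width `peak_width`, height the site's `height`)
#' centred on the site apex; evaluated at probe midpoints.
#'
#' @param design a [make_array_design()] result.
#' @param sites data.frame with chrom, apex_bp, height (may have 0 rows).
#' @param config a [sim_config()] (peak_width, noise_sd).
#' @param seed seed for this track (defaults to `config$seed`).
#' @return a `probe_track` data.frame: chrom, start, strand, ratio.
#' @export
simulate_chip_track <- function(design, sites, config, seed = config$seed) {
  stopifnot(inherits(design, "probe_design"))
  plen <- attr(design, "probe_length")
  set.seed(seed)
  ratio <- rnorm(nrow(design), 0, config$noise_sd)
  if (nrow(sites) > 0) {
    mid <- design$start + plen / 2
    for (k in seq_len(nrow(sites))) {
      sel <- design$chrom == sites$chrom[k]
      d <- abs(mid[sel] - sites$apex_bp[k])
      ratio[sel] <- ratio[sel] +
        sites$height[k] * pmax(0, 1 - d / config$peak_width)
    }
  }
  probe_track(design$chrom, design$start, design$strand, ratio,
              probe_length = plen)
}

#' Simulate expression time courses for wt, atf1-delete and pcr1-delete
#'
#' Induced genes rise linearly (in log2) to a per-gene amplitude drawn from
#' a floored normal (floor log2(2.5), so the >2-fold rule is exercisable
#' under noise), sustained through 120 min; bound (directly regulated) genes
#' reach full amplitude by `rise_direct` min, unbound induced genes by
#' `rise_indirect` min (the indirect-response delay). In a deletion strain,
#' genes depending on the deleted factor keep only `attenuation` of their
#' amplitude. Replicate Gaussian noise is applied everywhere, including at
#' time 0.
#'
#' @param annotation annotation from [make_genome_annotation()] (uses the
#'   `bound` flag to decide which induced genes are direct targets).
#' @param config a [sim_config()].
#' @param seed seed (defaults to `config$seed + 1`).
#' @return object of class `expression_timecourse`: list with `data` (named
#'   list of gene x (time,replicate) matrices for strains wt, atf1, pcr1;
#'   columns named `t<min>_r<rep>`), `time_points`, `n_replicates`, and
#'   `truth` (gene_id, status, dependency, bound, rise, amplitude).
#' @export
simulate_expression <- function(annotation, config, seed = config$seed + 1L) {
  set.seed(seed)
  genes <- annotation$gene_id
  ng <- length(genes)
  status <- rep("unresponsive", ng)
  n_ind <- round(config$induced_fraction * ng)
  n_rep <- round(config$repressed_fraction * ng)
  # induced genes preferentially drawn from the bound (planted-target) genes
  bound_idx <- which(annotation$bound)
  other_idx <- setdiff(seq_len(ng), bound_idx)
  ind <- c(bound_idx[seq_len(min(length(bound_idx), ceiling(n_ind / 2)))],
           sample(other_idx, max(0, n_ind - min(length(bound_idx),
                                                ceiling(n_ind / 2)))))
  ind <- ind[seq_len(min(n_ind, length(ind)))]
  rep_pool <- setdiff(seq_len(ng), ind)
  repg <- sample(rep_pool, min(n_rep, length(rep_pool)))
  status[ind] <- "induced"
  status[repg] <- "repressed"

  dependency <- rep(NA_character_, ng)
  resp <- status != "unresponsive"
  dependency[resp] <- sample(names(config$dependency_probs), sum(resp),
                             replace = TRUE, prob = config$dependency_probs)

  # amplitudes floored at log2(2.5) so the >2-fold rule is exercisable under
  # noise; centred at 2.5 log2 (4-8 fold) so group-average induction crosses
  # the 4-fold level, as the stress-response profiles it emulates do
  amplitude <- numeric(ng)
  amplitude[resp] <- pmax(log2(2.5), rnorm(sum(resp), 2.5, 0.5))
  amplitude[status == "repressed"] <- -amplitude[status == "repressed"]
  rise <- ifelse(annotation$bound, config$rise_direct, config$rise_indirect)

  tp <- config$time_points
  nr <- config$n_replicates
  # columns grouped by time point, replicates within: t0_r1, t0_r2, ...
  cn <- as.vector(outer(seq_len(nr), tp,
                        function(r, t) sprintf("t%g_r%d", t, r)))
  base_profile <- function(amp, rise_t) {
    sapply(tp, function(t) amp * pmin(1, t / rise_t))
  }
  strain_amp <- list(
    wt = amplitude,
    atf1 = ifelse(!is.na(dependency) & dependency %in% c("both", "atf1_only"),
                  amplitude * config$attenuation, amplitude),
    pcr1 = ifelse(!is.na(dependency) & dependency %in% c("both", "pcr1_only"),
                  amplitude * config$attenuation, amplitude))
  data <- lapply(strain_amp, function(a) {
    prof <- t(vapply(seq_len(ng),
                     function(i) base_profile(a[i], rise[i]),
                     numeric(length(tp))))
    m <- prof[, rep(seq_along(tp), each = nr), drop = FALSE] +
      matrix(rnorm(ng * length(tp) * nr, 0, config$expr_noise_sd),
             nrow = ng)
    dimnames(m) <- list(genes, cn)
    m
  })
  structure(list(data = data, time_points = tp, n_replicates = nr,
                 truth = data.frame(gene_id = genes, status = status,
                                    dependency = dependency,
                                    bound = annotation$bound, rise = rise,
                                    amplitude = amplitude,
                                    stringsAsFactors = FALSE)),
            class = "expression_timecourse")
}

#' Simulate mini-culture growth curves
#'
#' Logistic growth OD(t) = K / (1 + exp(-r (t - t0))). Under stress the
#' midpoint shifts right by `sensitivity * lag_stress` minutes; Gaussian
#' measurement noise is added and OD floored at 0.
#'
#' @param strains data.frame with columns `strain` and `sensitivity`
#'   (multiplier of the wild-type stress lag; the wild type must be present
#'   with sensitivity 1), or a character vector of strain names (all
#'   sensitivity 1).
#' @param config a [sim_config()].
#' @param n_replicates replicates per strain and condition (>= 3).
#' @param seed seed (defaults to `config$seed + 2`).
#' @return `growth_curves` data.frame: well, strain, condition
#'   ("optimal"/"stress"), replicate, time_min, od.
#' @export
simulate_growth_curves <- function(strains, config, n_replicates = 3L,
                                   seed = config$seed + 2L) {
  if (is.character(strains))
    strains <- data.frame(strain = strains, sensitivity = 1,
                          stringsAsFactors = FALSE)
  stopifnot(n_replicates >= 3, all(c("strain", "sensitivity") %in% names(strains)))
  set.seed(seed)
  tt <- config$growth_times
  rows <- list()
  well <- 0L
  for (i in seq_len(nrow(strains))) {
    for (cond in c("optimal", "stress")) {
      for (r in seq_len(n_replicates)) {
        well <- well + 1L
        t0 <- config$lag_optimal +
          if (cond == "stress") strains$sensitivity[i] * config$lag_stress else 0
        od <- config$growth_K / (1 + exp(-config$growth_r * (tt - t0))) +
          rnorm(length(tt), 0, config$growth_noise_sd)
        rows[[well]] <- data.frame(well = sprintf("W%03d", well),
                                   strain = strains$strain[i],
                                   condition = cond, replicate = r,
                                   time_min = tt, od = pmax(0, od),
                                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("growth_curves", "data.frame")
  out
}
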