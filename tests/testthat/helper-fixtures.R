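# Shared synthetic fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# default study-condition simulation (seed 7): genome + annotation + planted
# sites + array design + one ChIP track
chip_fixture <- function() {
  if (is.null(.fixture_env$chip)) {
    cfg <- sim_config(seed = 7)
    ga <- make_genome_annotation(cfg)
    des <- make_array_design(ga$genome, cfg$probe_length, cfg$probe_step)
    track <- simulate_chip_track(des, ga$sites, cfg, seed = 7)
    .fixture_env$chip <- list(cfg = cfg, genome = ga$genome,
                              annotation = ga$annotation, sites = ga$sites,
                              design = des, track = track)
  }
  .fixture_env$chip
}

# expression fixture at seed 3 (the dependency-recovery condition)
expr_fixture <- function() {
  if (is.null(.fixture_env$expr)) {
    cfg <- sim_config(seed = 3)
    ga <- make_genome_annotation(cfg)
    .fixture_env$expr <- list(cfg = cfg, annotation = ga$annotation,
                              tc = simulate_expression(ga$annotation, cfg))
  }
  .fixture_env$expr
}

# tiny single-chromosome track with one noiseless triangular peak
toy_peak_track <- function(height = 3, noise_sd = 0, seed = 1,
                           apex = 5000, n_probes = 500, step = 17,
                           peak_width = 250) {
  set.seed(seed)
  start <- seq(1, by = step, length.out = n_probes)
  mid <- start + 25
  ratio <- rnorm(n_probes, 0, max(noise_sd, 0)) +
    height * pmax(0, 1 - abs(mid - apex) / peak_width)
  if (noise_sd == 0) ratio <- height * pmax(0, 1 - abs(mid - apex) / peak_width)
  probe_track(rep("chr1", n_probes), start,
              rep_len(c("+", "-"), n_probes), ratio)
}

table1_path <- function() {
  system.file("extdata", "atf1_pcr1_top_bound_genes.tsv",
              package = "stresschip")
}

table4_path <- function() {
  system.file("extdata", "sty1_dependency_genes.tsv", package = "stresschip")
}

counts_path <- function() {
  system.file("extdata", "study_counts.tsv", package = "stresschip")
}

read_counts <- function() {
  x <- read.table(counts_path(), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  setNames(x$value, x$quantity)
}
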