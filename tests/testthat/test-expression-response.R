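# SAM-style statistic, permutation FDR, the consecutive-time-point
# responsiveness rule, dependency classes, time-to-fold and ranking.

# small constructed matrix helper: genes x (5 time points x 3 reps)
mk_expr <- function(profiles, noise_sd = 0.05, seed = 1,
                    tp = c(0, 10, 30, 60, 120), nr = 3) {
  set.seed(seed)
  ng <- nrow(profiles)
  cn <- as.vector(outer(seq_len(nr), tp,
                        function(r, t) sprintf("t%g_r%d", t, r)))
  m <- profiles[, rep(seq_along(tp), each = nr), drop = FALSE] +
    matrix(rnorm(ng * nr * length(tp), 0, noise_sd), ng)
  dimnames(m) <- list(rownames(profiles), cn)
  m
}

test_that("sam_d matches the direct formula", {
  a <- matrix(c(3, 3, 3), 1)
  expect_equal(unname(sam_d(a, a, 0.1)), 0)
  # means 3 and 1, pooled SE 0.5, s0 0.5 -> d = 2
  set.seed(1)
  va <- c(2.5, 3.0, 3.5)
  vb <- c(0.5, 1.0, 1.5)
  s <- sam_s(matrix(va, 1), matrix(vb, 1))
  d <- sam_d(matrix(va, 1), matrix(vb, 1), s0 = 0.5)
  expect_equal(unname(d), (mean(va) - mean(vb)) / (s + 0.5))
  expect_equal(unname(s), sqrt((1/3 + 1/3) * (var(va) + var(vb)) / 2))
  # scaling both groups by c is NOT d-invariant unless s0 rescales
  d2 <- sam_d(matrix(2 * va, 1), matrix(2 * vb, 1), s0 = 0.5)
  d2r <- sam_d(matrix(2 * va, 1), matrix(2 * vb, 1), s0 = 1.0)
  expect_false(isTRUE(all.equal(unname(d2), unname(d))))
  expect_equal(unname(d2r), unname(d))
  expect_error(sam_d(matrix(1, 1, 1), matrix(1, 1, 1)), "2 replicates")
})

test_that("permutation FDR separates a planted effect and handles edges", {
  set.seed(2)
  d <- c(10, rnorm(99, 0, 0.5))
  d_perm <- matrix(rnorm(100 * 30, 0, 0.5), 100, 30)
  q <- permutation_fdr(d, d_perm)
  expect_lt(q[1], 0.05)
  expect_true(all(diff(q[order(abs(d), decreasing = TRUE)]) >= 0))
  # thresholds above max |d|: FDR 0 by convention
  ft <- permutation_fdr(d, d_perm, thresholds = c(1, 100))
  expect_equal(ft$fdr[2], 0)
})

test_that("responsiveness needs >2-fold at two consecutive points", {
  profiles <- rbind(
    yes      = c(0, 0.1, 1.35, 1.35, 0.5),   # >2-fold at 30 and 60 min
    single   = c(0, 0, 1.6, 0, 0),           # one time point only
    gap      = c(0, 1.4, 0, 1.4, 0),         # two non-consecutive points
    flat     = c(0, 0, 0, 0, 0),
    down     = c(0, -1.3, -1.4, -1.3, -1.2)) # repressed
  m <- mk_expr(profiles, noise_sd = 0.05, seed = 3)
  calls <- call_responsive(m, response_params(seed = 3))
  st <- setNames(calls$status, calls$gene_id)
  expect_equal(unname(st["yes"]), "induced")
  expect_equal(unname(st["single"]), "unresponsive")
  expect_equal(unname(st["gap"]), "unresponsive")
  expect_equal(unname(st["flat"]), "unresponsive")
  expect_equal(unname(st["down"]), "repressed")
  # all-zero matrix: everything unresponsive
  z <- mk_expr(matrix(0, 5, 5,
                      dimnames = list(paste0("g", 1:5), NULL)),
               noise_sd = 0.05, seed = 4)
  expect_true(all(call_responsive(z)$status == "unresponsive"))
  # missing time 0 is an error
  expect_error(call_responsive(m[, -grep("^t0_", colnames(m))]),
               "time 0")
})

test_that("raising the fold-change cutoff never adds responsive genes", {
  fx <- expr_fixture()
  lo <- call_responsive(fx$tc, response_params(fold_change_min = 2))
  hi <- call_responsive(fx$tc, response_params(fold_change_min = 3))
  lo_set <- lo$gene_id[lo$status != "unresponsive"]
  hi_set <- hi$gene_id[hi$status != "unresponsive"]
  expect_true(all(hi_set %in% lo_set))
})

test_that("dependency calling flags constructed disruption only", {
  fx <- expr_fixture()
  tc <- fx$tc
  # identical matrices: nothing disrupted
  expect_length(call_dependent(tc$data$wt, tc$data$wt), 0)
  a_set <- call_dependent(tc$data$atf1, tc$data$wt)
  p_set <- call_dependent(tc$data$pcr1, tc$data$wt)
  truth <- tc$truth
  both_genes <- truth$gene_id[!is.na(truth$dependency) &
                                truth$dependency == "both" &
                                truth$status == "induced"]
  expect_gte(mean(both_genes %in% a_set), 0.9)
  expect_gte(mean(both_genes %in% p_set), 0.9)
  indep <- truth$gene_id[!is.na(truth$dependency) &
                           truth$dependency == "independent"]
  expect_lte(mean(indep %in% a_set), 0.1)
  expect_error(call_dependent(tc$data$atf1[1:5, ], tc$data$wt),
               "share genes")

  # at low replicate noise the construction is exact: every both-dependent
  # gene is flagged in both deletion strains
  cfg <- sim_config(seed = 5, expr_noise_sd = 0.1,
                    genome_length = 60000L, n_chromosomes = 1L,
                    n_genes = 40L, n_planted_sites = 10L)
  ga <- make_genome_annotation(cfg)
  tc2 <- simulate_expression(ga$annotation, cfg)
  a2 <- call_dependent(tc2$data$atf1, tc2$data$wt)
  p2 <- call_dependent(tc2$data$pcr1, tc2$data$wt)
  bg2 <- tc2$truth$gene_id[!is.na(tc2$truth$dependency) &
                             tc2$truth$dependency == "both"]
  expect_true(all(bg2 %in% a2))
  expect_true(all(bg2 %in% p2))
})

test_that("dependency labels recover the ground truth", {
  fx <- expr_fixture()
  tc <- fx$tc
  calls <- call_responsive(tc)
  resp <- calls$gene_id[calls$status != "unresponsive"]
  dep <- classify_dependency(call_dependent(tc$data$atf1, tc$data$wt),
                             call_dependent(tc$data$pcr1, tc$data$wt),
                             resp)
  key <- c(both = "both", atf1_only = "atf1_specific",
           pcr1_only = "pcr1_specific", independent = "independent")
  m <- merge(dep, tc$truth, by = "gene_id")
  m <- m[m$status != "unresponsive", ]
  acc <- mean(m$dependency.x == key[m$dependency.y])
  expect_gte(acc, 0.9)
  # trivial labels
  d <- classify_dependency(c("g1", "g2"), c("g1"), c("g1", "g2", "g3"))
  expect_equal(d$dependency, c("both", "atf1_specific", "independent"))
})

test_that("time-to-fold interpolates linearly in log2", {
  tp <- c(0, 10, 30, 60, 120)
  expect_equal(time_to_fold(c(0, 2, 2.5, 2.5, 2.5), tp), 10)
  expect_equal(time_to_fold(c(0, NA, 3, 3, 3)[-2], tp[-2]), 20)
  expect_equal(time_to_fold(c(0, 0, 0, 0, 0), tp), Inf)
  expect_equal(time_to_fold(c(0, 1, 1.5, 3, 3), tp, fold = 8), 60)
})

test_that("response ranking is dense, tie-sharing and order-invariant", {
  m <- mk_expr(rbind(g1 = c(0, 1, 2, 2, 2),
                     g2 = c(0, 1, 2, 2, 2),
                     g3 = c(0, 0.5, 1, 1, 1)),
               noise_sd = 0, seed = 5)
  r <- response_rank(c("g1", "g2", "g3"), m)
  expect_equal(r$rank, c(1, 1, 2))
  r2 <- response_rank(c("g3", "g1", "g2"), m)
  expect_equal(r2$rank[r2$gene_id == "g3"], 2)
  expect_equal(response_rank("g1", m)$rank, 1)
})

test_that("null expression data stays within the FDR budget", {
  set.seed(6)
  ng <- 200
  null_m <- mk_expr(matrix(0, ng, 5,
                           dimnames = list(sprintf("g%03d", 1:ng), NULL)),
                    noise_sd = 0.3, seed = 6)
  calls <- call_responsive(null_m, response_params(seed = 6))
  expect_lte(mean(calls$status != "unresponsive"), 0.05 + 0.02)
})
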