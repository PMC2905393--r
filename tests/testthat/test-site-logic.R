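# Overlap matching, major/minor classification, common-site merging,
# promoter assignment and intergenic-class labels.

mk_sites <- function(apex, chrom = "chr1", level = 1) {
  data.frame(chrom = rep_len(chrom, length(apex)), apex_bp = apex,
             level = rep_len(level, length(apex)),
             stringsAsFactors = FALSE)
}

test_that("overlap boundary is inclusive at 200 bp and configurable", {
  a <- mk_sites(1000)
  expect_equal(nrow(overlap_sites(a, mk_sites(1200), 200)$pairs), 1)
  expect_equal(nrow(overlap_sites(a, mk_sites(1201), 200)$pairs), 0)
  # strict variant excludes the boundary
  expect_equal(nrow(overlap_sites(a, mk_sites(1200), 200,
                                  inclusive = FALSE)$pairs), 0)
  # different chromosomes never match
  expect_equal(nrow(overlap_sites(a, mk_sites(1000, chrom = "chr2"),
                                  200)$pairs), 0)
})

test_that("overlap matching is symmetric, greedy-nearest and one-to-one", {
  a <- mk_sites(c(100, 400, 2000))
  b <- mk_sites(c(150, 380, 5000))
  ov <- overlap_sites(a, b, 200)
  expect_equal(nrow(ov$pairs), 2)
  expect_equal(ov$unmatched_a, 3)
  expect_equal(ov$unmatched_b, 3)
  # swapped arguments give the mirrored pairing
  vo <- overlap_sites(b, a, 200)
  expect_equal(vo$pairs$idx_a, ov$pairs$idx_b)
  expect_equal(vo$pairs$idx_b, ov$pairs$idx_a)
  # identical lists: everything matched at distance 0
  ii <- overlap_sites(a, a, 200)
  expect_equal(nrow(ii$pairs), 3)
  expect_equal(ii$pairs$distance, rep(0, 3))
  expect_length(ii$unmatched_a, 0)
  # each site used at most once even with competing candidates
  c1 <- mk_sites(c(100, 140))
  c2 <- mk_sites(120)
  ovc <- overlap_sites(c1, c2, 200)
  expect_equal(nrow(ovc$pairs), 1)
  expect_equal(ovc$pairs$idx_a, 1)  # nearest (distance 20)
})

test_that("major/minor classification follows the overlap", {
  a <- mk_sites(c(100, 1000), level = c(3, 2))
  b <- mk_sites(c(5000, 9000), level = c(1, 1))
  cm <- classify_major(a, b)
  expect_true(all(cm$pre$class == "minor"))
  expect_true(all(cm$post$class == "minor"))

  cm2 <- classify_major(a, a)
  expect_true(all(cm2$pre$class == "major"))

  # construction: 70% shared truth gives ~70% major calls
  set.seed(10)
  shared <- mk_sites(sort(sample(seq(1000, 9e4, by = 1500), 35)))
  only_a <- mk_sites(sort(sample(seq(1e5, 1.4e5, by = 1500), 15)))
  only_b <- mk_sites(sort(sample(seq(1.5e5, 1.9e5, by = 1500), 15)))
  pre <- rbind(shared, only_a)
  post <- rbind(shared, only_b)
  cm3 <- classify_major(pre, post)
  expect_equal(mean(cm3$pre$class == "major"), 0.7)
})

test_that("common major sites merge at the apex midpoint", {
  a <- mk_sites(1000, level = 2)
  b <- mk_sites(1100, level = 4)
  cm <- common_major_sites(a, b)
  expect_equal(cm$apex_bp, 1050)
  expect_equal(cm$level_mean, 3)
  expect_equal(nrow(common_major_sites(a, mk_sites(numeric(0)))), 0)
})

test_that("promoter assignment windows anchored at the ORF and TSS", {
  ann <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(5000, 20000), end = c(8000, 23000),
    strand = "+", coding = TRUE, tss = c(4900, 18500),
    stringsAsFactors = FALSE)
  sp <- site_params()
  # 500 bp upstream: assigned under the ORF rule
  expect_equal(assign_promoters(mk_sites(4500), ann, sp, "orf")$gene_id, "gA")
  # 1100 bp upstream: outside the 1 kb window
  expect_equal(nrow(assign_promoters(mk_sites(3900), ann, sp, "orf")), 0)
  # 100 bp into the coding sequence: still promoter under the ORF rule
  expect_equal(assign_promoters(mk_sites(5100), ann, sp, "orf")$gene_id, "gA")
  # 250 bp into the coding sequence: no
  expect_equal(nrow(assign_promoters(mk_sites(5250), ann, sp, "orf")), 0)
  # gB: TSS far upstream of the ATG; a site 1400 bp upstream of the ATG is
  # recovered only through the TSS rule
  s <- mk_sites(18600)
  expect_equal(nrow(assign_promoters(s, ann, sp, "orf")), 0)
  expect_equal(assign_promoters(s, ann, sp, "tss")$gene_id, "gB")
  either <- assign_promoters(s, ann, sp, "either")
  expect_equal(either$gene_id, "gB")
  expect_equal(either$rule_hit, "tss")
})

test_that("divergent sites may map to both genes; either contains orf", {
  ann <- data.frame(
    gene_id = c("gL", "gR"), chrom = "chr1",
    start = c(1000, 4500), end = c(3000, 6500),
    strand = c("-", "+"), coding = TRUE, tss = c(3100, 4400),
    stringsAsFactors = FALSE)
  sp <- site_params()
  asg <- assign_promoters(mk_sites(3700), ann, sp, "orf")
  expect_setequal(asg$gene_id, c("gL", "gR"))

  fx <- chip_fixture()
  a_orf <- assign_promoters(fx$sites, fx$annotation, sp, "orf")
  a_any <- assign_promoters(fx$sites, fx$annotation, sp, "either")
  expect_true(all(paste(a_orf$site_id, a_orf$gene_id) %in%
                    paste(a_any$site_id, a_any$gene_id)))
})

test_that("upstream windows stop at neighbouring gene bodies and skip non-coding", {
  ann <- data.frame(
    gene_id = c("gUp", "gMain"), chrom = "chr1",
    start = c(1000, 3200), end = c(2900, 6000),
    strand = "+", coding = c(TRUE, TRUE), tss = c(950, 3150),
    stringsAsFactors = FALSE)
  sp <- site_params()
  # apex inside gUp's body, 400 bp upstream of gMain's ATG: the upstream
  # span is not intergenic there, so no assignment to gMain
  asg <- assign_promoters(mk_sites(2800), ann, sp, "orf")
  expect_false("gMain" %in% asg$gene_id)
  # non-coding gene never assigned
  ann$coding[2] <- FALSE
  asg2 <- assign_promoters(mk_sites(3000), ann, sp, "orf")
  expect_false("gMain" %in% asg2$gene_id)
})

test_that("intergenic classes: intragenic, divergent, tandem", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1000, 5000, 9000), end = c(3000, 7000, 11000),
    strand = c("-", "+", "+"), coding = TRUE,
    tss = c(3100, 4900, 8900), stringsAsFactors = FALSE)
  expect_equal(classify_intergenic(mk_sites(2000), ann), "intragenic")
  expect_equal(classify_intergenic(mk_sites(4000), ann), "divergent")
  expect_equal(classify_intergenic(mk_sites(8000), ann), "tandem")
  expect_warning(cls <- classify_intergenic(mk_sites(12000), ann),
                 "single flank")
  expect_true(cls %in% c("tandem", "divergent"))
})
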