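one_site_tables <- function(mod1, unmod1, mod2, unmod2,
                            reps = 1, site_pos = 500L) {
  n <- c(mod1 + unmod1, mod2 + unmod2)
  stage <- rep(c("A", "B"), n)
  rep_id <- unlist(lapply(n, function(k)
    rep_len(seq_len(reps), k)))
  reads <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(sum(n))),
    sample_id = sprintf("%s_rep%d", stage, rep_id),
    stage = stage, gene_id = "g1", transcript_id = "t1", strand = "+",
    three_prime_pos = 1000L, polya_len = 50, full_length = TRUE,
    as_class = "none")
  modcalls <- tibble::tibble(
    read_id = reads$read_id, gene_id = "g1", site_chrom = "chr1",
    site_pos = site_pos, site_strand = "+",
    modified = c(rep(c(TRUE, FALSE), c(mod1, unmod1)),
                 rep(c(TRUE, FALSE), c(mod2, unmod2))))
  list(reads = reads, modcalls = modcalls)
}

test_that("site stoichiometry is modified over total covering reads", {
  t <- one_site_tables(7, 3, 0, 10)
  sc <- m6a_site_counts(t$modcalls, t$reads)
  expect_equal(sc$ratio[sc$stage == "A"], 0.7)
  expect_equal(sc$ratio[sc$stage == "B"], 0.0)
  t2 <- one_site_tables(10, 0, 5, 5)
  sc2 <- m6a_site_counts(t2$modcalls, t2$reads)
  expect_equal(sc2$ratio[sc2$stage == "A"], 1.0)
})

test_that("a zero-coverage condition is untestable, never ratio 0", {
  t <- one_site_tables(6, 4, 0, 0)
  sc <- m6a_site_counts(t$modcalls, t$reads)
  expect_equal(nrow(sc), 1)  # only stage A has coverage
  res <- m6a_diff_test(sc, "A", "B")
  expect_false(res$tested)
  expect_equal(res$reason, "no_coverage_condition2")
  expect_true(is.na(res$p_value))
})

test_that("duplicate calls from one read at one site are rejected", {
  t <- one_site_tables(2, 2, 2, 2)
  dup <- dplyr::bind_rows(t$modcalls, t$modcalls[1, ])
  expect_error(m6a_site_counts(dup, t$reads),
               class = "tailshift_validation_error")
})

test_that("region assignment is strand-aware with inclusive CDS termini", {
  ann_plus <- as_annotation(
    tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", cds_start = 51L, cds_end = 250L,
                   as_class = "none"),
    tibble::tibble(transcript_id = "t1", start = 1L, end = 300L))
  sites <- tibble::tibble(gene_id = "g1", site_chrom = "chr1",
                          site_pos = c(250L, 251L, 50L, 51L),
                          site_strand = "+")
  out <- assign_site_region(sites, ann_plus)
  expect_equal(out$region[match(c(250, 251, 50, 51), out$site_pos)],
               c("CDS", "3UTR", "5UTR", "CDS"))

  # minus-strand mirror about 301: CDS (51,250), site 250 -> still CDS
  ann_minus <- as_annotation(
    tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "-", cds_start = 51L, cds_end = 250L,
                   as_class = "none"),
    tibble::tibble(transcript_id = "t1", start = 1L, end = 300L))
  out_m <- assign_site_region(
    tibble::tibble(gene_id = "g1", site_chrom = "chr1",
                   site_pos = c(51L, 50L, 250L, 251L), site_strand = "-"),
    ann_minus)
  expect_equal(out_m$region[match(c(51, 50, 250, 251), out_m$site_pos)],
               c("CDS", "3UTR", "CDS", "5UTR"))

  # outside the exons: unassigned, reported
  expect_message(
    out_u <- assign_site_region(
      tibble::tibble(gene_id = "g1", site_chrom = "chr1",
                     site_pos = 400L, site_strand = "+"), ann_plus),
    "unassigned")
  expect_equal(out_u$region, "unassigned")
})

test_that("a single mid-CDS site concentrates all metagene mass in one bin", {
  sites <- tibble::tibble(region = "CDS", frac = 0.4975)  # 100th base of 200
  prof <- metagene_profile(sites, bins_per_region = 10)
  expect_equal(nrow(prof), 30)
  expect_equal(prof$density[prof$bin == 15], 1)
  expect_equal(sum(prof$density), 1)
})

test_that("the metagene profile is a normalized density for any input", {
  set.seed(301)
  sites <- tibble::tibble(
    region = sample(c("5UTR", "CDS", "3UTR"), 500, replace = TRUE),
    frac = runif(500))
  prof <- metagene_profile(sites, bins_per_region = 7)
  expect_equal(sum(prof$density), 1, tolerance = 1e-12)
  expect_true(all(prof$density >= 0))
})

test_that("uniform sites yield a flat profile", {
  set.seed(302)
  sites <- tibble::tibble(
    region = sample(c("5UTR", "CDS", "3UTR"), 10000, replace = TRUE),
    frac = runif(10000))
  prof <- metagene_profile(sites, bins_per_region = 10)
  chisq <- stats::chisq.test(prof$density * 10000)
  expect_gt(chisq$p.value, 0.001)
})

test_that("no assignable sites gives an explicit empty profile", {
  expect_warning(
    prof <- metagene_profile(tibble::tibble(region = "unassigned",
                                            frac = NA_real_)),
    "empty profile")
  expect_equal(sum(prof$density), 0)
  expect_equal(attr(prof, "n_sites"), 0L)
})

test_that("differential m6A matches the Fisher/delta rule on known tables", {
  # ((5,5),(5,5)): no association
  t <- one_site_tables(5, 5, 5, 5)
  res <- m6a_diff_test(m6a_site_counts(t$modcalls, t$reads), "A", "B")
  expect_equal(res$p_value, 1)
  expect_equal(res$delta, 0)
  expect_false(res$significant)

  # ((10,0),(0,10)): maximal association
  t2 <- one_site_tables(10, 0, 0, 10)
  res2 <- m6a_diff_test(m6a_site_counts(t2$modcalls, t2$reads), "A", "B")
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res2$delta, -1)
  expect_true(res2$significant)

  # ((8,2),(2,8)): p ~ 0.023, delta -0.6
  t3 <- one_site_tables(8, 2, 2, 8)
  res3 <- m6a_diff_test(m6a_site_counts(t3$modcalls, t3$reads), "A", "B")
  expect_equal(res3$p_value, 0.023014, tolerance = 1e-4)
  expect_equal(res3$delta, -0.6)
  expect_true(res3$significant)
})

test_that("delta averages per-replicate ratios while Fisher pools counts", {
  # replicate ratios A: 1.0 and 0.5 (mean 0.75); pooled 3/4
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:8),
    sample_id = c("A_rep1", "A_rep1", "A_rep2", "A_rep2",
                  "B_rep1", "B_rep1", "B_rep2", "B_rep2"),
    stage = rep(c("A", "B"), each = 4), gene_id = "g1",
    transcript_id = "t1", strand = "+", three_prime_pos = 1000L,
    polya_len = 50, full_length = TRUE, as_class = "none")
  modcalls <- tibble::tibble(
    read_id = reads$read_id, gene_id = "g1", site_chrom = "chr1",
    site_pos = 500L, site_strand = "+",
    modified = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  sc <- m6a_site_counts(modcalls, reads)
  res <- m6a_diff_test(sc, "A", "B")
  expect_equal(res$ratio_1, 0.75)
  expect_equal(res$ratio_2, 0.25)
  expect_equal(res$delta, -0.5)
  expect_equal(res$p_value, fisher_exact2(3, 1, 1, 3), tolerance = 1e-12)
})

test_that("condition swap negates delta and preserves the Fisher p", {
  sim <- small_sim(seed = 93, n_genes = 20, reads = 60)
  sc <- m6a_site_counts(sim$modcalls, sim$reads)
  a <- m6a_diff_test(sc, "SubPeg", "ExpPod2")
  b <- m6a_diff_test(sc, "ExpPod2", "SubPeg")
  j <- dplyr::inner_join(a, b, by = "site_id", suffix = c("_ab", "_ba")) %>%
    dplyr::filter(tested_ab)
  expect_gt(nrow(j), 10)
  expect_equal(j$delta_ba, -j$delta_ab, tolerance = 1e-12)
  expect_equal(j$p_value_ba, j$p_value_ab, tolerance = 1e-12)
})

test_that("per-gene rates average site stoichiometries", {
  t <- one_site_tables(4, 6, 4, 6)                  # site 1: 0.4
  t2 <- one_site_tables(6, 4, 6, 4, site_pos = 900L) # site 2: 0.6
  reads <- t$reads
  modcalls <- dplyr::bind_rows(
    t$modcalls,
    dplyr::mutate(t2$modcalls, read_id = t$modcalls$read_id))
  sc <- m6a_site_counts(modcalls, reads)
  rates <- m6a_gene_rates(sc)
  expect_equal(rates$gene_rate[rates$stage == "A"], 0.5)
  expect_warning(m6a_stage_rates(sc, stages = c("A", "B", "C")),
                 "no testable genes")
})

test_that("metagene profile is invariant under translation and mirroring", {
  sim <- small_sim(seed = 94, n_genes = 15, reads = 40)
  sites <- sim$sites %>%
    dplyr::select(gene_id, site_chrom, site_pos, site_strand)
  base <- metagene_profile(assign_site_region(sites, sim$annotation))

  shifted <- metagene_profile(assign_site_region(
    dplyr::mutate(sites, site_pos = site_pos + 10000L),
    shift_annotation(sim$annotation, 10000L)))
  mirrored <- metagene_profile(assign_site_region(
    dplyr::mutate(sites, site_pos = 10000000L - site_pos,
                  site_strand = flip_strand(site_strand)),
    mirror_annotation(sim$annotation)))
  expect_equal(shifted$density, base$density)
  expect_equal(mirrored$density, base$density)
})
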