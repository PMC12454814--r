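one_gene_annotation <- function(strand = "+") {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = strand)
  tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                       strand = strand, cds_start = 101L, cds_end = 1000L,
                       as_class = "none")
  ex <- tibble::tibble(transcript_id = "t1", start = 1L, end = 2000L)
  as_annotation(genes, tx, ex)
}

endpoint_reads <- function(positions, stage = "A", sample_id = "A_rep1") {
  tibble::tibble(read_id = sprintf("r%04d", seq_along(positions)),
                 sample_id = sample_id, stage = stage, gene_id = "g1",
                 transcript_id = "t1", strand = "+",
                 three_prime_pos = as.integer(positions),
                 polya_len = 50, full_length = TRUE, as_class = "none")
}

# brute-force transitive-closure clustering: merge any two positions within
# `window`, then take connected components
cluster_oracle <- function(positions, window) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(positions[i] - positions[j]) <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(positions, comp)
}

test_that("single-linkage clustering follows the inclusive gap rule", {
  reads <- endpoint_reads(c(rep(1100, 3), rep(1101, 2), rep(1160, 4)))
  cl <- cluster_pas(reads, one_gene_annotation(), window = 24)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$mode_pos, c(1100, 1160))
  expect_equal(cl$n_total[cl$mode_pos == 1100], 5)
  expect_equal(cl$n_total[cl$mode_pos == 1160], 4)

  # single endpoint: one cluster of span zero
  cl1 <- cluster_pas(endpoint_reads(1500), one_gene_annotation(), window = 24)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$span_end - cl1$span_start, 0)

  # a gap exactly equal to the window still merges
  cl2 <- cluster_pas(endpoint_reads(c(1100, 1124)), one_gene_annotation(),
                     window = 24)
  expect_equal(nrow(cl2), 1)
  cl3 <- cluster_pas(endpoint_reads(c(1100, 1125)), one_gene_annotation(),
                     window = 24)
  expect_equal(nrow(cl3), 2)

  expect_error(cluster_pas(endpoint_reads(1), one_gene_annotation(),
                           window = -1),
               class = "tailshift_config_error")
})

test_that("mode ties break towards the stop codon, strand-aware", {
  # two positions with equal counts in one cluster
  plus <- cluster_pas(endpoint_reads(c(1200, 1200, 1210, 1210)),
                      one_gene_annotation("+"), window = 24)
  expect_equal(plus$mode_pos, 1200)   # stop at 1000: 1200 is nearer
  minus_ann <- one_gene_annotation("-")  # stop codon at 101
  minus <- cluster_pas(endpoint_reads(c(60, 60, 50, 50)), minus_ann,
                       window = 24)
  expect_equal(minus$mode_pos, 60)    # on '-', larger coordinate is nearer
})

test_that("single-linkage equals brute-force transitive closure", {
  set.seed(201)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    w <- sample(0:30, 1)
    pos <- sample(1000:1990, n, replace = TRUE)
    cl <- cluster_pas(endpoint_reads(pos), one_gene_annotation(), window = w)
    oracle <- cluster_oracle(pos, w)
    expect_equal(nrow(cl), length(oracle))
    sizes <- sort(unname(vapply(oracle, length, integer(1))))
    expect_equal(sort(cl$n_total), sizes)
  }
})

test_that("pair selection takes the top-2 final-exon sites ordered by distance", {
  # three clusters at stop+50/+300/+500 with counts 50/30/5 in each condition
  pos <- c(rep(1050, 100), rep(1300, 60), rep(1500, 10))
  reads <- dplyr::bind_rows(
    endpoint_reads(pos, stage = "A", sample_id = "A_rep1"),
    endpoint_reads(pos, stage = "B", sample_id = "B_rep1"))
  reads$read_id <- sprintf("r%05d", seq_len(nrow(reads)))
  cl <- cluster_pas(reads, one_gene_annotation(), window = 24)
  pair <- select_pas_pairs(cl, "A", "B")
  expect_equal(pair$ppas_pos, 1050)
  expect_equal(pair$dpas_pos, 1300)
  expect_equal(pair$ppas_1, 100)
  expect_equal(pair$dpas_2, 60)

  # only one qualifying cluster -> gene excluded
  few <- endpoint_reads(rep(1050, 20))
  clf <- cluster_pas(few, one_gene_annotation(), window = 24)
  expect_equal(nrow(select_pas_pairs(clf, "A", "B")), 0)

  # sites below the per-condition minimum count do not qualify
  unbal <- dplyr::bind_rows(
    endpoint_reads(c(rep(1050, 20), rep(1300, 2)), "A", "A_rep1"),
    endpoint_reads(c(rep(1050, 20), rep(1300, 20)), "B", "B_rep1"))
  unbal$read_id <- sprintf("r%05d", seq_len(nrow(unbal)))
  clu <- cluster_pas(unbal, one_gene_annotation(), window = 24)
  expect_equal(nrow(select_pas_pairs(clu, "A", "B", min_count = 5)), 0)
})

test_that("the APA D statistic matches the printed formula", {
  d <- apa_d_statistic(2, 8, 8, 2, pseudocount = 1e-12)
  expect_equal(d$d_statistic, 4, tolerance = 1e-6)
  expect_true(d$significant)

  eq <- apa_d_statistic(5, 5, 5, 5)
  expect_equal(eq$d_statistic, 0)
  expect_false(eq$significant)

  # pseudocount handling: (PPAS1=5, DPAS1=5, PPAS2=5, DPAS2=0), c = 1
  pc <- apa_d_statistic(5, 5, 5, 0, pseudocount = 1)
  expect_equal(pc$d_statistic, log2(6), tolerance = 1e-12)

  expect_error(apa_d_statistic(-1, 2, 3, 4),
               class = "tailshift_validation_error")
  expect_error(apa_d_statistic(1, 2, 3, 4, pseudocount = 0),
               class = "tailshift_config_error")
})

test_that("alternative threshold interpretations are selectable", {
  # d = 1.0: significant under the log2 reading and the 1.3-fold reading
  d <- apa_d_statistic(10, 10, 10, 5, pseudocount = 1e-12)
  expect_true(d$significant)
  expect_true(apa_d_statistic(10, 10, 10, 5, pseudocount = 1e-12,
                              mode = "fold")$significant)
  # usage change: 50% -> 50/15 ~ 77% proximal = 27 points, under 30
  expect_false(apa_d_statistic(10, 10, 10, 3, pseudocount = 1e-12,
                               mode = "usage")$significant)
  expect_true(apa_d_statistic(10, 10, 30, 3, pseudocount = 1e-12,
                              mode = "usage")$significant)
})

test_that("RED scores carry the shortening sign convention", {
  pairs <- tibble::tibble(ppas_1 = 4, dpas_1 = 4, ppas_2 = 8, dpas_2 = 2)
  red <- red_scores(pairs, pseudocount = 1e-12)
  expect_equal(red$red_1, 0, tolerance = 1e-6)
  expect_equal(red$red_2, -2, tolerance = 1e-6)
  expect_equal(red$delta_red, -2, tolerance = 1e-6)

  same <- red_scores(tibble::tibble(ppas_1 = 6, dpas_1 = 9,
                                    ppas_2 = 6, dpas_2 = 9))
  expect_equal(same$delta_red, 0)

  expect_equal(global_red(tibble::tibble(delta_red = double()))$n_genes, 0)
  expect_true(is.na(global_red(tibble::tibble(delta_red = double()))$mean_red))
})

test_that("shift classification requires significance and a sign", {
  base <- tibble::tibble(significant = c(TRUE, TRUE, FALSE, TRUE),
                         delta_red = c(-2, 2, -2, 0))
  out <- classify_apa_shift(base)
  expect_equal(out$shift_class,
               c("proximal_up", "distal_up", "unchanged", "unchanged"))
})

test_that("condition swap negates delta_red and preserves D", {
  sim <- small_sim(seed = 81, n_genes = 25, reads = 100)
  a <- apa_test(sim$reads, sim$annotation, "SubPeg", "ExpPod2")
  b <- apa_test(sim$reads, sim$annotation, "ExpPod2", "SubPeg")
  j <- dplyr::inner_join(as_tibble(a), as_tibble(b), by = "gene_id",
                         suffix = c("_ab", "_ba"))
  expect_gt(nrow(j), 20)
  expect_equal(j$d_statistic_ba, j$d_statistic_ab, tolerance = 1e-12)
  expect_equal(j$delta_red_ba, -j$delta_red_ab, tolerance = 1e-12)
  expect_equal(j$significant_ba, j$significant_ab)
})

test_that("coordinate translation and strand mirroring leave APA results unchanged", {
  sim <- small_sim(seed = 82, n_genes = 20, reads = 100)
  base <- as_tibble(apa_test(sim$reads, sim$annotation, "SubPeg", "ExpPod2"))

  shifted_ann <- shift_annotation(sim$annotation, 10000L)
  shifted_reads <- dplyr::mutate(sim$reads,
                                 three_prime_pos = three_prime_pos + 10000L)
  shifted <- as_tibble(apa_test(shifted_reads, shifted_ann,
                                "SubPeg", "ExpPod2"))

  mirrored <- as_tibble(apa_test(mirror_reads(sim$reads),
                                 mirror_annotation(sim$annotation),
                                 "SubPeg", "ExpPod2"))

  cmp <- function(x) x %>%
    dplyr::arrange(gene_id) %>%
    dplyr::select(gene_id, ppas_1, dpas_1, ppas_2, dpas_2, d_statistic,
                  red_1, red_2, delta_red, significant, shift_class)
  expect_equal(as.data.frame(cmp(shifted)), as.data.frame(cmp(base)))
  expect_equal(as.data.frame(cmp(mirrored)), as.data.frame(cmp(base)))
})

test_that("APA results are invariant to input row order", {
  sim <- small_sim(seed = 83, n_genes = 15, reads = 80)
  base <- as_tibble(apa_test(sim$reads, sim$annotation, "AerPeg", "ExpPod2"))
  shuf <- sim$reads[withr::with_seed(1, sample(nrow(sim$reads))), ]
  redo <- as_tibble(apa_test(shuf, sim$annotation, "AerPeg", "ExpPod2"))
  expect_equal(as.data.frame(dplyr::arrange(redo, gene_id)),
               as.data.frame(dplyr::arrange(base, gene_id)))
})

test_that("BED export converts to 0-based half-open single-base intervals", {
  sim <- small_sim(seed = 84, n_genes = 5, reads = 60)
  apa <- apa_test(sim$reads, sim$annotation, "AerPeg", "ExpPod2")
  path <- withr::local_tempfile(fileext = ".bed")
  export_pas_bed(apa, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(bed$end - bed$start, rep(1L, nrow(bed)))
  expect_equal(nrow(bed), 2 * nrow(apa))
  prox <- bed[grepl(":proximal$", bed$name), ]
  expect_setequal(prox$start + 1L, apa$ppas_pos)
})
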