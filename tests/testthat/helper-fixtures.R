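# Shared fixtures and transform helpers. The full-scale study fixture is
# generated once per test run and cached.

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      cache <<- simulate_reads(cfg, simulate_annotation(cfg))
    }
    cache
  }
})

small_sim <- function(seed = 11, n_genes = 40, reads = 80, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    reads_per_gene_mean = reads, ...)
  simulate_reads(cfg, simulate_annotation(cfg))
}

# hand-built single-transcript read table for the PAL tests
make_pal_reads <- function(control_vals, treatment_vals,
                           control = "A", treatment = "B",
                           transcript_id = "tx1") {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(length(control_vals) + length(treatment_vals))),
    sample_id = c(rep(paste0(control, "_rep1"), length(control_vals)),
                  rep(paste0(treatment, "_rep1"), length(treatment_vals))),
    stage = c(rep(control, length(control_vals)),
              rep(treatment, length(treatment_vals))),
    gene_id = "g1", transcript_id = transcript_id, strand = "+",
    three_prime_pos = 1000L,
    polya_len = c(control_vals, treatment_vals),
    full_length = TRUE, as_class = "none")
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# reflect every coordinate about `c0` and flip strands
mirror_annotation <- function(ann, c0 = 10000000L) {
  genes <- dplyr::mutate(ann$genes, strand = flip_strand(strand))
  tx <- ann$transcripts %>%
    dplyr::transmute(transcript_id, gene_id, chrom,
                     strand = flip_strand(strand), as_class,
                     cds_start = c0 - ann$transcripts$cds_end,
                     cds_end = c0 - ann$transcripts$cds_start)
  ex <- ann$exons %>%
    dplyr::transmute(transcript_id,
                     start = c0 - ann$exons$end,
                     end = c0 - ann$exons$start)
  as_annotation(genes, tx, ex)
}

mirror_reads <- function(reads, c0 = 10000000L) {
  dplyr::mutate(reads,
                three_prime_pos = as.integer(c0 - three_prime_pos),
                strand = flip_strand(strand))
}

shift_annotation <- function(ann, delta) {
  tx <- ann$transcripts %>%
    dplyr::transmute(transcript_id, gene_id, chrom, strand, as_class,
                     cds_start = cds_start + delta,
                     cds_end = cds_end + delta)
  ex <- ann$exons %>%
    dplyr::mutate(start = start + delta, end = end + delta)
  as_annotation(ann$genes, tx, ex)
}
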