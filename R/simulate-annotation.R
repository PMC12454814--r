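#' Generate a synthetic annotation
#'
#' Lays out `n_genes` two-exon genes (one mRNA each) on two chromosomes,
#' alternating strands, each with a CDS strictly inside the exon span and a
#' 3' UTR long enough to hold a proximal and a distal poly(A) site
#' separated by `pas_pair_distance_nt`. Region proportions mirror a typical
#' mRNA: ~5% 5' UTR, ~75% CDS, ~20% 3' UTR. One alternative-splicing class
#' label is drawn per transcript from `as_class_probs`.
#'
#' The two planted poly(A) sites of each gene are recorded in the
#' `pas_truth` attribute (gene_id, ppas_pos, dpas_pos, genomic
#' coordinates).
#'
#' @param config A [sim_config()].
#' @return A `tailshift_annotation`; attribute `pas_truth` holds the
#'   planted site positions.
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 5))
#' ann$transcripts$utr3_len
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  dist <- config$pas_pair_distance_nt

  # transcript-coordinate layout shared by all genes
  utr5 <- 100L; cds <- 1500L
  ppas_off <- 80L                       # nt downstream of the stop codon
  utr3 <- ppas_off + dist + 120L
  tx_len <- utr5 + cds + utr3
  exon1_len <- 900L; intron <- 200L
  span <- tx_len + intron

  idx <- seq_len(n)
  chrom <- paste0("chr", ((idx - 1L) %% 2L) + 1L)
  strand <- ifelse(idx %% 2L == 1L, "+", "-")
  pos_on_chrom <- ((idx - 1L) %/% 2L)
  gstart <- pos_on_chrom * (span + 5000L) + 1L
  gend <- gstart + span - 1L
  gene_id <- sprintf("gene%04d", idx)
  transcript_id <- sprintf("tx%04d", idx)

  as_class <- withr::with_seed(config$seed, {
    sample(names(config$as_class_probs), n, replace = TRUE,
           prob = config$as_class_probs)
  })

  # exon intervals: transcription-first exon has length exon1_len
  ex <- purrr::map_dfr(idx, function(i) {
    s <- gstart[i]; e <- gend[i]
    if (strand[i] == "+") {
      tibble(transcript_id = transcript_id[i],
             start = c(s, s + exon1_len + intron),
             end = c(s + exon1_len - 1L, e))
    } else {
      tibble(transcript_id = transcript_id[i],
             start = c(s, e - exon1_len + 1L),
             end = c(s + (tx_len - exon1_len) - 1L, e))
    }
  })

  # CDS spans tx coords (utr5+1) .. (utr5+cds)
  cds_coords <- purrr::map_dfr(idx, function(i) {
    exi <- ex[ex$transcript_id == transcript_id[i], ]
    g <- tx_to_genomic(c(utr5 + 1L, utr5 + cds), exi$start, exi$end, strand[i])
    tibble(transcript_id = transcript_id[i],
           cds_start = min(g), cds_end = max(g))
  })

  genes <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = gstart, end = gend)
  transcripts <- tibble(transcript_id = transcript_id, gene_id = gene_id,
                        chrom = chrom, strand = strand,
                        as_class = as_class) %>%
    left_join(cds_coords, by = "transcript_id")

  ann <- as_annotation(genes, transcripts, ex)

  pas_truth <- purrr::map_dfr(idx, function(i) {
    exi <- ex[ex$transcript_id == transcript_id[i], ]
    g <- tx_to_genomic(c(utr5 + cds + ppas_off, utr5 + cds + ppas_off + dist),
                       exi$start, exi$end, strand[i])
    tibble(gene_id = gene_id[i], transcript_id = transcript_id[i],
           ppas_pos = g[1], dpas_pos = g[2])
  })
  attr(ann, "pas_truth") <- pas_truth
  ann
}
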