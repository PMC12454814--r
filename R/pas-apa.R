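# gene-level reference transcript: the one whose stop codon is most 3'
gene_reference <- function(annotation) {
  annotation$transcripts %>%
    filter(!is.na(stop_codon_pos)) %>%
    group_by(gene_id) %>%
    arrange(if (first(strand) == "+") -stop_codon_pos else stop_codon_pos,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(gene_id, chrom, strand, stop_codon_pos,
           final_exon_start, final_exon_end)
}

#' Cluster read 3' ends into poly(A) sites
#'
#' Single-linkage clustering of per-gene read 3'-end positions: positions
#' are sorted and adjacent positions at most `window` nt apart (inclusive)
#' are merged. Each cluster's representative coordinate (`mode_pos`) is its
#' most frequent endpoint; ties are broken towards the position most
#' proximal to the gene's stop codon in transcription direction. Clusters
#' are flagged `in_final_exon` when `mode_pos` lies in the final exon of
#' the gene's reference transcript (the one with the most-3' stop codon).
#'
#' @param reads Read table with gene_id, sample_id, stage,
#'   three_prime_pos.
#' @param annotation A `tailshift_annotation`.
#' @param window Merge window in nt (>= 0).
#' @return Tibble with one row per cluster: gene_id, chrom, strand,
#'   cluster_id, mode_pos, span_start, span_end, n_total, in_final_exon and
#'   a `counts` list-column of per-sample tibbles.
#' @export
cluster_pas <- function(reads, annotation, window = 24) {
  if (length(window) != 1 || is.na(window) || window < 0) {
    rlang::abort("`window` must be a single nonnegative number",
                 class = "tailshift_config_error")
  }
  if (nrow(reads) == 0) {
    rlang::abort("no read endpoints to cluster",
                 class = "tailshift_validation_error")
  }
  ref <- gene_reference(annotation)

  assigned <- reads %>%
    select(gene_id, sample_id, stage, pos = three_prime_pos) %>%
    arrange(gene_id, pos) %>%
    group_by(gene_id) %>%
    mutate(gap = pos - dplyr::lag(pos, default = dplyr::first(pos)),
           cluster_rank = cumsum(gap > window)) %>%
    ungroup() %>%
    mutate(cluster_id = paste0(gene_id, "#", cluster_rank))

  per_pos <- assigned %>%
    count(gene_id, cluster_id, pos, name = "n_pos")

  modes <- per_pos %>%
    left_join(ref %>% select(gene_id, strand, stop_codon_pos),
              by = "gene_id") %>%
    mutate(dist_stop = if_else(strand == "+", pos - stop_codon_pos,
                               stop_codon_pos - pos)) %>%
    group_by(gene_id, cluster_id) %>%
    arrange(desc(n_pos), abs(dist_stop), .by_group = TRUE) %>%
    summarise(mode_pos = first(pos), .groups = "drop")

  counts <- assigned %>%
    count(cluster_id, sample_id, stage, name = "n") %>%
    tidyr::nest(counts = c(sample_id, stage, n))

  clusters <- assigned %>%
    group_by(gene_id, cluster_id) %>%
    summarise(span_start = min(pos), span_end = max(pos),
              n_total = dplyr::n(), .groups = "drop") %>%
    left_join(modes, by = c("gene_id", "cluster_id")) %>%
    left_join(counts, by = "cluster_id") %>%
    left_join(ref, by = "gene_id") %>%
    mutate(in_final_exon = !is.na(final_exon_start) &
             mode_pos >= final_exon_start & mode_pos <= final_exon_end) %>%
    select(gene_id, chrom, strand, cluster_id, mode_pos, span_start,
           span_end, n_total, in_final_exon, stop_codon_pos, counts)
  clusters
}

#' Select the proximal/distal poly(A)-site pair per gene
#'
#' Among a gene's final-exon clusters with at least `min_count` reads in
#' each of the two conditions, the two with the highest total count are
#' taken; ties are broken by proximity to the stop codon. The member of the
#' pair nearer the stop codon in transcription direction is the proximal
#' site (pPAS), the farther the distal site (dPAS). Genes with fewer than
#' two qualifying clusters are absent from the result.
#'
#' @param clusters Output of [cluster_pas()].
#' @param control,treatment Stage labels of the two conditions (control
#'   first).
#' @param min_count Minimum reads per site per condition (default 5).
#' @return Tibble with one row per testable gene: positions and the four
#'   counts ppas_1, dpas_1 (control), ppas_2, dpas_2 (treatment).
#' @export
select_pas_pairs <- function(clusters, control, treatment, min_count = 5) {
  cond_counts <- clusters %>%
    tidyr::unnest(counts) %>%
    filter(stage %in% c(control, treatment)) %>%
    mutate(cond = if_else(stage == control, "n_1", "n_2")) %>%
    group_by(gene_id, cluster_id, cond) %>%
    summarise(n = sum(n), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = cond, values_from = n, values_fill = 0L)
  if (!"n_1" %in% names(cond_counts)) cond_counts$n_1 <- 0L
  if (!"n_2" %in% names(cond_counts)) cond_counts$n_2 <- 0L

  cand <- clusters %>%
    filter(in_final_exon) %>%
    inner_join(cond_counts, by = c("gene_id", "cluster_id")) %>%
    filter(n_1 >= min_count, n_2 >= min_count) %>%
    mutate(total = n_1 + n_2,
           dist_stop = if_else(strand == "+", mode_pos - stop_codon_pos,
                               stop_codon_pos - mode_pos))

  cand %>%
    group_by(gene_id) %>%
    arrange(desc(total), dist_stop, .by_group = TRUE) %>%
    slice(1:2) %>%
    filter(dplyr::n() == 2) %>%
    arrange(dist_stop, .by_group = TRUE) %>%
    summarise(chrom = first(chrom), strand = first(strand),
              ppas_pos = mode_pos[1], dpas_pos = mode_pos[2],
              ppas_1 = n_1[1], dpas_1 = n_1[2],
              ppas_2 = n_2[1], dpas_2 = n_2[2],
              .groups = "drop")
}

#' APA difference statistic
#'
#' The two-condition usage-shift statistic
#' `D = |log2((dpas_1 + c)/(dpas_2 + c)) - log2((ppas_1 + c)/(ppas_2 + c))|`
#' with pseudocount `c`. Significance follows the chosen reading of the
#' "more than 30%" rule: `"log2"` calls `D > threshold` (default 0.3),
#' `"fold"` calls `D > log2(1 + threshold)` (a 1.3-fold odds change), and
#' `"usage"` calls a proximal-usage change of more than `threshold` (30
#' percentage points). Vectorized over the four count vectors.
#'
#' @param ppas_1,dpas_1 Proximal/distal read counts in condition 1.
#' @param ppas_2,dpas_2 Counts in condition 2.
#' @param pseudocount Pseudocount `c` (> 0 guards zero counts).
#' @param threshold Significance threshold (see above).
#' @param mode One of `"log2"`, `"fold"`, `"usage"`.
#' @return Tibble with `d_statistic` and `significant`.
#' @examples
#' apa_d_statistic(2, 8, 8, 2, pseudocount = 1e-9)  # D = 4
#' @export
apa_d_statistic <- function(ppas_1, dpas_1, ppas_2, dpas_2,
                            pseudocount = 1, threshold = 0.3,
                            mode = c("log2", "fold", "usage")) {
  mode <- match.arg(mode)
  counts <- cbind(ppas_1, dpas_1, ppas_2, dpas_2)
  if (anyNA(counts) || any(counts < 0)) {
    rlang::abort("PAS counts must be nonnegative",
                 class = "tailshift_validation_error")
  }
  if (any(pseudocount <= 0)) {
    rlang::abort("`pseudocount` must be positive",
                 class = "tailshift_config_error")
  }
  c0 <- pseudocount
  d <- abs(log2((dpas_1 + c0) / (dpas_2 + c0)) -
             log2((ppas_1 + c0) / (ppas_2 + c0)))
  significant <- switch(
    mode,
    log2 = d > threshold,
    fold = d > log2(1 + threshold),
    usage = {
      u1 <- ppas_1 / pmax(ppas_1 + dpas_1, 1)
      u2 <- ppas_2 / pmax(ppas_2 + dpas_2, 1)
      abs(u2 - u1) > threshold
    })
  tibble(d_statistic = d, significant = significant)
}

#' RED scores
#'
#' Per-condition relative expression difference
#' `red_k = log2((dpas_k + c)/(ppas_k + c))` and the change
#' `delta_red = red_2 - red_1`. Negative `delta_red` means the distal/
#' proximal balance moved towards the proximal site in condition 2, i.e. a
#' 3' UTR shortening; the mean of `delta_red` over testable genes is the
#' global RED value.
#'
#' @param pairs Tibble with ppas_1, dpas_1, ppas_2, dpas_2 (e.g. from
#'   [select_pas_pairs()]).
#' @param pseudocount Pseudocount.
#' @return `pairs` with red_1, red_2, delta_red columns appended.
#' @export
red_scores <- function(pairs, pseudocount = 1) {
  c0 <- pseudocount
  pairs %>%
    mutate(red_1 = log2((dpas_1 + c0) / (ppas_1 + c0)),
           red_2 = log2((dpas_2 + c0) / (ppas_2 + c0)),
           delta_red = red_2 - red_1)
}

#' Global mean RED
#'
#' Mean `delta_red` over testable genes; an explicit empty (NA with n = 0)
#' result when no gene is testable.
#'
#' @param apa An APA result tibble with a `delta_red` column.
#' @return Tibble with `mean_red` and `n_genes`.
#' @export
global_red <- function(apa) {
  if (nrow(apa) == 0) return(tibble(mean_red = NA_real_, n_genes = 0L))
  tibble(mean_red = mean(apa$delta_red), n_genes = nrow(apa))
}

#' Classify the APA shift of each gene
#'
#' `proximal_up` when significant with `delta_red < 0`, `distal_up` when
#' significant with `delta_red > 0`, otherwise `unchanged` (a significant
#' D with `delta_red` exactly 0 stays `unchanged`: a sign is required).
#'
#' @param apa Tibble with `significant` and `delta_red`.
#' @return `apa` with a `shift_class` column appended.
#' @export
classify_apa_shift <- function(apa) {
  apa %>%
    mutate(shift_class = case_when(
      significant & delta_red < 0 ~ "proximal_up",
      significant & delta_red > 0 ~ "distal_up",
      TRUE ~ "unchanged"))
}

#' Gene-level APA test between two conditions
#'
#' Runs the full APA stage for one condition pair: clusters the two
#' conditions' read 3' ends into poly(A) sites ([cluster_pas()]), selects
#' each gene's proximal/distal pair in the final exon
#' ([select_pas_pairs()]), computes the D statistic
#' ([apa_d_statistic()]), RED scores ([red_scores()]) and the shift class
#' ([classify_apa_shift()]).
#'
#' @param reads Read table.
#' @param annotation A `tailshift_annotation`.
#' @param control,treatment Stage labels (condition 1 = control).
#' @param window Clustering window in nt.
#' @param pseudocount Pseudocount for log ratios.
#' @param threshold,mode Significance rule, see [apa_d_statistic()].
#' @param min_count Minimum reads per site per condition.
#' @return A tibble (class `tailshift_apa`) with one row per testable gene.
#' @examples
#' cfg <- sim_config(n_genes = 30, reads_per_gene_mean = 60)
#' sim <- simulate_reads(cfg, simulate_annotation(cfg))
#' apa <- apa_test(sim$reads, sim$annotation, "SubPeg", "ExpPod2")
#' table(apa$shift_class)
#' @export
apa_test <- function(reads, annotation, control, treatment,
                     window = 24, pseudocount = 1, threshold = 0.3,
                     mode = c("log2", "fold", "usage"), min_count = 5) {
  mode <- match.arg(mode)
  sub <- reads %>% filter(stage %in% c(control, treatment))
  if (nrow(sub) == 0) {
    rlang::abort(sprintf("no reads in stages %s/%s", control, treatment),
                 class = "tailshift_validation_error")
  }
  clusters <- cluster_pas(sub, annotation, window = window)
  pairs <- select_pas_pairs(clusters, control, treatment,
                            min_count = min_count)
  if (nrow(pairs) == 0) {
    out <- tibble(gene_id = character())
  } else {
    ds <- apa_d_statistic(pairs$ppas_1, pairs$dpas_1, pairs$ppas_2,
                          pairs$dpas_2, pseudocount = pseudocount,
                          threshold = threshold, mode = mode)
    out <- pairs %>%
      bind_cols(ds) %>%
      red_scores(pseudocount = pseudocount) %>%
      classify_apa_shift()
  }
  structure(out, class = c("tailshift_apa", class(out)),
            control = control, treatment = treatment,
            params = list(window = window, pseudocount = pseudocount,
                          threshold = threshold, mode = mode,
                          min_count = min_count))
}

#' Export selected poly(A)-site pairs as BED6
#'
#' Converts 1-based inclusive site coordinates to BED's 0-based half-open
#' single-base intervals. Names are `gene:proximal` / `gene:distal`;
#' scores are total read counts.
#'
#' @param apa An APA result (from [apa_test()] or [select_pas_pairs()]).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_pas_bed <- function(apa, path) {
  bed <- bind_rows(
    tibble(chrom = apa$chrom, start = apa$ppas_pos - 1L, end = apa$ppas_pos,
           name = paste0(apa$gene_id, ":proximal"),
           score = apa$ppas_1 + apa$ppas_2, strand = apa$strand),
    tibble(chrom = apa$chrom, start = apa$dpas_pos - 1L, end = apa$dpas_pos,
           name = paste0(apa$gene_id, ":distal"),
           score = apa$dpas_1 + apa$dpas_2, strand = apa$strand)) %>%
    arrange(chrom, start)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
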