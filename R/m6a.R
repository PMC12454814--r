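#' Aggregate per-site modification counts
#'
#' Pools per-read modification calls into per-site, per-stage modified /
#' unmodified counts, keeping per-replicate counts alongside. The m6A
#' stoichiometry of a site is `n_mod / (n_mod + n_unmod)`; sites with zero
#' covering reads in a stage have `ratio = NA` (untestable, never 0). A
#' read contributing two calls at one site is a validation error.
#'
#' @param modcalls Modification-call table (read_id, gene_id, site_chrom,
#'   site_pos, site_strand, modified).
#' @param reads Read table supplying sample_id/stage per read_id.
#' @return Tibble with one row per site x stage: site_id, gene_id, site
#'   coordinates, n_mod, n_unmod, ratio, and a `by_rep` list-column of
#'   per-replicate counts.
#' @export
m6a_site_counts <- function(modcalls, reads) {
  dup <- modcalls %>%
    count(read_id, site_chrom, site_pos, site_strand) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf(
      "read %s contributes %d calls at site %s:%d", dup$read_id[1],
      dup$n[1], dup$site_chrom[1], dup$site_pos[1]),
      class = "tailshift_validation_error")
  }
  calls <- modcalls %>%
    inner_join(reads %>% select(read_id, sample_id, stage), by = "read_id") %>%
    mutate(site_id = sprintf("%s:%d:%s", site_chrom, site_pos, site_strand))

  by_rep <- calls %>%
    group_by(site_id, gene_id, site_chrom, site_pos, site_strand, stage,
             sample_id) %>%
    summarise(n_mod = sum(modified), n_unmod = sum(!modified),
              .groups = "drop") %>%
    mutate(ratio = if_else(n_mod + n_unmod > 0,
                           n_mod / (n_mod + n_unmod), NA_real_))

  by_rep %>%
    group_by(site_id, gene_id, site_chrom, site_pos, site_strand, stage) %>%
    summarise(by_rep = list(tibble(sample_id = sample_id,
                                   n_mod = n_mod, n_unmod = n_unmod,
                                   ratio = ratio)),
              n_mod = sum(n_mod), n_unmod = sum(n_unmod),
              .groups = "drop") %>%
    mutate(ratio = if_else(n_mod + n_unmod > 0,
                           n_mod / (n_mod + n_unmod), NA_real_))
}

#' Assign sites to transcript regions
#'
#' Strand-aware assignment of genomic sites to 5' UTR, CDS or 3' UTR of
#' their gene, using the longest CDS-containing transcript when a gene has
#' several. CDS bounds are inclusive of both termini. Sites outside the
#' exons are returned with region `"unassigned"` and reported.
#'
#' @param sites Tibble with gene_id, site_chrom, site_pos, site_strand.
#' @param annotation A `tailshift_annotation`.
#' @return `sites` with `region`, transcript coordinate `tx_pos`, and the
#'   fractional position `frac` within the region appended.
#' @export
assign_site_region <- function(sites, annotation) {
  ref <- annotation$transcripts %>%
    filter(!is.na(cds_start)) %>%
    group_by(gene_id) %>%
    arrange(desc(tx_len), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  per_tx <- split(annotation$exons, annotation$exons$transcript_id)
  out <- sites %>%
    left_join(ref %>% select(gene_id, transcript_id, strand, tx_len,
                             utr5_len, cds_len, utr3_len),
              by = "gene_id") %>%
    group_by(transcript_id) %>%
    group_modify(function(df, key) {
      ex <- per_tx[[key$transcript_id]]
      if (is.null(ex)) { df$tx_pos <- NA_integer_; return(df) }
      df$tx_pos <- genomic_to_tx(df$site_pos, ex$start, ex$end,
                                 df$strand[1])
      df
    }) %>%
    ungroup() %>%
    mutate(
      region = case_when(
        is.na(tx_pos) ~ "unassigned",
        tx_pos <= utr5_len ~ "5UTR",
        tx_pos <= utr5_len + cds_len ~ "CDS",
        TRUE ~ "3UTR"),
      frac = case_when(
        region == "5UTR" ~ (tx_pos - 0.5) / utr5_len,
        region == "CDS" ~ (tx_pos - utr5_len - 0.5) / cds_len,
        region == "3UTR" ~ (tx_pos - utr5_len - cds_len - 0.5) / utr3_len,
        TRUE ~ NA_real_))
  n_un <- sum(out$region == "unassigned")
  if (n_un > 0) {
    rlang::inform(sprintf("assign_site_region: %d site(s) outside exons left unassigned",
                          n_un))
  }
  out
}

#' Metagene profile of site positions
#'
#' Histograms sites along a concatenated, region-scaled 5'UTR | CDS |
#' 3'UTR axis: each site's fractional position within its region is
#' binned into `bins_per_region` bins per region, and the profile is
#' normalized to sum to 1. With no assignable sites the profile is
#' explicitly empty (all densities 0, `n_sites` attribute 0).
#'
#' @param sites_assigned Output of [assign_site_region()].
#' @param bins_per_region Bins per region (>= 1, default 10).
#' @return Tibble with bin (1..3*bins_per_region), region, density;
#'   attribute `n_sites`.
#' @export
metagene_profile <- function(sites_assigned, bins_per_region = 10) {
  if (bins_per_region < 1) {
    rlang::abort("`bins_per_region` must be >= 1",
                 class = "tailshift_config_error")
  }
  B <- as.integer(bins_per_region)
  regions <- c("5UTR", "CDS", "3UTR")
  grid <- tibble(bin = seq_len(3L * B),
                 region = rep(regions, each = B))
  usable <- sites_assigned %>% filter(region %in% regions, !is.na(frac))
  if (nrow(usable) == 0) {
    rlang::warn("metagene_profile: no assignable sites; empty profile")
    out <- grid %>% mutate(density = 0)
    attr(out, "n_sites") <- 0L
    return(out)
  }
  binned <- usable %>%
    mutate(bin = (match(region, regions) - 1L) * B +
             pmin(pmax(floor(frac * B), 0L), B - 1L) + 1L) %>%
    count(bin, name = "n")
  out <- grid %>%
    left_join(binned, by = "bin") %>%
    mutate(n = tidyr::replace_na(n, 0L),
           density = n / sum(n)) %>%
    select(bin, region, density)
  attr(out, "n_sites") <- nrow(usable)
  out
}

#' Differential m6A test between two conditions
#'
#' For every site testable (covered) in both conditions, a two-sided
#' Fisher exact test ([fisher_exact2()]) on the pooled 2x2 table of
#' modified/unmodified counts, and a stoichiometry difference
#' `delta = ratio_2 - ratio_1` where each `ratio_k` is the mean of the
#' per-replicate ratios (replicates without coverage excluded). A site is
#' significant when `|delta| > delta_threshold` and
#' `p < p_threshold`. Sites lacking coverage in a condition are returned
#' untested with a reason code.
#'
#' @param site_counts Output of [m6a_site_counts()].
#' @param control,treatment Stage labels (condition 1 = control).
#' @param delta_threshold Minimum |mean ratio difference| (default 0.1).
#' @param p_threshold P-value threshold (default 0.05).
#' @return Tibble per site: ratio_1, ratio_2, delta, p_value, significant,
#'   tested, reason.
#' @examples
#' # pooled table ((10,0),(0,10)) is maximally imbalanced:
#' fisher_exact2(10, 0, 0, 10)  # ~1.08e-5
#' @export
m6a_diff_test <- function(site_counts, control, treatment,
                          delta_threshold = 0.1, p_threshold = 0.05) {
  sub <- site_counts %>% filter(stage %in% c(control, treatment))
  mean_rep_ratio <- function(br) {
    r <- br$ratio[!is.na(br$ratio)]
    if (length(r) == 0) NA_real_ else mean(r)
  }
  wide <- sub %>%
    mutate(cond = if_else(stage == control, "1", "2"),
           rep_ratio = purrr::map_dbl(by_rep, mean_rep_ratio)) %>%
    select(site_id, gene_id, site_chrom, site_pos, site_strand, cond,
           n_mod, n_unmod, rep_ratio) %>%
    tidyr::pivot_wider(names_from = cond,
                       values_from = c(n_mod, n_unmod, rep_ratio),
                       names_sep = "_")
  for (col in c("n_mod_1", "n_unmod_1", "n_mod_2", "n_unmod_2")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  for (col in c("rep_ratio_1", "rep_ratio_2")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide %>%
    mutate(
      tot_1 = tidyr::replace_na(n_mod_1, 0L) + tidyr::replace_na(n_unmod_1, 0L),
      tot_2 = tidyr::replace_na(n_mod_2, 0L) + tidyr::replace_na(n_unmod_2, 0L),
      reason = case_when(
        tot_1 == 0 & tot_2 == 0 ~ "no_coverage",
        tot_1 == 0 ~ "no_coverage_condition1",
        tot_2 == 0 ~ "no_coverage_condition2",
        TRUE ~ NA_character_),
      tested = is.na(reason))
  tested_rows <- wide %>% filter(tested)
  p <- purrr::pmap_dbl(
    list(tested_rows$n_mod_1, tested_rows$n_unmod_1,
         tested_rows$n_mod_2, tested_rows$n_unmod_2),
    fisher_exact2)
  tested_rows$p_value <- p
  out <- wide %>%
    filter(!tested) %>%
    mutate(p_value = NA_real_) %>%
    bind_rows(tested_rows) %>%
    mutate(ratio_1 = rep_ratio_1, ratio_2 = rep_ratio_2,
           delta = ratio_2 - ratio_1,
           significant = tested & !is.na(delta) &
             abs(delta) > delta_threshold & p_value < p_threshold) %>%
    select(site_id, gene_id, site_chrom, site_pos, site_strand,
           n_mod_1, n_unmod_1, n_mod_2, n_unmod_2,
           ratio_1, ratio_2, delta, p_value, tested, significant, reason) %>%
    arrange(site_chrom, site_pos)
  out
}

#' Per-gene m6A modification rates by stage
#'
#' For each gene and stage, the mean stoichiometry over its covered sites.
#'
#' @param site_counts Output of [m6a_site_counts()].
#' @return Tibble gene_id, stage, n_sites, gene_rate.
#' @export
m6a_gene_rates <- function(site_counts) {
  site_counts %>%
    filter(!is.na(ratio)) %>%
    group_by(gene_id, stage) %>%
    summarise(n_sites = dplyr::n(), gene_rate = mean(ratio),
              .groups = "drop")
}

#' Per-stage distribution of gene m6A rates
#'
#' Median and quartiles of the per-gene mean stoichiometries
#' ([m6a_gene_rates()]) per stage; stages without a testable gene are
#' omitted with a warning.
#'
#' @param site_counts Output of [m6a_site_counts()].
#' @param stages Optional stage labels expected present.
#' @return Tibble stage, n_genes, median, q1, q3.
#' @export
m6a_stage_rates <- function(site_counts, stages = NULL) {
  rates <- m6a_gene_rates(site_counts)
  out <- rates %>%
    group_by(stage) %>%
    summarise(n_genes = dplyr::n(),
              median = stats::median(gene_rate),
              q1 = unname(stats::quantile(gene_rate, 0.25)),
              q3 = unname(stats::quantile(gene_rate, 0.75)),
              .groups = "drop")
  if (!is.null(stages)) {
    missing <- setdiff(stages, out$stage)
    if (length(missing) > 0) {
      rlang::warn(sprintf("m6a_stage_rates: no testable genes in stage(s) %s",
                          paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Classify transcripts as m6A-modified per stage
#'
#' A transcript counts as modified in a stage when it carries at least one
#' site with `>= min_reads` covering reads and stoichiometry
#' `>= min_ratio` in that stage.
#'
#' @param site_counts Output of [m6a_site_counts()].
#' @param annotation A `tailshift_annotation` (maps genes to transcripts).
#' @param min_ratio Stoichiometry threshold (default 0.1).
#' @param min_reads Coverage threshold (default 10).
#' @return Tibble transcript_id, stage, modified.
#' @export
classify_modified_transcripts <- function(site_counts, annotation,
                                          min_ratio = 0.1, min_reads = 10) {
  mod_genes <- site_counts %>%
    filter(!is.na(ratio), n_mod + n_unmod >= min_reads,
           ratio >= min_ratio) %>%
    distinct(gene_id, stage) %>%
    mutate(modified = TRUE)
  tidyr::expand_grid(
    annotation$transcripts %>% select(transcript_id, gene_id),
    stage = unique(site_counts$stage)) %>%
    left_join(mod_genes, by = c("gene_id", "stage")) %>%
    mutate(modified = tidyr::replace_na(modified, FALSE)) %>%
    select(transcript_id, gene_id, stage, modified)
}
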