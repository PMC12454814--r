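#' Summarize poly(A)-tail-length distributions
#'
#' Per-group median, quartiles (linear interpolation, `stats::quantile`
#' type 7) and count of non-missing tail lengths. Groups with no
#' non-missing values are omitted with a warning.
#'
#' @param reads Read table with `polya_len` and the grouping columns.
#' @param by Grouping columns (default `"stage"`; use
#'   `c("stage", "full_length")` for the full-length split).
#' @return Tibble with the grouping columns, n, median, q1, q3.
#' @examples
#' summarize_pal(tibble::tibble(stage = "A", polya_len = c(70, 80, 90)))
#' @export
summarize_pal <- function(reads, by = "stage") {
  groups_all <- reads %>% distinct(across(all_of(by)))
  out <- reads %>%
    filter(!is.na(polya_len)) %>%
    group_by(across(all_of(by))) %>%
    summarise(n = dplyr::n(),
              median = stats::median(polya_len),
              q1 = unname(stats::quantile(polya_len, 0.25)),
              q3 = unname(stats::quantile(polya_len, 0.75)),
              .groups = "drop")
  omitted <- anti_join(groups_all, out, by = by)
  if (nrow(omitted) > 0) {
    rlang::warn(sprintf(
      "summarize_pal: omitted %d group(s) with no non-missing tail lengths",
      nrow(omitted)))
  }
  out
}

#' Per-transcript poly(A)-tail-length difference test
#'
#' For each transcript with at least `min_n` non-missing tail lengths in
#' both conditions, compares control vs treatment with a two-sided
#' Mann-Whitney U test ([mann_whitney()]; exact tie-aware enumeration when
#' `n_1 + n_2 <= 12`, tie/continuity-corrected normal approximation
#' otherwise). The fold change is `control_median / treatment_median`; a
#' transcript is significant when `p < p_threshold` and
#' `max(FC, 1/FC) > fc_threshold` (the fold rule is applied two-sidedly so
#' both lengthening and shortening can be called). Direction is `longer`
#' when the treatment median exceeds the control median of a significant
#' transcript, `shorter` when below, else `none`. Transcripts failing
#' `min_n` are returned untested (`tested = FALSE`), never silently
#' significant.
#'
#' @param reads Read table.
#' @param control,treatment Stage labels; the control median is the fold
#'   numerator.
#' @param min_n Minimum non-missing reads per condition (default 10).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param p_threshold P-value threshold (default 0.05).
#' @return Tibble with one row per transcript observed in either
#'   condition: n_1, n_2, medians, fold_change, u_statistic, p_value,
#'   tested, significant, direction.
#' @examples
#' cfg <- sim_config(n_genes = 10, reads_per_gene_mean = 40)
#' sim <- simulate_reads(cfg, simulate_annotation(cfg))
#' res <- pal_test(sim$reads, "AerPeg", "ExpPod2")
#' head(res)
#' @export
pal_test <- function(reads, control, treatment, min_n = 10,
                     fc_threshold = 1.5, p_threshold = 0.05) {
  sub <- reads %>%
    filter(stage %in% c(control, treatment), !is.na(polya_len)) %>%
    mutate(cond = if_else(stage == control, 1L, 2L))
  by_tx <- sub %>% group_by(transcript_id)
  res <- by_tx %>%
    summarise(
      n_1 = sum(cond == 1L), n_2 = sum(cond == 2L),
      control_median = stats::median(polya_len[cond == 1L]),
      treatment_median = stats::median(polya_len[cond == 2L]),
      .groups = "drop") %>%
    mutate(tested = n_1 >= min_n & n_2 >= min_n)

  stat <- purrr::map_dfr(res$transcript_id[res$tested], function(txid) {
    v <- sub %>% filter(transcript_id == txid)
    mw <- mann_whitney(v$polya_len[v$cond == 1L], v$polya_len[v$cond == 2L])
    tibble(transcript_id = txid, u_statistic = mw$u, p_value = mw$p_value)
  })
  if (nrow(stat) == 0) {
    stat <- tibble(transcript_id = character(), u_statistic = double(),
                   p_value = double())
  }
  res %>%
    left_join(stat, by = "transcript_id") %>%
    mutate(
      fold_change = control_median / treatment_median,
      significant = tested & !is.na(p_value) & p_value < p_threshold &
        pmax(fold_change, 1 / fold_change) > fc_threshold,
      direction = case_when(
        significant & treatment_median > control_median ~ "longer",
        significant & treatment_median < control_median ~ "shorter",
        TRUE ~ "none")) %>%
    select(transcript_id, n_1, n_2, control_median, treatment_median,
           fold_change, u_statistic, p_value, tested, significant,
           direction)
}
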