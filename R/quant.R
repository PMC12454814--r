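#' TPM quantification from assigned reads
#'
#' Counts assigned reads per transcript per sample and converts to
#' transcripts-per-kilobase-million: per-kilobase rates normalized so every
#' sample sums to 1e6. Samples with zero assigned reads get all-zero TPM
#' with a warning (the sum rule is waived for them). Transcript lengths
#' come from the annotation; a non-positive length is a validation error.
#'
#' @param reads Read table.
#' @param annotation A `tailshift_annotation`.
#' @return Tibble transcript_id, sample_id, stage, count, tpm (all
#'   transcript x sample combinations, zero-filled).
#' @examples
#' # two transcripts of 1 and 2 kb with 10 and 20 reads -> both 500000 TPM
#' @export
quantify_tpm <- function(reads, annotation) {
  lens <- annotation$transcripts %>% select(transcript_id, tx_len)
  if (any(lens$tx_len <= 0 | is.na(lens$tx_len))) {
    rlang::abort("all transcript lengths must be positive",
                 class = "tailshift_validation_error")
  }
  samples <- reads %>% distinct(sample_id, stage)
  counts <- reads %>% count(transcript_id, sample_id, name = "count")
  grid <- tidyr::expand_grid(lens, samples) %>%
    left_join(counts, by = c("transcript_id", "sample_id")) %>%
    mutate(count = tidyr::replace_na(count, 0L),
           rate = count / (tx_len / 1000))
  out <- grid %>%
    group_by(sample_id) %>%
    mutate(tpm = if (sum(rate) > 0) rate / sum(rate) * 1e6 else 0) %>%
    ungroup()
  empty <- out %>% group_by(sample_id) %>%
    summarise(tot = sum(count), .groups = "drop") %>% filter(tot == 0)
  if (nrow(empty) > 0) {
    rlang::warn(sprintf("quantify_tpm: sample(s) %s have zero assigned reads",
                        paste(empty$sample_id, collapse = ", ")))
  }
  out %>% select(transcript_id, sample_id, stage, count, tpm)
}

#' Differential expression stand-in test
#'
#' A deliberately simple stand-in for a count-model DE test: per
#' transcript, `log2_fc = log2((mean TPM_2 + 1) / (mean TPM_1 + 1))` and a
#' two-sample unequal-variance (Welch) t test on `log2(TPM + 1)` across
#' replicates. Significance uses the thresholds `p < p_threshold` and
#' `|log2_fc| > lfc_threshold`. Refuses to run with fewer than two
#' replicates per condition. Output headers written by the pipeline label
#' the method `welch_t_log2_tpm_standin`.
#'
#' @param tpm Output of [quantify_tpm()].
#' @param control,treatment Stage labels (condition 1 = control).
#' @param p_threshold,lfc_threshold Significance thresholds (defaults 0.05
#'   and 1).
#' @return Tibble transcript_id, mean_tpm_1, mean_tpm_2, log2_fc, p_value,
#'   significant.
#' @export
de_test <- function(tpm, control, treatment, p_threshold = 0.05,
                    lfc_threshold = 1) {
  sub <- tpm %>% filter(stage %in% c(control, treatment)) %>%
    mutate(cond = if_else(stage == control, 1L, 2L))
  nrep <- sub %>% distinct(cond, sample_id) %>% count(cond)
  if (nrow(nrep) < 2 || any(nrep$n < 2)) {
    rlang::abort("de_test needs >= 2 replicates per condition",
                 class = "tailshift_validation_error")
  }
  sub %>%
    group_by(transcript_id) %>%
    summarise(
      mean_tpm_1 = mean(tpm[cond == 1L]),
      mean_tpm_2 = mean(tpm[cond == 2L]),
      p_value = {
        x <- log2(tpm[cond == 1L] + 1); y <- log2(tpm[cond == 2L] + 1)
        if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        } else {
          stats::t.test(y, x)$p.value
        }
      },
      .groups = "drop") %>%
    mutate(log2_fc = log2((mean_tpm_2 + 1) / (mean_tpm_1 + 1)),
           significant = p_value < p_threshold &
             abs(log2_fc) > lfc_threshold) %>%
    select(transcript_id, mean_tpm_1, mean_tpm_2, log2_fc, p_value,
           significant)
}

#' Compare a numeric feature across groups
#'
#' One-way ANOVA omnibus over the groups plus all pairwise Welch t tests;
#' with exactly two groups the result reduces to the unpaired t test alone
#' (the omnibus p equals the pairwise p is not forced — the pairwise table
#' carries the t test). Groups with fewer than `min_n` items are dropped
#' with a warning; fewer than two remaining groups is an error. Used for
#' the stratified integration analyses (feature by alternative-splicing
#' class, by m6A status, by APA shift class).
#'
#' @param data Data frame.
#' @param value Column (tidy-eval) holding the numeric feature.
#' @param group Column holding the group label.
#' @param min_n Minimum items per group (default 3).
#' @return An object of class `tailshift_groupcomp` with [tidy()] (pairwise
#'   tests), [glance()] (omnibus) and [autoplot()] methods.
#' @examples
#' d <- data.frame(v = c(rnorm(5), rnorm(5, 2)), g = rep(c("a", "b"), each = 5))
#' glance(group_compare(d, v, g))
#' @export
group_compare <- function(data, value, group, min_n = 3) {
  df <- tibble(value = dplyr::pull(data, {{ value }}),
               group = as.character(dplyr::pull(data, {{ group }}))) %>%
    filter(!is.na(value), !is.na(group))
  sizes <- df %>% count(group)
  small <- sizes$group[sizes$n < min_n]
  if (length(small) > 0) {
    rlang::warn(sprintf("group_compare: dropped group(s) with < %d items: %s",
                        min_n, paste(small, collapse = ", ")))
    df <- df %>% filter(!group %in% small)
  }
  groups <- sort(unique(df$group))
  if (length(groups) < 2) {
    rlang::abort("group_compare needs >= 2 groups after filtering",
                 class = "tailshift_validation_error")
  }
  summary_tbl <- df %>%
    group_by(group) %>%
    summarise(n = dplyr::n(), median = stats::median(value),
              q1 = unname(stats::quantile(value, 0.25)),
              q3 = unname(stats::quantile(value, 0.75)),
              mean = mean(value), .groups = "drop")
  pairs <- utils::combn(groups, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- df$value[df$group == g1]; y <- df$value[df$group == g2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: both groups constant
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      tt <- list(statistic = c(t = if (eq) 0 else Inf),
                 p.value = if (eq) 1 else 0)
    } else {
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    }
    tibble(group_1 = g1, group_2 = g2,
           estimate = mean(x) - mean(y),
           statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  if (length(groups) == 2) {
    omnibus <- tibble(method = "welch_t", statistic = pairwise$statistic[1],
                      df = NA_real_, p_value = pairwise$p_value[1])
  } else {
    fit <- stats::aov(value ~ group, data = df)
    s <- summary(fit)[[1]]
    omnibus <- tibble(method = "one_way_anova",
                      statistic = s[["F value"]][1],
                      df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1])
  }
  structure(list(data = df, summary = summary_tbl, omnibus = omnibus,
                 pairwise = pairwise),
            class = "tailshift_groupcomp")
}

#' @export
print.tailshift_groupcomp <- function(x, ...) {
  cat("<tailshift_groupcomp>", nrow(x$summary), "groups;",
      x$omnibus$method, "p =", signif(x$omnibus$p_value, 3), "\n")
  print(x$summary)
  invisible(x)
}

#' Rank correlation between two per-transcript features
#'
#' Spearman correlation with p-value; requires at least `min_n` complete
#' pairs, and reports an undefined correlation (NA, with a reason) when
#' either side is constant. Used to relate per-transcript PAL or m6A
#' stoichiometry to expression.
#'
#' @param x,y Numeric vectors.
#' @param min_n Minimum complete pairs (default 10).
#' @return One-row tibble: n, rho, p_value, method, reason.
#' @export
correlate_features <- function(x, y, min_n = 10) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) {
    rlang::abort(sprintf("correlate_features needs >= %d complete pairs", min_n),
                 class = "tailshift_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(n = n, rho = NA_real_, p_value = NA_real_,
                  method = "spearman", reason = "constant_input"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(n = n, rho = unname(ct$estimate), p_value = ct$p.value,
         method = "spearman", reason = NA_character_)
}
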