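#' Simulate per-read features and modification calls
#'
#' Draws, for every gene x sample, a negative-binomial read count, then per
#' read: a 3' end from the gene's two-site proximal/distal mixture (stage
#' dependent, with planted genes' proximal odds multiplied in the later
#' stages) plus rounded-Gaussian positional noise; a poly(A) tail length
#' from a gamma whose scale is solved so the distribution median equals the
#' stage target (planted transcripts multiplied by `pal_planted_fold` in
#' the later stages); a full-length flag; and one modification call per
#' m6A site of the gene, modified with the site's Bernoulli rate (planted
#' sites shifted by `m6a_planted_delta` in the later stages). Every planted
#' effect is recorded in the returned ground truth.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [simulate_annotation()] (carries the planted
#'   poly(A)-site positions).
#' @return A list of class `tailshift_sim` with elements `reads`,
#'   `modcalls`, `sites`, `truth`, `annotation`, `config`.
#' @examples
#' cfg <- sim_config(n_genes = 5, reads_per_gene_mean = 20)
#' sim <- simulate_reads(cfg, simulate_annotation(cfg))
#' head(sim$reads)
#' @export
simulate_reads <- function(config, annotation) {
  validate_sim_config(config)
  if (!inherits(annotation, "tailshift_annotation") ||
      nrow(annotation$genes) == 0) {
    rlang::abort("`annotation` must be a non-empty tailshift_annotation.",
                 class = "tailshift_config_error")
  }
  pas <- attr(annotation, "pas_truth")
  if (is.null(pas)) {
    rlang::abort("annotation lacks planted poly(A) sites; use simulate_annotation().",
                 class = "tailshift_config_error")
  }
  tx <- annotation$transcripts
  stages <- config$stages
  late <- later_stages(config)
  n_genes <- nrow(pas)

  withr::with_seed(config$seed, {
    # ---- planted effect assignment -------------------------------------
    apa_genes <- sort(sample(pas$gene_id,
                             round(config$apa_planted_fraction * n_genes)))
    pal_tx <- sort(sample(tx$transcript_id,
                          round(config$pal_planted_fraction * nrow(tx))))
    de_genes <- sort(sample(pas$gene_id,
                            round(config$de_planted_fraction * n_genes)))
    z_gene <- stats::setNames(
      if (config$gene_log2_expr_sd > 0)
        rnorm(n_genes, 0, config$gene_log2_expr_sd) else rep(0, n_genes),
      pas$gene_id)

    # ---- m6A sites ------------------------------------------------------
    n_sites <- rpois(n_genes, config$m6a_sites_per_gene_mean)
    sites <- purrr::map_dfr(which(n_sites > 0), function(i) {
      txi <- tx[tx$gene_id == pas$gene_id[i], ][1, ]
      exi <- annotation$exons[annotation$exons$transcript_id == txi$transcript_id, ]
      tpos <- sort(sample.int(txi$tx_len, n_sites[i]))
      tibble(gene_id = pas$gene_id[i], transcript_id = txi$transcript_id,
             site_chrom = txi$chrom, site_strand = txi$strand,
             tx_pos = tpos,
             site_pos = tx_to_genomic(tpos, exi$start, exi$end, txi$strand))
    })
    if (nrow(sites) > 0) {
      sites$base_rate <- rbeta(nrow(sites), config$m6a_ratio_alpha,
                               config$m6a_ratio_beta)
      sites$planted <- runif(nrow(sites)) < config$m6a_planted_fraction
      sites$late_rate <- pmin(1, pmax(0, sites$base_rate +
        ifelse(sites$planted, config$m6a_planted_delta, 0)))
      sites$site_id <- sprintf("%s:%d:%s", sites$site_chrom, sites$site_pos,
                               sites$site_strand)
    } else {
      sites <- tibble(gene_id = character(), transcript_id = character(),
                      site_chrom = character(), site_strand = character(),
                      tx_pos = integer(), site_pos = integer(),
                      base_rate = double(), planted = logical(),
                      late_rate = double(), site_id = character())
    }

    # ---- per gene x sample counts --------------------------------------
    design <- tidyr::expand_grid(
      gene_id = pas$gene_id,
      stage = factor(stages, levels = stages),
      rep_id = seq_len(config$replicates_per_stage)) %>%
      mutate(stage = as.character(stage),
             sample_id = sprintf("%s_rep%d", stage, rep_id),
             mu = config$reads_per_gene_mean * 2^z_gene[gene_id] *
               ifelse(gene_id %in% de_genes & stage %in% late,
                      config$de_planted_fold, 1))
    design$n_reads <- rnbinom(nrow(design), mu = design$mu,
                              size = 1 / config$nb_dispersion)

    reads <- design %>%
      select(gene_id, stage, sample_id, n_reads) %>%
      tidyr::uncount(n_reads) %>%
      left_join(pas, by = "gene_id") %>%
      left_join(tx %>% select(transcript_id, strand, as_class),
                by = "transcript_id")

    # ---- 3' ends: proximal/distal mixture ------------------------------
    w <- config$proximal_weight_by_stage[reads$stage]
    k <- ifelse(reads$gene_id %in% apa_genes & reads$stage %in% late,
                config$apa_planted_odds_multiplier, 1)
    w_eff <- (w * k) / (w * k + (1 - w))
    reads$is_proximal <- runif(nrow(reads)) < w_eff
    reads$three_prime_pos <- as.integer(
      ifelse(reads$is_proximal, reads$ppas_pos, reads$dpas_pos) +
        round(rnorm(nrow(reads), 0, config$pas_positional_noise_sd)))

    # ---- poly(A) tail lengths ------------------------------------------
    gamma_med1 <- qgamma(0.5, shape = config$pal_shape)  # median at scale 1
    base_scale <- config$pal_median_by_stage[reads$stage] / gamma_med1
    mult <- ifelse(reads$transcript_id %in% pal_tx & reads$stage %in% late,
                   config$pal_planted_fold, 1) *
      2^(config$pal_expr_link * z_gene[reads$gene_id])
    reads$polya_len <- rgamma(nrow(reads), shape = config$pal_shape,
                              scale = base_scale * mult)
    reads$polya_len[runif(nrow(reads)) < config$pal_missing_prob] <- NA_real_
    reads$full_length <- runif(nrow(reads)) < config$full_length_prob
    reads$read_id <- sprintf("r%08d", seq_len(nrow(reads)))

    reads <- reads %>%
      select(read_id, sample_id, stage, gene_id, transcript_id, strand,
             three_prime_pos, polya_len, full_length, as_class)

    # ---- modification calls: one call per read per site of its gene ----
    modcalls <- reads %>%
      select(read_id, gene_id, stage) %>%
      inner_join(sites %>% select(gene_id, site_chrom, site_pos,
                                  site_strand, base_rate, late_rate),
                 by = "gene_id", relationship = "many-to-many")
    if (nrow(modcalls) > 0) {
      rate <- ifelse(modcalls$stage %in% late, modcalls$late_rate,
                     modcalls$base_rate)
      modcalls$modified <- runif(nrow(modcalls)) < rate
    } else {
      modcalls$modified <- logical(0)
    }
    modcalls <- modcalls %>%
      select(read_id, gene_id, site_chrom, site_pos, site_strand, modified)

    truth <- list(
      apa_shift_genes = tibble(
        gene_id = apa_genes,
        direction = if (config$apa_planted_odds_multiplier >= 1)
          "proximal_up" else "distal_up"),
      pal_diff_transcripts = tibble(
        transcript_id = pal_tx, fold = config$pal_planted_fold,
        direction = "longer"),
      m6a_diff_sites = sites %>% filter(planted) %>%
        select(site_id, gene_id, site_chrom, site_pos, site_strand) %>%
        mutate(delta = config$m6a_planted_delta),
      de_genes = tibble(gene_id = de_genes, fold = config$de_planted_fold),
      proximal_weight_by_stage = config$proximal_weight_by_stage,
      pal_median_by_stage = config$pal_median_by_stage,
      effect_stages = late
    )

    structure(list(reads = reads, modcalls = modcalls, sites = sites,
                   truth = truth, annotation = annotation, config = config),
              class = "tailshift_sim")
  })
}

#' @export
print.tailshift_sim <- function(x, ...) {
  cat("<tailshift_sim>", nrow(x$reads), "reads,", nrow(x$modcalls),
      "modification calls,", nrow(x$sites), "m6A sites\n")
  cat("  planted: ", nrow(x$truth$apa_shift_genes), " APA genes, ",
      nrow(x$truth$pal_diff_transcripts), " PAL transcripts, ",
      nrow(x$truth$m6a_diff_sites), " m6A sites, ",
      nrow(x$truth$de_genes), " DE genes\n", sep = "")
  invisible(x)
}
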