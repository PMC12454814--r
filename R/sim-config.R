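#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic per-read
#' generator. The defaults emulate a four-stage peanut pod development
#' direct-RNA-sequencing experiment: stage-specific poly(A)-tail medians of
#' 84.38 / 79.91 / 81.6 / 86.59 nt, a planted developmental shift from distal
#' to proximal poly(A)-site usage in the last two stages, per-site m6A
#' stoichiometry centred on 0.5, and negative-binomial expression counts over
#' 4 stages x 3 replicates.
#'
#' @param seed Integer seed; the same seed and config produce byte-identical
#'   outputs.
#' @param n_genes Number of genes to simulate (one transcript each).
#' @param stages Ordered character vector of stage labels; order defines
#'   "earlier" and "later" stages.
#' @param replicates_per_stage Biological replicates per stage.
#' @param reads_per_gene_mean Negative-binomial mean reads per gene per
#'   sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param pal_median_by_stage Named (or stage-ordered) numeric vector of
#'   target poly(A)-tail-length medians in nt, one per stage.
#' @param pal_shape Gamma shape for per-read tail lengths; the scale is
#'   solved so the distribution median equals the stage target.
#' @param pas_pair_distance_nt Distance in nt between the proximal and
#'   distal poly(A) site planted in every final exon.
#' @param proximal_weight_by_stage Per-stage probability that a read uses
#'   the proximal site (before any planted effect).
#' @param apa_planted_fraction Fraction of genes given a planted APA shift.
#' @param apa_planted_odds_multiplier Odds multiplier applied to the
#'   proximal/distal choice of planted genes in the later stages; values
#'   > 1 plant a proximal shift, < 1 a distal shift.
#' @param m6a_sites_per_gene_mean Poisson mean number of m6A sites per gene.
#' @param m6a_ratio_alpha,m6a_ratio_beta Beta parameters of per-site
#'   baseline modification stoichiometry (defaults give mean 0.5).
#' @param m6a_planted_fraction Fraction of sites with a planted
#'   stoichiometry change in the later stages.
#' @param m6a_planted_delta Stoichiometry shift added (clipped to \[0,1\])
#'   at planted sites in the later stages.
#' @param pal_planted_fraction Fraction of transcripts whose tail lengths
#'   are multiplied in the later stages.
#' @param pal_planted_fold Multiplicative tail-length fold for planted
#'   transcripts (> 1).
#' @param de_planted_fraction Fraction of genes whose expression mean is
#'   multiplied in the later stages.
#' @param de_planted_fold Expression fold for planted genes.
#' @param as_class_probs Named probabilities over alternative-splicing
#'   class labels \{AF, AL, A3, A5, SE, MX, RI, none\}; one label is drawn
#'   per transcript.
#' @param pas_positional_noise_sd SD (nt) of the rounded-Gaussian noise on
#'   read 3' ends around their poly(A) site.
#' @param full_length_prob Probability a read is flagged full-length.
#' @param pal_missing_prob Probability a read's tail-length estimate is
#'   missing.
#' @param gene_log2_expr_sd SD of a per-gene log2 expression offset
#'   (0 = homogeneous expression).
#' @param pal_expr_link Coefficient linking a gene's log2 expression offset
#'   to a multiplicative tail-length factor 2^(link * offset); negative
#'   values make highly expressed genes carry shorter tails.
#' @param effect_from_stage Index of the first "later" stage; planted APA,
#'   PAL, m6A and DE effects apply from this stage on.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 20, reads_per_gene_mean = 30)
#' cfg$stages
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       stages = c("AerPeg", "SubPeg", "ExpPod1", "ExpPod2"),
                       replicates_per_stage = 3L,
                       reads_per_gene_mean = 200,
                       nb_dispersion = 0.1,
                       pal_median_by_stage = c(84.38, 79.91, 81.6, 86.59),
                       pal_shape = 4,
                       pas_pair_distance_nt = 200L,
                       proximal_weight_by_stage = rep(0.5, length(stages)),
                       apa_planted_fraction = 0.06,
                       apa_planted_odds_multiplier = 6,
                       m6a_sites_per_gene_mean = 3,
                       m6a_ratio_alpha = 8,
                       m6a_ratio_beta = 8,
                       m6a_planted_fraction = 0.1,
                       m6a_planted_delta = 0.3,
                       pal_planted_fraction = 0.1,
                       pal_planted_fold = 1.8,
                       de_planted_fraction = 0.1,
                       de_planted_fold = 4,
                       as_class_probs = c(AF = 0.06, AL = 0.04, A3 = 0.12,
                                          A5 = 0.10, SE = 0.10, MX = 0.03,
                                          RI = 0.25, none = 0.30),
                       pas_positional_noise_sd = 5,
                       full_length_prob = 0.6,
                       pal_missing_prob = 0.02,
                       gene_log2_expr_sd = 0,
                       pal_expr_link = 0,
                       effect_from_stage = length(stages) - 1L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    stages = as.character(stages),
    replicates_per_stage = as.integer(replicates_per_stage),
    reads_per_gene_mean = reads_per_gene_mean,
    nb_dispersion = nb_dispersion,
    pal_median_by_stage = stats::setNames(
      unname(pal_median_by_stage), as.character(stages)),
    pal_shape = pal_shape,
    pas_pair_distance_nt = as.integer(pas_pair_distance_nt),
    proximal_weight_by_stage = stats::setNames(
      unname(proximal_weight_by_stage), as.character(stages)),
    apa_planted_fraction = apa_planted_fraction,
    apa_planted_odds_multiplier = apa_planted_odds_multiplier,
    m6a_sites_per_gene_mean = m6a_sites_per_gene_mean,
    m6a_ratio_alpha = m6a_ratio_alpha,
    m6a_ratio_beta = m6a_ratio_beta,
    m6a_planted_fraction = m6a_planted_fraction,
    m6a_planted_delta = m6a_planted_delta,
    pal_planted_fraction = pal_planted_fraction,
    pal_planted_fold = pal_planted_fold,
    de_planted_fraction = de_planted_fraction,
    de_planted_fold = de_planted_fold,
    as_class_probs = as_class_probs,
    pas_positional_noise_sd = pas_positional_noise_sd,
    full_length_prob = full_length_prob,
    pal_missing_prob = pal_missing_prob,
    gene_log2_expr_sd = gene_log2_expr_sd,
    pal_expr_link = pal_expr_link,
    effect_from_stage = as.integer(effect_from_stage)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    rlang::abort("`n_genes` must be a positive integer.",
                 class = "tailshift_config_error")
  }
  if (length(cfg$stages) < 2L || anyDuplicated(cfg$stages)) {
    rlang::abort("`stages` must be >= 2 distinct labels.",
                 class = "tailshift_config_error")
  }
  if (length(cfg$pal_median_by_stage) != length(cfg$stages) ||
      any(cfg$pal_median_by_stage <= 0)) {
    rlang::abort("`pal_median_by_stage` needs one positive value per stage.",
                 class = "tailshift_config_error")
  }
  if (length(cfg$proximal_weight_by_stage) != length(cfg$stages) ||
      any(cfg$proximal_weight_by_stage < 0 | cfg$proximal_weight_by_stage > 1)) {
    rlang::abort("`proximal_weight_by_stage` must lie in [0, 1] per stage.",
                 class = "tailshift_config_error")
  }
  expected_classes <- c("AF", "AL", "A3", "A5", "SE", "MX", "RI", "none")
  if (!setequal(names(cfg$as_class_probs), expected_classes)) {
    rlang::abort("`as_class_probs` must be named over AF, AL, A3, A5, SE, MX, RI, none.",
                 class = "tailshift_config_error")
  }
  if (abs(sum(cfg$as_class_probs) - 1) > 1e-9 || any(cfg$as_class_probs < 0)) {
    rlang::abort("`as_class_probs` must be nonnegative and sum to 1 (tol 1e-9).",
                 class = "tailshift_config_error")
  }
  for (fld in c("reads_per_gene_mean", "nb_dispersion", "pal_shape",
                "apa_planted_odds_multiplier", "m6a_ratio_alpha",
                "m6a_ratio_beta", "de_planted_fold")) {
    if (cfg[[fld]] <= 0) {
      rlang::abort(sprintf("`%s` must be positive.", fld),
                   class = "tailshift_config_error")
    }
  }
  for (fld in c("apa_planted_fraction", "m6a_planted_fraction",
                "m6a_planted_delta", "pal_planted_fraction",
                "de_planted_fraction", "full_length_prob",
                "pal_missing_prob")) {
    if (cfg[[fld]] < 0 || cfg[[fld]] > 1) {
      rlang::abort(sprintf("`%s` must lie in [0, 1].", fld),
                   class = "tailshift_config_error")
    }
  }
  if (cfg$pal_planted_fold <= 1) {
    rlang::abort("`pal_planted_fold` must exceed 1.",
                 class = "tailshift_config_error")
  }
  if (cfg$pas_pair_distance_nt < 1 || cfg$pas_positional_noise_sd < 0 ||
      cfg$m6a_sites_per_gene_mean < 0) {
    rlang::abort("distance/noise/site-rate parameters out of range.",
                 class = "tailshift_config_error")
  }
  if (cfg$effect_from_stage < 2L || cfg$effect_from_stage > length(cfg$stages)) {
    rlang::abort("`effect_from_stage` must index a non-first stage.",
                 class = "tailshift_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, " stages:", paste(x$stages, collapse = ", "), "\n")
  cat("  replicates/stage:", x$replicates_per_stage,
      " reads/gene/sample (NB mean):", x$reads_per_gene_mean, "\n")
  cat("  PAL medians:", paste(x$pal_median_by_stage, collapse = "/"), "nt\n")
  cat("  planted: APA", x$apa_planted_fraction, "| PAL",
      x$pal_planted_fraction, "| m6A", x$m6a_planted_fraction,
      "| DE", x$de_planted_fraction, "\n")
  invisible(x)
}

# stage labels on which planted effects act
later_stages <- function(cfg) {
  cfg$stages[seq(cfg$effect_from_stage, length(cfg$stages))]
}
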