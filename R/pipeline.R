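#' Pipeline run configuration
#'
#' Collects inputs (either a [sim_config()] to simulate from, or paths to
#' annotation/reads/modcalls files), the ordered condition comparisons and
#' all module thresholds. Round-trips through YAML unchanged
#' ([read_run_config()] / [write_run_config()]).
#'
#' @param simulate A [sim_config()], or NULL when reading from files.
#' @param annotation,reads,modcalls Input paths (ignored when `simulate`
#'   is given).
#' @param comparisons List of `c(control, treatment)` stage pairs; default
#'   all ordered stage pairs in stage order (earlier stage = control).
#' @param window PAS clustering window (nt).
#' @param pseudocount Pseudocount for APA log ratios.
#' @param apa_threshold,apa_mode APA significance rule
#'   (see [apa_d_statistic()]).
#' @param apa_min_count Minimum reads per PAS per condition.
#' @param pal_min_n Minimum reads per condition for the PAL test.
#' @param pal_fc_threshold PAL fold-change threshold.
#' @param m6a_delta_threshold Minimum |mean m6A ratio difference|.
#' @param de_lfc_threshold DE |log2 fold-change| threshold.
#' @param p_threshold Shared p-value threshold.
#' @param bins_per_region Metagene bins per region.
#' @param seed Seed recorded in outputs; overrides `simulate$seed` when
#'   given.
#' @return A list of class `tailshift_run_config`.
#' @export
run_config <- function(simulate = sim_config(),
                       annotation = NULL, reads = NULL, modcalls = NULL,
                       comparisons = NULL,
                       window = 24, pseudocount = 1,
                       apa_threshold = 0.3, apa_mode = "log2",
                       apa_min_count = 5,
                       pal_min_n = 10, pal_fc_threshold = 1.5,
                       m6a_delta_threshold = 0.1,
                       de_lfc_threshold = 1, p_threshold = 0.05,
                       bins_per_region = 10, seed = NULL) {
  if (!is.null(simulate) && !is.null(seed)) simulate$seed <- as.integer(seed)
  cfg <- list(simulate = simulate, annotation = annotation, reads = reads,
              modcalls = modcalls, comparisons = comparisons,
              window = window, pseudocount = pseudocount,
              apa_threshold = apa_threshold, apa_mode = apa_mode,
              apa_min_count = apa_min_count, pal_min_n = pal_min_n,
              pal_fc_threshold = pal_fc_threshold,
              m6a_delta_threshold = m6a_delta_threshold,
              de_lfc_threshold = de_lfc_threshold,
              p_threshold = p_threshold, bins_per_region = bins_per_region,
              seed = seed %||% (if (!is.null(simulate)) simulate$seed))
  class(cfg) <- "tailshift_run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$pal_median_by_stage)) {
      sim_args$pal_median_by_stage <- unlist(sim_args$pal_median_by_stage)
    }
    if (!is.null(sim_args$proximal_weight_by_stage)) {
      sim_args$proximal_weight_by_stage <- unlist(sim_args$proximal_weight_by_stage)
    }
    if (!is.null(sim_args$as_class_probs)) {
      sim_args$as_class_probs <- unlist(sim_args$as_class_probs)
    }
    if (!is.null(sim_args$stages)) sim_args$stages <- unlist(sim_args$stages)
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), "simulate")]
  if (!is.null(args$comparisons)) {
    args$comparisons <- lapply(args$comparisons, unlist)
  }
  do.call(run_config, c(list(simulate = sim), args))
}

#' @rdname run_config
#' @param config A `tailshift_run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$simulate)) {
    y$simulate <- unclass(y$simulate)
    y$simulate$pal_median_by_stage <- as.list(y$simulate$pal_median_by_stage)
    y$simulate$proximal_weight_by_stage <-
      as.list(y$simulate$proximal_weight_by_stage)
    y$simulate$as_class_probs <- as.list(y$simulate$as_class_probs)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

default_comparisons <- function(stages) {
  pairs <- utils::combn(stages, 2)
  lapply(seq_len(ncol(pairs)), function(j) pairs[, j])
}

#' Run the full analysis pipeline
#'
#' Orchestrates annotation parsing (or simulation), poly(A)-site
#' clustering and APA testing, PAL summaries and tests, m6A stoichiometry,
#' metagene and differential-methylation calling, TPM quantification, the
#' DE stand-in and the stratified integration analyses for every
#' comparison pair. Writes per-module TSVs, a BED of selected poly(A)-site
#' pairs, a machine-readable `summary.json` and a `run.log` with ISO
#' timestamps, seed and config hash into `out_dir`. Reruns with identical
#' config and inputs produce byte-identical tables and JSON. A failing
#' stage aborts with a stage-named message and leaves an `INCOMPLETE`
#' marker in `out_dir`.
#'
#' @param config A `tailshift_run_config` (or a YAML path).
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory results (`apa`, `pal`,
#'   `m6a`, `de`, `summary`, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tailshift_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   paste0(...))
    writeLines(msg, log_con); message(msg)
  }
  stage_do <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", label,
                           conditionMessage(e)),
                   class = "tailshift_pipeline_error", parent = e)
    })
  }
  cfg_hash <- rlang::hash(config)
  say("tailshift ", as.character(utils::packageVersion("tailshift")),
      " | seed ", config$seed %||% "NA", " | config hash ", cfg_hash)

  # ---- inputs ----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    res <- stage_do("simulate", {
      ann <- simulate_annotation(config$simulate)
      simulate_reads(config$simulate, ann)
    })
    annotation <- res$annotation; reads <- res$reads
    modcalls <- res$modcalls; truth <- res$truth
    say("simulated ", nrow(reads), " reads / ", nrow(modcalls), " calls")
  } else {
    annotation <- stage_do("annotation_core", read_annotation(config$annotation))
    reads <- stage_do("annotation_core", read_reads(config$reads, annotation))
    modcalls <- stage_do("annotation_core", read_modcalls(config$modcalls))
  }
  stages <- unique(reads$stage)
  comparisons <- config$comparisons %||% default_comparisons(
    if (!is.null(config$simulate)) config$simulate$stages else stages)
  for (cmp in comparisons) {
    missing <- setdiff(cmp, stages)
    if (length(missing) > 0) {
      rlang::abort(sprintf("comparison %s vs %s references missing stage(s): %s",
                           cmp[1], cmp[2], paste(missing, collapse = ", ")),
                   class = "tailshift_config_error")
    }
  }
  pair_id <- function(cmp) paste0(cmp[1], "_vs_", cmp[2])
  wtsv <- function(tb, name, header = NULL) {
    path <- file.path(out_dir, name)
    if (!is.null(header)) {
      writeLines(paste0("# ", header), path)
      readr::write_tsv(tb, path, append = TRUE, col_names = TRUE,
                       progress = FALSE)
    } else readr::write_tsv(tb, path, progress = FALSE)
    path
  }

  # ---- stage-level summaries ------------------------------------------
  pal_summary <- stage_do("pal", summarize_pal(reads, by = "stage"))
  pal_summary_fl <- stage_do("pal",
    summarize_pal(reads, by = c("stage", "full_length")))
  wtsv(pal_summary, "pal_summary.tsv")
  wtsv(pal_summary_fl, "pal_summary_by_full_length.tsv")

  site_counts <- stage_do("m6a", m6a_site_counts(modcalls, reads))
  sites_unique <- site_counts %>%
    distinct(site_id, gene_id, site_chrom, site_pos, site_strand)
  sites_assigned <- stage_do("m6a",
    assign_site_region(sites_unique, annotation))
  profile <- stage_do("m6a",
    metagene_profile(sites_assigned, config$bins_per_region))
  wtsv(profile, "metagene_profile.tsv")
  rates <- stage_do("m6a", m6a_stage_rates(site_counts))
  wtsv(rates, "m6a_stage_rates.tsv")
  sites_tsv <- site_counts %>%
    select(-by_rep) %>%
    left_join(sites_assigned %>% select(site_id, region),
              by = "site_id")
  wtsv(sites_tsv, "m6a_sites.tsv")

  tpm <- stage_do("quant", quantify_tpm(reads, annotation))
  wtsv(tpm, "tpm.tsv")

  # ---- per-comparison analyses ----------------------------------------
  apa_list <- list(); pal_list <- list(); m6a_list <- list(); de_list <- list()
  for (cmp in comparisons) {
    id <- pair_id(cmp)
    say("comparison ", id)
    apa <- stage_do("pas_apa", apa_test(
      reads, annotation, cmp[1], cmp[2], window = config$window,
      pseudocount = config$pseudocount, threshold = config$apa_threshold,
      mode = config$apa_mode, min_count = config$apa_min_count))
    wtsv(as_tibble(apa), paste0("apa_", id, ".tsv"))
    export_pas_bed(apa, file.path(out_dir, paste0("pas_", id, ".bed")))
    pal <- stage_do("pal", pal_test(
      reads, cmp[1], cmp[2], min_n = config$pal_min_n,
      fc_threshold = config$pal_fc_threshold,
      p_threshold = config$p_threshold))
    wtsv(pal, paste0("pal_", id, ".tsv"))
    m6a <- stage_do("m6a", m6a_diff_test(
      site_counts, cmp[1], cmp[2],
      delta_threshold = config$m6a_delta_threshold,
      p_threshold = config$p_threshold))
    wtsv(m6a, paste0("m6a_", id, ".tsv"))
    de <- stage_do("quant_integration", de_test(
      tpm, cmp[1], cmp[2], p_threshold = config$p_threshold,
      lfc_threshold = config$de_lfc_threshold))
    wtsv(de, paste0("de_", id, ".tsv"),
         header = "method: welch_t_log2_tpm_standin")
    apa_list[[id]] <- apa; pal_list[[id]] <- pal
    m6a_list[[id]] <- m6a; de_list[[id]] <- de
  }

  # ---- integration on the last comparison pair ------------------------
  last_cmp <- comparisons[[length(comparisons)]]
  integration <- stage_do("quant_integration", integrate_pair(
    reads, annotation, tpm, site_counts, apa_list[[pair_id(last_cmp)]],
    last_cmp[1], last_cmp[2]))
  wtsv(integration$tests, "integration_tests.tsv")

  # ---- summary ---------------------------------------------------------
  per_cmp <- lapply(comparisons, function(cmp) {
    id <- pair_id(cmp)
    apa <- apa_list[[id]]; pal <- pal_list[[id]]
    m6a <- m6a_list[[id]]; de <- de_list[[id]]
    gred <- global_red(apa)
    list(control = cmp[1], treatment = cmp[2],
         n_apa_tested = nrow(apa),
         n_apa_significant = sum(apa$significant %||% logical(0)),
         n_proximal_up = sum(apa$shift_class == "proximal_up"),
         n_distal_up = sum(apa$shift_class == "distal_up"),
         mean_red = gred$mean_red,
         n_pal_tested = sum(pal$tested),
         n_pal_significant = sum(pal$significant),
         n_pal_longer = sum(pal$direction == "longer"),
         n_pal_shorter = sum(pal$direction == "shorter"),
         n_m6a_tested = sum(m6a$tested),
         n_m6a_significant = sum(m6a$significant),
         n_de_significant = sum(de$significant))
  })
  names(per_cmp) <- vapply(comparisons, pair_id, character(1))
  summary <- list(
    seed = config$seed, config_hash = cfg_hash,
    n_genes = nrow(annotation$genes), n_reads = nrow(reads),
    n_m6a_sites = nrow(sites_unique),
    pal_median_by_stage = as.list(stats::setNames(pal_summary$median,
                                                  pal_summary$stage)),
    m6a_rate_by_stage = as.list(stats::setNames(rates$median, rates$stage)),
    comparisons = per_cmp,
    integration = integration$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  say("done")
  invisible(list(annotation = annotation, reads = reads,
                 modcalls = modcalls, truth = truth,
                 site_counts = site_counts, profile = profile, tpm = tpm,
                 apa = apa_list, pal = pal_list, m6a = m6a_list,
                 de = de_list, integration = integration,
                 summary = summary))
}

#' Stratified integration analyses
#'
#' Runs the relationship analyses for one condition pair, on the treatment
#' stage: transcript expression by alternative-splicing class, median PAL
#' by alternative-splicing class, per-gene m6A stoichiometry by APA shift
#' class, median PAL of m6A-modified vs unmodified transcripts, and
#' Spearman correlations of PAL and m6A stoichiometry with expression.
#'
#' @param reads Read table.
#' @param annotation A `tailshift_annotation`.
#' @param tpm Output of [quantify_tpm()].
#' @param site_counts Output of [m6a_site_counts()].
#' @param apa APA result for the pair ([apa_test()]).
#' @param control,treatment Stage labels.
#' @param min_group_n Minimum items per group (default 3).
#' @return List: `tests` (tibble of every omnibus/correlation), `summary`
#'   (same, as a named list), `objects` (the `tailshift_groupcomp`s).
#' @export
integrate_pair <- function(reads, annotation, tpm, site_counts, apa,
                           control, treatment, min_group_n = 3) {
  stage_sel <- treatment
  expr <- tpm %>%
    filter(stage == stage_sel) %>%
    group_by(transcript_id) %>%
    summarise(log_expr = log2(mean(tpm) + 1), .groups = "drop")
  pal_tx <- reads %>%
    filter(stage == stage_sel, !is.na(polya_len)) %>%
    group_by(transcript_id) %>%
    summarise(median_pal = stats::median(polya_len), n = dplyr::n(),
              .groups = "drop")
  cls <- annotation$transcripts %>% select(transcript_id, gene_id, as_class)

  objects <- list(); rows <- list()
  # group comparisons that end up with < 2 viable groups are skipped, not fatal
  add <- function(name, expr) {
    gc <- tryCatch(suppressWarnings(expr),
                   tailshift_validation_error = function(e) NULL)
    if (is.null(gc)) {
      rows[[name]] <<- tibble(analysis = name, method = "skipped",
                              statistic = NA_real_, p_value = NA_real_,
                              n_groups = NA_integer_, n_items = NA_integer_)
      return(invisible(NULL))
    }
    objects[[name]] <<- gc
    g <- glance(gc)
    rows[[name]] <<- tibble(analysis = name, method = g$method,
                            statistic = g$statistic, p_value = g$p_value,
                            n_groups = g$n_groups, n_items = g$n_items)
  }

  expr_as <- expr %>% inner_join(cls, by = "transcript_id")
  add("expression_by_as_class",
      group_compare(expr_as, log_expr, as_class, min_n = min_group_n))

  pal_as <- pal_tx %>% inner_join(cls, by = "transcript_id")
  add("pal_by_as_class",
      group_compare(pal_as, median_pal, as_class, min_n = min_group_n))

  if (nrow(apa) > 0) {
    gene_ratio <- site_counts %>%
      filter(stage == stage_sel, !is.na(ratio)) %>%
      group_by(gene_id) %>%
      summarise(mean_ratio = mean(ratio), .groups = "drop") %>%
      inner_join(as_tibble(apa) %>% select(gene_id, shift_class),
                 by = "gene_id")
    add("m6a_ratio_by_apa_shift",
        group_compare(gene_ratio, mean_ratio, shift_class,
                      min_n = min_group_n))
  }

  mod <- classify_modified_transcripts(site_counts, annotation) %>%
    filter(stage == stage_sel)
  pal_mod <- pal_tx %>% inner_join(mod, by = "transcript_id") %>%
    mutate(status = if_else(modified, "modified", "unmodified"))
  add("pal_by_m6a_status",
      group_compare(pal_mod, median_pal, status, min_n = min_group_n))

  corr_rows <- list()
  pe <- pal_tx %>% inner_join(expr, by = "transcript_id")
  if (nrow(pe) >= 10) {
    cr <- correlate_features(pe$median_pal, pe$log_expr)
    corr_rows$pal_expression_correlation <- tibble(
      analysis = "pal_expression_correlation", method = cr$method,
      statistic = cr$rho, p_value = cr$p_value, n_groups = NA_integer_,
      n_items = cr$n)
  }
  ratio_expr <- site_counts %>%
    filter(stage == stage_sel, !is.na(ratio)) %>%
    group_by(gene_id) %>%
    summarise(mean_ratio = mean(ratio), .groups = "drop") %>%
    inner_join(cls, by = "gene_id") %>%
    inner_join(expr, by = "transcript_id")
  if (nrow(ratio_expr) >= 10) {
    cr <- correlate_features(ratio_expr$mean_ratio, ratio_expr$log_expr)
    corr_rows$m6a_expression_correlation <- tibble(
      analysis = "m6a_expression_correlation", method = cr$method,
      statistic = cr$rho, p_value = cr$p_value, n_groups = NA_integer_,
      n_items = cr$n)
  }

  tests <- bind_rows(bind_rows(rows), bind_rows(corr_rows))
  summary <- stats::setNames(
    lapply(seq_len(nrow(tests)), function(i)
      list(method = tests$method[i], statistic = tests$statistic[i],
           p_value = tests$p_value[i])),
    tests$analysis)
  list(tests = tests, summary = summary, objects = objects)
}
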