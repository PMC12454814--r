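#' Write a simulated data set to disk
#'
#' Writes `reads.tsv`, `modcalls.tsv`, `annotation.gff3` and `truth.json`
#' into `dir`. Each TSV starts with a `# tailshift-fixture v1 <table>`
#' schema-version header line; `truth.json` carries a `schema` field.
#' Identical simulations produce byte-identical files.
#'
#' @param sim A `tailshift_sim` from [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "tailshift_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    rlang::abort(sprintf("cannot write to '%s'", dir),
                 class = "tailshift_io_error")
  }
  write_headed_tsv <- function(tb, name) {
    path <- file.path(dir, name)
    writeLines(sprintf("# tailshift-fixture v1 %s", name), path)
    readr::write_tsv(tb, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    path
  }
  reads_out <- sim$reads %>% mutate(full_length = as.integer(full_length))
  modcalls_out <- sim$modcalls %>% mutate(modified = as.integer(modified))
  write_headed_tsv(reads_out, "reads.tsv")
  write_headed_tsv(modcalls_out, "modcalls.tsv")
  write_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  truth <- sim$truth
  truth_json <- list(
    schema = "tailshift-fixture v1 truth",
    apa_shift_genes = truth$apa_shift_genes,
    pal_diff_transcripts = truth$pal_diff_transcripts,
    m6a_diff_sites = truth$m6a_diff_sites,
    de_genes = truth$de_genes,
    proximal_weight_by_stage = as.list(truth$proximal_weight_by_stage),
    pal_median_by_stage = as.list(truth$pal_median_by_stage),
    effect_stages = truth$effect_stages)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture directory back
#'
#' Round-trips the files written by [write_fixture()]: the returned tables
#' equal the simulated ones.
#'
#' @param dir Directory holding `reads.tsv`, `modcalls.tsv`,
#'   `annotation.gff3`, `truth.json`.
#' @return List with `reads`, `modcalls`, `annotation`, `truth`.
#' @export
read_fixture <- function(dir) {
  annotation <- read_annotation(file.path(dir, "annotation.gff3"))
  reads <- read_reads(file.path(dir, "reads.tsv"), annotation)
  modcalls <- read_modcalls(file.path(dir, "modcalls.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(reads = reads, modcalls = modcalls, annotation = annotation,
       truth = truth)
}
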