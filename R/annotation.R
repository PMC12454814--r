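#' Gene-model container
#'
#' A `tailshift_annotation` bundles three tibbles: `genes` (gene_id, chrom,
#' strand, start, end), `transcripts` (one row per mRNA with its CDS interval
#' and derived, strand-aware features: stop-codon position, final exon,
#' 3' UTR, region lengths in transcript coordinates) and `exons`
#' (transcript_id, start, end). All coordinates are 1-based inclusive, the
#' GFF3 convention, both externally and internally; BED exports convert to
#' 0-based half-open at the boundary.
#'
#' Derived features follow transcription direction: on `+` the stop-codon
#' position is the CDS end and the final exon is the rightmost exon; on `-`
#' they mirror. The 3' UTR is the exonic region strictly downstream of the
#' stop codon. The annotated CDS is taken to include the stop codon, the
#' common GFF3 dialect.
#'
#' @param genes,transcripts,exons Tibbles as described above; `transcripts`
#'   needs transcript_id, gene_id, chrom, strand, cds_start, cds_end and
#'   optionally as_class.
#' @return A list of class `tailshift_annotation` with derived transcript
#'   features filled in.
#' @export
as_annotation <- function(genes, transcripts, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("transcript_id", "gene_id", "chrom", "strand",
                  "cds_start", "cds_end") %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (!"as_class" %in% names(transcripts)) transcripts$as_class <- "none"
  exons <- exons %>% arrange(transcript_id, start)

  per_tx <- split(exons, exons$transcript_id)
  feats <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    ex <- per_tx[[tx$transcript_id]]
    if (is.null(ex) || nrow(ex) == 0) {
      rlang::abort(sprintf("transcript %s has no exons", tx$transcript_id),
                   class = "tailshift_validation_error")
    }
    derive_tx_features(tx$transcript_id, tx$strand, ex$start, ex$end,
                       tx$cds_start, tx$cds_end)
  })
  transcripts <- transcripts %>%
    select(-any_of(setdiff(names(feats), "transcript_id"))) %>%
    left_join(feats, by = "transcript_id")

  gene_spans <- exons %>%
    left_join(transcripts %>% select(transcript_id, gene_id),
              by = "transcript_id") %>%
    group_by(gene_id) %>%
    summarise(start = min(start), end = max(end), .groups = "drop")
  genes <- genes %>%
    select(-any_of(c("start", "end"))) %>%
    left_join(gene_spans, by = "gene_id")

  structure(list(genes = as_tibble(genes),
                 transcripts = as_tibble(transcripts),
                 exons = as_tibble(exons)),
            class = "tailshift_annotation")
}

# strand-aware derived features for one transcript; exons sorted by start
derive_tx_features <- function(transcript_id, strand, ex_start, ex_end,
                               cds_start, cds_end) {
  widths <- ex_end - ex_start + 1
  tx_len <- sum(widths)
  has_cds <- !is.na(cds_start) && !is.na(cds_end)
  if (has_cds) {
    in_exon <- function(p) any(p >= ex_start & p <= ex_end)
    if (!in_exon(cds_start) || !in_exon(cds_end) ||
        cds_start < min(ex_start) || cds_end > max(ex_end)) {
      rlang::abort(
        sprintf("CDS (%d, %d) of transcript %s falls outside its exons",
                cds_start, cds_end, transcript_id),
        class = "tailshift_validation_error")
    }
  }
  if (strand == "+") {
    fe <- length(widths)
    stop_pos <- if (has_cds) cds_end else NA_integer_
    utr3_start <- if (has_cds && cds_end < ex_end[fe]) cds_end + 1L else NA_integer_
    utr3_end <- if (!is.na(utr3_start)) ex_end[fe] else NA_integer_
  } else {
    fe <- 1L
    stop_pos <- if (has_cds) cds_start else NA_integer_
    utr3_start <- if (has_cds && cds_start > ex_start[fe]) ex_start[fe] else NA_integer_
    utr3_end <- if (!is.na(utr3_start)) cds_start - 1L else NA_integer_
  }
  if (has_cds) {
    t5 <- genomic_to_tx(if (strand == "+") cds_start else cds_end,
                        ex_start, ex_end, strand)
    t3 <- genomic_to_tx(if (strand == "+") cds_end else cds_start,
                        ex_start, ex_end, strand)
    utr5_len <- t5 - 1L
    cds_len <- t3 - t5 + 1L
    utr3_len <- tx_len - t3
  } else {
    utr5_len <- NA_integer_; cds_len <- NA_integer_; utr3_len <- NA_integer_
  }
  tibble(
    transcript_id = transcript_id,
    tx_start = min(ex_start), tx_end = max(ex_end), tx_len = tx_len,
    stop_codon_pos = stop_pos,
    final_exon_start = ex_start[fe], final_exon_end = ex_end[fe],
    utr3_start = utr3_start, utr3_end = utr3_end,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len
  )
}

#' Map genomic positions to transcript coordinates
#'
#' Transcript coordinates are 1-based along the spliced transcript in
#' transcription direction. Positions outside the exons return `NA`.
#'
#' @param pos Vector of genomic positions.
#' @param ex_start,ex_end Exon intervals sorted by genomic start.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of transcript coordinates.
#' @keywords internal
genomic_to_tx <- function(pos, ex_start, ex_end, strand) {
  widths <- ex_end - ex_start + 1
  if (strand == "+") {
    offs <- cumsum(c(0L, widths[-length(widths)]))
    vapply(pos, function(p) {
      i <- which(p >= ex_start & p <= ex_end)
      if (length(i) == 0) NA_integer_
      else as.integer(offs[i[1]] + (p - ex_start[i[1]] + 1))
    }, integer(1))
  } else {
    rw <- rev(widths)  # transcription order = decreasing genomic start
    offs <- rev(cumsum(c(0L, rw[-length(rw)])))
    vapply(pos, function(p) {
      i <- which(p >= ex_start & p <= ex_end)
      if (length(i) == 0) NA_integer_
      else as.integer(offs[i[1]] + (ex_end[i[1]] - p + 1))
    }, integer(1))
  }
}

# inverse of genomic_to_tx
tx_to_genomic <- function(tx_pos, ex_start, ex_end, strand) {
  widths <- ex_end - ex_start + 1
  if (strand == "+") {
    offs <- cumsum(c(0L, widths[-length(widths)]))
    vapply(tx_pos, function(t) {
      i <- max(which(t > offs))
      as.integer(ex_start[i] + (t - offs[i]) - 1)
    }, integer(1))
  } else {
    rw <- rev(widths)
    offs <- rev(cumsum(c(0L, rw[-length(rw)])))
    vapply(tx_pos, function(t) {
      i <- which(t > offs & t <= offs + widths)
      i <- i[length(i)]
      as.integer(ex_end[i] - (t - offs[i]) + 1)
    }, integer(1))
  }
}

#' @export
print.tailshift_annotation <- function(x, ...) {
  cat("<tailshift_annotation>", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features (via `rtracklayer`) into a
#' [as_annotation()] container and derives strand-aware stop-codon
#' positions, final exons and 3' UTRs. A CDS outside its transcript's exons
#' or an mRNA without a parent gene raises a validation error naming the
#' offender.
#'
#' @param path Path to a GFF3 file.
#' @return A `tailshift_annotation`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  parent1 <- function(p) vapply(p, function(x)
    if (length(x)) as.character(x)[1] else NA_character_, character(1))
  df$parent <- if ("Parent" %in% names(df)) parent1(df$Parent) else NA_character_

  genes <- df %>% filter(type == "gene") %>%
    transmute(gene_id = .data$ID, chrom = as.character(.data$seqnames),
              strand = strand, start = start, end = end)
  mrna <- df %>% filter(type == "mRNA") %>%
    transmute(transcript_id = .data$ID, gene_id = .data$parent,
              chrom = as.character(.data$seqnames), strand = strand,
              as_class = if ("as_class" %in% names(df)) .data$as_class
                         else "none")
  if (anyNA(mrna$gene_id)) {
    bad <- mrna$transcript_id[is.na(mrna$gene_id)]
    rlang::abort(sprintf("mRNA without Parent gene: %s",
                         paste(head(bad, 3), collapse = ", ")),
                 class = "tailshift_validation_error")
  }
  exons <- df %>% filter(type == "exon") %>%
    transmute(transcript_id = .data$parent, start = start, end = end)
  cds <- df %>% filter(type == "CDS") %>%
    group_by(transcript_id = .data$parent) %>%
    summarise(cds_start = min(start), cds_end = max(end), .groups = "drop")
  mrna <- mrna %>% left_join(cds, by = "transcript_id")
  mrna$as_class[is.na(mrna$as_class)] <- "none"
  as_annotation(genes, mrna, exons)
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA, exon and CDS rows (CDS split per exon with computed
#' phase) in 1-based inclusive coordinates via `rtracklayer`.
#'
#' @param annotation A `tailshift_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  tx <- annotation$transcripts
  rows <- list()
  g <- annotation$genes
  rows$gene <- tibble(seqnames = g$chrom, start = g$start, end = g$end,
                      strand = g$strand, type = "gene", ID = g$gene_id,
                      Parent = NA_character_, as_class = NA_character_,
                      phase = NA_integer_)
  rows$mrna <- tibble(seqnames = tx$chrom, start = tx$tx_start,
                      end = tx$tx_end, strand = tx$strand, type = "mRNA",
                      ID = tx$transcript_id, Parent = tx$gene_id,
                      as_class = tx$as_class, phase = NA_integer_)
  ex <- annotation$exons %>%
    left_join(tx %>% select(transcript_id, chrom, strand, cds_start, cds_end),
              by = "transcript_id")
  rows$exon <- tibble(seqnames = ex$chrom, start = ex$start, end = ex$end,
                      strand = ex$strand, type = "exon", ID = NA_character_,
                      Parent = ex$transcript_id, as_class = NA_character_,
                      phase = NA_integer_)
  cds_seg <- ex %>%
    filter(!is.na(cds_start), end >= cds_start, start <= cds_end) %>%
    mutate(seg_start = pmax(start, cds_start),
           seg_end = pmin(end, cds_end)) %>%
    group_by(transcript_id) %>%
    arrange(if (first(strand) == "+") seg_start else -seg_start,
            .by_group = TRUE) %>%
    mutate(phase = {
      w <- .data$seg_end - .data$seg_start + 1
      as.integer((3 - cumsum(dplyr::lag(w, default = 0L)) %% 3) %% 3)
    }) %>%
    ungroup()
  rows$cds <- tibble(seqnames = cds_seg$chrom, start = cds_seg$seg_start,
                     end = cds_seg$seg_end, strand = cds_seg$strand,
                     type = "CDS", ID = NA_character_,
                     Parent = cds_seg$transcript_id,
                     as_class = NA_character_, phase = cds_seg$phase)
  all_rows <- bind_rows(rows) %>% arrange(seqnames, start, type)
  gr <- GenomicRanges::GRanges(
    seqnames = all_rows$seqnames,
    ranges = IRanges::IRanges(all_rows$start, all_rows$end),
    strand = all_rows$strand)
  S4Vectors::mcols(gr)$type <- all_rows$type
  S4Vectors::mcols(gr)$phase <- all_rows$phase
  S4Vectors::mcols(gr)$ID <- all_rows$ID
  S4Vectors::mcols(gr)$Parent <- methods::as(
    lapply(all_rows$Parent, function(p) if (is.na(p)) character(0) else p),
    "CharacterList")
  S4Vectors::mcols(gr)$as_class <- all_rows$as_class
  rtracklayer::export(gr, path, format = "gff3")
  # date/tool-version header lines would break byte-identical reruns
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}

reads_schema_cols <- function() {
  readr::cols(
    read_id = readr::col_character(), sample_id = readr::col_character(),
    stage = readr::col_character(), gene_id = readr::col_character(),
    transcript_id = readr::col_character(), strand = readr::col_character(),
    three_prime_pos = readr::col_integer(),
    polya_len = readr::col_double(), full_length = readr::col_integer(),
    as_class = readr::col_character())
}

#' Read a per-read feature table
#'
#' Loads a `reads.tsv` (columns read_id, sample_id, stage, gene_id,
#' transcript_id, strand, three_prime_pos, polya_len, full_length,
#' as_class; `#`-prefixed header lines are ignored). Rows referencing
#' transcripts absent from the annotation are dropped and counted in a
#' message; empty `polya_len` fields stay missing (`NA`), never 0. Reads
#' whose 3' end falls outside the gene span by more than `span_slack` nt
#' are flagged in an `outside_span` column, not dropped. Malformed numeric
#' fields raise an error reporting the offending rows.
#'
#' @param path TSV path.
#' @param annotation Optional `tailshift_annotation` used to validate
#'   transcript ids and gene spans.
#' @param span_slack Slack in nt for the gene-span check (default 1000).
#' @return Tibble of read records.
#' @export
read_reads <- function(path, annotation = NULL, span_slack = 1000) {
  tb <- readr::read_tsv(path, comment = "#", col_types = reads_schema_cols(),
                        progress = FALSE)
  pr <- readr::problems(tb)
  if (nrow(pr) > 0) {
    rlang::abort(sprintf(
      "malformed fields in %s (first at line %d, column %s)",
      path, pr$row[1] + 1L, pr$col[1]), class = "tailshift_parse_error")
  }
  tb$full_length <- as.logical(tb$full_length)
  if (!is.null(annotation)) {
    known <- annotation$transcripts$transcript_id
    dropped <- sum(!tb$transcript_id %in% known)
    if (dropped > 0) {
      rlang::inform(sprintf("read_reads: dropped %d rows with unknown transcript ids",
                            dropped))
      tb <- tb %>% filter(transcript_id %in% known)
    }
    spans <- annotation$genes %>% select(gene_id, start, end)
    tb <- tb %>%
      left_join(spans, by = "gene_id") %>%
      mutate(outside_span = three_prime_pos < start - span_slack |
               three_prime_pos > end + span_slack) %>%
      select(-start, -end)
    n_out <- sum(tb$outside_span, na.rm = TRUE)
    if (n_out > 0) {
      rlang::inform(sprintf("read_reads: flagged %d reads with 3' ends > %d nt outside their gene span",
                            n_out, as.integer(span_slack)))
    }
  }
  tb
}

#' Read a per-read modification-call table
#'
#' Loads a `modcalls.tsv` (columns read_id, gene_id, site_chrom, site_pos,
#' site_strand, modified; `#` header lines ignored).
#'
#' @param path TSV path.
#' @return Tibble of modification calls with logical `modified`.
#' @export
read_modcalls <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    read_id = readr::col_character(), gene_id = readr::col_character(),
    site_chrom = readr::col_character(), site_pos = readr::col_integer(),
    site_strand = readr::col_character(), modified = readr::col_integer()),
    progress = FALSE)
  pr <- readr::problems(tb)
  if (nrow(pr) > 0) {
    rlang::abort(sprintf("malformed fields in %s (first at line %d)",
                         path, pr$row[1] + 1L),
                 class = "tailshift_parse_error")
  }
  tb$modified <- as.logical(tb$modified)
  tb
}
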