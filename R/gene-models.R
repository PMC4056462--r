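# gene model parsing (GTF / BED12) and transcript coordinate arithmetic
#
# A gene-model table has one row per transcript:
#   gene_id, tx_id, biotype, chrom, strand, exon_start, exon_end (parallel
#   integer list-columns, 0-based half-open, sorted, disjoint),
#   cds_start/cds_end (genomic 0-based half-open span, NA when noncoding),
#   tx_len (sum of exon lengths).
# All positions everywhere in occudiff are 0-based; intervals half-open.

#' Read gene models from GTF or BED12
#'
#' Parses transcript structures into a tibble with one row per transcript
#' and exon coordinates as list-columns (0-based half-open). For GTF,
#' `exon` features define the transcript footprint and `CDS` features its
#' coding span; for BED12, blocks define exons and the thick range the
#' coding span. BED12 files carry no gene/biotype annotation, so the name
#' field serves as both transcript and gene id and the biotype is inferred
#' from the presence of a thick range.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return tibble of gene models; see file header for columns.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("gene model file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  models <- switch(format,
    gtf = gene_models_from_gtf(path),
    bed12 = gene_models_from_bed12(path)
  )
  assert_that(nrow(models) > 0, "no transcripts parsed from gene model file")
  validate_gene_models(models)
  models
}

gene_models_from_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    stop("malformed GTF line ", body[which(nf < 9)[1]], ": expected 9 fields",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  assert_that(!is.null(md$transcript_id), "GTF lacks transcript_id attributes")
  biotype <- md$gene_biotype %||% md$transcript_biotype %||%
    rep(NA_character_, length(gr))
  feat <- tibble(
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    tx_id = as.character(md$transcript_id),
    biotype = as.character(biotype),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr)
  )
  multi_chrom <- feat |>
    group_by(.data$tx_id) |>
    summarise(nc = dplyr::n_distinct(.data$chrom), .groups = "drop") |>
    filter(.data$nc > 1)
  if (nrow(multi_chrom) > 0) {
    stop("transcript ", multi_chrom$tx_id[1],
         " has features on multiple chromosomes", call. = FALSE)
  }
  feat |>
    group_by(.data$gene_id, .data$tx_id) |>
    summarise(
      biotype = .data$biotype[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      exon_start = list(sort(.data$start0[.data$type == "exon"])),
      exon_end = list(sort(.data$end0[.data$type == "exon"])),
      cds_start = if (any(.data$type == "CDS"))
        min(.data$start0[.data$type == "CDS"]) else NA_integer_,
      cds_end = if (any(.data$type == "CDS"))
        max(.data$end0[.data$type == "CDS"]) else NA_integer_,
      .groups = "drop"
    ) |>
    mutate(tx_len = purrr::map2_int(.data$exon_start, .data$exon_end,
                                    ~ sum(.y - .x)))
}

gene_models_from_bed12 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 12)) {
    stop("malformed BED12 line ", body[which(nf < 12)[1]],
         ": expected 12 fields", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  blocks <- md$blocks
  assert_that(!is.null(blocks), "BED file lacks block (exon) structure")
  purrr::map_dfr(seq_along(gr), function(i) {
    chrom_start <- GenomicRanges::start(gr[i]) - 1L
    b <- blocks[[i]]  # block ranges relative to chromStart, 1-based
    es <- chrom_start + IRanges::start(b) - 1L
    ee <- chrom_start + IRanges::end(b)
    thick <- md$thick[i]
    ts <- IRanges::start(thick) - 1L
    te <- IRanges::end(thick)
    has_cds <- te > ts
    tibble(
      gene_id = md$name[i], tx_id = md$name[i],
      biotype = if (has_cds) "protein_coding" else "noncoding",
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(GenomicRanges::strand(gr[i])),
      exon_start = list(as.integer(es)), exon_end = list(as.integer(ee)),
      cds_start = if (has_cds) as.integer(ts) else NA_integer_,
      cds_end = if (has_cds) as.integer(te) else NA_integer_,
      tx_len = as.integer(sum(ee - es))
    )
  })
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    es <- models$exon_start[[i]]
    ee <- models$exon_end[[i]]
    assert_that(length(es) == length(ee) && all(ee > es),
                paste0("invalid exons for ", models$tx_id[i]))
    assert_that(!is.unsorted(es, strictly = TRUE) &&
                  all(utils::head(ee, -1) <= utils::tail(es, -1)),
                paste0("exons not sorted/disjoint for ", models$tx_id[i]))
    if (!is.na(models$cds_start[i])) {
      assert_that(models$cds_start[i] >= es[1] &&
                    models$cds_end[i] <= ee[length(ee)],
                  paste0("CDS outside exon footprint for ", models$tx_id[i]))
    }
  }
  invisible(models)
}

#' Pick one representative transcript per gene
#'
#' Longest CDS wins; ties broken by longest transcript, then by
#' lexicographically smallest transcript id.
#'
#' @param models gene-model tibble from [read_gene_models()].
#' @return tibble with one row per gene.
#' @export
representative_transcripts <- function(models) {
  models |>
    mutate(.cds_len = ifelse(is.na(.data$cds_start), 0L,
                             .data$cds_end - .data$cds_start)) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$.cds_len), desc(.data$tx_len), .data$tx_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".cds_len") |>
    arrange(.data$gene_id)
}

# transcript coordinate maps ------------------------------------------------

# cumulative exon offsets for one model row (a one-row tibble or list)
exon_offsets <- function(es, ee) {
  w <- ee - es
  cumsum(c(0L, utils::head(w, -1)))
}

#' Map genomic positions to transcript coordinates
#'
#' @param model one gene-model row (one-row tibble).
#' @param gpos integer vector of genomic 0-based positions.
#' @return integer vector of transcript 0-based positions (index 0 = 5'
#'   end); `NA` for positions outside the exon footprint.
#' @export
genomic_to_tx <- function(model, gpos) {
  es <- model$exon_start[[1]]
  ee <- model$exon_end[[1]]
  off <- exon_offsets(es, ee)
  idx <- findInterval(gpos, es)
  tpos <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1 & idx <= length(es)
  ok[ok] <- gpos[ok] < ee[idx[ok]]
  tpos[ok] <- off[idx[ok]] + (gpos[ok] - es[idx[ok]])
  if (model$strand[1] == "-") tpos <- model$tx_len[1] - 1L - tpos
  as.integer(tpos)
}

#' Map transcript coordinates to genomic positions
#'
#' Inverse of [genomic_to_tx()] on exonic positions.
#'
#' @param model one gene-model row.
#' @param tpos integer vector of transcript 0-based positions.
#' @return integer vector of genomic 0-based positions.
#' @export
tx_to_genomic <- function(model, tpos) {
  assert_that(all(tpos >= 0 & tpos < model$tx_len[1]),
              "transcript position out of range")
  es <- model$exon_start[[1]]
  ee <- model$exon_end[[1]]
  off <- exon_offsets(es, ee)
  plus_pos <- if (model$strand[1] == "-") model$tx_len[1] - 1L - tpos else tpos
  idx <- findInterval(plus_pos, off)
  as.integer(es[idx] + (plus_pos - off[idx]))
}

# CDS span in transcript coordinates: c(start, end) half-open, or NULL
cds_tx_span <- function(model) {
  if (is.na(model$cds_start[1])) return(NULL)
  g <- c(model$cds_start[1], model$cds_end[1] - 1L)
  t <- genomic_to_tx(model, g)
  c(min(t), max(t) + 1L)
}

#' Annotate transcript positions by region
#'
#' Classifies positions of a coding transcript as `5UTR`, `CDS` or `3UTR`
#' by the CDS span in transcript coordinates (half-open); transcripts
#' without a CDS are `noncoding` throughout.
#'
#' @param tpos integer vector of transcript 0-based positions.
#' @param model one gene-model row.
#' @return character vector of regions.
#' @export
annotate_region <- function(tpos, model) {
  assert_that(all(tpos >= 0 & tpos < model$tx_len[1]),
              "transcript position out of range")
  span <- cds_tx_span(model)
  if (is.null(span)) return(rep("noncoding", length(tpos)))
  dplyr::case_when(
    tpos < span[1] ~ "5UTR",
    tpos < span[2] ~ "CDS",
    TRUE ~ "3UTR"
  )
}

# genomic exon-footprint positions of a model (0-based), 5'->3' order
footprint_positions <- function(model) {
  es <- model$exon_start[[1]]
  ee <- model$exon_end[[1]]
  g <- unlist(purrr::map2(es, ee, ~ seq.int(.x, .y - 1L)))
  if (model$strand[1] == "-") g <- rev(g)
  as.integer(g)
}

# spliced sense-strand transcript sequence (DNA alphabet)
transcript_seq <- function(model, genome) {
  es <- model$exon_start[[1]]
  ee <- model$exon_end[[1]]
  s <- paste0(purrr::map2_chr(es, ee,
                              ~ genome_seq(genome, model$chrom[1], .x, .y)),
              collapse = "")
  if (model$strand[1] == "-") s <- revcomp(s)
  s
}
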