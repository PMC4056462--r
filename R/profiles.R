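# occupancy profiles: coverage + T-C transition events from alignments
#
# A profile is a sparse tibble (chrom, pos, coverage, transitions) with pos
# 0-based; absent positions are zero. Transition events follow the
# sense-strand rule for a stranded 4SU protocol: reference T read C on
# forward alignments, reference A read G on reverse alignments.

#' Read alignment records from BAM (or SAM)
#'
#' Returns a normalized per-read view of a coordinate-sorted alignment
#' file: position, strand, CIGAR, forward-genomic read sequence, mapping
#' quality and duplicate flag. SAM input is converted (and sorted) on the
#' fly with Rsamtools; BAM input must declare `SO:coordinate` in its
#' header.
#'
#' @param path BAM or SAM file.
#' @param min_mapq minimum mapping quality (default 0: keep all).
#' @param collapse_duplicates keep a single record per
#'   (chrom, start, strand, sequence) when `TRUE`.
#' @return tibble with one row per mapped read.
#' @export
read_alignments <- function(path, min_mapq = 0, collapse_duplicates = FALSE) {
  assert_that(file.exists(path), paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
    so <- unlist(hdr[names(hdr) == "@HD"])
    if (!any(grepl("^SO:coordinate$", so))) {
      stop("alignments must be coordinate-sorted (header lacks SO:coordinate)",
           call. = FALSE)
    }
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  rec <- tibble(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    pos0 = res$pos - 1L,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq)
  ) |>
    filter(bitwAnd(.data$flag, 4L) == 0L, !is.na(.data$pos0)) |>
    mutate(is_dup = bitwAnd(.data$flag, 1024L) != 0L)
  rec <- filter(rec, is.na(.data$mapq) | .data$mapq >= min_mapq)
  if (collapse_duplicates && nrow(rec) > 0) {
    rec <- dplyr::distinct(rec, .data$chrom, .data$pos0, .data$strand,
                           .data$seq, .keep_all = TRUE)
  }
  rec
}

# aligned M-blocks of each record on reference and query space.
# Returns a tibble: read index, chrom, strand, ref_start0/ref_end0 (0-based
# half-open), q_start/q_end (1-based closed within SEQ).
alignment_blocks <- function(rec) {
  if (nrow(rec) == 0) {
    return(tibble(read = integer(), chrom = character(), strand = character(),
                  ref_start0 = integer(), ref_end0 = integer(),
                  q_start = integer(), q_end = integer()))
  }
  ops <- c("M", "=", "X")
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos0 + 1L, ops = ops)
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(rec$cigar, ops = ops)
  nb <- S4Vectors::elementNROWS(rref)
  idx <- rep.int(seq_len(nrow(rec)), nb)
  fr <- unlist(rref, use.names = FALSE)
  fq <- unlist(rqry, use.names = FALSE)
  tibble(
    read = idx,
    chrom = rec$chrom[idx],
    strand = rec$strand[idx],
    ref_start0 = IRanges::start(fr) - 1L,
    ref_end0 = IRanges::end(fr),
    q_start = IRanges::start(fq),
    q_end = IRanges::end(fq)
  )
}

# per-read mismatches against the genome: tibble(read, chrom, strand,
# gpos0, ref_base, read_base). One row per read-position.
call_mismatches <- function(rec, blocks, genome) {
  if (nrow(blocks) == 0) {
    return(tibble(read = integer(), chrom = character(), strand = character(),
                  gpos0 = integer(), ref_base = character(),
                  read_base = character()))
  }
  refseq <- character(nrow(blocks))
  for (ch in unique(blocks$chrom)) {
    i <- which(blocks$chrom == ch)
    refseq[i] <- as.character(Biostrings::extractAt(
      genome[[ch]], iranges0(blocks$ref_start0[i], blocks$ref_end0[i])))
  }
  readseq <- substr(rec$seq[blocks$read], blocks$q_start, blocks$q_end)
  a <- charToRaw(paste(refseq, collapse = ""))
  b <- charToRaw(paste(readseq, collapse = ""))
  mm <- which(a != b)
  if (length(mm) == 0) {
    return(tibble(read = integer(), chrom = character(), strand = character(),
                  gpos0 = integer(), ref_base = character(),
                  read_base = character()))
  }
  w <- blocks$ref_end0 - blocks$ref_start0
  cum <- cumsum(c(0L, utils::head(w, -1)))
  bi <- findInterval(mm - 1L, cum)
  within <- (mm - 1L) - cum[bi]
  tibble(
    read = blocks$read[bi],
    chrom = blocks$chrom[bi],
    strand = blocks$strand[bi],
    gpos0 = blocks$ref_start0[bi] + within,
    ref_base = strsplit(rawToChar(a[mm]), NULL)[[1]],
    read_base = strsplit(rawToChar(b[mm]), NULL)[[1]]
  )
}

#' Build an occupancy profile from alignments
#'
#' Coverage counts every reference base covered by an aligned block;
#' transition events count crosslink-diagnostic mismatches (sense-strand
#' T-to-C): reference `T` read `C` on forward alignments, reference `A`
#' read `G` on reverse alignments. A read contributes at most one event
#' per position; a read with several diagnostic mismatches contributes one
#' event at each.
#'
#' @param alignments BAM/SAM path or a record tibble from
#'   [read_alignments()].
#' @param genome genome as returned by [read_genome()].
#' @param min_mapq,collapse_duplicates passed to [read_alignments()] when
#'   `alignments` is a path.
#' @return sparse profile tibble (chrom, pos, coverage, transitions).
#' @export
extract_profiles <- function(alignments, genome, min_mapq = 0,
                             collapse_duplicates = FALSE) {
  rec <- if (is.character(alignments)) {
    read_alignments(alignments, min_mapq, collapse_duplicates)
  } else alignments
  blocks <- alignment_blocks(rec)
  cov <- coverage_from_blocks(blocks)
  mm <- call_mismatches(rec, blocks, genome)
  tc <- mm |>
    filter((.data$strand == "+" & .data$ref_base == "T" &
              .data$read_base == "C") |
             (.data$strand == "-" & .data$ref_base == "A" &
                .data$read_base == "G")) |>
    dplyr::count(.data$chrom, pos = .data$gpos0, name = "transitions")
  prof <- dplyr::full_join(cov, tc, by = c("chrom", "pos")) |>
    mutate(coverage = dplyr::coalesce(.data$coverage, 0),
           transitions = dplyr::coalesce(as.numeric(.data$transitions), 0)) |>
    arrange(.data$chrom, .data$pos)
  attr(prof, "kind") <- "replicate"
  prof
}

# sparse per-position coverage from block table
coverage_from_blocks <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(chrom = character(), pos = integer(), coverage = numeric()))
  }
  purrr::map_dfr(split(blocks, blocks$chrom), function(b) {
    cv <- IRanges::coverage(iranges0(b$ref_start0, b$ref_end0))
    rl <- S4Vectors::runLength(cv)
    rv <- S4Vectors::runValue(cv)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    keep <- rv > 0
    pos <- unlist(purrr::map2(starts[keep], ends[keep], seq.int))
    tibble(chrom = b$chrom[1], pos = as.integer(pos) - 1L,
           coverage = as.numeric(rep.int(rv[keep], rl[keep])))
  })
}

#' Tabulate the read mismatch spectrum
#'
#' Counts mapped reads, reads with zero and exactly one mismatch, and the
#' twelve substitution types among single-mismatch reads, in
#' sense-of-alignment orientation (mismatches on reverse alignments are
#' complemented). A high T-C fraction among single-mismatch reads is the
#' hallmark of efficient 4SU crosslinking.
#'
#' @inheritParams extract_profiles
#' @return object of class `occudiff_spectrum`; `tidy()` gives the 12-row
#'   substitution table, `glance()` the one-row read summary.
#' @export
mismatch_spectrum <- function(alignments, genome, min_mapq = 0) {
  rec <- if (is.character(alignments)) {
    read_alignments(alignments, min_mapq)
  } else alignments
  blocks <- alignment_blocks(rec)
  mm <- call_mismatches(rec, blocks, genome)
  n_mm <- tabulate(mm$read, nbins = max(nrow(rec), 1L))
  reads_mapped <- nrow(rec)
  reads_0mm <- sum(n_mm == 0) * (reads_mapped > 0)
  one <- which(n_mm == 1)
  mm1 <- filter(mm, .data$read %in% one)
  sense_ref <- ifelse(mm1$strand == "-", complement_base(mm1$ref_base),
                      mm1$ref_base)
  sense_read <- ifelse(mm1$strand == "-", complement_base(mm1$read_base),
                       mm1$read_base)
  bases <- c("A", "C", "G", "T")
  types <- expand.grid(from = bases, to = bases, stringsAsFactors = FALSE) |>
    filter(.data$from != .data$to) |>
    arrange(.data$from, .data$to) |>
    mutate(substitution = paste0(.data$from, ">", .data$to))
  obs <- table(factor(paste0(sense_ref, ">", sense_read),
                      levels = types$substitution))
  spectrum <- tibble(
    substitution = types$substitution,
    count = as.integer(obs),
    fraction = if (sum(obs) > 0) as.numeric(obs) / sum(obs) else 0
  )
  out <- list(
    summary = tibble(
      reads_mapped = reads_mapped,
      reads_0mm = as.integer(reads_0mm),
      reads_1mm = length(one),
      tc_fraction = spectrum$fraction[spectrum$substitution == "T>C"],
      defined = length(one) > 0
    ),
    spectrum = spectrum
  )
  class(out) <- "occudiff_spectrum"
  out
}

#' @export
print.occudiff_spectrum <- function(x, ...) {
  cat("Mismatch spectrum:", x$summary$reads_mapped, "mapped reads,",
      x$summary$reads_0mm, "with 0 mismatches,",
      x$summary$reads_1mm, "with 1 mismatch\n")
  cat(sprintf("T>C fraction of single-mismatch reads: %.3f\n",
              x$summary$tc_fraction))
  invisible(x)
}

#' Average replicate profiles into a consensus profile
#'
#' Per position, the arithmetic mean of transition counts and of coverage
#' across replicates; positions absent from a replicate count as zero.
#'
#' @param profiles list of profile tibbles.
#' @return consensus profile tibble (real-valued).
#' @export
consensus_profile <- function(profiles) {
  assert_that(length(profiles) >= 1, "need at least one profile")
  n <- length(profiles)
  prof <- bind_rows(profiles) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(coverage = sum(.data$coverage) / n,
              transitions = sum(.data$transitions) / n, .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
  attr(prof, "kind") <- "consensus"
  prof
}

#' Project a profile onto transcript coordinates
#'
#' @param profile profile tibble.
#' @param model one gene-model row.
#' @return tibble with one row per transcript position
#'   (tx_pos, gpos, coverage, transitions, region); index 0 is the 5' end,
#'   introns excluded.
#' @export
project_to_transcript <- function(profile, model) {
  gpos <- footprint_positions(model)
  tx <- tibble(tx_pos = seq_along(gpos) - 1L, gpos = gpos)
  if (!model$chrom[1] %in% profile$chrom) {
    warning("chromosome ", model$chrom[1], " absent from profile; zero signal")
    p <- tibble(gpos = integer(), coverage = numeric(),
                transitions = numeric())
  } else {
    p <- profile |>
      filter(.data$chrom == model$chrom[1]) |>
      select(gpos = "pos", "coverage", "transitions")
  }
  tx |>
    left_join(p, by = "gpos") |>
    mutate(coverage = dplyr::coalesce(.data$coverage, 0),
           transitions = dplyr::coalesce(.data$transitions, 0),
           region = annotate_region(.data$tx_pos, model))
}

#' Distribution of reads over RNA types
#'
#' Assigns each read to exactly one biotype by a fixed priority
#' (protein_coding > lincRNA > other annotated > unannotated); a read
#' counts for a biotype if any aligned block overlaps an exon of a
#' transcript of that biotype by at least one base.
#'
#' @inheritParams extract_profiles
#' @param models gene-model tibble with biotype annotations.
#' @return tibble (rna_type, reads, fraction).
#' @export
rna_type_distribution <- function(alignments, models, genome = NULL,
                                  min_mapq = 0) {
  rec <- if (is.character(alignments)) {
    read_alignments(alignments, min_mapq)
  } else alignments
  blocks <- alignment_blocks(rec)
  exons <- exon_table(models)
  pri <- function(bt) dplyr::case_when(
    bt == "protein_coding" ~ 1L,
    bt == "lincRNA" ~ 2L,
    TRUE ~ 3L
  )
  hit <- interval_overlap_join(blocks, exons)
  best <- hit |>
    mutate(priority = pri(.data$biotype)) |>
    group_by(.data$read) |>
    summarise(priority = min(.data$priority), .groups = "drop")
  n_total <- nrow(rec)
  counts <- c(
    protein_coding = sum(best$priority == 1L),
    lincRNA = sum(best$priority == 2L),
    other = sum(best$priority == 3L),
    unannotated = n_total - nrow(best)
  )
  tibble(rna_type = names(counts), reads = as.integer(counts),
         fraction = if (n_total > 0) as.numeric(counts) / n_total else 0)
}

# flat exon table: chrom, start0, end0, gene_id, tx_id, biotype
exon_table <- function(models) {
  tidyr::unnest(
    models |>
      mutate(exon = purrr::map2(.data$exon_start, .data$exon_end,
                                ~ tibble(start0 = .x, end0 = .y))) |>
      select("gene_id", "tx_id", "biotype", "chrom", "strand", "exon"),
    "exon"
  )
}

# overlap join of read blocks against an interval table; returns block rows
# paired with interval annotation columns
interval_overlap_join <- function(blocks, intervals) {
  if (nrow(blocks) == 0 || nrow(intervals) == 0) {
    return(bind_cols(blocks[0, ], intervals[0, setdiff(names(intervals),
                                                       names(blocks))]))
  }
  q <- GenomicRanges::GRanges(blocks$chrom,
                              iranges0(blocks$ref_start0, blocks$ref_end0))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              iranges0(intervals$start0, intervals$end0))
  ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                    ignore.strand = TRUE)
  bind_cols(
    blocks[S4Vectors::queryHits(ov), ],
    intervals[S4Vectors::subjectHits(ov),
              setdiff(names(intervals), names(blocks))]
  )
}

#' @rdname mismatch_spectrum
#' @param x an `occudiff_spectrum` object.
#' @param ... unused.
#' @export
tidy.occudiff_spectrum <- function(x, ...) {
  x$spectrum
}

#' @rdname mismatch_spectrum
#' @export
glance.occudiff_spectrum <- function(x, ...) {
  x$summary
}
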