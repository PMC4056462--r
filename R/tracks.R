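# UCSC-style track export of occupancy profiles

#' Write profile tracks (bedGraph coverage + BED6 transitions)
#'
#' Coverage goes to `<prefix>.coverage.bedGraph` as maximal runs of equal
#' coverage (0-based half-open); transition positions to
#' `<prefix>.transitions.bed` with the event count in the score column.
#' [read_tracks()] on the pair reproduces the profile exactly.
#'
#' @param profile profile tibble.
#' @param out_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_tracks <- function(profile, out_prefix) {
  cov_path <- paste0(out_prefix, ".coverage.bedGraph")
  bed_path <- paste0(out_prefix, ".transitions.bed")
  cov_lines <- 'track type=bedGraph name="occudiff coverage"'
  bed_lines <- 'track name="occudiff transitions"'
  cov <- profile |> filter(.data$coverage > 0) |> arrange(.data$chrom, .data$pos)
  if (nrow(cov) > 0) {
    runs <- cov |>
      group_by(.data$chrom) |>
      mutate(new_run = c(TRUE, diff(.data$pos) != 1L |
                           diff(.data$coverage) != 0)) |>
      mutate(run = cumsum(.data$new_run)) |>
      group_by(.data$chrom, .data$run) |>
      summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                value = .data$coverage[1], .groups = "drop") |>
      arrange(.data$chrom, .data$start)
    cov_lines <- c(cov_lines, sprintf("%s\t%d\t%d\t%s", runs$chrom,
                                      runs$start, runs$end,
                                      format(runs$value, trim = TRUE)))
  }
  tc <- profile |> filter(.data$transitions > 0) |> arrange(.data$chrom, .data$pos)
  if (nrow(tc) > 0) {
    bed_lines <- c(bed_lines, sprintf("%s\t%d\t%d\ttc\t%s\t+", tc$chrom,
                                      tc$pos, tc$pos + 1L,
                                      format(tc$transitions, trim = TRUE)))
  }
  writeLines(cov_lines, cov_path)
  writeLines(bed_lines, bed_path)
  invisible(c(coverage = cov_path, transitions = bed_path))
}

#' Read profile tracks back into a profile tibble
#'
#' @param out_prefix prefix used in [write_tracks()].
#' @return profile tibble.
#' @export
read_tracks <- function(out_prefix) {
  cov_path <- paste0(out_prefix, ".coverage.bedGraph")
  bed_path <- paste0(out_prefix, ".transitions.bed")
  cov_gr <- rtracklayer::import(cov_path, format = "bedGraph")
  bed_gr <- rtracklayer::import(bed_path, format = "bed")
  cov <- if (length(cov_gr) == 0) {
    tibble(chrom = character(), pos = integer(), coverage = numeric())
  } else {
    tibble(
      chrom = rep(as.character(GenomicRanges::seqnames(cov_gr)),
                  GenomicRanges::width(cov_gr)),
      pos = unlist(purrr::map2(GenomicRanges::start(cov_gr) - 1L,
                               GenomicRanges::end(cov_gr) - 1L, seq.int)),
      coverage = rep(as.numeric(S4Vectors::mcols(cov_gr)$score),
                     GenomicRanges::width(cov_gr))
    )
  }
  tc <- if (length(bed_gr) == 0) {
    tibble(chrom = character(), pos = integer(), transitions = numeric())
  } else {
    tibble(
      chrom = as.character(GenomicRanges::seqnames(bed_gr)),
      pos = GenomicRanges::start(bed_gr) - 1L,
      transitions = as.numeric(S4Vectors::mcols(bed_gr)$score)
    )
  }
  dplyr::full_join(cov, tc, by = c("chrom", "pos")) |>
    mutate(coverage = dplyr::coalesce(.data$coverage, 0),
           transitions = dplyr::coalesce(.data$transitions, 0)) |>
    arrange(.data$chrom, .data$pos)
}
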