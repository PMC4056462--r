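# overlap of position sets with external binding-site interval collections

#' Read a BED interval set
#'
#' @param path BED file (>= 3 columns; strand used when present).
#' @param name dataset name (default: file name).
#' @return tibble (chrom, start0, end0, strand) with attribute `name`.
#' @export
read_interval_set <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |> arrange(.data$chrom, .data$start0)
  attr(out, "name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  out
}

#' Count positions overlapping an interval set
#'
#' Point-in-interval with half-open semantics; a position inside several
#' intervals counts once. With `strand_aware = TRUE` (the default when
#' the intervals carry strands) only same-strand intervals match.
#'
#' @param positions position set with `chrom`, `gpos` (and `strand`).
#' @param intervals interval tibble from [read_interval_set()].
#' @param strand_aware match strands; `NULL` (default) enables it when
#'   both sides carry strand information.
#' @return list: `n_overlap`, `overlaps` (logical per position).
#' @export
overlap_count <- function(positions, intervals, strand_aware = NULL) {
  if (is.null(strand_aware)) {
    strand_aware <- "strand" %in% names(positions) &&
      "strand" %in% names(intervals) &&
      any(intervals$strand %in% c("+", "-"))
  }
  hit <- rep(FALSE, nrow(positions))
  if (nrow(positions) > 0 && nrow(intervals) > 0) {
    q <- GenomicRanges::GRanges(
      positions$chrom, iranges0(positions$gpos, positions$gpos + 1L),
      strand = if (strand_aware) positions$strand else "*")
    s <- GenomicRanges::GRanges(
      intervals$chrom, iranges0(intervals$start0, intervals$end0),
      strand = if (strand_aware) intervals$strand else "*")
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                  ignore.strand = !strand_aware))
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  list(n_overlap = sum(hit), overlaps = hit)
}

#' Fisher-exact overlap enrichment of top versus random positions
#'
#' For every interval collection, a 2x2 table (overlapping / not, top /
#' random) is scored with the two-sided Fisher exact test
#' (minimum-likelihood rule) and BH-adjusted across all collections
#' tested in the run. Degenerate margins give p = 1.
#'
#' @param top,random position sets.
#' @param interval_sets named list of interval tibbles.
#' @param strand_aware see [overlap_count()].
#' @return tibble (set, n_top, frac_top, n_random, frac_random, p_value,
#'   bh_fdr).
#' @export
overlap_test <- function(top, random, interval_sets, strand_aware = NULL) {
  assert_that(nrow(top) > 0 && nrow(random) > 0,
              "both position sets must be non-empty")
  if (is.null(names(interval_sets))) {
    names(interval_sets) <- paste0("set", seq_along(interval_sets))
  }
  res <- purrr::imap_dfr(interval_sets, function(iv, nm) {
    ot <- overlap_count(top, iv, strand_aware)$n_overlap
    or <- overlap_count(random, iv, strand_aware)$n_overlap
    tab <- matrix(c(ot, nrow(top) - ot, or, nrow(random) - or), nrow = 2)
    p <- if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) 1
         else fisher.test(tab)$p.value
    tibble(set = nm, n_top = ot, frac_top = ot / nrow(top),
           n_random = or, frac_random = or / nrow(random), p_value = p)
  })
  res$bh_fdr <- p.adjust(res$p_value, method = "BH")
  res
}
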