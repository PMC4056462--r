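# RNA-seq feature counting and differential expression screening.
#
# Differential occupancy positions that sit inside differentially
# expressed exons can reflect exon usage rather than protein contact; this
# module counts mRNA-seq reads per gene/transcript/exon, screens features
# for differential expression with the same NB kernels (global
# normalization this time), and flags occupancy positions inside
# significant features.

#' Count reads per annotation feature
#'
#' A read is assigned to a feature when any aligned block overlaps it by
#' at least one base; a read increments a feature at most once, and a
#' junction read spanning two exons of one transcript increments both
#' exons and the transcript/gene once each.
#'
#' @inheritParams extract_profiles
#' @param models gene-model tibble.
#' @param level `"gene"`, `"transcript"` or `"exon"`.
#' @return tibble (feature, level, gene, tx, chrom, start0, end0, count).
#' @export
count_reads_per_feature <- function(alignments, models,
                                    level = c("gene", "transcript", "exon")) {
  level <- match.arg(level)
  rec <- if (is.character(alignments)) read_alignments(alignments) else alignments
  blocks <- alignment_blocks(rec)
  exons <- exon_table(models) |>
    group_by(.data$tx_id) |>
    mutate(exon_ord = dplyr::row_number()) |>
    ungroup() |>
    mutate(exon_id = paste0(.data$tx_id, ":exon", .data$exon_ord))
  features <- switch(level,
    exon = exons |>
      mutate(feature = .data$exon_id),
    transcript = exons |>
      mutate(feature = .data$tx_id),
    gene = exons |>
      mutate(feature = .data$gene_id)
  )
  hits <- interval_overlap_join(blocks, features) |>
    dplyr::distinct(.data$read, .data$feature)
  counts <- dplyr::count(hits, .data$feature, name = "count")
  features |>
    group_by(.data$feature) |>
    summarise(level = level, gene = .data$gene_id[1], tx = .data$tx_id[1],
              chrom = .data$chrom[1], start0 = min(.data$start0),
              end0 = max(.data$end0), .groups = "drop") |>
    left_join(counts, by = "feature") |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$chrom, .data$start0)
}

#' Differential expression screen with NB exact tests
#'
#' Reuses the occupancy kernels with global normalization: library sizes
#' are total counts per sample, one set of TMM factors is computed across
#' all features, and common plus feature-wise dispersions are estimated
#' over the whole table. P-values come from the conditional NB exact test
#' and are BH-adjusted.
#'
#' @param counts tibble with columns `feature`, `sample`, `condition`,
#'   `count` (use [count_reads_per_feature()] per sample and bind rows).
#' @param prior_weight tagwise shrinkage weight.
#' @return tibble (feature, mean_a, mean_b, log2_fc, p_value, bh_fdr,
#'   excluded) — all-zero features are excluded from testing and flagged.
#' @export
differential_expression <- function(counts, prior_weight = 10) {
  needed <- c("feature", "sample", "condition", "count")
  assert_that(all(needed %in% names(counts)),
              paste("counts needs columns:", paste(needed, collapse = ", ")))
  design <- dplyr::distinct(counts, .data$sample, .data$condition) |>
    arrange(.data$condition, .data$sample)
  lv <- unique(design$condition)
  assert_that(length(lv) == 2, "exactly two conditions required")
  assert_that(all(table(design$condition) >= 2),
              "at least two replicates per condition required")
  wide <- counts |>
    select("feature", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0) |>
    arrange(.data$feature)
  m <- as.matrix(wide[, design$sample, drop = FALSE])
  nonzero <- rowSums(m) > 0
  cond <- design$condition
  out <- tibble(feature = wide$feature, excluded = !nonzero,
                mean_a = NA_real_, mean_b = NA_real_, log2_fc = NA_real_,
                p_value = NA_real_, bh_fdr = NA_real_)
  if (!any(nonzero)) return(out)
  mz <- m[nonzero, , drop = FALSE]
  lib <- colSums(m)
  factors <- suppressWarnings(tmm_factors(mz, lib))
  eq <- equalize_libraries(mz, lib * factors)
  pseudo <- eq$counts
  phi <- estimate_tagwise_dispersion(pseudo, cond, prior_weight)
  a_cols <- cond == lv[1]
  b_cols <- cond == lv[2]
  s_a <- rowSums(pseudo[, a_cols, drop = FALSE])
  s_b <- rowSums(pseudo[, b_cols, drop = FALSE])
  pvals <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_test(pseudo[i, a_cols], pseudo[i, b_cols], phi[i])
  }, numeric(1))
  out$mean_a[nonzero] <- s_a / sum(a_cols)
  out$mean_b[nonzero] <- s_b / sum(b_cols)
  out$log2_fc[nonzero] <- log2((s_b / sum(b_cols) + 0.5) /
                                 (s_a / sum(a_cols) + 0.5))
  out$p_value[nonzero] <- pvals
  out$bh_fdr[nonzero] <- p.adjust(pvals, method = "BH")
  out
}

#' Flag occupancy positions inside differentially expressed features
#'
#' A position is flagged as removed when its genomic base lies inside any
#' selected feature with BH FDR below `fdr_max` and absolute fold change
#' above `min_fc`. The flag is annotative: rows are marked, not dropped.
#' Positions covered by no tested feature are kept and marked
#' `unassessed`.
#'
#' @param positions tibble with `chrom` and `gpos` columns (e.g.
#'   `tidy()` of a [run_differential()] fit).
#' @param de differential-expression table from
#'   [differential_expression()], joined with feature coordinates
#'   (`chrom`, `start0`, `end0`).
#' @param fdr_max,min_fc removal thresholds (defaults 0.01 and 2; the fold
#'   change is compared on the natural scale, direction ignored).
#' @return `positions` with `expr_filter` (`removed`/`kept`/`unassessed`)
#'   and `expr_removed` (logical) columns.
#' @export
filter_positions_by_expression <- function(positions, de, fdr_max = 0.01,
                                           min_fc = 2) {
  assert_that(all(c("chrom", "gpos") %in% names(positions)),
              "positions need chrom and gpos columns")
  assert_that(all(c("chrom", "start0", "end0", "bh_fdr", "log2_fc")
                  %in% names(de)),
              "de table needs chrom/start0/end0/bh_fdr/log2_fc columns")
  de_tested <- filter(de, !is.na(.data$bh_fdr))
  if (nrow(positions) == 0) {
    positions$expr_filter <- character(0)
    positions$expr_removed <- logical(0)
    return(positions)
  }
  q <- GenomicRanges::GRanges(positions$chrom,
                              iranges0(positions$gpos, positions$gpos + 1L))
  s <- GenomicRanges::GRanges(de_tested$chrom,
                              iranges0(de_tested$start0, de_tested$end0))
  ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                    ignore.strand = TRUE)
  assessed <- rep(FALSE, nrow(positions))
  removed <- rep(FALSE, nrow(positions))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  assessed[unique(qh)] <- TRUE
  sig <- de_tested$bh_fdr[sh] < fdr_max &
    2^abs(de_tested$log2_fc[sh]) > min_fc
  removed[unique(qh[sig])] <- TRUE
  positions$expr_filter <- dplyr::case_when(
    removed ~ "removed",
    assessed ~ "kept",
    TRUE ~ "unassessed"
  )
  positions$expr_removed <- removed
  positions
}
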