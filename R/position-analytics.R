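# analytics on differential position sets: top/random site selection,
# clustering statistics, region and metagene distributions, cross-profile
# correlation and regression

#' Select the top differential positions
#'
#' Greedy selection of the most significant positions, enforcing a
#' minimum genomic spacing so that two selected sites cannot originate
#' from one protein footprint: candidates are visited in order of p-value
#' (ties: larger |log2FC| first, then coordinate) and skipped when within
#' `min_spacing` nucleotides (strictly: the distance must exceed it) of an
#' already selected position of the same gene. Positions flagged by the
#' expression filter are excluded.
#'
#' @param positions tidy position table (needs `gene`, `gpos`, `p_value`,
#'   `log2_fc`; optional `direction`, `expr_removed`, `chrom`, `strand`).
#' @param n set size (default 300).
#' @param min_spacing minimum spacing in nucleotides (default 20).
#' @param direction optionally restrict to `"increased"` or `"decreased"`.
#' @return tibble of selected positions with a `rank` column; attributes
#'   `provenance = "top"` and `min_spacing`.
#' @export
select_top_positions <- function(positions, n = 300, min_spacing = 20,
                                 direction = NULL) {
  d <- positions
  if (!is.null(direction)) d <- filter(d, .data$direction == !!direction)
  if ("expr_removed" %in% names(d)) d <- filter(d, !.data$expr_removed)
  d <- arrange(d, .data$p_value, -abs(.data$log2_fc), .data$gpos)
  sel <- logical(nrow(d))
  chosen <- list()
  for (i in seq_len(nrow(d))) {
    g <- d$gene[i]
    prev <- chosen[[g]]
    if (!is.null(prev) && any(abs(prev - d$gpos[i]) <= min_spacing)) next
    sel[i] <- TRUE
    chosen[[g]] <- c(prev, d$gpos[i])
    if (sum(sel) >= n) break
  }
  out <- d[sel, , drop = FALSE]
  if (nrow(out) < n) {
    warning("only ", nrow(out), " eligible positions (requested ", n, ")")
  }
  out$rank <- seq_len(nrow(out))
  attr(out, "provenance") <- "top"
  attr(out, "min_spacing") <- min_spacing
  out
}

#' Generate matched random positions by shifting top positions
#'
#' Each top position is shifted upstream or downstream by one of the
#' offsets (tried in seeded random order); the first shift that stays
#' inside the same gene's exon footprint is kept and then snapped to the
#' closest genomic thymine (plus-strand gene) or adenine (minus-strand
#' gene) within the footprint, so every random position sits on a
#' sense-strand uridine like the real crosslink sites. Snapping ties break
#' downstream in transcript orientation. Positions with no valid shift are
#' dropped and reported.
#'
#' @param top position set from [select_top_positions()].
#' @param models gene-model tibble.
#' @param genome genome from [read_genome()].
#' @param shifts offset magnitudes to try (default 100, 50, 30 nt).
#' @param seed integer seed; the output is bit-identical per seed.
#' @return tibble of random positions (attributes `provenance = "random"`,
#'   `n_dropped`).
#' @export
generate_random_positions <- function(top, models, genome,
                                      shifts = c(100, 50, 30), seed = 1L) {
  reps <- representative_transcripts(models)
  offsets <- c(shifts, -shifts)
  out <- purrr::map_dfr(seq_len(nrow(top)), function(i) {
    mod <- reps[reps$gene_id == top$gene[i], ]
    if (nrow(mod) == 0) return(tibble())
    fp <- sort(footprint_positions(mod))
    target <- if (mod$strand[1] == "+") "T" else "A"
    bases <- genome_base(genome, mod$chrom[1], fp)
    t_pos <- fp[bases == target]
    if (length(t_pos) == 0) return(tibble())
    order_i <- with_seed(child_seed(seed, i), sample(length(offsets)))
    for (off in offsets[order_i]) {
      cand <- top$gpos[i] + off
      if (!cand %in% fp) next
      dist <- abs(t_pos - cand)
      best <- t_pos[dist == min(dist)]
      snapped <- if (mod$strand[1] == "+") max(best) else min(best)
      return(tibble(gene = top$gene[i], chrom = mod$chrom[1],
                    gpos = snapped, strand = mod$strand[1],
                    source_gpos = top$gpos[i], shift = off))
    }
    tibble()
  })
  attr(out, "provenance") <- "random"
  attr(out, "n_dropped") <- nrow(top) - nrow(out)
  out
}

#' Distance to the closest significant position
#'
#' For every tested position, the transcript-coordinate distance to the
#' nearest *other* significant position of the same gene; query positions
#' in genes with no (other) significant position are excluded and
#' counted. Significant and non-significant query sets are kept apart so
#' their ECDFs can be compared (clustering of differential sites shows as
#' a left-shifted significant ECDF).
#'
#' @param positions tidy position table with `gene`, `position`,
#'   `significant`.
#' @return tibble (gene, position, query_set, distance); attribute
#'   `n_excluded` counts queries with no eligible neighbor.
#' @export
nearest_significant_distance <- function(positions) {
  excl <- 0L
  out <- purrr::map_dfr(split(positions, positions$gene), function(d) {
    sig_pos <- d$position[d$significant]
    purrr::map_dfr(seq_len(nrow(d)), function(i) {
      ref <- if (d$significant[i]) setdiff(sig_pos, d$position[i]) else sig_pos
      if (length(ref) == 0) {
        excl <<- excl + 1L
        return(tibble())
      }
      tibble(gene = d$gene[i], position = d$position[i],
             query_set = if (d$significant[i]) "significant"
                         else "nonsignificant",
             distance = min(abs(ref - d$position[i])))
    })
  })
  attr(out, "n_excluded") <- excl
  out
}

#' Direction consistency of neighboring significant positions
#'
#' Compares each significant position's direction of change with that of
#' its nearest significant neighbor in the same gene.
#'
#' @param positions tidy table with `gene`, `position`, `significant`,
#'   `direction`.
#' @return list: `fraction_same`, and `pairs` tibble (gene, position,
#'   distance, same_direction).
#' @export
direction_consistency <- function(positions) {
  sig <- filter(positions, .data$significant)
  pairs <- purrr::map_dfr(split(sig, sig$gene), function(d) {
    if (nrow(d) < 2) return(tibble())
    purrr::map_dfr(seq_len(nrow(d)), function(i) {
      others <- d[-i, ]
      j <- which.min(abs(others$position - d$position[i]))
      tibble(gene = d$gene[i], position = d$position[i],
             distance = abs(others$position[j] - d$position[i]),
             same_direction = others$direction[j] == d$direction[i])
    })
  })
  list(
    fraction_same = if (nrow(pairs) > 0) mean(pairs$same_direction)
                    else NA_real_,
    pairs = pairs
  )
}

#' Region distribution of a position set
#'
#' Fractions over 5'UTR / CDS / 3'UTR among positions in coding
#' transcripts; positions in noncoding transcripts are excluded from the
#' three-way fractions and reported in their own row (fraction `NA`).
#'
#' @param positions tibble with a `region` column.
#' @return tibble (region, n, fraction).
#' @export
region_distribution <- function(positions) {
  assert_that(nrow(positions) > 0, "empty position set")
  coding <- c("5UTR", "CDS", "3UTR")
  n_cod <- sum(positions$region %in% coding)
  n <- vapply(c(coding, "noncoding"),
              function(r) sum(positions$region == r), integer(1))
  frac <- if (n_cod > 0) n / n_cod else rep(NA_real_, 4)
  frac[4] <- NA_real_  # noncoding reported separately, outside the 3-way
  tibble(region = c(coding, "noncoding"), n = unname(n),
         fraction = unname(frac))
}

#' Metagene density over scaled transcript regions
#'
#' Each coding transcript's 5'UTR, CDS and 3'UTR are linearly rescaled to
#' fixed bin counts, per-position signal is accumulated, per-transcript
#' mass is normalized to 1 (each transcript weighs equally) and densities
#' are averaged; the output sums to 1. Transcripts lacking any of the
#' three regions are skipped and counted.
#'
#' @param positions tibble with `gene`, `position` (transcript
#'   coordinates) and optional `weight`.
#' @param models gene-model tibble.
#' @param bins bins per region, `c(utr5, cds, utr3)` (default 10, 50, 40).
#' @return tibble (bin, region, density); attribute `n_skipped`.
#' @export
metagene_density <- function(positions, models, bins = c(10, 50, 40)) {
  reps <- representative_transcripts(models)
  total_bins <- sum(bins)
  acc <- numeric(total_bins)
  n_tx <- 0L
  n_skipped <- 0L
  for (g in unique(positions$gene)) {
    mod <- reps[reps$gene_id == g, ]
    if (nrow(mod) == 0) next
    span <- cds_tx_span(mod)
    len <- mod$tx_len[1]
    if (is.null(span) || span[1] < 1 || span[2] >= len) {
      n_skipped <- n_skipped + 1L
      next
    }
    d <- positions[positions$gene == g, ]
    w <- if ("weight" %in% names(d)) d$weight else rep(1, nrow(d))
    l5 <- span[1]
    lc <- span[2] - span[1]
    l3 <- len - span[2]
    tp <- d$position
    bin <- ifelse(tp < l5,
                  floor(tp / l5 * bins[1]),
                  ifelse(tp < span[2],
                         bins[1] + floor((tp - l5) / lc * bins[2]),
                         bins[1] + bins[2] +
                           floor((tp - span[2]) / l3 * bins[3])))
    bin <- pmin(pmax(bin, 0), total_bins - 1)
    mass <- tapply(w, factor(bin, levels = 0:(total_bins - 1)), sum)
    mass[is.na(mass)] <- 0
    if (sum(mass) == 0) next
    acc <- acc + as.numeric(mass) / sum(mass)
    n_tx <- n_tx + 1L
  }
  dens <- if (n_tx > 0) acc / n_tx else acc
  out <- tibble(
    bin = seq_len(total_bins),
    region = rep(c("5UTR", "CDS", "3UTR"), times = bins),
    density = dens
  )
  attr(out, "n_transcripts") <- n_tx
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Sliding-window profile correlation between two experiments
#'
#' Per representative transcript, coverage is summed in non-overlapping
#' windows and the Spearman rank correlation (average-rank ties) across
#' windows compares the two profiles; the median over eligible genes
#' summarizes profile similarity. Genes with too few windows or zero
#' variance in either profile are excluded.
#'
#' @param profile_a,profile_b profile tibbles.
#' @param models gene-model tibble.
#' @param window window width in nt (default 50, non-overlapping).
#' @param min_windows minimum windows per gene (default 10).
#' @return list: `per_gene` tibble (gene, rho, n_windows), `median_rho`.
#' @export
sliding_window_correlation <- function(profile_a, profile_b, models,
                                       window = 50, min_windows = 10) {
  reps <- representative_transcripts(models)
  per_gene <- purrr::map_dfr(seq_len(nrow(reps)), function(j) {
    mod <- reps[j, ]
    nw <- mod$tx_len[1] %/% window
    if (nw < min_windows) return(tibble())
    pa <- suppressWarnings(project_to_transcript(profile_a, mod))
    pb <- suppressWarnings(project_to_transcript(profile_b, mod))
    idx <- rep(seq_len(nw), each = window)
    used <- seq_len(nw * window)
    wa <- tapply(pa$coverage[used], idx, sum)
    wb <- tapply(pb$coverage[used], idx, sum)
    if (sd(wa) == 0 || sd(wb) == 0) return(tibble())
    tibble(gene = mod$gene_id[1],
           rho = cor(wa, wb, method = "spearman"),
           n_windows = nw)
  })
  assert_that(nrow(per_gene) > 0, "no eligible genes for correlation")
  list(per_gene = per_gene, median_rho = median(per_gene$rho))
}

#' Per-transcript variance in occupancy explained by expression
#'
#' Ordinary least squares of occupancy coverage on mRNA-seq coverage at
#' each transcript position; reports R-squared per transcript and the
#' mean over transcripts. Low explained variance indicates that occupancy
#' profiles carry information beyond expression.
#'
#' @param occupancy,expression profile tibbles.
#' @param models gene-model tibble.
#' @return list: `per_gene` tibble (gene, r_squared), `mean_r2`.
#' @export
explained_variance <- function(occupancy, expression, models) {
  reps <- representative_transcripts(models)
  per_gene <- purrr::map_dfr(seq_len(nrow(reps)), function(j) {
    mod <- reps[j, ]
    occ <- suppressWarnings(project_to_transcript(occupancy, mod))$coverage
    expr <- suppressWarnings(project_to_transcript(expression, mod))$coverage
    if (var(expr) == 0) return(tibble())
    fit <- lm(occ ~ expr)
    tibble(gene = mod$gene_id[1], r_squared = summary(fit)$r.squared)
  })
  list(per_gene = per_gene,
       mean_r2 = if (nrow(per_gene) > 0) mean(per_gene$r_squared) else NA_real_)
}

#' Correlation of gene-wise fold changes between two assays
#'
#' Per gene, log2 abundances `log2((count + 1) / library size)` give one
#' fold change per assay; the Pearson correlation across genes (with the
#' best-fit line) quantifies how much of the occupancy change is
#' explained by the expression change.
#'
#' @param counts tibble with columns `gene`, `occ_a`, `occ_b`, `expr_a`,
#'   `expr_b` (raw counts).
#' @return one-row tibble (r, slope, intercept, n_genes).
#' @export
genewise_fc_correlation <- function(counts) {
  needed <- c("gene", "occ_a", "occ_b", "expr_a", "expr_b")
  assert_that(all(needed %in% names(counts)),
              paste("counts needs columns:", paste(needed, collapse = ", ")))
  assert_that(nrow(counts) >= 3, "need at least 3 genes")
  la <- function(x) log2((x + 1) / sum(x))
  fc_occ <- la(counts$occ_b) - la(counts$occ_a)
  fc_expr <- la(counts$expr_b) - la(counts$expr_a)
  fit <- lm(fc_occ ~ fc_expr)
  tibble(r = cor(fc_occ, fc_expr),
         slope = coef(fit)[2], intercept = coef(fit)[1],
         n_genes = nrow(counts))
}
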