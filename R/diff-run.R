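# differential occupancy pipeline: normalization -> filters -> dispersion ->
# exact test -> replicate-swap empirical FDR

#' Configuration for the differential occupancy test
#'
#' Defaults are the workflow's standard filter constants: positions need
#' at least two T-C events in at least two of the samples, genes need at
#' least 50 such positions, genes with more than two-thirds of positional
#' fold changes in one direction are excluded, and positions are reported
#' at empirical FDR < 0.1.
#'
#' @param min_count,min_samples position validity filter.
#' @param min_positions minimum valid positions per gene.
#' @param direction_threshold direction-mixture exclusion threshold.
#' @param fdr_target empirical FDR threshold for significance calls.
#' @param prior_weight tagwise dispersion shrinkage weight
#'   (pseudo-positions).
#' @param average_swaps with 2v2 designs there are two balanced label
#'   swaps; `FALSE` (default) uses the first, `TRUE` pools both null runs.
#' @param seed integer seed echoed into outputs (the test itself is
#'   deterministic).
#' @return a list of class `occudiff_config`.
#' @export
occudiff_config <- function(min_count = 2, min_samples = 2,
                            min_positions = 50,
                            direction_threshold = 2 / 3,
                            fdr_target = 0.1, prior_weight = 10,
                            average_swaps = FALSE, seed = 1L) {
  assert_that(min_count >= 0 && min_samples >= 1 && min_positions >= 1,
              "invalid filter constants")
  assert_that(direction_threshold > 0 && direction_threshold <= 1,
              "direction threshold must be in (0, 1]")
  assert_that(fdr_target > 0 && fdr_target < 1, "fdr target must be in (0,1)")
  structure(list(min_count = min_count, min_samples = min_samples,
                 min_positions = min_positions,
                 direction_threshold = direction_threshold,
                 fdr_target = fdr_target, prior_weight = prior_weight,
                 average_swaps = average_swaps, seed = as.integer(seed)),
            class = "occudiff_config")
}

#' Test positions for differential occupancy from a count table
#'
#' The statistical entry point: takes a long table of per-position T-C
#' transition counts and runs the full per-transcript testing scheme:
#' global quantile normalization across samples, position and gene
#' filters, then per gene TMM factors, direction-mixture filter, library
#' equalization, common and tagwise dispersion estimation and the
#' conditional NB exact test; finally a replicate-label-swap rerun
#' provides the null p-values for the empirical FDR.
#'
#' @param counts tibble with columns `gene`, `position`, `sample`,
#'   `condition`, `count`. The row universe (gene x position set) defines
#'   the distribution that quantile normalization equalizes.
#' @param config an [occudiff_config()].
#' @return object of class `occudiff_diff`; see [tidy.occudiff_diff()] and
#'   [glance.occudiff_diff()].
#' @export
diff_occupancy <- function(counts, config = occudiff_config()) {
  needed <- c("gene", "position", "sample", "condition", "count")
  assert_that(all(needed %in% names(counts)),
              paste("counts needs columns:", paste(needed, collapse = ", ")))
  design <- dplyr::distinct(counts, .data$sample, .data$condition) |>
    arrange(.data$condition, .data$sample)
  lv <- unique(design$condition)
  assert_that(length(lv) == 2, "exactly two conditions required")
  n_per <- table(design$condition)
  assert_that(all(n_per >= 2),
              "at least two replicates per condition are required (the swap null needs them)")

  wide <- counts |>
    select("gene", "position", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0) |>
    arrange(.data$gene, .data$position)
  sample_ids <- design$sample
  m <- as.matrix(wide[, sample_ids, drop = FALSE])
  norm <- round_half_up(quantile_normalize(m))

  real_cond <- design$condition
  null_cond <- swap_labels(design)

  valid <- valid_position_mask(norm, config$min_count, config$min_samples)
  valid_per_gene <- tapply(valid, wide$gene, sum)
  kept_genes <- filter_genes(valid_per_gene, config$min_positions)

  rows_by_gene <- split(which(valid), wide$gene[valid])

  run_one <- function(cond_labels) {
    res <- purrr::map(kept_genes, function(g) {
      rows <- rows_by_gene[[g]]
      test_one_gene(norm[rows, , drop = FALSE], cond_labels,
                    wide$position[rows], g, config)
    })
    list(
      positions = bind_rows(purrr::map(res, "positions")),
      genes = bind_rows(purrr::map(res, "gene_log"))
    )
  }

  real <- run_one(real_cond)
  null <- run_one(null_cond)
  if (config$average_swaps) {
    null2 <- run_one(swap_labels(design, alt = TRUE))
    null$positions <- bind_rows(null$positions, null2$positions)
  }

  positions <- real$positions
  if (nrow(positions) > 0) {
    ef <- empirical_fdr(positions$p_value, null$positions$p_value,
                        config$fdr_target)
    positions$emp_fdr <- ef$fdr
    positions$bh_fdr <- p.adjust(positions$p_value, method = "BH")
    positions$significant <- positions$emp_fdr < config$fdr_target
    threshold <- ef$threshold
  } else {
    threshold <- NA_real_
  }

  gene_log <- tibble(gene = names(valid_per_gene),
                     n_valid = as.integer(valid_per_gene),
                     passed_min_positions =
                       names(valid_per_gene) %in% kept_genes) |>
    left_join(real$genes, by = "gene")

  structure(list(
    positions = positions,
    null_positions = null$positions,
    genes = gene_log,
    design = design,
    config = config,
    p_threshold = threshold
  ), class = "occudiff_diff")
}

# balanced replicate-label swap for the null run: first replicate of each
# condition vs the rest (default), or the alternative pairing
swap_labels <- function(design, alt = FALSE) {
  lv <- unique(design$condition)
  a_idx <- which(design$condition == lv[1])
  b_idx <- which(design$condition == lv[2])
  swapped <- design$condition
  if (!alt) {
    swapped[c(a_idx[1], b_idx[1])] <- "null_1"
    swapped[c(a_idx[-1], b_idx[-1])] <- "null_2"
  } else {
    swapped[c(a_idx[1], b_idx[length(b_idx)])] <- "null_1"
    swapped[c(a_idx[-1], b_idx[-length(b_idx)])] <- "null_2"
  }
  swapped
}

# per-gene testing kernel on the valid-position count matrix
test_one_gene <- function(m, cond, positions, gene, config) {
  lv <- unique(cond)
  lib <- colSums(m)
  gene_log <- tibble(gene = gene, tmm_ok = TRUE, direction_kept = TRUE)
  if (any(lib == 0)) {
    gene_log$tmm_ok <- FALSE
    return(list(positions = empty_positions(), gene_log = gene_log))
  }
  factors <- suppressWarnings(tmm_factors(m, lib))
  eff <- lib * factors
  dir <- direction_mixture_filter(m, cond, eff, config$direction_threshold)
  gene_log$direction_kept <- dir$keep
  if (!dir$keep) {
    return(list(positions = empty_positions(), gene_log = gene_log))
  }
  eq <- equalize_libraries(m, eff)
  pseudo <- eq$counts
  phi_p <- estimate_tagwise_dispersion(pseudo, cond, config$prior_weight)
  a_cols <- cond == lv[1]
  b_cols <- cond == lv[2]
  n_a <- sum(a_cols)
  n_b <- sum(b_cols)
  s_a <- rowSums(pseudo[, a_cols, drop = FALSE])
  s_b <- rowSums(pseudo[, b_cols, drop = FALSE])
  pvals <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_test(pseudo[i, a_cols], pseudo[i, b_cols], phi_p[i])
  }, numeric(1))
  log2_fc <- log2((s_b / n_b + 0.5) / (s_a / n_a + 0.5))
  list(
    positions = tibble(
      gene = gene, position = positions,
      mean_a = s_a / n_a, mean_b = s_b / n_b,
      log2_fc = log2_fc,
      direction = ifelse(log2_fc > 0, "increased", "decreased"),
      dispersion = phi_p,
      p_value = pvals
    ),
    gene_log = gene_log
  )
}

empty_positions <- function() {
  tibble(gene = character(), position = integer(), mean_a = numeric(),
         mean_b = numeric(), log2_fc = numeric(), direction = character(),
         dispersion = numeric(), p_value = numeric())
}

#' Run the differential test from occupancy profiles
#'
#' Projects each replicate profile onto the representative transcript of
#' every gene, assembles the per-position transition count table and runs
#' [diff_occupancy()]. Output positions carry genomic coordinates, strand
#' and region annotation.
#'
#' @param profiles_a,profiles_b lists (>= 2 each) of profile tibbles from
#'   [extract_profiles()], one per replicate.
#' @param models gene-model tibble.
#' @param config an [occudiff_config()].
#' @return `occudiff_diff` object with annotated positions.
#' @export
run_differential <- function(profiles_a, profiles_b, models,
                             config = occudiff_config()) {
  assert_that(length(profiles_a) >= 2 && length(profiles_b) >= 2,
              "at least two replicates per condition are required (the swap null needs them)")
  reps <- representative_transcripts(models)
  samples <- c(paste0("A", seq_along(profiles_a)),
               paste0("B", seq_along(profiles_b)))
  conds <- c(rep("A", length(profiles_a)), rep("B", length(profiles_b)))
  profs <- c(profiles_a, profiles_b)
  counts <- purrr::imap_dfr(profs, function(p, i) {
    purrr::map_dfr(seq_len(nrow(reps)), function(j) {
      proj <- suppressWarnings(project_to_transcript(p, reps[j, ]))
      tibble(gene = reps$gene_id[j], position = proj$tx_pos,
             sample = samples[i], condition = conds[i],
             count = proj$transitions)
    })
  })
  fit <- diff_occupancy(counts, config)
  if (nrow(fit$positions) > 0) {
    ann <- purrr::map_dfr(split(fit$positions, fit$positions$gene),
                          function(d) {
      mod <- reps[reps$gene_id == d$gene[1], ]
      d$gpos <- tx_to_genomic(mod, d$position)
      d$chrom <- mod$chrom[1]
      d$strand <- mod$strand[1]
      d$region <- annotate_region(d$position, mod)
      d
    })
    fit$positions <- arrange(ann, .data$p_value)
  }
  fit$models <- reps
  fit
}

# broom-style accessors ------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the differential positions of a fit
#'
#' @param x an `occudiff_diff` object.
#' @param ... unused.
#' @return tibble of tested positions with fold changes, p-values and FDRs.
#' @export
tidy.occudiff_diff <- function(x, ...) {
  as_tibble(x$positions)
}

#' One-row summary of a differential occupancy fit
#'
#' @param x an `occudiff_diff` object.
#' @param ... unused.
#' @return one-row tibble: genes tested, positions tested, significant
#'   positions, p-value threshold at the FDR target.
#' @export
glance.occudiff_diff <- function(x, ...) {
  tibble(
    n_genes_tested = dplyr::n_distinct(x$positions$gene),
    n_positions_tested = nrow(x$positions),
    n_significant = sum(x$positions$significant %||% logical(0)),
    fdr_target = x$config$fdr_target,
    p_threshold = x$p_threshold
  )
}

#' @export
print.occudiff_diff <- function(x, ...) {
  g <- glance(x)
  cat("Differential occupancy fit:", g$n_positions_tested,
      "positions in", g$n_genes_tested, "genes;",
      g$n_significant, "significant at empirical FDR <",
      g$fdr_target, "\n")
  invisible(x)
}

#' Diagnostic plot of a differential occupancy fit
#'
#' Real versus replicate-swap null p-value distributions; a null shifted
#' toward large p-values relative to the real run indicates a low
#' empirical FDR.
#'
#' @param object an `occudiff_diff` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.occudiff_diff <- function(object, ...) {
  d <- bind_rows(
    tibble(p = object$positions$p_value, set = "real"),
    tibble(p = object$null_positions$p_value, set = "replicate-swap null")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$p, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "exact-test p-value", y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
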