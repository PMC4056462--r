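# PWM scanning and sequence enrichment around crosslink sites.
#
# Regions are the +/- w nt windows around positions, read in transcript
# space (spliced, sense strand) and written in the RNA alphabet. PWM
# scores follow the RNAcompete scanning convention: per k-window product
# of column probabilities, summed over all windows of the region.

#' Load position weight matrices
#'
#' Reads tab-delimited PWM files (rows = A/C/G/U, columns = motif
#' positions), adds a pseudo-count of 0.01 to every entry and renormalizes
#' each column to sum to 1. An optional RBP mapping table attaches protein
#' names.
#'
#' @param paths one or more PWM file paths (file name minus extension
#'   becomes the PWM id), or a directory containing them.
#' @param rbp_map optional tibble with columns `pwm_id`, `rbp`.
#' @param pseudocount added to each column entry before normalization.
#' @return list of PWM objects: `id`, `rbp`, `mat` (4 x k probability
#'   matrix with rownames A,C,G,U).
#' @export
load_pwms <- function(paths, rbp_map = NULL, pseudocount = 0.01) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(txt|tsv|pwm)$",
                        full.names = TRUE)
  }
  purrr::map(paths, function(p) {
    raw <- as.matrix(utils::read.table(p, header = FALSE, sep = "\t",
                                       row.names = 1))
    assert_that(nrow(raw) == 4, paste0("PWM must have 4 rows (A/C/G/U): ", p))
    assert_that(all(raw >= 0), paste0("negative PWM entries: ", p))
    rn <- toupper(rownames(raw))
    rn[rn == "T"] <- "U"
    raw <- raw[match(c("A", "C", "G", "U"), rn), , drop = FALSE]
    mat <- raw + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
    rownames(mat) <- c("A", "C", "G", "U")
    colnames(mat) <- NULL
    id <- sub("\\.[^.]*$", "", basename(p))
    rbp <- if (!is.null(rbp_map) && id %in% rbp_map$pwm_id) {
      rbp_map$rbp[match(id, rbp_map$pwm_id)]
    } else NA_character_
    list(id = id, rbp = rbp, mat = mat)
  })
}

# normalize an in-memory count/probability matrix the same way
normalize_pwm <- function(mat, pseudocount = 0.01) {
  mat <- mat + pseudocount
  sweep(mat, 2, colSums(mat), "/")
}

#' Extract RNA regions around positions
#'
#' The +/- `w` nt window around each position, read across exon junctions
#' in transcript space on the sense strand and converted to the RNA
#' alphabet (T -> U). Windows truncated at transcript ends are flagged.
#'
#' @param positions position set with `gene` and `gpos` columns.
#' @param models gene-model tibble.
#' @param genome genome from [read_genome()].
#' @param w half-window (default 25 nt).
#' @return tibble (gene, gpos, tx_pos, seq, truncated).
#' @export
extract_regions <- function(positions, models, genome, w = 25) {
  reps <- representative_transcripts(models)
  purrr::map_dfr(seq_len(nrow(positions)), function(i) {
    mod <- reps[reps$gene_id == positions$gene[i], ]
    if (nrow(mod) == 0) return(tibble())
    tp <- genomic_to_tx(mod, positions$gpos[i])
    if (is.na(tp)) return(tibble())
    txs <- transcript_seq(mod, genome)
    len <- mod$tx_len[1]
    lo <- max(0L, tp - w)
    hi <- min(len, tp + w + 1L)
    s <- substr(txs, lo + 1L, hi)
    tibble(gene = positions$gene[i], gpos = positions$gpos[i], tx_pos = tp,
           seq = chartr("T", "U", s),
           truncated = (hi - lo) < (2L * w + 1L))
  })
}

#' Score a region with a PWM
#'
#' Sum over all length-k subsequences of the product of column
#' probabilities; `N` bases contribute a neutral 0.25 per column. Regions
#' shorter than the motif score 0.
#'
#' @param seq region sequence (RNA alphabet character scalar).
#' @param pwm a PWM object from [load_pwms()] (or a bare 4 x k matrix
#'   with rownames A,C,G,U).
#' @return numeric score.
#' @export
pwm_region_score <- function(seq, pwm) {
  mat <- if (is.list(pwm)) pwm$mat else pwm
  k <- ncol(mat)
  chars <- strsplit(seq, NULL)[[1]]
  L <- length(chars)
  if (L < k) return(0)
  row <- match(chars, c("A", "C", "G", "U"))  # NA for N
  probs <- matrix(0.25, nrow = L - k + 1, ncol = k)
  for (j in seq_len(k)) {
    b <- row[j:(j + L - k)]
    pj <- mat[, j][b]
    pj[is.na(b)] <- 0.25
    probs[, j] <- pj
  }
  sum(apply(probs, 1, prod))
}

# score many same-alphabet regions against one PWM (vectorized across
# regions); equivalent to vapply(seqs, pwm_region_score, ..) but builds the
# base-index matrix once per call
pwm_score_batch <- function(seqs, pwm) {
  mat <- if (is.list(pwm)) pwm$mat else pwm
  k <- ncol(mat)
  lens <- nchar(seqs)
  out <- numeric(length(seqs))
  for (L in unique(lens)) {
    i <- which(lens == L)
    if (L < k) next
    chars <- matrix(unlist(strsplit(seqs[i], NULL)), nrow = length(i),
                    byrow = TRUE)
    row <- matrix(match(chars, c("A", "C", "G", "U")), nrow = length(i))
    total <- numeric(length(i))
    for (s in 0:(L - k)) {
      prod_w <- rep(1, length(i))
      for (j in seq_len(k)) {
        b <- row[, s + j]
        pj <- mat[, j][b]
        pj[is.na(b)] <- 0.25
        prod_w <- prod_w * pj
      }
      total <- total + prod_w
    }
    out[i] <- total
  }
  out
}

#' PWM enrichment in top versus random regions
#'
#' Scores every region with every PWM and compares top against random
#' scores with a one-sided Wilcoxon rank-sum test (top > random;
#' average-rank ties, exact enumeration when both sets have at most 25
#' regions, normal approximation with continuity correction otherwise).
#'
#' @param top_regions,random_regions region tibbles from
#'   [extract_regions()].
#' @param pwms list from [load_pwms()].
#' @param alpha significance threshold (default 0.01).
#' @return tibble (pwm_id, rbp, p_value, log2_ratio, significant), sorted
#'   by p-value.
#' @export
pwm_enrichment <- function(top_regions, random_regions, pwms, alpha = 0.01) {
  assert_that(nrow(top_regions) > 0 && nrow(random_regions) > 0,
              "both region sets must be non-empty")
  purrr::map_dfr(pwms, function(pwm) {
    st <- pwm_score_batch(top_regions$seq, pwm)
    sr <- pwm_score_batch(random_regions$seq, pwm)
    if (all(c(st, sr) == c(st, sr)[1])) {
      p <- 1  # degenerate: identical scores everywhere
    } else {
      exact <- length(st) <= 25 && length(sr) <= 25
      p <- suppressWarnings(
        wilcox.test(st, sr, alternative = "greater", exact = exact,
                    correct = TRUE)$p.value)
    }
    tibble(pwm_id = pwm$id, rbp = pwm$rbp, p_value = p,
           log2_ratio = log2(mean(st) / mean(sr)),
           significant = p < alpha)
  }) |>
    arrange(.data$p_value)
}

# overlapping occurrence count of a k-mer in one sequence
count_kmer <- function(seq, kmer) {
  if (nchar(seq) < nchar(kmer)) return(0L)
  length(Biostrings::matchPattern(Biostrings::RNAString(kmer),
                                  Biostrings::RNAString(seq)))
}

#' k-mer enrichment in top versus random regions
#'
#' For every k-mer occurring in either set, a 2x2 Fisher exact test on
#' region-level presence (regions containing the k-mer vs not, top vs
#' random), BH-adjusted across all tested k-mers. Overlapping occurrence
#' counts are reported alongside.
#'
#' @inheritParams pwm_enrichment
#' @param k k-mer length (default 7).
#' @return tibble (kmer, n_top, n_random, present_top, present_random,
#'   p_value, bh_fdr) sorted by p-value.
#' @export
kmer_enrichment <- function(top_regions, random_regions, k = 7) {
  kmers_of <- function(seqs) {
    unlist(purrr::map(seqs, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      substring(s, 1:(L - k + 1), k:L)
    }))
  }
  top_k <- kmers_of(top_regions$seq)
  rnd_k <- kmers_of(random_regions$seq)
  universe <- sort(unique(c(top_k, rnd_k)))
  universe <- universe[!grepl("N", universe)]
  n_top <- nrow(top_regions)
  n_rnd <- nrow(random_regions)
  res <- purrr::map_dfr(universe, function(km) {
    pt <- sum(stringr::str_detect(top_regions$seq, stringr::fixed(km)))
    pr <- sum(stringr::str_detect(random_regions$seq, stringr::fixed(km)))
    tab <- matrix(c(pt, n_top - pt, pr, n_rnd - pr), nrow = 2)
    tibble(kmer = km,
           n_top = sum(top_k == km), n_random = sum(rnd_k == km),
           present_top = pt, present_random = pr,
           p_value = fisher.test(tab)$p.value)
  })
  res$bh_fdr <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value)
}

#' AU-rich element frequency test
#'
#' One-sided binomial test of whether top regions contain the ARE core
#' (default `AUUUA`) more often than random regions: the null success
#' probability is the fraction of random regions containing the core and
#' the p-value is the upper binomial tail at the observed top count. When
#' no random region contains the core but top regions do, the p-value is
#' bounded by 1/(n_random + 1) and flagged.
#'
#' @inheritParams pwm_enrichment
#' @param core ARE core sequence (default `"AUUUA"`).
#' @return one-row tibble (n_top, n_top_with_core, p0, p_value, bounded).
#' @export
are_frequency_test <- function(top_regions, random_regions, core = "AUUUA") {
  assert_that(nrow(top_regions) > 0 && nrow(random_regions) > 0,
              "both region sets must be non-empty")
  has <- function(seqs) stringr::str_detect(seqs, stringr::fixed(core))
  obs <- sum(has(top_regions$seq))
  p0 <- mean(has(random_regions$seq))
  n <- nrow(top_regions)
  bounded <- FALSE
  if (p0 == 0 && obs > 0) {
    p <- 1 / (nrow(random_regions) + 1)
    bounded <- TRUE
  } else if (obs == 0) {
    p <- 1
  } else {
    p <- pbinom(obs - 1, n, p0, lower.tail = FALSE)
  }
  tibble(n_top = n, n_top_with_core = obs, p0 = p0, p_value = p,
         bounded = bounded)
}
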