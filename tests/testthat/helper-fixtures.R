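# shared in-code fixtures; everything deterministic

`%||%` <- function(x, y) if (is.null(x)) y else x

# small toy annotation reused across files (built once per test run)
toy_ann <- make_toy_annotation(n_genes = 8, n_chroms = 2, seed = 7)

# a hand-built genome + single-gene models for coordinate tests
hand_genome <- function(seq_chr1 = NULL) {
  s <- seq_chr1 %||% paste(rep("ACGT", 100), collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

one_model <- function(strand = "+", exon_start = list(100L),
                      exon_end = list(110L), cds_start = NA_integer_,
                      cds_end = NA_integer_, biotype = "protein_coding") {
  tibble::tibble(
    gene_id = "gX", tx_id = "gX.t1", biotype = biotype, chrom = "chr1",
    strand = strand, exon_start = exon_start, exon_end = exon_end,
    cds_start = cds_start, cds_end = cds_end,
    tx_len = sum(unlist(exon_end) - unlist(exon_start))
  )
}

# write a SAM file from a record tibble (chrom, pos1, flag, cigar, seq)
write_sam <- function(records, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  records <- records[order(records$chrom, records$pos1), ]
  body <- sprintf("r%03d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                  seq_len(nrow(records)), records$flag, records$chrom,
                  records$pos1, records$cigar, records$seq)
  writeLines(c(header, body), path)
  path
}

# brute-force conditional exact test oracle: enumerate every per-sample
# count composition of the total, weight by the joint NB probability, and
# sum the split probabilities as or less likely than the observed split.
# Independent of the analytic group-sum route used by nb_exact_test.
exact_test_oracle <- function(s_a, s_b, n_a, n_b, phi, mu = 7) {
  tot <- s_a + s_b
  lpr <- function(y) {
    if (phi == 0) dpois(y, mu, log = TRUE)
    else dnbinom(y, mu = mu, size = 1 / phi, log = TRUE)
  }
  parts <- as.matrix(expand.grid(rep(list(0:tot), n_a + n_b - 1)))
  last <- tot - rowSums(parts)
  keep <- last >= 0
  parts <- cbind(parts[keep, , drop = FALSE], last[keep])
  lp <- rowSums(matrix(lpr(parts), nrow = nrow(parts)))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  split_a <- rowSums(parts[, seq_len(n_a), drop = FALSE])
  psplit <- tapply(w, split_a, sum)
  obs <- psplit[as.character(s_a)]
  unname(sum(psplit[psplit <= obs * (1 + 1e-9)]))
}

# straight-line reimplementation of the trimmed-mean normalization rule,
# used as the oracle for tmm_factors
tmm_oracle <- function(m, lib = colSums(m)) {
  f75 <- sapply(seq_len(ncol(m)), function(j) {
    unname(quantile(m[, j], 0.75)) / lib[j]
  })
  ref <- which.min(abs(f75 - mean(f75)))
  f <- sapply(seq_len(ncol(m)), function(j) {
    o <- m[, j]; r <- m[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  })
  f / exp(mean(log(f)))
}

# build a small full study on disk: annotation, 2+2 occupancy SAM files
# with planted differential positions, and a config; returns paths + truth
build_e2e_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- make_toy_annotation(n_genes = 6, seed = 101)
  paths <- write_toy_annotation(ann, dir)
  reps <- representative_transcripts(ann$models)
  base <- NULL
  diff_truth <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(nrow(reps))) {
      mod <- reps[i, ]
      txs <- occudiff:::transcript_seq(mod, ann$genome)
      t_pos <- which(strsplit(txs, NULL)[[1]] == "T") - 1L
      t_pos <- t_pos[seq_len(min(70, length(t_pos)))]
      base <- dplyr::bind_rows(base, tibble::tibble(
        gene = mod$gene_id, tx_pos = t_pos,
        lambda = 4 + rpois(length(t_pos), 2)))
      if (i <= 2) {  # two genes carry planted 4x increases in B
        diff_truth <- dplyr::bind_rows(diff_truth, tibble::tibble(
          gene = mod$gene_id, tx_pos = t_pos[seq(5, 40, by = 5)]))
      }
    }
  })
  mk_sam <- function(sample_id, cond, s) {
    events <- withr::with_seed(s, {
      lam <- base$lambda
      key <- paste(base$gene, base$tx_pos)
      boost <- key %in% paste(diff_truth$gene, diff_truth$tx_pos) &
        cond == "B"
      lam <- ifelse(boost, lam * 4, lam)
      pmax(2L, rpois(nrow(base), lam))
    })
    planted <- tibble::tibble(gene = base$gene, tx_pos = base$tx_pos,
                              events = as.integer(events))
    out <- file.path(dir, paste0(sample_id, ".sam"))
    simulate_alignments(ann, planted, out, seed = s)
    out
  }
  sams_a <- c(mk_sam("A1", "A", 211), mk_sam("A2", "A", 212))
  sams_b <- c(mk_sam("B1", "B", 213), mk_sam("B2", "B", 214))
  list(ann = ann, fasta = unname(paths["fasta"]), gtf = unname(paths["gtf"]),
       cond_a = sams_a, cond_b = sams_b, diff_truth = diff_truth)
}

# one shared on-disk study for the pipeline and end-to-end determinism tests
e2e <- build_e2e_study(file.path(tempdir(), "e2e"), seed = 1L)
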