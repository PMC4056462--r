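# Deterministic seeded generators for every input the pipeline consumes:
# toy genome + gene models, NB positional count studies, SAM alignments
# with planted T-C mismatches, and FPKM triplets from known decay rates.
# Every generator is a pure function of (parameters, seed) and returns a
# ground-truth manifest sufficient to compute expected outcomes.

#' Generate a toy genome and gene models
#'
#' Multi-exon genes on both strands of a small set of chromosomes, with
#' 5'UTR/CDS/3'UTR partitions (a configurable fraction are noncoding
#' lincRNA-like models). Sense-strand sequences are uridine-rich (T
#' probability 0.35) so crosslink-site planting and T-snapping always
#' find substrate. Deterministic per seed.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms chromosomes to spread genes over.
#' @param exon_range range of exon counts per gene.
#' @param tx_len_range transcript length range in nt.
#' @param frac_noncoding fraction of genes without CDS.
#' @param seed integer seed.
#' @return list: `genome` (DNAStringSet), `models` (gene-model tibble).
#' @export
make_toy_annotation <- function(n_genes = 30, n_chroms = 2,
                                exon_range = c(1, 3),
                                tx_len_range = c(240, 600),
                                frac_noncoding = 0.1, seed = 1L) {
  assert_that(n_genes >= 1, "need at least one gene")
  with_seed(child_seed(seed, 1L), {
    chroms <- paste0("chr", seq_len(n_chroms))
    chrom_seq <- setNames(vector("list", n_chroms), chroms)
    for (ch in chroms) chrom_seq[[ch]] <- character(0)
    cursor <- setNames(rep(0L, n_chroms), chroms)
    base_probs <- c(A = 0.25, C = 0.2, G = 0.2, T = 0.35)
    rand_seq <- function(n) paste(sample(names(base_probs), n, replace = TRUE,
                                         prob = base_probs), collapse = "")
    rows <- purrr::map(seq_len(n_genes), function(i) {
      ch <- chroms[(i - 1L) %% n_chroms + 1L]
      strand <- sample(c("+", "-"), 1)
      tx_len <- sample(tx_len_range[1]:tx_len_range[2], 1)
      n_ex <- sample(exon_range[1]:exon_range[2], 1)
      # split transcript length into exons (each >= 30 nt)
      cuts <- sort(sample(seq(30, tx_len - 30), n_ex - 1)) |> unique()
      while (length(cuts) < n_ex - 1 ||
             any(diff(c(0, cuts, tx_len)) < 30)) {
        cuts <- sort(sample(seq(30, tx_len - 30), n_ex - 1)) |> unique()
      }
      ex_len <- diff(c(0, cuts, tx_len))
      introns <- if (n_ex > 1) sample(20:100, n_ex - 1, replace = TRUE)
                 else integer(0)
      gap <- sample(80:150, 1)
      start <- cursor[ch] + gap
      es <- integer(n_ex); ee <- integer(n_ex)
      pos <- start
      for (e in seq_len(n_ex)) {
        es[e] <- pos
        ee[e] <- pos + ex_len[e]
        pos <- ee[e] + if (e < n_ex) introns[e] else 0L
      }
      locus_len <- pos - start
      # sense-strand sequence over the whole locus (introns included)
      sense <- rand_seq(locus_len)
      genomic <- if (strand == "-") revcomp(sense) else sense
      chrom_seq[[ch]] <<- c(chrom_seq[[ch]], rand_seq(gap), genomic)
      cursor[ch] <<- pos
      noncoding <- runif(1) < frac_noncoding
      if (noncoding) {
        cs <- NA_integer_; ce <- NA_integer_
        biotype <- "lincRNA"
      } else {
        # CDS occupies the middle of the transcript; UTRs at least 20 nt
        u5 <- sample(20:min(60, tx_len %/% 4), 1)
        u3 <- sample(40:min(150, tx_len %/% 3), 1)
        span_t <- c(u5, tx_len - u3)  # transcript coords, half-open
        biotype <- "protein_coding"
      }
      model <- tibble(
        gene_id = sprintf("g%03d", i), tx_id = sprintf("g%03d.t1", i),
        biotype = biotype, chrom = ch, strand = strand,
        exon_start = list(as.integer(es)), exon_end = list(as.integer(ee)),
        cds_start = NA_integer_, cds_end = NA_integer_,
        tx_len = as.integer(tx_len)
      )
      if (!noncoding) {
        # map the transcript-space CDS span to a genomic span
        g1 <- tx_to_genomic(model, span_t[1])
        g2 <- tx_to_genomic(model, span_t[2] - 1L)
        model$cds_start <- min(g1, g2)
        model$cds_end <- max(g1, g2) + 1L
      }
      model
    })
    models <- bind_rows(rows)
    genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste,
                                              character(1), collapse = ""))
    names(genome) <- chroms
    validate_gene_models(models)
    list(genome = genome, models = models)
  })
}

#' Write a toy annotation to FASTA + GTF
#'
#' @param ann list from [make_toy_annotation()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths.
#' @export
write_toy_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "models.gtf")
  Biostrings::writeXStringSet(ann$genome, fasta)
  lines <- purrr::map(seq_len(nrow(ann$models)), function(i) {
    m <- ann$models[i, ]
    at <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                  m$gene_id, m$tx_id, m$biotype)
    es <- m$exon_start[[1]]; ee <- m$exon_end[[1]]
    ex <- sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, es + 1L, ee, m$strand, at)
    cds <- if (!is.na(m$cds_start)) {
      # emit CDS pieces clipped to exons
      cs <- pmax(es, m$cds_start); ce <- pmin(ee, m$cds_end)
      keep <- ce > cs
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, cs[keep] + 1L, ce[keep], m$strand, at)
    } else character(0)
    c(ex, cds)
  })
  writeLines(unlist(lines), gtf)
  c(fasta = fasta, gtf = gtf)
}

#' Simulate a positional T-C count study
#'
#' Draws NB counts for a two-condition replicated design over
#' positions x genes, with per-sample library factors, a fraction of
#' planted differential positions (mean multiplied by `effect` in one
#' condition) and optional whole-gene scaling to emulate expression
#' confounds. Returns the long count table the statistical entry point
#' consumes plus a truth manifest.
#'
#' @param n_genes,n_positions study dimensions (defaults 500 x 200).
#' @param n_rep replicates per condition (default 2).
#' @param dispersion NB dispersion (0 = Poisson).
#' @param baseline_mean mean T-C count per position at library factor 1.
#' @param frac_planted fraction of positions carrying a planted effect.
#' @param effect fold effect at planted positions (applied in condition B,
#'   direction randomized per position).
#' @param gene_scaling optional named vector: per-gene multiplier applied
#'   to all positions of condition B (expression confound).
#' @param position_cv lognormal sd of per-position baseline variation.
#' @param libsize_cv lognormal sd of per-sample library factors.
#' @param seed integer seed.
#' @return list: `counts` (long tibble: gene, position, sample,
#'   condition, count), `truth` (gene, position, effect, direction),
#'   `lib_factors`.
#' @export
simulate_count_study <- function(n_genes = 500, n_positions = 200,
                                 n_rep = 2, dispersion = 0.2,
                                 baseline_mean = 20, frac_planted = 0.05,
                                 effect = 4, gene_scaling = NULL,
                                 position_cv = 0.4, libsize_cv = 0.1,
                                 seed = 1L) {
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  with_seed(child_seed(seed, 2L), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(paste0("A", seq_len(n_rep)), paste0("B", seq_len(n_rep)))
    conds <- rep(c("A", "B"), each = n_rep)
    lib <- exp(rnorm(2 * n_rep, 0, libsize_cv))
    base <- matrix(baseline_mean *
                     exp(rnorm(n_genes * n_positions, 0, position_cv)),
                   nrow = n_genes * n_positions)
    idx <- tibble(gene = rep(genes, each = n_positions),
                  position = rep(seq_len(n_positions) - 1L, n_genes))
    n_tot <- nrow(idx)
    planted <- sort(sample(n_tot, round(frac_planted * n_tot)))
    dir_up <- runif(length(planted)) < 0.5
    truth <- tibble(gene = idx$gene[planted],
                    position = idx$position[planted],
                    effect = effect,
                    direction = ifelse(dir_up, "increased", "decreased"))
    scale_b <- rep(1, n_tot)
    scale_b[planted] <- ifelse(dir_up, effect, 1 / effect)
    if (!is.null(gene_scaling)) {
      gs <- gene_scaling[idx$gene]
      gs[is.na(gs)] <- 1
      scale_b <- scale_b * gs
    }
    draw <- function(mu) {
      if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else rpois(length(mu), mu)
    }
    counts <- purrr::map_dfr(seq_along(samples), function(s) {
      mu <- base[, 1] * lib[s] * (if (conds[s] == "B") scale_b else 1)
      tibble(gene = idx$gene, position = idx$position,
             sample = samples[s], condition = conds[s],
             count = draw(mu))
    })
    list(counts = counts, truth = truth,
         lib_factors = setNames(lib, samples))
  })
}

#' Simulate alignments with planted T-C transitions
#'
#' Writes a coordinate-sorted SAM file whose reads tile the transcripts
#' of a toy annotation; designated reads carry a crosslink-diagnostic
#' mismatch at planted transcript positions (genomic T read as C for
#' plus-strand genes, A read as G for minus-strand genes — the SAM
#' forward-orientation view of a sense-strand T-to-C event). Background
#' reads are mismatch-free, so [extract_profiles()] recovers the planted
#' per-position transition counts exactly.
#'
#' @param ann annotation from [make_toy_annotation()].
#' @param planted tibble (gene, tx_pos, events): transition events to
#'   plant; every position must be a sense-strand T (error otherwise).
#' @param sam_path output SAM path.
#' @param read_length read length (default 30 nt).
#' @param tile_step tiling step for background coverage (default 10 nt).
#' @param depth optional named per-gene count of extra random-start reads.
#' @param seed integer seed.
#' @return list: `sam` (path), `truth` (planted with genomic
#'   coordinates), `n_reads`.
#' @export
simulate_alignments <- function(ann, planted = NULL, sam_path,
                                read_length = 30, tile_step = 10,
                                depth = NULL, seed = 1L) {
  genome <- ann$genome
  models <- ann$models
  planted <- planted %||% tibble(gene = character(), tx_pos = integer(),
                                 events = integer())
  reads <- list()
  truth <- list()
  with_seed(child_seed(seed, 3L), {
    for (j in seq_len(nrow(models))) {
      mod <- models[j, ]
      g <- mod$gene_id
      len <- mod$tx_len
      starts <- seq(0L, max(0L, len - read_length), by = tile_step)
      if (!is.null(depth) && g %in% names(depth)) {
        extra <- sample(0:max(0L, len - read_length), depth[[g]],
                        replace = TRUE)
        starts <- c(starts, extra)
      }
      mm_by_read <- vector("list", length(starts))
      pl <- planted[planted$gene == g, ]
      if (nrow(pl) > 0) {
        for (q in seq_len(nrow(pl))) {
          tp <- pl$tx_pos[q]
          gp <- tx_to_genomic(mod, tp)
          sense_base <- if (mod$strand == "+") {
            genome_base(genome, mod$chrom, gp)
          } else {
            complement_base(genome_base(genome, mod$chrom, gp))
          }
          if (sense_base != "T") {
            stop("planted position ", g, ":", tp,
                 " is not a sense-strand T", call. = FALSE)
          }
          cover <- which(starts <= tp & starts + read_length > tp)
          need <- pl$events[q]
          if (length(cover) < need) {
            # add dedicated reads centered on the position
            add <- pmin(pmax(tp - read_length %/% 2L, 0L),
                        len - read_length)
            starts <- c(starts, rep(add, need - length(cover)))
            mm_by_read <- c(mm_by_read,
                            vector("list", need - length(cover)))
            cover <- c(cover, seq(length(starts) - (need - length(cover)) +
                                    1L, length(starts)))
          }
          chosen <- cover[seq_len(need)]
          for (r in chosen) mm_by_read[[r]] <- c(mm_by_read[[r]], tp)
          truth[[length(truth) + 1L]] <- tibble(
            gene = g, tx_pos = tp, gpos = gp, chrom = mod$chrom,
            strand = mod$strand, events = need)
        }
      }
      for (r in seq_along(starts)) {
        reads[[length(reads) + 1L]] <-
          build_read(mod, genome, starts[r], read_length, mm_by_read[[r]])
      }
    }
  })
  sam <- bind_rows(reads) |> arrange(.data$chrom, .data$pos1)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  body <- sprintf("r%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                  seq_len(nrow(sam)), sam$flag, sam$chrom, sam$pos1,
                  sam$cigar, sam$seq)
  writeLines(c(header, body), sam_path)
  list(sam = sam_path,
       truth = if (length(truth) > 0) bind_rows(truth) else
         tibble(gene = character(), tx_pos = integer(), gpos = integer(),
                chrom = character(), strand = character(),
                events = integer()),
       n_reads = nrow(sam))
}

# one read spanning transcript positions [tstart, tstart + rl) of a model,
# with optional sense T->C mismatches at transcript positions mm_tpos.
# Returns the SAM forward-orientation view (chrom, pos1, flag, cigar, seq).
build_read <- function(mod, genome, tstart, rl, mm_tpos = NULL) {
  tpos <- tstart:(tstart + rl - 1L)
  gpos <- tx_to_genomic(mod, tpos)
  ord <- order(gpos)
  g_sorted <- gpos[ord]
  breaks <- which(diff(g_sorted) != 1L)
  blk_start <- g_sorted[c(1L, breaks + 1L)]
  blk_end <- g_sorted[c(breaks, length(g_sorted))] + 1L
  seq_fwd <- paste(purrr::map2_chr(blk_start, blk_end,
                                   ~ genome_seq(genome, mod$chrom, .x, .y)),
                   collapse = "")
  # apply planted mismatches in forward-genomic orientation
  if (length(mm_tpos) > 0) {
    offsets <- match(gpos[match(mm_tpos, tpos)],
                     unlist(purrr::map2(blk_start, blk_end,
                                        ~ seq.int(.x, .y - 1L))))
    for (o in offsets) {
      ref <- substr(seq_fwd, o, o)
      new <- if (mod$strand == "+") "C" else "G"  # T>C sense == A>G fwd
      substr(seq_fwd, o, o) <- new
    }
  }
  gaps <- blk_start[-1] - blk_end[-length(blk_end)]
  widths <- blk_end - blk_start
  cigar <- paste0(widths[1], "M")
  if (length(widths) > 1) {
    for (i in 2:length(widths)) {
      cigar <- paste0(cigar, gaps[i - 1], "N", widths[i], "M")
    }
  }
  tibble(chrom = mod$chrom, pos1 = blk_start[1] + 1L,
         flag = if (mod$strand == "+") 0L else 16L,
         cigar = cigar, seq = seq_fwd)
}

#' Simulate a 4SU half-life study
#'
#' Draws per-gene decay rates, computes the exact newly synthesized
#' fraction `f = 1 - exp(-k t)` and emits FPKM triplets
#' `L = f T`, `U = (1 - f) T` with multiplicative lognormal noise.
#'
#' @param n_genes number of genes.
#' @param t_label labeling duration in minutes (default 60).
#' @param noise_sd lognormal noise sd (0 = exact fractions).
#' @param hl_meanlog,hl_sdlog lognormal parameters of true half-lives in
#'   minutes (default median 240 min).
#' @param seed integer seed.
#' @return list: `fpkm` tibble (gene, total, labeled, unlabeled),
#'   `truth` (gene, k, half_life).
#' @export
simulate_halflife_study <- function(n_genes = 1000, t_label = 60,
                                    noise_sd = 0, hl_meanlog = log(240),
                                    hl_sdlog = 0.6, seed = 1L) {
  with_seed(child_seed(seed, 4L), {
    genes <- sprintf("g%05d", seq_len(n_genes))
    hl <- rlnorm(n_genes, hl_meanlog, hl_sdlog)
    k <- log(2) / hl
    f <- 1 - exp(-k * t_label)
    total <- rlnorm(n_genes, log(50), 1)
    noise <- function(n) if (noise_sd > 0) rlnorm(n, 0, noise_sd) else 1
    list(
      fpkm = tibble(gene = genes, total = total,
                    labeled = f * total * noise(n_genes),
                    unlabeled = (1 - f) * total * noise(n_genes)),
      truth = tibble(gene = genes, k = k, half_life = hl)
    )
  })
}
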