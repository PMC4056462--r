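# top/random sets, clustering statistics, distributions, correlations

test_that("greedy top selection respects strict spacing and ordering", {
  d <- tibble::tibble(
    gene = "g", chrom = "chr1", gpos = c(100L, 110L, 130L),
    p_value = c(1e-6, 1e-5, 1e-4), log2_fc = 2)
  top <- select_top_positions(d, n = 10, min_spacing = 20)
  expect_equal(top$gpos, c(100L, 130L))  # 110 within 20 of 100 -> skipped
  # exactly 20 apart: strictly "more than 20" required, second skipped
  d2 <- tibble::tibble(gene = "g", chrom = "chr1", gpos = c(100L, 120L),
                       p_value = c(1e-6, 1e-5), log2_fc = 2)
  expect_equal(select_top_positions(d2, n = 10, min_spacing = 20)$gpos, 100L)
  # fewer than n eligible warns
  expect_warning(select_top_positions(d, n = 5, min_spacing = 20), "eligible")
  # spacing never violated on a large random table (within genes)
  set.seed(12)
  big <- tibble::tibble(
    gene = sample(paste0("g", 1:5), 400, TRUE), chrom = "chr1",
    gpos = sample(1:2000, 400), p_value = runif(400), log2_fc = rnorm(400))
  topb <- suppressWarnings(select_top_positions(big, n = 100))
  for (g in unique(topb$gene)) {
    gp <- sort(topb$gpos[topb$gene == g])
    if (length(gp) > 1) expect_true(all(diff(gp) > 20))
  }
  # positions flagged by the expression filter are excluded
  d3 <- d
  d3$expr_removed <- c(TRUE, FALSE, FALSE)
  expect_false(100L %in% suppressWarnings(
    select_top_positions(d3, n = 10))$gpos)
})

test_that("random positions sit on sense-strand T and are seed-stable", {
  reps <- representative_transcripts(toy_ann$models)
  pos <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    mod <- reps[i, ]
    fp <- sort(occudiff:::footprint_positions(mod))
    tibble::tibble(gene = mod$gene_id, chrom = mod$chrom,
                   gpos = fp[round(length(fp) / 2)],
                   strand = mod$strand, p_value = 1e-5, log2_fc = 1)
  })
  rnd1 <- generate_random_positions(pos, toy_ann$models, toy_ann$genome,
                                    seed = 5)
  rnd2 <- generate_random_positions(pos, toy_ann$models, toy_ann$genome,
                                    seed = 5)
  expect_identical(rnd1, rnd2)
  rnd3 <- generate_random_positions(pos, toy_ann$models, toy_ann$genome,
                                    seed = 6)
  expect_false(identical(rnd1$gpos, rnd3$gpos))
  for (i in seq_len(nrow(rnd1))) {
    mod <- reps[reps$gene_id == rnd1$gene[i], ]
    base <- genome_base(toy_ann$genome, rnd1$chrom[i], rnd1$gpos[i])
    expect_equal(base, if (mod$strand == "+") "T" else "A")
    # stays inside the exon footprint
    expect_false(is.na(genomic_to_tx(mod, rnd1$gpos[i])))
  }
  # snapping is a no-op when the shifted base already carries the target:
  # every snapped distance is the minimum over footprint target bases
  for (i in seq_len(nrow(rnd1))) {
    mod <- reps[reps$gene_id == rnd1$gene[i], ]
    fp <- sort(occudiff:::footprint_positions(mod))
    bases <- genome_base(toy_ann$genome, mod$chrom, fp)
    t_fp <- fp[bases == (if (mod$strand == "+") "T" else "A")]
    cand <- rnd1$source_gpos[i] + rnd1$shift[i]
    expect_equal(abs(rnd1$gpos[i] - cand), min(abs(t_fp - cand)))
  }
})

test_that("nearest-distance statistics match the worked example", {
  d <- tibble::tibble(gene = "g",
                      position = c(100L, 115L, 400L, 50L),
                      significant = c(TRUE, TRUE, TRUE, FALSE))
  nd <- nearest_significant_distance(d)
  sig <- nd[nd$query_set == "significant", ]
  expect_equal(sort(sig$distance), c(15, 15, 285))
  expect_equal(mean(sig$distance <= 20), 2 / 3)
  non <- nd[nd$query_set == "nonsignificant", ]
  expect_equal(non$distance, 50)
  # a lone significant position is excluded and counted
  lone <- tibble::tibble(gene = "h", position = 10L, significant = TRUE)
  nd2 <- nearest_significant_distance(lone)
  expect_equal(nrow(nd2), 0)
  expect_equal(attr(nd2, "n_excluded"), 1L)
})

test_that("direction consistency separates clustered from alternating sites", {
  clustered <- tibble::tibble(
    gene = "g", position = c(10L, 15L, 300L, 305L),
    significant = TRUE,
    direction = c("increased", "increased", "decreased", "decreased"))
  expect_equal(direction_consistency(clustered)$fraction_same, 1)
  alternating <- tibble::tibble(
    gene = "g", position = seq(0L, 90L, by = 10L), significant = TRUE,
    direction = rep(c("increased", "decreased"), 5))
  expect_equal(direction_consistency(alternating)$fraction_same, 0)
  # clustered same-direction pairs are closer than opposing pairs
  set.seed(4)
  mixed <- dplyr::bind_rows(
    purrr::map_dfr(1:20, function(i) tibble::tibble(
      gene = paste0("g", i),
      position = as.integer(c(0, 5, 500)),
      significant = TRUE,
      direction = c("increased", "increased", "decreased"))))
  dc <- direction_consistency(mixed)
  expect_lt(median(dc$pairs$distance[dc$pairs$same_direction]),
            median(dc$pairs$distance[!dc$pairs$same_direction]))
})

test_that("region distribution sums to one over coding regions", {
  d <- tibble::tibble(region = c("CDS", "CDS", "3UTR", "3UTR", "noncoding"))
  rd <- region_distribution(d)
  expect_equal(rd$fraction[rd$region == "5UTR"], 0)
  expect_equal(rd$fraction[rd$region == "CDS"], 0.5)
  expect_equal(rd$fraction[rd$region == "3UTR"], 0.5)
  expect_equal(rd$n[rd$region == "noncoding"], 1L)
  expect_true(is.na(rd$fraction[rd$region == "noncoding"]))
  all3 <- tibble::tibble(region = rep("3UTR", 4))
  expect_equal(region_distribution(all3)$fraction[2:3], c(0, 1))
  expect_error(region_distribution(d[0, ]), "empty")
})

test_that("metagene density is a proper distribution", {
  reps <- representative_transcripts(toy_ann$models)
  coding <- reps[!is.na(reps$cds_start), ]
  set.seed(6)
  pos <- purrr::map_dfr(seq_len(nrow(coding)), function(i) {
    tibble::tibble(gene = coding$gene_id[i],
                   position = sort(sample(0:(coding$tx_len[i] - 1), 40)))
  })
  md <- metagene_density(pos, toy_ann$models)
  expect_equal(sum(md$density), 1, tolerance = 1e-9)
  expect_equal(nrow(md), 100)
  expect_equal(as.vector(table(md$region)[c("5UTR", "CDS", "3UTR")]),
               c(10L, 50L, 40L))
  # all mass at CDS start concentrates in the first CDS bin
  spike <- purrr::map_dfr(seq_len(nrow(coding)), function(i) {
    mod <- coding[i, ]
    span <- occudiff:::cds_tx_span(mod)
    tibble::tibble(gene = mod$gene_id, position = span[1])
  })
  ms <- metagene_density(spike, toy_ann$models)
  expect_equal(ms$density[11], 1, tolerance = 1e-9)
})

test_that("sliding-window correlation is a rank statistic", {
  reps <- representative_transcripts(toy_ann$models)
  long <- reps[reps$tx_len >= 500, ][1, ]
  fp <- occudiff:::footprint_positions(long)
  set.seed(13)
  cover <- rpois(length(fp), 20) + seq_along(fp) / 50
  prof_a <- tibble::tibble(chrom = long$chrom, pos = sort(fp),
                           coverage = cover[order(fp)], transitions = 0)
  # identical profile: rho 1
  sw <- sliding_window_correlation(prof_a, prof_a, long,
                                   window = 50, min_windows = 5)
  expect_equal(sw$median_rho, 1)
  # monotone transform: rank invariance
  prof_sq <- prof_a
  prof_sq$coverage <- prof_a$coverage^2
  sw2 <- sliding_window_correlation(prof_a, prof_sq, long,
                                    window = 50, min_windows = 5)
  expect_equal(sw2$median_rho, 1)
  # anti-ranked windows on a strictly monotone fixture: rho -1
  nw <- long$tx_len %/% 50
  tpos <- 0:(nw * 50 - 1)
  gpos <- tx_to_genomic(long, tpos)
  mono <- tibble::tibble(chrom = long$chrom, pos = gpos,
                         coverage = tpos + 1, transitions = 0)
  anti <- tibble::tibble(chrom = long$chrom, pos = gpos,
                         coverage = rev(tpos + 1), transitions = 0)
  sw3 <- sliding_window_correlation(mono, anti, long,
                                    window = 50, min_windows = 5)
  expect_equal(sw3$median_rho, -1)
  expect_error(sliding_window_correlation(prof_a, prof_a, long,
                                          window = 50, min_windows = 100),
               "no eligible")
})

test_that("explained variance matches closed-form least squares", {
  reps <- representative_transcripts(toy_ann$models)
  mod <- reps[1, ]
  fp <- sort(occudiff:::footprint_positions(mod))
  set.seed(23)
  expr_cov <- rpois(length(fp), 30)
  expr <- tibble::tibble(chrom = mod$chrom, pos = fp,
                         coverage = expr_cov, transitions = 0)
  occ_lin <- expr
  occ_lin$coverage <- 2 * expr_cov + 3
  ev <- explained_variance(occ_lin, expr, mod)
  expect_equal(ev$mean_r2, 1, tolerance = 1e-12)
  # hand least squares on a 5-point toy
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.2, 2.9, 4.1, 4.8, 6.3)
  r2_hand <- cor(x, y)^2
  expect_equal(summary(lm(y ~ x))$r.squared, r2_hand, tolerance = 1e-12)
})

test_that("gene-wise fold-change correlation matches closed form", {
  ident <- tibble::tibble(gene = paste0("g", 1:5),
                          occ_a = c(10, 50, 20, 80, 40),
                          occ_b = c(12, 60, 25, 70, 45))
  ident$expr_a <- ident$occ_a
  ident$expr_b <- ident$occ_b
  expect_equal(genewise_fc_correlation(ident)$r, 1, tolerance = 1e-12)
  # hand-computed 4-gene example
  d <- tibble::tibble(gene = paste0("g", 1:4),
                      occ_a = c(10, 20, 30, 40), occ_b = c(40, 10, 60, 20),
                      expr_a = c(5, 10, 15, 20), expr_b = c(30, 5, 25, 10))
  la <- function(x) log2((x + 1) / sum(x))
  fo <- la(d$occ_b) - la(d$occ_a)
  fe <- la(d$expr_b) - la(d$expr_a)
  expect_equal(genewise_fc_correlation(d)$r, cor(fo, fe), tolerance = 1e-12)
  # independent fold changes: negligible correlation at 1,000 genes
  set.seed(3)
  big <- tibble::tibble(gene = paste0("g", 1:1000),
                        occ_a = rpois(1000, 100), occ_b = rpois(1000, 100),
                        expr_a = rpois(1000, 100), expr_b = rpois(1000, 100))
  expect_lt(abs(genewise_fc_correlation(big)$r), 0.1)
  expect_error(genewise_fc_correlation(ident[1:2, ]), "at least 3")
})
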