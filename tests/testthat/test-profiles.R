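# occupancy profile construction from alignments

# genome with a known layout: chr1 is 400 nt, all A except planted bases
profile_genome <- function() {
  s <- strrep("A", 400)
  substr(s, 106, 106) <- "T"  # 0-based 105
  substr(s, 120, 140) <- strrep("G", 21)
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

test_that("clean reads add coverage and no transitions", {
  g <- profile_genome()
  ref30 <- as.character(Biostrings::subseq(g[[1]], 51, 80))
  sam <- write_sam(tibble::tibble(chrom = "chr1", pos1 = 51L, flag = 0L,
                                  cigar = "30M", seq = ref30), g,
                   tempfile(fileext = ".sam"))
  prof <- extract_profiles(sam, g)
  expect_equal(nrow(prof), 30)
  expect_true(all(prof$coverage == 1))
  expect_true(all(prof$transitions == 0))
  expect_equal(prof$pos, 50:79)
})

test_that("sense-strand transition rule counts T>C forward and A>G reverse only", {
  g <- profile_genome()
  # forward read covering 0-based 100..129; reference T at 105 read as C
  fwd <- as.character(Biostrings::subseq(g[[1]], 101, 130))
  substr(fwd, 6, 6) <- "C"
  # reverse-aligned read covering 200..229 (all A): one A>G (counted at 200)
  # and one G>A at the planted G run would not be on this window; instead
  # plant a non-diagnostic A>T at 210 to confirm it is ignored
  rev <- as.character(Biostrings::subseq(g[[1]], 201, 230))
  substr(rev, 1, 1) <- "G"
  substr(rev, 11, 11) <- "T"
  sam <- write_sam(tibble::tibble(
    chrom = "chr1", pos1 = c(101L, 201L), flag = c(0L, 16L),
    cigar = "30M", seq = c(fwd, rev)), g, tempfile(fileext = ".sam"))
  prof <- extract_profiles(sam, g)
  tc <- prof[prof$transitions > 0, ]
  expect_equal(tc$pos, c(105L, 200L))
  expect_equal(tc$transitions, c(1, 1))
  # a forward G>A mismatch is not a transition event
  gfwd <- as.character(Biostrings::subseq(g[[1]], 120, 149))
  substr(gfwd, 1, 1) <- "A"
  sam2 <- write_sam(tibble::tibble(chrom = "chr1", pos1 = 120L, flag = 0L,
                                   cigar = "30M", seq = gfwd), g,
                    tempfile(fileext = ".sam"))
  prof2 <- extract_profiles(sam2, g)
  expect_equal(sum(prof2$transitions), 0)
})

test_that("duplicate collapse keeps one record per start/strand/sequence", {
  g <- profile_genome()
  ref30 <- as.character(Biostrings::subseq(g[[1]], 51, 80))
  rec <- tibble::tibble(chrom = "chr1", pos1 = rep(51L, 3), flag = 0L,
                        cigar = "30M", seq = ref30)
  sam <- write_sam(rec, g, tempfile(fileext = ".sam"))
  expect_equal(max(extract_profiles(sam, g)$coverage), 3)
  expect_equal(max(extract_profiles(sam, g,
                                    collapse_duplicates = TRUE)$coverage), 1)
})

test_that("unsorted BAM input is rejected", {
  g <- profile_genome()
  sam <- tempfile(fileext = ".sam")
  ref30 <- as.character(Biostrings::subseq(g[[1]], 51, 80))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chr1\tLN:%d", 400),
               sprintf("r1\t0\tchr1\t51\t255\t30M\t*\t0\t0\t%s\t*", ref30)),
             sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  expect_error(extract_profiles(bam, g), "SO:coordinate")
})

test_that("mismatch spectrum types substitutions in sense orientation", {
  g <- profile_genome()
  ref30 <- as.character(Biostrings::subseq(g[[1]], 51, 80))
  tc <- as.character(Biostrings::subseq(g[[1]], 101, 130))
  substr(tc, 6, 6) <- "C"  # forward T>C
  ga <- as.character(Biostrings::subseq(g[[1]], 120, 149))
  substr(ga, 1, 1) <- "A"  # forward G>A
  rec <- tibble::tibble(
    chrom = "chr1",
    pos1 = c(rep(51L, 6), 101L, 120L),
    flag = 0L, cigar = "30M",
    seq = c(rep(ref30, 6), tc, ga))
  spec <- mismatch_spectrum(write_sam(rec, g, tempfile(fileext = ".sam")), g)
  s <- glance(spec)
  expect_equal(s$reads_mapped, 8L)
  expect_equal(s$reads_0mm, 6L)
  expect_equal(s$reads_1mm, 2L)
  tab <- tidy(spec)
  expect_equal(tab$count[tab$substitution == "T>C"], 1L)
  expect_equal(tab$count[tab$substitution == "G>A"], 1L)
  expect_equal(sum(tab$count), 2L)
  expect_equal(sum(tab$fraction), 1)
  # empty input: all zeros, fraction flagged undefined
  empty <- write_sam(rec[0, ], g, tempfile(fileext = ".sam"))
  s0 <- glance(mismatch_spectrum(empty, g))
  expect_equal(s0$reads_mapped, 0L)
  expect_false(s0$defined)
  expect_equal(sum(tidy(mismatch_spectrum(empty, g))$count), 0L)
})

test_that("consensus profile is the per-position mean with absent = 0", {
  p1 <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                       coverage = c(4, 2), transitions = c(2, 1))
  p2 <- tibble::tibble(chrom = "chr1", pos = c(10L, 30L),
                       coverage = c(8, 6), transitions = c(4, 6))
  cons <- consensus_profile(list(p1, p2))
  expect_equal(cons$transitions[cons$pos == 10], 3)
  expect_equal(cons$transitions[cons$pos == 20], 0.5)
  expect_equal(cons$transitions[cons$pos == 30], 3)
  expect_equal(cons$coverage[cons$pos == 30], 3)
  ident <- consensus_profile(list(p1, p1, p1))
  expect_equal(ident$coverage, p1$coverage)
  expect_equal(ident$transitions, p1$transitions)
  expect_error(consensus_profile(list()), "at least one")
})

test_that("projection reverses minus-strand transcripts and maps junctions", {
  prof <- tibble::tibble(chrom = "chr1", pos = c(100L, 109L, 120L),
                         coverage = c(5, 7, 9), transitions = c(1, 2, 3))
  mp <- one_model("+", list(c(100L, 120L)), list(c(110L, 130L)))
  proj <- project_to_transcript(prof, mp)
  expect_equal(nrow(proj), 20)
  expect_equal(proj$coverage[proj$tx_pos == 0], 5)
  expect_equal(proj$coverage[proj$tx_pos == 10], 9)  # junction: 120 -> 10
  mm <- one_model("-", list(100L), list(110L))
  projm <- project_to_transcript(prof, mm)
  expect_equal(projm$coverage[projm$tx_pos == 0], 7)  # genomic 109 -> 0
  expect_equal(projm$transitions[projm$tx_pos == 9], 1)
  other <- one_model("+", list(0L), list(10L))
  other$chrom <- "chrZ"
  expect_warning(pz <- project_to_transcript(prof, other), "absent")
  expect_true(all(pz$coverage == 0))
})

test_that("RNA type assignment follows the priority order", {
  g <- profile_genome()
  models <- dplyr::bind_rows(
    one_model("+", list(40L), list(100L), biotype = "protein_coding"),
    one_model("+", list(60L), list(130L), biotype = "lincRNA"))
  models$gene_id <- c("mrna", "linc")
  models$tx_id <- c("mrna.t", "linc.t")
  ref30 <- function(p1) as.character(Biostrings::subseq(g[[1]], p1, p1 + 29))
  rec <- tibble::tibble(
    chrom = "chr1",
    pos1 = c(rep(51L, 8), rep(301L, 2)),  # 8 in both models, 2 unannotated
    flag = 0L, cigar = "30M",
    seq = c(rep(ref30(51), 8), rep(ref30(301), 2)))
  dist <- rna_type_distribution(write_sam(rec, g, tempfile(fileext = ".sam")),
                                models)
  expect_equal(dist$fraction[dist$rna_type == "protein_coding"], 0.8)
  expect_equal(dist$fraction[dist$rna_type == "lincRNA"], 0)
  expect_equal(dist$fraction[dist$rna_type == "unannotated"], 0.2)
  expect_equal(sum(dist$fraction), 1)
})

test_that("profile extraction reproduces planted truth on the toy study", {
  planted <- NULL
  reps <- representative_transcripts(toy_ann$models)
  for (i in seq_len(min(3, nrow(reps)))) {
    mod <- reps[i, ]
    txs <- occudiff:::transcript_seq(mod, toy_ann$genome)
    tpos <- which(strsplit(txs, NULL)[[1]] == "T")[c(5, 12)] - 1L
    planted <- dplyr::bind_rows(planted, tibble::tibble(
      gene = mod$gene_id, tx_pos = tpos, events = c(2L, 4L)))
  }
  sim <- simulate_alignments(toy_ann, planted, tempfile(fileext = ".sam"),
                             seed = 21)
  prof <- extract_profiles(sim$sam, toy_ann$genome)
  got <- prof[prof$transitions > 0, ]
  expect_equal(nrow(got), nrow(sim$truth))
  expect_equal(got$transitions[match(sim$truth$gpos, got$pos)],
               as.numeric(sim$truth$events))
  expect_true(all(prof$transitions <= prof$coverage))
})
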