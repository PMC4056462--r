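# reference genome access

#' Read a reference genome from FASTA
#'
#' @param path path to an (optionally indexed) FASTA file.
#' @return a [Biostrings::DNAStringSet] with uppercase sequences, named by
#'   chromosome.
#' @export
read_genome <- function(path) {
  assert_that(file.exists(path), paste0("genome FASTA not found: ", path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Look up genome bases at 0-based positions
#'
#' @param genome a `DNAStringSet` as returned by [read_genome()].
#' @param chrom chromosome name (scalar).
#' @param pos0 integer vector of 0-based positions.
#' @return character vector of bases in `A,C,G,T,N`.
#' @export
genome_base <- function(genome, chrom, pos0) {
  assert_that(chrom %in% names(genome),
              paste0("chromosome not in genome: ", chrom))
  len <- length(genome[[chrom]])
  if (any(pos0 < 0L | pos0 >= len)) {
    stop("position out of range for ", chrom, " (length ", len, ")",
         call. = FALSE)
  }
  as.character(Biostrings::extractAt(genome[[chrom]],
                                     iranges0(pos0, pos0 + 1L)))
}

# fetch the sequence of a 0-based half-open interval as a character scalar
genome_seq <- function(genome, chrom, start0, end0) {
  assert_that(chrom %in% names(genome),
              paste0("chromosome not in genome: ", chrom))
  len <- length(genome[[chrom]])
  assert_that(start0 >= 0 && end0 <= len && start0 <= end0,
              "interval out of range")
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}
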