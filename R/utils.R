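# shared helpers: rounding, seeds, coordinate conversion

#' Round half away from zero
#'
#' Quantile-normalized counts are real-valued; the count model needs
#' integers. Base `round()` rounds half to even, which would turn equal
#' normalized values into unequal integers depending on parity, so
#' normalized counts re-enter the model via round-half-up.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

# run `code` under a fixed RNG seed without touching global RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a child seed from a base seed and a stream index, staying < 2^31
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483647L
}

# 0-based half-open -> IRanges (1-based closed)
iranges0 <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# stop unless all conditions hold, with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# reverse complement for plain character vectors (DNA alphabet)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}
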