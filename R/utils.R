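#' @importFrom stats quantile rnorm rpois runif sd setNames
#' @importFrom utils read.table write.table
NULL

# Seeds handed to downstream generators are derived by offsetting the user
# seed; the modulus keeps the result inside R's 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483629)
}

#' Reverse complement of nucleotide strings
#'
#' Case is preserved (lowercase marks masked bases) and `N` maps to `N`.
#'
#' @param x Character vector of nucleotide sequences over `ACGTNacgtn`.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Uniform draw from lo..hi, safe when lo == hi (base::sample() would
# interpret a scalar as 1:x).
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_dna <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Effective (unmasked) length of a sequence
#'
#' Lowercase bases are masked (poly-A/poly-T tails) and carry no coding
#' signal, so they are excluded from length accounting.
#'
#' @param seq Character vector of sequences.
#' @return Integer vector of unmasked base counts.
#' @export
effective_length <- function(seq) {
  nchar(gsub("[a-z]", "", seq))
}

# Round half away from zero (for non-negative input, half-up), as printed
# tables round 50.05 -> 50.1. base::round() rounds half to even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' The standard genetic code
#'
#' @return Named character vector mapping the 64 codons (DNA alphabet) to
#'   one-letter amino acids, with `*` for stop codons.
#' @export
genetic_code <- function() {
  c(Biostrings::GENETIC_CODE)
}

stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

all_codons <- function() {
  names(genetic_code())
}
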