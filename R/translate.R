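#' Codons of a sequence read in a given frame
#'
#' Frames follow the translated-search convention: `+k` reads from
#' position `k` of the sequence, `-k` from position `k` of its reverse
#' complement. Case is ignored; the trailing partial codon is dropped.
#'
#' @param seq A single nucleotide sequence.
#' @param frame One of +1, +2, +3, -1, -2, -3.
#' @return Character vector of codons.
#' @export
codons_in_frame <- function(seq, frame) {
  check_frame(frame)
  s <- toupper(seq)
  if (frame < 0) s <- revcomp(s)
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = n)
  substring(s, starts, starts + 2L)
}

check_frame <- function(frame) {
  if (length(frame) != 1 || is.na(frame) || !frame %in% c(1:3, -(1:3)))
    stop("frame must be one of +1, +2, +3, -1, -2, -3", call. = FALSE)
  invisible(frame)
}

#' Conceptual translation in a fixed frame
#'
#' Standard genetic code; stop codons render as `*`, and any codon
#' containing an ambiguity character translates to `X`.
#'
#' @inheritParams codons_in_frame
#' @return Single amino-acid string.
#' @export
translate_frame <- function(seq, frame) {
  cods <- codons_in_frame(seq, frame)
  aa <- unname(genetic_code()[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translation of the longest stop-free codon run in the frame (ties: the
# first run). Used for the conceptual peptide of homology-tier calls.
peptide_in_frame <- function(seq, frame) {
  cods <- codons_in_frame(seq, frame)
  if (!length(cods)) return("")
  is_stop <- cods %in% stop_codons()
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open <- which(!r$values)
  if (!length(open)) return("")
  k <- open[which.max(r$lengths[open])]
  aa <- unname(genetic_code()[cods[starts[k]:ends[k]]])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
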