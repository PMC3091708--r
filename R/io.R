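#' Read and write FASTA with case preserved
#'
#' Lowercase bases mark masked regions (poly-A/poly-T), so sequences are
#' handled through [Biostrings::BStringSet] which round-trips case exactly.
#' Output is wrapped at 70 columns.
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), filepath = path,
                              width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readBStringSet(path))
}

hit_table_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "sframe", "staxid")
}

#' Write and read ranked homology-hit tables
#'
#' The on-disk dialect is the 12-column tabular alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), extended with `sframe` (query reading frame of the
#' hit, +1..+3/-1..-3) and `staxid` (subject taxon), with no header, as
#' emitted by translated-search tools. Hit rank is positional: rows of one
#' query are consecutive and ordered; the reader re-derives a `rank`
#' column from row order. E-values are written with `%.6g`, which
#' round-trips the simulator's 4-significant-digit values exactly.
#'
#' @param hits Data frame carrying at least the 14 dialect columns.
#' @param path File path.
#' @return `write_hit_table` returns `path` invisibly; `read_hit_table`
#'   returns the hit data frame with a `rank` column appended.
#' @export
write_hit_table <- function(hits, path) {
  cols <- hit_table_columns()
  missing_cols <- setdiff(cols, names(hits))
  if (length(missing_cols))
    stop("hit table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- hits[cols]
  out$evalue <- sprintf("%.6g", out$evalue)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  cols <- hit_table_columns()
  hits <- read.table(path, sep = "\t", quote = "", comment.char = "",
                     col.names = cols, stringsAsFactors = FALSE,
                     colClasses = c(
                       qseqid = "character", sseqid = "character",
                       pident = "numeric", length = "integer",
                       mismatch = "integer", gapopen = "integer",
                       qstart = "integer", qend = "integer",
                       sstart = "integer", send = "integer",
                       evalue = "numeric", bitscore = "numeric",
                       sframe = "integer", staxid = "integer"
                     ))
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                          FUN = seq_along)
  hits
}

#' Write and read ground-truth tables
#'
#' Plain TSV with a header; coordinates are 0-based half-open.
#'
#' @param truth Ground-truth data frame from [simulate_contigs()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
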