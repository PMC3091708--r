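#' Trim adapter oligos from contig ends
#'
#' Removes leading and trailing occurrences of each adapter, tolerating up
#' to `max_mismatch` substitutions (Hamming matching, no indels; set
#' `max_mismatch = 0` for exact matching). Trimming repeats until neither
#' end matches, so a second pass is a no-op. Internal occurrences are
#' reported (`action = "internal"`) but the sequence is left intact.
#' Coordinates in the report are 0-based half-open on the sequence at the
#' time of the event.
#'
#' @param contigs Contig data frame (`id`, `sequence`, ...).
#' @param adapters Character vector of adapter sequences, each >= 10 nt.
#' @param max_mismatch Substitutions tolerated per adapter match
#'   (default 1).
#' @return List with `contigs` (trimmed) and `report` (data frame `id`,
#'   `action`, `start`, `end`).
#' @export
trim_adapters <- function(contigs, adapters, max_mismatch = 1L) {
  if (!length(adapters)) stop("no adapters supplied", call. = FALSE)
  if (any(nchar(adapters) < 10))
    stop("adapters must be at least 10 nt", call. = FALSE)
  adapters <- toupper(adapters)
  events <- list()
  out <- contigs
  for (i in seq_len(nrow(out))) {
    res <- trim_one(out$sequence[i], adapters, max_mismatch)
    out$sequence[i] <- res$sequence
    if (nrow(res$events))
      events[[length(events) + 1L]] <-
        cbind(data.frame(id = out$id[i], stringsAsFactors = FALSE),
              res$events)
  }
  report <- if (length(events)) {
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(), action = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  list(contigs = out, report = report)
}

adapter_matches <- function(seq_upper, adapter, max_mismatch) {
  if (nchar(seq_upper) < nchar(adapter)) return(NULL)
  subj <- Biostrings::DNAString(seq_upper)
  m <- Biostrings::matchPattern(adapter, subj,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (!length(m)) return(NULL)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

trim_one <- function(seq, adapters, max_mismatch) {
  events <- data.frame(action = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  repeat {
    su <- toupper(seq)
    hit <- NULL
    for (ad in adapters) {
      m <- adapter_matches(su, ad, max_mismatch)
      if (is.null(m)) next
      lead <- m[m$start == 1L, , drop = FALSE]
      trail <- m[m$end == nchar(su), , drop = FALSE]
      if (nrow(lead)) {
        hit <- list(action = "trim5", start = 0L, end = lead$end[1])
        seq <- substr(seq, lead$end[1] + 1L, nchar(seq))
      } else if (nrow(trail)) {
        hit <- list(action = "trim3", start = trail$start[1] - 1L,
                    end = nchar(su))
        seq <- substr(seq, 1L, trail$start[1] - 1L)
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    events <- rbind(events, data.frame(action = hit$action,
                                       start = hit$start, end = hit$end,
                                       stringsAsFactors = FALSE))
  }
  # remaining (necessarily internal) occurrences: flag, do not cut
  su <- toupper(seq)
  for (ad in adapters) {
    m <- adapter_matches(su, ad, max_mismatch)
    if (is.null(m)) next
    for (j in seq_len(nrow(m)))
      events <- rbind(events, data.frame(action = "internal",
                                         start = m$start[j] - 1L,
                                         end = m$end[j],
                                         stringsAsFactors = FALSE))
  }
  list(sequence = seq, events = events)
}

#' Mask terminal poly-A / poly-T runs
#'
#' Lowercases a 3' run of `A` or a 5' run of `T` of length `>= min_run`
#' (a reverse-complemented transcript carries its tail as a leading
#' poly-T). Masked bases are excluded from effective length; internal
#' runs are untouched. A fully masked contig is flagged
#' `discarded_empty`.
#'
#' @param contigs Contig data frame.
#' @param min_run Minimum run length to mask (default 10, minimum 5).
#' @return Contig data frame with masked sequences.
#' @export
mask_polya <- function(contigs, min_run = 10L) {
  if (min_run < 5) stop("'min_run' must be at least 5", call. = FALSE)
  out <- contigs
  for (i in seq_len(nrow(out))) {
    s <- out$sequence[i]
    m <- regexpr("[Aa]+$", s)
    if (m > 0 && attr(m, "match.length") >= min_run) {
      k <- as.integer(m)
      s <- paste0(substr(s, 1L, k - 1L), tolower(substr(s, k, nchar(s))))
    }
    m <- regexpr("^[Tt]+", s)
    if (m > 0 && attr(m, "match.length") >= min_run) {
      k <- attr(m, "match.length")
      s <- paste0(tolower(substr(s, 1L, k)), substr(s, k + 1L, nchar(s)))
    }
    out$sequence[i] <- s
    if (effective_length(s) == 0L) out$status[i] <- "discarded_empty"
  }
  out
}

#' Partition contigs by effective length
#'
#' The gate keeps contigs whose unmasked length is at least `min_len`
#' (the boundary value is kept; only strictly shorter contigs are
#' dropped). Fully masked or empty contigs are `discarded_empty`.
#'
#' @param contigs Contig data frame.
#' @param min_len Minimum effective length in bp (default 40).
#' @return List with data frames `kept` and `discarded`; together they
#'   partition the input.
#' @export
length_filter <- function(contigs, min_len = 40L) {
  if (min_len < 1) stop("'min_len' must be >= 1", call. = FALSE)
  out <- contigs
  if (nrow(out)) {
    eff <- effective_length(out$sequence)
    out$status <- ifelse(eff == 0L, "discarded_empty",
                         ifelse(eff < min_len, "discarded_short", "kept"))
  }
  list(kept = out[out$status == "kept", , drop = FALSE],
       discarded = out[out$status != "kept", , drop = FALSE])
}

#' Composed preprocessing pass
#'
#' The pipeline contract: adapter trimming, then poly-A masking, then the
#' length gate. Every input contig lands in exactly one of the output
#' partitions, and rerunning the pass on its own output changes nothing.
#'
#' @param contigs Contig data frame.
#' @param adapters Adapter sequences (see [trim_adapters()]).
#' @param max_mismatch Adapter mismatch tolerance.
#' @param min_polya_run Poly-A masking threshold (see [mask_polya()]).
#' @param min_len Length-gate threshold (see [length_filter()]).
#' @return List with `contigs` (kept), `discarded`, and `report` (trim
#'   events).
#' @export
preprocess_contigs <- function(contigs, adapters, max_mismatch = 1L,
                               min_polya_run = 10L, min_len = 40L) {
  tr <- trim_adapters(contigs, adapters, max_mismatch)
  masked <- mask_polya(tr$contigs, min_polya_run)
  parts <- length_filter(masked, min_len)
  list(contigs = parts$kept, discarded = parts$discarded,
       report = tr$report)
}
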