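#' Train a codon-usage log-odds model
#'
#' Estimates preferential codon usage from contigs whose reading frame was
#' fixed by the homology tiers, then scores codons as
#' `log(coding frequency / background probability)`, the background being
#' an independent mononucleotide model fitted on the full training
#' sequences. For each training contig the longest stop-free codon run in
#' the called frame is counted; codons containing ambiguity characters
#' are skipped. Uniform codon counts against a uniform background give
#' all-zero log-odds; the pseudocount keeps every entry finite.
#'
#' @param contigs Contig data frame (`id`, `sequence`).
#' @param calls Frame-call data frame with `contig_id`, `frame`, `tier`;
#'   only tiers `strict` and `relaxed` are used for training.
#' @param pseudocount Positive smoothing count added per codon and per
#'   base (default 1).
#' @return Object of class `codon_model`: `log_odds` (64 entries),
#'   `coding_freq`, `background` (4 base probabilities), `pseudocount`,
#'   `training_codons`.
#' @export
train_codon_model <- function(contigs, calls, pseudocount = 1) {
  if (pseudocount <= 0) stop("'pseudocount' must be positive", call. = FALSE)
  use <- calls[calls$tier %in% c("strict", "relaxed") & !is.na(calls$frame),
               , drop = FALSE]
  if (!nrow(use))
    stop("no homology-tier frame calls available for training",
         call. = FALSE)
  seq_of <- setNames(contigs$sequence, contigs$id)
  missing_ids <- setdiff(use$contig_id, contigs$id)
  if (length(missing_ids))
    stop("calls reference unknown contig(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)

  counts <- setNames(numeric(64), all_codons())
  bg_counts <- setNames(numeric(4), c("A", "C", "G", "T"))
  stops <- stop_codons()
  for (i in seq_len(nrow(use))) {
    s <- seq_of[[use$contig_id[i]]]
    cods <- codons_in_frame(s, use$frame[i])
    if (!length(cods)) next
    is_stop <- cods %in% stops
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    open <- which(!r$values)
    if (length(open)) {
      k <- open[which.max(r$lengths[open])]
      run <- cods[starts[k]:ends[k]]
      run <- run[run %in% names(counts)]   # drop ambiguous codons
      if (length(run)) {
        tab <- table(run)
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
    }
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    tab <- table(ch[ch %in% names(bg_counts)])
    bg_counts[names(tab)] <- bg_counts[names(tab)] + as.numeric(tab)
  }
  training_codons <- sum(counts)
  if (training_codons == 0)
    stop("zero training codons counted", call. = FALSE)

  coding_freq <- (counts + pseudocount) / sum(counts + pseudocount)
  background <- (bg_counts + pseudocount) / sum(bg_counts + pseudocount)
  b1 <- substr(names(counts), 1, 1)
  b2 <- substr(names(counts), 2, 2)
  b3 <- substr(names(counts), 3, 3)
  bg_codon <- background[b1] * background[b2] * background[b3]
  log_odds <- setNames(log(coding_freq / bg_codon), names(counts))

  structure(list(log_odds = log_odds, coding_freq = coding_freq,
                 background = background, pseudocount = pseudocount,
                 training_codons = as.integer(training_codons)),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("codon_model trained on %d codons (pseudocount %g)\n",
              x$training_codons, x$pseudocount))
  cat(sprintf("  log-odds range [%.2f, %.2f], background A/C/G/T = %s\n",
              min(x$log_odds), max(x$log_odds),
              paste(sprintf("%.3f", x$background), collapse = "/")))
  invisible(x)
}
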