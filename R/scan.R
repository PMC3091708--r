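# Best-scoring contiguous window of at least min_len entries.
# Prefix sums with a lagged cumulative minimum give the optimum in O(n).
best_window_minlen <- function(v, min_len) {
  n <- length(v)
  if (n < min_len) return(NULL)
  S <- c(0, cumsum(v))
  M <- cummin(S[seq_len(n - min_len + 1L)])
  cand <- S[(min_len + 1L):(n + 1L)] - M
  j <- which.max(cand)
  e <- min_len + j - 1L
  i <- which.min(S[seq_len(e - min_len + 1L)])
  list(score = cand[j], start = i, end = e)
}

# Best coding window across all six frames: for each frame, stop codons
# break the sequence into stop-free segments; within each segment long
# enough to yield min_peptide residues, the maximum-sum window of at
# least min_peptide codons is taken (ambiguous codons score 0 and do not
# break windows). Returns NULL when no frame offers an eligible window.
scan_best <- function(sequence, model, min_peptide = 30L) {
  s <- toupper(sequence)
  stops <- stop_codons()
  best <- NULL
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    cods <- codons_in_frame(s, fr)
    if (length(cods) < min_peptide) next
    lo <- unname(model$log_odds[cods])
    lo[is.na(lo)] <- 0
    is_stop <- cods %in% stops
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values & r$lengths >= min_peptide)) {
      w <- best_window_minlen(lo[starts[k]:ends[k]], min_peptide)
      if (is.null(best) || w$score > best$score) {
        best <- list(frame = fr, score = w$score,
                     codon_start = starts[k] + w$start - 1L,
                     codon_end = starts[k] + w$end - 1L,
                     codons = cods)
      }
    }
  }
  best
}

#' Codon-usage coding scan of a contig
#'
#' Six-frame scan against a trained codon log-odds model: in every frame
#' the best stop-free window of at least `min_peptide` codons is summed,
#' and the top-scoring frame is called when its score reaches
#' `score_threshold`; otherwise the contig stays unassigned. Contigs
#' shorter than `3 * min_peptide` bases are unassigned by construction
#' (not an error).
#'
#' @param sequence A single nucleotide sequence.
#' @param model A [train_codon_model()] object.
#' @param min_peptide Minimum peptide length, in residues (default 30).
#' @param score_threshold Minimum summed log-odds for a call; see
#'   [calibrate_scan_threshold()] for the null-based default used by the
#'   cascade.
#' @return List with `frame`, `tier` (`"scan"` or `"unassigned"`),
#'   `score`, and `peptide` (NA when unassigned).
#' @export
scan_coding <- function(sequence, model, min_peptide = 30L,
                        score_threshold) {
  stopifnot(inherits(model, "codon_model"))
  if (min_peptide < 1) stop("'min_peptide' must be >= 1", call. = FALSE)
  unassigned <- list(frame = NA_integer_, tier = "unassigned",
                     score = NA_real_, peptide = NA_character_)
  if (nchar(sequence) < 3L * min_peptide) return(unassigned)
  best <- scan_best(sequence, model, min_peptide)
  if (is.null(best)) return(unassigned)
  if (best$score < score_threshold) {
    unassigned$score <- best$score
    return(unassigned)
  }
  aa <- unname(genetic_code()[best$codons[best$codon_start:best$codon_end]])
  aa[is.na(aa)] <- "X"
  list(frame = best$frame, tier = "scan", score = best$score,
       peptide = paste(aa, collapse = ""))
}

#' Calibrate the coding-scan score threshold on a simulated null
#'
#' Draws sequences from the model's mononucleotide background, scores
#' each with the same best-window statistic the scan uses, and returns
#' the requested quantile (default the 99th percentile) as the score
#' threshold. Null draws with no eligible window score `-Inf`.
#'
#' @param model A [train_codon_model()] object.
#' @param n Number of null sequences (default 500).
#' @param len Null sequence length in bases (default 600).
#' @param p Quantile used as threshold (default 0.99).
#' @param min_peptide Minimum peptide length, matching the scan.
#' @param seed Integer seed for the null draws.
#' @return Object of class `scan_null`: `threshold`, `scores`, `n`,
#'   `len`, `p`.
#' @export
calibrate_scan_threshold <- function(model, n = 500L, len = 600L,
                                     p = 0.99, min_peptide = 30L,
                                     seed = 1L) {
  stopifnot(inherits(model, "codon_model"))
  set.seed(derive_seed(seed, 4))
  probs <- model$background
  scores <- vapply(seq_len(n), function(i) {
    s <- random_dna(len, probs)
    b <- scan_best(s, model, min_peptide)
    if (is.null(b)) -Inf else b$score
  }, numeric(1))
  fin <- scores[is.finite(scores)]
  threshold <- if (length(fin)) {
    unname(quantile(scores, p, names = FALSE))
  } else {
    Inf
  }
  structure(list(threshold = threshold, scores = scores, n = as.integer(n),
                 len = as.integer(len), p = p),
            class = "scan_null")
}

#' @export
print.scan_null <- function(x, ...) {
  cat(sprintf(
    "scan_null: threshold %.2f (%.0fth percentile of %d draws of %d nt)\n",
    x$threshold, 100 * x$p, x$n, x$len))
  invisible(x)
}
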