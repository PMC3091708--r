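#' Three-tier reading-frame cascade
#'
#' The frame-annotation triage: (1) a strict homology tier at
#' `tier1_e = 1e-6`; (2) a relaxed homology tier at `tier2_e = 1e-2` over
#' the remaining queries; (3) a codon-usage coding scan over everything
#' still unassigned, with the scoring model trained on the frames fixed
#' by tiers 1-2 and, unless a threshold is supplied, a score cutoff
#' calibrated as the 99th percentile of a simulated background null.
#' Every contig ends in exactly one of the four buckets strict / relaxed
#' / scan / unassigned.
#'
#' @param contigs Preprocessed (kept) contig data frame.
#' @param hits_tier1 Ranked hit table for the strict search.
#' @param hits_tier2 Ranked hit table for the relaxed re-query (defaults
#'   to the same table).
#' @param tier1_e,tier2_e E-value cutoffs of the two homology tiers.
#' @param min_peptide Minimum peptide length for a scan call (default 30
#'   residues).
#' @param pseudocount Codon-model smoothing (see [train_codon_model()]).
#' @param score_threshold Scan score cutoff; `NULL` (default) calibrates
#'   it from the null (see [calibrate_scan_threshold()]).
#' @param null_n,null_len Size and sequence length of the calibration
#'   null; `null_len = NULL` uses the median contig length.
#' @param seed Integer seed for the null calibration.
#' @return List with `calls` (one row per contig: `contig_id`, `tier`,
#'   `frame`, `support`, `peptide`, `peptide_length`), `accounting`
#'   (per-tier counts and their sum), `model`, `score_threshold`, and
#'   `null` (the calibration object or `NULL`).
#' @export
run_cascade <- function(contigs, hits_tier1, hits_tier2 = hits_tier1,
                        tier1_e = 1e-6, tier2_e = 1e-2,
                        min_peptide = 30L, pseudocount = 1,
                        score_threshold = NULL, null_n = 300L,
                        null_len = NULL, seed = 1L) {
  h1 <- hits_tier1[hits_tier1$qseqid %in% contigs$id, , drop = FALSE]
  t1 <- assign_frames_homology(h1, tier1_e, "strict")
  rem1 <- setdiff(contigs$id, t1$calls$contig_id)
  h2 <- hits_tier2[hits_tier2$qseqid %in% rem1, , drop = FALSE]
  t2 <- assign_frames_homology(h2, tier2_e, "relaxed")
  hom <- rbind(t1$calls, t2$calls)
  rem2 <- setdiff(contigs$id, hom$contig_id)

  model <- NULL
  null <- NULL
  scan_rows <- NULL
  if (!nrow(hom)) {
    warning("no homology-tier calls; coding scan skipped", call. = FALSE)
    score_threshold <- NA_real_
  } else {
    model <- train_codon_model(contigs, hom, pseudocount)
    if (is.null(score_threshold)) {
      if (is.null(null_len))
        null_len <- as.integer(round(stats::median(nchar(contigs$sequence))))
      null <- calibrate_scan_threshold(model, n = null_n, len = null_len,
                                       min_peptide = min_peptide,
                                       seed = seed)
      score_threshold <- null$threshold
    }
    if (length(rem2)) {
      seq_of <- setNames(contigs$sequence, contigs$id)
      scan_rows <- lapply(rem2, function(id) {
        r <- scan_coding(seq_of[[id]], model, min_peptide, score_threshold)
        data.frame(contig_id = id, frame = r$frame, tier = r$tier,
                   support = r$score, peptide = r$peptide,
                   stringsAsFactors = FALSE)
      })
      scan_rows <- do.call(rbind, c(scan_rows, list(make.row.names = FALSE)))
    }
  }

  seq_of <- setNames(contigs$sequence, contigs$id)
  cols <- c("contig_id", "frame", "tier", "support", "peptide")
  if (nrow(hom)) {
    hom$peptide <- vapply(seq_len(nrow(hom)), function(i) {
      peptide_in_frame(seq_of[[hom$contig_id[i]]], hom$frame[i])
    }, character(1))
    hom <- hom[cols]
  } else {
    hom <- data.frame(contig_id = character(), frame = integer(),
                      tier = character(), support = numeric(),
                      peptide = character(), stringsAsFactors = FALSE)
  }
  if (is.null(scan_rows)) {
    left <- setdiff(contigs$id, hom$contig_id)
    scan_rows <- data.frame(contig_id = left,
                            frame = rep(NA_integer_, length(left)),
                            tier = rep("unassigned", length(left)),
                            support = rep(NA_real_, length(left)),
                            peptide = rep(NA_character_, length(left)),
                            stringsAsFactors = FALSE)
  }

  calls <- rbind(hom, scan_rows[cols])
  calls <- calls[match(contigs$id, calls$contig_id), , drop = FALSE]
  row.names(calls) <- NULL
  calls$peptide_length <- ifelse(is.na(calls$peptide), 0L,
                                 nchar(calls$peptide))

  tiers <- table(factor(calls$tier,
                        levels = c("strict", "relaxed", "scan",
                                   "unassigned")))
  accounting <- list(
    n_strict = unname(tiers[["strict"]]),
    n_relaxed = unname(tiers[["relaxed"]]),
    n_scan = unname(tiers[["scan"]]),
    n_unassigned = unname(tiers[["unassigned"]]),
    total_translated = unname(tiers[["strict"]] + tiers[["relaxed"]] +
                                tiers[["scan"]])
  )
  list(calls = calls, accounting = accounting, model = model,
       score_threshold = score_threshold, null = null)
}
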