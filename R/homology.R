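# Validates the per-query hit invariants: ranks consecutive from 1 in
# row order and E-values non-decreasing with rank. Errors name the query.
validate_hit_table <- function(hits) {
  if (!nrow(hits)) return(invisible(hits))
  if (!"rank" %in% names(hits))
    hits$rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                            FUN = seq_along)
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    if (!identical(as.integer(h$rank), seq_len(nrow(h))))
      stop("malformed hit ranks for query ", q, call. = FALSE)
    if (is.unsorted(h$evalue))
      stop("E-values not non-decreasing with rank for query ", q,
           call. = FALSE)
  }
  invisible(hits)
}

#' Assign reading frames from ranked homology hits
#'
#' A query is assigned when at least one of its hits reaches the E-value
#' cutoff; the frame is taken from the qualifying hit with the lowest
#' E-value (ties broken by higher bit score, then lower rank). The
#' assigned and unassigned queries partition the hit-bearing queries.
#'
#' @param hits Hit data frame (with or without a `rank` column; rank is
#'   row order within each query).
#' @param e_cutoff E-value cutoff; the strict tier uses `1e-6`, the
#'   relaxed re-query tier `1e-2`.
#' @param tier Tier label stamped on the calls (`"strict"` or
#'   `"relaxed"`).
#' @return List with `calls` (data frame `contig_id`, `frame`, `tier`,
#'   `support` = best E-value, `subject_id`) and `unassigned` (query ids
#'   with hits but none qualifying).
#' @export
assign_frames_homology <- function(hits, e_cutoff, tier = "strict") {
  if (!is.finite(e_cutoff) || e_cutoff <= 0)
    stop("'e_cutoff' must be positive", call. = FALSE)
  empty <- data.frame(contig_id = character(), frame = integer(),
                      tier = character(), support = numeric(),
                      subject_id = character(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(list(calls = empty, unassigned = character(0)))
  if (!"rank" %in% names(hits))
    hits$rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                            FUN = seq_along)
  validate_hit_table(hits)
  qual <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  if (!nrow(qual))
    return(list(calls = empty, unassigned = unique(hits$qseqid)))
  ord <- order(qual$qseqid, qual$evalue, -qual$bitscore, qual$rank)
  qual <- qual[ord, , drop = FALSE]
  best <- qual[!duplicated(qual$qseqid), , drop = FALSE]
  calls <- data.frame(contig_id = best$qseqid,
                      frame = as.integer(best$sframe),
                      tier = tier,
                      support = best$evalue,
                      subject_id = best$sseqid,
                      stringsAsFactors = FALSE)
  list(calls = calls,
       unassigned = setdiff(unique(hits$qseqid), calls$contig_id))
}
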