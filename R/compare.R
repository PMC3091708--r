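#' Filter cross-database protein matches
#'
#' An A-side protein counts as matched when it carries a domain
#' annotation, and at least one of its hits lands on a domain-annotated
#' B-side subject with `evalue <= e_cutoff` and
#' `bitscore >= bit_threshold` (both boundaries inclusive). The matched
#' set can only shrink as the bit threshold rises.
#'
#' @param hits Hit table keyed by A-side queries (`qseqid`, `sseqid`,
#'   `evalue`, `bitscore`).
#' @param annotated_a,annotated_b Ids of domain-annotated proteins on
#'   each side.
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @param bit_threshold Bit-score floor (the screen uses 90, 120, 200).
#' @return Sorted character vector of matched A-side protein ids.
#' @export
filter_matches <- function(hits, annotated_a, annotated_b,
                           e_cutoff = 1e-5, bit_threshold = 120) {
  keep <- hits$qseqid %in% annotated_a &
    hits$sseqid %in% annotated_b &
    hits$evalue <= e_cutoff &
    hits$bitscore >= bit_threshold
  sort(unique(hits$qseqid[keep]))
}

#' Per-category shared-annotation percentages
#'
#' For each reporting category, the percentage of one database's
#' annotated products that are shared with the other:
#' `100 * shared / total`, rounded half-up to one decimal. Categories
#' with `total = 0` report `NA`.
#'
#' @param totals Named numeric vector: per-category product counts in the
#'   query database.
#' @param shared Named numeric vector over the same categories: products
#'   also matched in the subject database. Must not exceed `totals`.
#' @return Data frame (`category`, `total`, `shared`,
#'   `shared_percentage`).
#' @export
shared_go_table <- function(totals, shared) {
  if (is.null(names(totals)) || is.null(names(shared)))
    stop("'totals' and 'shared' must be named by category", call. = FALSE)
  shared <- shared[names(totals)]
  shared[is.na(shared)] <- 0
  if (any(shared > totals))
    stop("shared count exceeds total for: ",
         paste(names(totals)[shared > totals], collapse = ", "),
         call. = FALSE)
  pct <- ifelse(totals > 0, round_half_up(100 * shared / totals, 1),
                NA_real_)
  data.frame(category = names(totals), total = unname(totals),
             shared = unname(shared), shared_percentage = unname(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Shared annotation categories between two protein sets
#'
#' Convenience composition for the two-database comparison: category
#' counts (via [propagate_counts()]) over all annotated A-side products
#' and over the matched subset, then the shared-percentage table.
#'
#' @param products_a All A-side product ids under comparison.
#' @param matched Matched subset (e.g. from [filter_matches()]).
#' @param assignments Term assignments (`product_id`, `term_id`) for the
#'   A side.
#' @param dag An [ontology_dag].
#' @param report_depth Category depth below the namespace roots.
#' @return Data frame as [shared_go_table()], plus `namespace` and
#'   `name` columns.
#' @export
shared_go_categories <- function(products_a, matched, assignments, dag,
                                 report_depth = 1L) {
  if (!all(matched %in% products_a))
    stop("'matched' must be a subset of 'products_a'", call. = FALSE)
  asg_a <- assignments[assignments$product_id %in% products_a, ,
                       drop = FALSE]
  asg_m <- assignments[assignments$product_id %in% matched, ,
                       drop = FALSE]
  tot <- propagate_counts(asg_a, dag, report_depth)
  shr <- propagate_counts(asg_m, dag, report_depth)
  totals <- setNames(tot$count, tot$term_id)
  shared <- setNames(shr$count, shr$term_id)[names(totals)]
  shared[is.na(shared)] <- 0
  out <- shared_go_table(totals, shared)
  out$namespace <- tot$namespace[match(out$category, tot$term_id)]
  out$name <- tot$name[match(out$category, tot$term_id)]
  out[, c("namespace", "category", "name", "total", "shared",
          "shared_percentage")]
}
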