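#' Assembly and annotation accounting
#'
#' The standard summary of an EST assembly-and-triage run: contig totals
#' partitioned by read support (singletons, two-read, more-than-two-read)
#' and transcript totals partitioned by frame-assignment tier. Internal
#' sums are verified and any mismatch flagged.
#'
#' @param contigs Contig data frame carrying `read_count`.
#' @param calls Frame-call data frame carrying `tier` (see
#'   [run_cascade()]).
#' @return Object of class `assembly_summary` (a named list of counts
#'   with logical `partition_ok` / `tiers_ok` flags).
#' @export
assembly_summary <- function(contigs, calls) {
  n <- nrow(contigs)
  n1 <- sum(contigs$read_count == 1L)
  n2 <- sum(contigs$read_count == 2L)
  n3 <- sum(contigs$read_count > 2L)
  tiers <- table(factor(calls$tier,
                        levels = c("strict", "relaxed", "scan",
                                   "unassigned")))
  total <- unname(tiers[["strict"]] + tiers[["relaxed"]] + tiers[["scan"]])
  structure(list(
    n_contigs = n,
    n_singletons = n1,
    n_two_read = n2,
    n_gt_two_read = n3,
    n_strict = unname(tiers[["strict"]]),
    n_relaxed = unname(tiers[["relaxed"]]),
    n_scan = unname(tiers[["scan"]]),
    n_unassigned = unname(tiers[["unassigned"]]),
    total_transcripts = total,
    partition_ok = (n1 + n2 + n3) == n,
    tiers_ok = (total + unname(tiers[["unassigned"]])) == nrow(calls)
  ), class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",")
  cat("Assembly and annotation summary\n")
  cat(sprintf("  Contigs:            %s\n", fmt(x$n_contigs)))
  cat(sprintf("    singletons:       %s\n", fmt(x$n_singletons)))
  cat(sprintf("    with 2 reads:     %s\n", fmt(x$n_two_read)))
  cat(sprintf("    with > 2 reads:   %s\n", fmt(x$n_gt_two_read)))
  cat(sprintf("  Strict homology:    %s\n", fmt(x$n_strict)))
  cat(sprintf("  Relaxed homology:   %s\n", fmt(x$n_relaxed)))
  cat(sprintf("  Coding scan:        %s\n", fmt(x$n_scan)))
  cat(sprintf("  Total transcripts:  %s\n", fmt(x$total_transcripts)))
  if (!x$partition_ok || !x$tiers_ok)
    cat("  WARNING: internal sums do not reconcile\n")
  invisible(x)
}

#' Run the full synthetic annotation-triage pipeline
#'
#' Generates every input (contigs with ground truth, ranked hits,
#' ontology, taxonomy, term assignments), then executes preprocessing,
#' the three-tier frame cascade, ontology propagation counting, the
#' bacterial rank-curve screen, and the assembly summary. With a fixed
#' seed the run is byte-reproducible; when `outdir` is given, every
#' stage output is written there (FASTA / TSV / OBO / taxonomy dump plus
#' a JSON manifest whose only non-reproducible field is the timestamp).
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param n_ontology_terms,taxonomy_depth Sizes of the synthetic ontology
#'   and taxonomy.
#' @return Invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL, n_ontology_terms = 120L,
                         taxonomy_depth = 4L) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_contigs(config)
  taxonomy <- simulate_taxonomy(depth = taxonomy_depth, seed = config$seed)
  dag <- simulate_ontology(n_ontology_terms, seed = config$seed)
  hits <- simulate_hits(sim$contigs, sim$truth, config, taxonomy)

  pre <- preprocess_contigs(sim$contigs, adapters = config$adapter_sequence)
  hits_kept <- hits[hits$qseqid %in% pre$contigs$id, , drop = FALSE]
  casc <- run_cascade(pre$contigs, hits_kept,
                      seed = derive_seed(config$seed, 7))

  translated <- casc$calls$contig_id[casc$calls$tier != "unassigned"]
  go <- simulate_go_assignments(translated, dag,
                                seed = derive_seed(config$seed, 8))
  go_report <- propagate_counts(go, dag)
  curve <- bacterial_rank_curve(hits_kept, taxonomy)
  plateau <- detect_plateau(curve)
  summ <- assembly_summary(pre$contigs, casc$calls)

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("ventannot")),
    config = config[setdiff(names(config), "codon_usage")],
    counts = list(
      contigs_generated = nrow(sim$contigs),
      contigs_kept = nrow(pre$contigs),
      contigs_discarded = nrow(pre$discarded),
      hit_rows = nrow(hits),
      strict = casc$accounting$n_strict,
      relaxed = casc$accounting$n_relaxed,
      scan = casc$accounting$n_scan,
      unassigned = casc$accounting$n_unassigned,
      total_translated = casc$accounting$total_translated,
      go_assigned_products = length(unique(go$product_id)),
      bacterial_plateau_value = plateau$plateau_value
    ),
    score_threshold = casc$score_threshold
  )
  conserved <- manifest$counts$contigs_kept +
    manifest$counts$contigs_discarded == manifest$counts$contigs_generated
  if (!conserved)
    stop("stage accounting violated: kept + discarded != generated",
         call. = FALSE)

  result <- list(contigs_raw = sim$contigs, truth = sim$truth,
                 taxonomy = taxonomy, dag = dag, hits = hits,
                 preprocessed = pre, cascade = casc,
                 go_assignments = go, go_report = go_report,
                 curve = curve, plateau = plateau, summary = summ,
                 manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(setNames(result$contigs_raw$sequence, result$contigs_raw$id),
              p("contigs_raw.fasta"))
  write_fasta(setNames(result$preprocessed$contigs$sequence,
                       result$preprocessed$contigs$id),
              p("contigs_clean.fasta"))
  write_truth(result$truth, p("truth.tsv"))
  write_hit_table(result$hits, p("hits.tsv"))
  write_obo(result$dag, p("ontology.obo"))
  write_taxdump(result$taxonomy, p("nodes.dmp"), p("names.dmp"))
  write.table(result$preprocessed$report, p("preprocess_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- result$cascade$calls
  write.table(calls[, c("contig_id", "tier", "frame", "support",
                        "peptide_length")],
              p("frame_calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  pep <- calls[calls$tier != "unassigned" & calls$peptide_length > 0, ,
               drop = FALSE]
  if (nrow(pep))
    write_fasta(setNames(pep$peptide, pep$contig_id), p("peptides.fasta"))
  write.table(result$go_report, p("go_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  curve_df <- data.frame(rank = seq_along(result$curve$f),
                         f = result$curve$f,
                         increment = result$curve$increments)
  write.table(curve_df, p("rank_curve.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- result$summary
  write.table(data.frame(key = names(unclass(s)),
                         value = unlist(lapply(unclass(s), as.character))),
              p("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
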