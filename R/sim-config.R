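#' Default codon-usage table for synthetic coding regions
#'
#' A 64-entry joint frequency table over codons (summing to 1; stop codons
#' carry zero mass). The amino-acid marginal follows a typical animal
#' proteome composition; within each synonymous family, codons are skewed
#' geometrically (ratio 1/2 in the fixed codon-table order) so that coding
#' sequence is clearly distinguishable from a mononucleotide background.
#'
#' @return Named numeric vector of length 64 (names are DNA codons).
#' @export
default_codon_usage <- function() {
  code <- genetic_code()
  aa_freq <- c(
    A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, E = 0.058,
    Q = 0.037, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
    M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
    Y = 0.033, V = 0.068
  )
  aa_freq <- aa_freq / sum(aa_freq)
  usage <- setNames(numeric(length(code)), names(code))
  for (aa in names(aa_freq)) {
    fam <- names(code)[code == aa]
    w <- 0.5^(seq_along(fam) - 1)
    usage[fam] <- aa_freq[[aa]] * w / sum(w)
  }
  usage
}

#' Configuration for the synthetic EST generators
#'
#' Bundles and validates every parameter of the synthetic-data module:
#' contig architecture (planted coding regions drawn from a codon-usage
#' table, flanking UTRs, poly-A tails, adapter contamination, rare `N`
#' calls), the ranked homology-hit model, and the taxonomic composition of
#' hit subjects. A fixed `seed` makes every generator byte-reproducible.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_contigs Number of contigs to emit.
#' @param coding_fraction Proportion of contigs carrying a planted coding
#'   region (reading frame ground truth).
#' @param codon_usage 64-entry non-negative frequency table over codons,
#'   summing to 1; mass on stop codons is ignored for interior codons.
#' @param orf_length_range Planted coding length range, in codons.
#' @param utr_length_range Flanking UTR length range, in base pairs.
#' @param polya_rate Proportion of contigs carrying a 3' poly-A run.
#' @param polya_length_range Poly-A run length range, in base pairs.
#' @param adapter_sequence Adapter oligo planted at contig ends. The
#'   default is a 24-nt SMART-style oligo; a length divisible by 3 keeps
#'   planted frames invariant under full-adapter end trims.
#' @param adapter_rate Probability that each end carries the adapter.
#' @param n_rate Per-base rate of ambiguous `N` calls (exercises
#'   degenerate-input handling downstream).
#' @param hit_fraction Proportion of coding contigs that receive ranked
#'   homology hits.
#' @param bacterial_fraction Proportion of hit-bearing contigs whose true
#'   source superkingdom is Bacteria.
#' @param frame_noise Probability that an individual hit reports a wrong
#'   frame.
#' @param hit_depth Maximum ranked hits per query (the screen assesses the
#'   best 25 hits).
#' @param evalue_decay Positive rate of exponential E-value growth with
#'   hit rank.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_contigs = 625L,
                       coding_fraction = 0.8,
                       codon_usage = default_codon_usage(),
                       orf_length_range = c(120L, 300L),
                       utr_length_range = c(30L, 150L),
                       polya_rate = 0.3,
                       polya_length_range = c(12L, 30L),
                       adapter_sequence = "AAGCAGTGGTATCAACGCAGAGTA",
                       adapter_rate = 0.25,
                       n_rate = 0.001,
                       hit_fraction = 0.6,
                       bacterial_fraction = 0.3,
                       frame_noise = 0.05,
                       hit_depth = 25L,
                       evalue_decay = 1.5) {
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single finite integer 'seed' is required", call. = FALSE)
  props <- c(coding_fraction = coding_fraction, polya_rate = polya_rate,
             adapter_rate = adapter_rate, n_rate = n_rate,
             hit_fraction = hit_fraction,
             bacterial_fraction = bacterial_fraction,
             frame_noise = frame_noise)
  bad <- props[!is.finite(props) | props < 0 | props > 1]
  if (length(bad))
    stop("proportions must lie in [0, 1]: ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  if (length(codon_usage) != 64 || is.null(names(codon_usage)) ||
      !setequal(names(codon_usage), all_codons()))
    stop("'codon_usage' must be a named 64-entry table over DNA codons",
         call. = FALSE)
  codon_usage <- codon_usage[all_codons()]
  if (any(!is.finite(codon_usage)) || any(codon_usage < 0) ||
      sum(codon_usage) <= 0)
    stop("'codon_usage' entries must be non-negative with positive total",
         call. = FALSE)
  codon_usage <- codon_usage / sum(codon_usage)
  if (n_contigs < 0) stop("'n_contigs' must be non-negative", call. = FALSE)
  if (nchar(adapter_sequence) < 10)
    stop("'adapter_sequence' must be at least 10 nt", call. = FALSE)
  if (!is.finite(evalue_decay) || evalue_decay <= 0)
    stop("'evalue_decay' must be positive", call. = FALSE)
  if (hit_depth < 1) stop("'hit_depth' must be at least 1", call. = FALSE)
  for (rng in list(orf_length_range, utr_length_range, polya_length_range)) {
    if (length(rng) != 2 || any(rng < 0) || rng[1] > rng[2])
      stop("length ranges must be non-decreasing pairs of non-negative values",
           call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    coding_fraction = coding_fraction,
    codon_usage = codon_usage,
    orf_length_range = as.integer(orf_length_range),
    utr_length_range = as.integer(utr_length_range),
    polya_rate = polya_rate,
    polya_length_range = as.integer(polya_length_range),
    adapter_sequence = toupper(adapter_sequence),
    adapter_rate = adapter_rate,
    n_rate = n_rate,
    hit_fraction = hit_fraction,
    bacterial_fraction = bacterial_fraction,
    frame_noise = frame_noise,
    hit_depth = as.integer(hit_depth),
    evalue_decay = evalue_decay
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EST simulation config\n")
  cat(sprintf("  seed %d, %d contigs (%.0f%% coding, %.0f%% of coding with hits)\n",
              x$seed, x$n_contigs, 100 * x$coding_fraction,
              100 * x$hit_fraction))
  cat(sprintf("  bacterial fraction %.2f, hit depth %d, frame noise %.2f\n",
              x$bacterial_fraction, x$hit_depth, x$frame_noise))
  invisible(x)
}
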