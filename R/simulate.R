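#' Simulate assembled contigs with planted coding regions
#'
#' Emits a contig set emulating a de novo 454 EST assembly, together with
#' per-contig ground truth. A coding contig is built as
#' `5'UTR + coding stretch + 3'UTR (+ poly-A)`, the coding stretch drawn
#' codon-by-codon from the configured codon-usage table and terminated by
#' a stop codon; the whole transcript is reverse-complemented with
#' probability 1/2 (negative planted frames, poly-A becoming a 5' poly-T
#' run), and each end then carries the adapter oligo with probability
#' `adapter_rate`. Non-coding contigs are uniform random sequence subject
#' to the same poly-A/adapter contamination. Ambiguous `N` calls are
#' injected at rate `n_rate` after truth coordinates are fixed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `contigs` (data frame: `id`, `sequence`,
#'   `read_count`, `status`) and `truth` (data frame: `id`, `coding`,
#'   `frame` with NA for non-coding, `cds_start`/`cds_end` 0-based
#'   half-open on the emitted sequence, `hit_bearing`, `superkingdom`).
#' @export
simulate_contigs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 0))
  n <- config$n_contigs
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  p_sense <- config$codon_usage[sense]
  if (config$coding_fraction > 0 && n > 0 && sum(p_sense) <= 0)
    stop("codon-usage table assigns no mass to sense codons", call. = FALSE)
  if (sum(p_sense) > 0) p_sense <- p_sense / sum(p_sense)

  n_coding <- round(n * config$coding_fraction)
  is_coding <- rep(FALSE, n)
  if (n_coding > 0) is_coding[sample.int(n, n_coding)] <- TRUE

  ids <- sprintf("contig%05d", seq_len(n))
  sequence <- character(n)
  frame <- rep(NA_integer_, n)
  cds_start <- rep(NA_integer_, n)
  cds_end <- rep(NA_integer_, n)
  ad <- config$adapter_sequence
  ad_len <- nchar(ad)

  for (i in seq_len(n)) {
    if (is_coding[i]) {
      n_cod <- sample_range(config$orf_length_range[1], config$orf_length_range[2])
      orf <- paste(c(sample(sense, n_cod - 1, replace = TRUE, prob = p_sense),
                     sample(stops, 1)), collapse = "")
      utr5 <- random_dna(sample_range(config$utr_length_range[1], config$utr_length_range[2]))
      utr3 <- random_dna(sample_range(config$utr_length_range[1], config$utr_length_range[2]))
      s <- paste0(utr5, orf, utr3)
      s_orf <- nchar(utr5)                 # 0-based
      e_orf <- s_orf + nchar(orf)
      if (runif(1) < config$polya_rate)
        s <- paste0(s, strrep("A", sample_range(config$polya_length_range[1], config$polya_length_range[2])))
      minus <- runif(1) < 0.5
      if (minus) {
        L <- nchar(s)
        s <- revcomp(s)
        tmp <- s_orf
        s_orf <- L - e_orf
        e_orf <- L - tmp
      }
      if (runif(1) < config$adapter_rate) {
        s <- paste0(ad, s)
        s_orf <- s_orf + ad_len
        e_orf <- e_orf + ad_len
      }
      if (runif(1) < config$adapter_rate) s <- paste0(s, ad)
      frame[i] <- if (minus) {
        -(((nchar(s) - e_orf) %% 3L) + 1L)
      } else {
        (s_orf %% 3L) + 1L
      }
      cds_start[i] <- s_orf
      cds_end[i] <- e_orf
    } else {
      s <- random_dna(sample_range(300L, 900L))
      if (runif(1) < config$polya_rate)
        s <- paste0(s, strrep("A", sample_range(config$polya_length_range[1], config$polya_length_range[2])))
      if (runif(1) < config$adapter_rate) s <- paste0(ad, s)
      if (runif(1) < config$adapter_rate) s <- paste0(s, ad)
    }
    if (config$n_rate > 0) {
      pos <- which(runif(nchar(s)) < config$n_rate)
      if (length(pos)) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[pos] <- "N"
        s <- paste(ch, collapse = "")
      }
    }
    sequence[i] <- s
  }

  u <- runif(n)
  read_count <- ifelse(u < 0.04, 1L, ifelse(u < 0.43, 2L, 3L + rpois(n, 4)))
  hit_bearing <- is_coding & runif(n) < config$hit_fraction
  superkingdom <- ifelse(hit_bearing & runif(n) < config$bacterial_fraction,
                         "Bacteria", "Eukaryota")

  list(
    contigs = data.frame(id = ids, sequence = sequence,
                         read_count = as.integer(read_count),
                         status = "kept", stringsAsFactors = FALSE),
    truth = data.frame(id = ids, coding = is_coding, frame = frame,
                       cds_start = cds_start, cds_end = cds_end,
                       hit_bearing = hit_bearing,
                       superkingdom = superkingdom,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate ranked homology-hit tables
#'
#' Each hit-bearing contig (per the ground truth) receives 5..`hit_depth`
#' ranked hits. E-values grow exponentially with rank at rate
#' `evalue_decay` from a best E-value whose log10 is uniform on
#' (-30, 0); bit scores decrease monotonically with rank. Hit frames equal
#' the true planted frame except for a `frame_noise` fraction flipped to a
#' random other frame. For contigs of bacterial origin the best bacterial
#' hit rank is drawn geometrically within 1..20 and later hits mix both
#' superkingdoms; eukaryote-origin contigs receive only eukaryote
#' subjects.
#'
#' @param contigs,truth Output of [simulate_contigs()].
#' @param config A [sim_config()] object.
#' @param taxonomy A [taxonomy_table] from [simulate_taxonomy()]; hit
#'   subject taxa are drawn from its Bacteria/Eukaryota tips.
#' @return Hit data frame in the extended tabular dialect (see
#'   [write_hit_table()]) plus a `rank` column.
#' @export
simulate_hits <- function(contigs, truth, config, taxonomy) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(contigs$id, truth$id))
    stop("contigs and truth must be aligned by identifier", call. = FALSE)
  set.seed(derive_seed(config$seed, 1))
  bact <- taxonomy_tips(taxonomy, "Bacteria")
  euk <- taxonomy_tips(taxonomy, "Eukaryota")
  frames_all <- c(1L, 2L, 3L, -1L, -2L, -3L)
  rows <- vector("list", nrow(contigs))
  for (i in which(truth$hit_bearing)) {
    k <- sample_range(min(5L, config$hit_depth), config$hit_depth)
    ev <- signif(pmin(10, 10^runif(1, -30, 0) *
                        exp(config$evalue_decay * (0:(k - 1)))), 4)
    bits <- round(pmax(35, 40 - 2 * log10(ev)), 1)
    fr <- rep(truth$frame[i], k)
    flip <- which(runif(k) < config$frame_noise)
    for (j in flip) fr[j] <- sample(setdiff(frames_all, truth$frame[i]), 1)
    if (truth$superkingdom[i] == "Bacteria") {
      r_max <- min(20L, k)
      r_best <- sample.int(r_max, 1, prob = 0.8^seq_len(r_max))
      is_b <- runif(k) < 0.5
      is_b[seq_len(r_best)] <- FALSE
      is_b[r_best] <- TRUE
    } else {
      is_b <- rep(FALSE, k)
    }
    staxid <- sample(euk, k, replace = TRUE)
    if (any(is_b)) staxid[is_b] <- sample(bact, sum(is_b), replace = TRUE)
    aa_len <- as.integer((truth$cds_end[i] - truth$cds_start[i]) / 3)
    al <- pmax(30L, aa_len - sample(0:20, k, replace = TRUE))
    pid <- round(runif(k, 40, 98), 1)
    rows[[i]] <- data.frame(
      qseqid = contigs$id[i],
      sseqid = sprintf("sp%06d", sample.int(999999L, k)),
      pident = pid,
      length = al,
      mismatch = as.integer(round(al * (100 - pid) / 100)),
      gapopen = 0L,
      qstart = truth$cds_start[i] + 1L,
      qend = truth$cds_end[i],
      sstart = 1L,
      send = al,
      evalue = ev,
      bitscore = bits,
      sframe = fr,
      staxid = as.integer(staxid),
      rank = seq_len(k),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      sframe = integer(), staxid = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate term assignments against a synthetic ontology
#'
#' Each product receives between `terms_range[1]` and `terms_range[2]`
#' distinct non-root terms, uniformly sampled.
#'
#' @param product_ids Character vector of product (contig/peptide) ids.
#' @param dag An [ontology_dag] object.
#' @param seed Integer seed.
#' @param terms_range Integer pair: per-product assignment count range.
#' @return Data frame with columns `product_id`, `term_id`.
#' @export
simulate_go_assignments <- function(product_ids, dag, seed = 1L,
                                    terms_range = c(1L, 4L)) {
  set.seed(derive_seed(seed, 5))
  pool <- setdiff(dag$terms$id, dag$roots)
  if (!length(pool)) pool <- dag$roots
  out <- lapply(product_ids, function(id) {
    m <- sample_range(terms_range[1], terms_range[2])
    data.frame(product_id = id,
               term_id = pool[sample.int(length(pool), min(m, length(pool)))],
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(product_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
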