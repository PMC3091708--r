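# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: translation goes
# through Biostrings, graph closures through naive recursion, and curves
# and filters through plain double loops.

# Frame of the longest stop-free translated run, by exhaustive 6-frame
# scan through Biostrings::translate (ambiguous codons become X).
oracle_longest_orf_frame <- function(seq) {
  best <- NA_integer_
  best_len <- -1L
  s0 <- Biostrings::DNAString(toupper(seq))
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr < 0) Biostrings::reverseComplement(s0) else s0
    s <- Biostrings::subseq(s, start = abs(fr))
    n <- length(s) %/% 3L
    if (n == 0L) next
    pep <- as.character(Biostrings::translate(
      Biostrings::subseq(s, 1L, 3L * n), if.fuzzy.codon = "X",
      no.init.codon = TRUE))
    runs <- nchar(strsplit(pep, "*", fixed = TRUE)[[1]])
    if (length(runs) && max(runs) > best_len) {
      best_len <- max(runs)
      best <- fr
    }
  }
  best
}

# Transitive ancestor closure by naive recursion over the parent lists.
oracle_ancestors <- function(dag, term) {
  ps <- dag$parents[[term]]
  if (!length(ps)) return(character(0))
  unique(c(ps, unlist(lapply(ps, function(p) oracle_ancestors(dag, p)))))
}

# Per-category product counts by per-product ancestor-set union.
oracle_propagate <- function(assignments, dag, depth_terms) {
  counts <- stats::setNames(numeric(length(depth_terms)), depth_terms)
  for (pid in unique(assignments$product_id)) {
    terms <- assignments$term_id[assignments$product_id == pid]
    terms <- terms[terms %in% dag$terms$id]
    closure <- unique(c(terms, unlist(lapply(terms, function(t)
      oracle_ancestors(dag, t)))))
    for (cat in depth_terms)
      if (cat %in% closure) counts[cat] <- counts[cat] + 1
  }
  counts
}

# Cumulative bacterial-hit curve by a double loop over (query, rank).
oracle_rank_curve <- function(hits, bacterial_taxids, max_rank) {
  qs <- unique(hits$qseqid)
  f <- integer(max_rank)
  for (r in seq_len(max_rank)) {
    n <- 0L
    for (q in qs) {
      h <- hits[hits$qseqid == q, ]
      br <- h$rank[h$staxid %in% bacterial_taxids]
      if (length(br) && min(br) <= r) n <- n + 1L
    }
    f[r] <- n
  }
  f
}

# Match filter by row-wise loop.
oracle_filter <- function(hits, annotated_a, annotated_b, e_cutoff,
                          bit_threshold) {
  out <- character(0)
  for (i in seq_len(nrow(hits))) {
    if (hits$qseqid[i] %in% annotated_a &&
        hits$sseqid[i] %in% annotated_b &&
        hits$evalue[i] <= e_cutoff &&
        hits$bitscore[i] >= bit_threshold)
      out <- c(out, hits$qseqid[i])
  }
  sort(unique(out))
}

# Best-scoring window of >= min_len codons by exhaustive O(n^2)
# enumeration across all frames and all stop-free windows.
oracle_scan <- function(seq, model, min_peptide) {
  stops <- names(ventannot::genetic_code())[ventannot::genetic_code() == "*"]
  best <- NULL
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    cods <- ventannot::codons_in_frame(seq, fr)
    if (length(cods) < min_peptide) next
    lo <- unname(model$log_odds[cods])
    lo[is.na(lo)] <- 0
    is_stop <- cods %in% stops
    for (i in seq_along(cods)) {
      if (i + min_peptide - 1L > length(cods)) break
      for (j in seq(i + min_peptide - 1L, length(cods))) {
        if (any(is_stop[i:j])) next
        sc <- sum(lo[i:j])
        if (is.null(best) || sc > best$score)
          best <- list(frame = fr, score = sc)
      }
    }
  }
  best
}

# Small random ranked hit table with valid per-query invariants.
random_hit_table <- function(n_queries, taxid_pool, max_hits = 8L) {
  rows <- lapply(seq_len(n_queries), function(i) {
    k <- sample.int(max_hits, 1)
    ev <- sort(10^runif(k, -20, 0))
    data.frame(qseqid = sprintf("q%03d", i),
               sseqid = sprintf("s%03d", sample.int(999, k)),
               evalue = ev,
               bitscore = round(sort(runif(k, 40, 200), decreasing = TRUE), 1),
               sframe = sample(c(1:3, -(1:3)), k, replace = TRUE),
               staxid = sample(taxid_pool, k, replace = TRUE),
               rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

make_contigs <- function(sequences, ids = sprintf("c%03d", seq_along(sequences)),
                         read_count = 2L) {
  data.frame(id = ids, sequence = sequences,
             read_count = rep_len(read_count, length(sequences)),
             status = rep("kept", length(sequences)), stringsAsFactors = FALSE)
}

# Coding sequence sampled from an explicit codon table (no stops).
random_cds <- function(n_codons, usage = ventannot::default_codon_usage()) {
  gc <- ventannot::genetic_code()
  sense <- names(gc)[gc != "*"]
  p <- usage[sense] / sum(usage[sense])
  paste(sample(sense, n_codons, replace = TRUE, prob = p), collapse = "")
}

# Random test DNA; optionally guaranteed not to end in A or start with T
# (so poly-A/poly-T masking expectations stay exact).
random_dna_test <- function(n, no_a_tail = FALSE) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
             collapse = "")
  if (no_a_tail) {
    s <- sub("^T+", "", sub("A+$", "", s))
    s <- paste0(s, strrep("C", n - nchar(s)))
  }
  s
}
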