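test_that("conceptual translation follows the standard code in all frames", {
  expect_identical(translate_frame("ATGGCC", 1), "MA")
  expect_identical(translate_frame("GGCCAT", -1), "MA")
  expect_identical(translate_frame("ATGNAA", 1), "MX")
  expect_identical(translate_frame("ATGTAAGCC", 1), "M*A")
  expect_error(translate_frame("ATG", 0), "frame")
  expect_error(translate_frame("ATG", 4), "frame")

  # cross-check against an independent translator over random sequences
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna_test(sample(30:90, 1))
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      d <- Biostrings::DNAString(s)
      if (fr < 0) d <- Biostrings::reverseComplement(d)
      d <- Biostrings::subseq(d, abs(fr))
      n <- length(d) %/% 3L
      if (n == 0) next
      ref <- as.character(Biostrings::translate(Biostrings::subseq(d, 1, 3 * n),
                                                if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
      expect_identical(translate_frame(s, fr), ref)
    }
  }
})

test_that("homology tiers assign by E-value cutoff with stated tie-breaks", {
  one <- function(ev, frame = 2L, bitscore = 100, rank = 1L,
                  q = "c1", s = "s1") {
    data.frame(qseqid = q, sseqid = s, evalue = ev, bitscore = bitscore,
               sframe = frame, rank = rank, stringsAsFactors = FALSE)
  }
  strict <- assign_frames_homology(one(1e-7), 1e-6, "strict")
  expect_identical(strict$calls$tier, "strict")
  expect_identical(strict$calls$frame, 2L)

  weak <- one(1e-5)
  t1 <- assign_frames_homology(weak, 1e-6, "strict")
  expect_identical(nrow(t1$calls), 0L)
  expect_identical(t1$unassigned, "c1")
  t2 <- assign_frames_homology(weak, 1e-2, "relaxed")
  expect_identical(t2$calls$tier, "relaxed")

  two <- rbind(one(1e-9, frame = 2L, rank = 1L),
               one(1e-8, frame = -1L, rank = 2L))
  expect_identical(assign_frames_homology(two, 1e-6)$calls$frame, 2L)

  # equal E-values: higher bit score wins, then lower rank
  tie <- rbind(one(1e-9, frame = 1L, bitscore = 90, rank = 1L),
               one(1e-9, frame = 3L, bitscore = 120, rank = 2L))
  expect_identical(assign_frames_homology(tie, 1e-6)$calls$frame, 3L)

  bad <- one(1e-9, rank = 2L)
  expect_error(assign_frames_homology(bad, 1e-6), "c1")
})

test_that("lowering the strict cutoff never gains tier-1 assignments", {
  set.seed(41)
  for (i in 1:10) {
    hits <- random_hit_table(30, taxid_pool = 1:5)
    cuts <- sort(10^runif(4, -12, -1))
    sizes <- vapply(cuts, function(e)
      nrow(assign_frames_homology(hits, e)$calls), integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("codon model is null on uniform input and excludes N codons", {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  set.seed(51)
  # uniform codons, uniform background mononucleotides by construction
  seqs <- vapply(1:400, function(i)
    paste(sample(names(gc), 250, replace = TRUE), collapse = ""),
    character(1))
  contigs <- make_contigs(seqs)
  calls <- data.frame(contig_id = contigs$id, frame = 1L, tier = "strict",
                      stringsAsFactors = FALSE)
  m <- train_codon_model(contigs, calls)
  expect_gte(m$training_codons, 50000 * 0.3) # stop-split runs shorten counts
  # stop codons cannot occur inside stop-free training runs, so the
  # zero-log-odds property holds over the sense codons
  expect_lte(max(abs(m$log_odds[sense])), 0.25)

  # ambiguity codons are skipped without derailing the count
  cds <- paste(rep("GCTTCA", 20), collapse = "")
  c1 <- make_contigs(cds, ids = "p1")
  c2 <- make_contigs(paste0("ANT", cds), ids = "p1")
  call1 <- data.frame(contig_id = "p1", frame = 1L, tier = "strict",
                      stringsAsFactors = FALSE)
  m1 <- train_codon_model(c1, call1)
  m2 <- train_codon_model(c2, call1)
  expect_identical(m2$training_codons, m1$training_codons)

  expect_error(train_codon_model(c1, call1[0, ]), "no homology-tier")
  expect_error(train_codon_model(c1, call1, pseudocount = 0), "positive")
})

test_that("planted skewed codon usage is recovered from emitted contigs", {
  cfg <- sim_config(seed = 61, n_contigs = 220, coding_fraction = 1,
                    orf_length_range = c(240L, 300L), n_rate = 0)
  sim <- simulate_contigs(cfg)
  calls <- data.frame(contig_id = sim$truth$id, frame = sim$truth$frame,
                      tier = "strict", stringsAsFactors = FALSE)
  m <- train_codon_model(sim$contigs, calls)
  expect_gte(m$training_codons, 50000)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  est <- m$coding_freq[sense] / sum(m$coding_freq[sense])
  truth <- cfg$codon_usage[sense] / sum(cfg$codon_usage[sense])
  expect_lte(sum(abs(est - truth)), 0.05)
})

test_that("the coding scan recovers planted frames and honors floors", {
  cfg <- sim_config(seed = 71, n_contigs = 150, coding_fraction = 1,
                    n_rate = 0)
  sim <- simulate_contigs(cfg)
  calls <- data.frame(contig_id = sim$truth$id, frame = sim$truth$frame,
                      tier = "strict", stringsAsFactors = FALSE)
  model <- train_codon_model(sim$contigs, calls)

  set.seed(72)
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    cds <- random_cds(150, cfg$codon_usage)
    utr5 <- random_dna_test(39) # divisible by 3: cds sits in frame +1/-1
    utr3 <- random_dna_test(40)
    s <- paste0(utr5, cds, utr3)
    if (fr < 0) s <- revcomp(s)
    pad <- abs(fr) - 1L
    s <- if (fr < 0) paste0(s, strrep("G", pad)) else paste0(strrep("G", pad), s)
    res <- scan_coding(s, model, score_threshold = 0)
    expect_identical(res$frame, fr)
    expect_identical(res$tier, "scan")
    expect_gte(nchar(res$peptide), 30L)
  }

  # shorter than 3 * min_peptide bases: unassigned by construction
  short <- scan_coding(random_dna_test(89), model, min_peptide = 30,
                       score_threshold = -Inf)
  expect_identical(short$tier, "unassigned")
  # a 29-codon stop-free stretch can never seed a 30-residue window
  expect_null(ventannot:::best_window_minlen(rep(1, 29), 30L))
})

test_that("scan scores equal exhaustive window enumeration", {
  cfg <- sim_config(seed = 81, n_contigs = 120, coding_fraction = 1,
                    n_rate = 0)
  sim <- simulate_contigs(cfg)
  calls <- data.frame(contig_id = sim$truth$id, frame = sim$truth$frame,
                      tier = "strict", stringsAsFactors = FALSE)
  model <- train_codon_model(sim$contigs, calls)
  set.seed(82)
  for (i in 1:12) {
    s <- paste0(random_dna_test(60), random_cds(45, cfg$codon_usage),
                random_dna_test(60))
    got <- scan_coding(s, model, min_peptide = 20, score_threshold = -Inf)
    ora <- oracle_scan(s, model, min_peptide = 20)
    expect_identical(got$frame, ora$frame)
    expect_equal(got$score, ora$score, tolerance = 1e-10)
  }
})

test_that("null calibration keeps background false calls at or below 1%", {
  cfg <- sim_config(seed = 91, n_contigs = 150, coding_fraction = 1,
                    n_rate = 0)
  sim <- simulate_contigs(cfg)
  calls <- data.frame(contig_id = sim$truth$id, frame = sim$truth$frame,
                      tier = "strict", stringsAsFactors = FALSE)
  model <- train_codon_model(sim$contigs, calls)
  null <- calibrate_scan_threshold(model, n = 400, len = 600, seed = 5)
  expect_true(is.finite(null$threshold))
  # the decision rule applied end-to-end over the null population
  set.seed(ventannot:::derive_seed(5, 4))
  called <- vapply(seq_len(null$n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), null$len, replace = TRUE,
                      prob = model$background), collapse = "")
    scan_coding(s, model, score_threshold = null$threshold)$tier == "scan"
  }, logical(1))
  expect_lte(mean(called), 0.01)
})

test_that("the cascade partitions contigs over the four tiers", {
  cfg <- sim_config(seed = 101, n_contigs = 150)
  sim <- simulate_contigs(cfg)
  tax <- simulate_taxonomy(seed = cfg$seed)
  hits <- simulate_hits(sim$contigs, sim$truth, cfg, tax)
  pre <- preprocess_contigs(sim$contigs, cfg$adapter_sequence)
  hk <- hits[hits$qseqid %in% pre$contigs$id, ]
  res <- run_cascade(pre$contigs, hk, seed = 1)

  expect_identical(sort(res$calls$contig_id), sort(pre$contigs$id))
  expect_identical(anyDuplicated(res$calls$contig_id), 0L)
  acc <- res$accounting
  expect_identical(acc$n_strict + acc$n_relaxed + acc$n_scan +
                     acc$n_unassigned, nrow(pre$contigs))
  expect_identical(acc$total_translated,
                   acc$n_strict + acc$n_relaxed + acc$n_scan)
  scan_calls <- res$calls[res$calls$tier == "scan", ]
  expect_true(all(scan_calls$peptide_length >= 30))
})

test_that("a hitless corpus leaves everything unassigned with a warning", {
  set.seed(111)
  contigs <- make_contigs(vapply(1:5, function(i) random_dna_test(200),
                                 character(1)))
  empty_hits <- data.frame(qseqid = character(), sseqid = character(),
                           evalue = numeric(), bitscore = numeric(),
                           sframe = integer(), rank = integer(),
                           stringsAsFactors = FALSE)
  expect_warning(res <- run_cascade(contigs, empty_hits, seed = 1),
                 "scan skipped")
  expect_true(all(res$calls$tier == "unassigned"))
  expect_identical(res$accounting$total_translated, 0L)
})
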