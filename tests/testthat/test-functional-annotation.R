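# A small hand-built ontology used across the propagation tests:
#   bp_root <- {bp_cat1, bp_cat2}; bp_cat1 <- {bp_leaf1, bp_leaf2};
#   bp_cat2 <- {bp_leaf3}; mf_root <- {mf_cat1 <- mf_leaf1}
toy_dag <- function() {
  terms <- data.frame(
    id = c("bp_root", "bp_cat1", "bp_cat2", "bp_leaf1", "bp_leaf2",
           "bp_leaf3", "mf_root", "mf_cat1", "mf_leaf1", "cc_root"),
    name = paste("term", 1:10),
    namespace = c(rep("biological_process", 6),
                  rep("molecular_function", 3), "cellular_component"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = c("bp_cat1", "bp_cat2", "bp_leaf1", "bp_leaf2", "bp_leaf3",
              "mf_cat1", "mf_leaf1"),
    parent = c("bp_root", "bp_root", "bp_cat1", "bp_cat1", "bp_cat2",
               "mf_root", "mf_cat1"),
    stringsAsFactors = FALSE
  )
  ontology_dag(terms, edges)
}

test_that("OBO parsing handles minimal, obsolete and broken files", {
  f <- withr::local_tempfile()
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000003", "name: cellular_component",
    "namespace: cellular_component", ""
  ), f)
  dag <- load_obo(f)
  expect_identical(nrow(dag$terms), 3L)
  expect_identical(nrow(dag$edges), 0L)
  expect_setequal(dag$roots, dag$terms$id)

  f2 <- withr::local_tempfile()
  writeLines(c(
    "[Term]", "id: GO:0000001", "name: r", "namespace: bp", "",
    "[Term]", "id: GO:0000009", "name: dead", "namespace: bp",
    "is_obsolete: true", "",
    "[Term]", "id: GO:0000004", "name: kid", "namespace: bp",
    "is_a: GO:0000001 ! r", ""
  ), f2)
  expect_warning(dag2 <- load_obo(f2), "obsolete")
  expect_false("GO:0000009" %in% dag2$terms$id)
  expect_identical(dag2$edges$parent, "GO:0000001")

  f3 <- withr::local_tempfile()
  writeLines(c(
    "[Term]", "id: GO:0000001", "name: r", "namespace: bp",
    "is_a: GO:9999999", ""
  ), f3)
  expect_error(load_obo(f3), "GO:9999999")
})

test_that("cycles are format errors naming the terms involved", {
  terms <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      namespace = "bp", stringsAsFactors = FALSE)
  edges <- data.frame(child = c("a", "b"), parent = c("b", "a"),
                      stringsAsFactors = FALSE)
  expect_error(ontology_dag(terms, edges), "cycle")
})

test_that("a product is counted once per category however many leaves hit", {
  dag <- toy_dag()
  one <- data.frame(product_id = "p1", term_id = "bp_leaf1",
                    stringsAsFactors = FALSE)
  rep1 <- propagate_counts(one, dag)
  counts <- setNames(rep1$count, rep1$term_id)
  expect_identical(unname(counts["bp_cat1"]), 1)
  expect_identical(unname(counts["bp_cat2"]), 0)
  expect_identical(unname(counts["mf_cat1"]), 0)

  # two leaves under the same depth-1 ancestor: still one
  two <- data.frame(product_id = "p1",
                    term_id = c("bp_leaf1", "bp_leaf2"),
                    stringsAsFactors = FALSE)
  rep2 <- propagate_counts(two, dag)
  expect_identical(unname(setNames(rep2$count, rep2$term_id)["bp_cat1"]), 1)

  # two leaves under different categories: one each
  split2 <- data.frame(product_id = "p1",
                       term_id = c("bp_leaf1", "bp_leaf3"),
                       stringsAsFactors = FALSE)
  rep3 <- propagate_counts(split2, dag)
  c3 <- setNames(rep3$count, rep3$term_id)
  expect_identical(unname(c3[c("bp_cat1", "bp_cat2")]), c(1, 1))
})

test_that("root-only annotations are reported, unknown terms skipped", {
  dag <- toy_dag()
  asg <- data.frame(product_id = c("p1", "p2"),
                    term_id = c("bp_root", "GO:bogus"),
                    stringsAsFactors = FALSE)
  expect_warning(rep <- propagate_counts(asg, dag), "unknown")
  expect_identical(attr(rep, "skipped"), 1L)
  expect_identical(unname(attr(rep, "root_only")["biological_process"]), 1)
  expect_true(all(rep$count == 0))
})

test_that("propagation counts equal brute force on random DAGs", {
  set.seed(123)
  dag <- simulate_ontology(200, seed = 33)
  prods <- sprintf("p%02d", 1:50)
  asg <- simulate_go_assignments(prods, dag, seed = 34)
  rep <- propagate_counts(asg, dag)
  depth_terms <- rep$term_id
  ora <- oracle_propagate(asg, dag, depth_terms)
  expect_identical(setNames(rep$count, rep$term_id)[depth_terms], ora)
  # per-namespace percentages sum to 100 up to one-decimal rounding
  for (ns in unique(rep$namespace)) {
    p <- rep$percent[rep$namespace == ns]
    if (all(is.na(p))) next
    expect_lt(abs(sum(p, na.rm = TRUE) - 100), 0.5)
  }
})

test_that("adding an is_a edge never decreases an ancestor's count", {
  set.seed(321)
  for (i in 1:5) {
    dag <- simulate_ontology(60, seed = 40 + i)
    prods <- sprintf("p%02d", 1:20)
    asg <- simulate_go_assignments(prods, dag, seed = 50 + i)
    before <- propagate_counts(asg, dag)
    # connect a random term to a random same-namespace non-descendant
    ns <- setNames(dag$terms$namespace, dag$terms$id)
    anc <- dag_ancestors(dag)
    cand <- setdiff(dag$terms$id, dag$roots)
    child <- sample(cand, 1)
    pool <- setdiff(dag$terms$id[ns[dag$terms$id] == ns[[child]]],
                    c(child, anc[[child]]))
    # avoid creating a cycle: the new parent must not descend from child
    pool <- pool[!vapply(pool, function(p) child %in% anc[[p]], logical(1))]
    if (!length(pool)) next
    parent <- sample(pool, 1)
    dag2 <- ontology_dag(dag$terms, rbind(dag$edges,
                                          data.frame(child = child,
                                                     parent = parent)))
    after <- propagate_counts(asg, dag2)
    b <- setNames(before$count, before$term_id)
    a <- setNames(after$count, after$term_id)
    # the new edge may promote terms in or out of the reporting depth;
    # counts of categories present both times must not shrink
    common <- intersect(names(a), names(b))
    expect_true(all(a[common] >= b[common]))
  }
})

test_that("annotation accounting counts products per evidence type", {
  calls <- data.frame(contig_id = c("p1", "p2", "p3", "p4"),
                      tier = c("strict", "relaxed", "scan", "unassigned"),
                      stringsAsFactors = FALSE)
  interpro <- data.frame(product_id = c("p1", "p1", "p3"),
                         domain_id = c("IPR1", "IPR2", "IPR3"),
                         stringsAsFactors = FALSE)
  go <- data.frame(product_id = c("p2"), term_id = "GO:1",
                   stringsAsFactors = FALSE)
  s <- annotation_summary(calls, interpro, go)
  expect_identical(s$n_products, 3L)
  expect_identical(s$n_protein_match, 2L)
  expect_identical(s$n_domain, 2L)
  expect_identical(s$n_go, 1L)
  empty <- annotation_summary(calls[0, ], NULL, NULL)
  expect_identical(unlist(empty), c(n_products = 0L, n_protein_match = 0L,
                                    n_domain = 0L, n_go = 0L))
})
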