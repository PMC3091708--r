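#' Construct a multi-root ontology DAG
#'
#' Validates and indexes a term graph: `is_a` edges must reference known
#' terms, stay within one namespace, and form no cycle. Roots are the
#' terms without parents.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `child`, `parent` (`is_a` edges).
#' @return An object of class `ontology_dag` with elements `terms`,
#'   `edges`, `parents` (named list), `children` (named list), `roots`,
#'   and `order` (a topological order, parents first).
#' @export
ontology_dag <- function(terms, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(terms$id))
    stop("duplicate term ids", call. = FALSE)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown))
    stop("is_a edge references unknown term(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ns <- setNames(terms$namespace, terms$id)
  cross <- edges$child[ns[edges$child] != ns[edges$parent]]
  if (length(cross))
    stop("is_a edge crosses namespaces at term(s): ",
         paste(unique(cross), collapse = ", "), call. = FALSE)

  parents <- setNames(vector("list", nrow(terms)), terms$id)
  for (id in terms$id) parents[[id]] <- character(0)
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      parents[[edges$child[i]]] <- c(parents[[edges$child[i]]],
                                     edges$parent[i])
  children <- setNames(vector("list", nrow(terms)), terms$id)
  for (id in terms$id) children[[id]] <- character(0)
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      children[[edges$parent[i]]] <- c(children[[edges$parent[i]]],
                                       edges$child[i])

  order <- topo_order(terms$id, parents)
  roots <- terms$id[lengths(parents[terms$id]) == 0]
  structure(list(terms = terms, edges = edges, parents = parents,
                 children = children, roots = roots, order = order),
            class = "ontology_dag")
}

# Kahn-style topological sort over the parent relation; terms appear after
# all of their parents. Errors listing the terms caught in a cycle.
topo_order <- function(ids, parents) {
  placed <- setNames(rep(FALSE, length(ids)), ids)
  order <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(parents[remaining],
                              function(p) all(placed[p]), logical(1))]
    if (!length(ready))
      stop("cycle detected among terms: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    placed[ready] <- TRUE
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d is_a edges, %d root(s)\n",
              nrow(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Ancestor sets for every term
#'
#' @param dag An [ontology_dag] object.
#' @return Named list mapping each term id to the character vector of its
#'   proper ancestors (the term itself excluded).
#' @export
dag_ancestors <- function(dag) {
  anc <- setNames(vector("list", nrow(dag$terms)), dag$terms$id)
  for (t in dag$order) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

# Minimum edge distance of each term from its namespace root.
term_depths <- function(dag) {
  depth <- setNames(rep(NA_real_, nrow(dag$terms)), dag$terms$id)
  depth[dag$roots] <- 0
  for (t in dag$order) {
    ps <- dag$parents[[t]]
    if (length(ps)) depth[t] <- min(depth[ps]) + 1
  }
  depth
}

#' Simulate a small multi-root ontology
#'
#' Generates an acyclic term graph with the three namespace roots
#' (biological_process, molecular_function, cellular_component). Every
#' further term joins one namespace and draws 1..`max_parents` `is_a`
#' parents among earlier terms of that namespace, so each non-root term
#' reaches exactly its own namespace root.
#'
#' @param n_terms Total number of terms, at least 3.
#' @param max_parents Maximum `is_a` parents per term.
#' @param seed Integer seed.
#' @return An [ontology_dag] object.
#' @export
simulate_ontology <- function(n_terms, max_parents = 3L, seed = 1L) {
  if (n_terms < 3)
    stop("'n_terms' must be at least 3 (the three namespace roots)",
         call. = FALSE)
  if (max_parents < 1)
    stop("'max_parents' must be at least 1", call. = FALSE)
  set.seed(derive_seed(seed, 2))
  ns <- c("biological_process", "molecular_function", "cellular_component")
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  namespace <- character(n_terms)
  namespace[1:3] <- ns
  name <- sprintf("synthetic term %d", seq_len(n_terms))
  name[1:3] <- ns
  parents <- vector("list", n_terms)
  if (n_terms > 3) {
    for (i in 4:n_terms) {
      namespace[i] <- ns[sample.int(3L, 1L)]
      pool <- which(namespace[seq_len(i - 1)] == namespace[i])
      np <- sample.int(min(max_parents, length(pool)), 1L)
      parents[[i]] <- ids[pool[sample.int(length(pool), np)]]
    }
  }
  edges <- data.frame(child = rep(ids, lengths(parents)),
                      parent = unlist(parents, use.names = FALSE),
                      stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  ontology_dag(data.frame(id = ids, name = name, namespace = namespace,
                          stringsAsFactors = FALSE), edges)
}

#' Read and write an OBO v1.2 subset
#'
#' Only the fields this pipeline consumes are handled: `id`, `name`,
#' `namespace`, `is_a` (trailing `! comment` stripped). Obsolete terms are
#' dropped with a warning. Cycles and `is_a` references to unknown ids are
#' format errors.
#'
#' @param path OBO file path.
#' @param dag An [ontology_dag] (for `write_obo`).
#' @return `load_obo` returns an [ontology_dag]; `write_obo` returns
#'   `path` invisibly.
#' @export
load_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts))
    stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- list()
  edges <- list()
  n_obsolete <- 0L
  for (k in seq_along(stanza_starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- field("id")[1]
    if (is.na(id)) next
    if (any(field("is_obsolete") == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    terms[[length(terms) + 1L]] <- data.frame(
      id = id,
      name = field("name")[1],
      namespace = field("namespace")[1],
      stringsAsFactors = FALSE
    )
    isa <- sub("\\s*!.*$", "", field("is_a"))
    if (length(isa))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = isa,
                                                stringsAsFactors = FALSE)
  }
  if (n_obsolete > 0)
    warning(sprintf("dropped %d obsolete term(s)", n_obsolete),
            call. = FALSE)
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  ontology_dag(terms, edges)
}

#' @rdname load_obo
#' @export
write_obo <- function(dag, path) {
  name_of <- setNames(dag$terms$name, dag$terms$id)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[i]),
             paste0("namespace: ", dag$terms$namespace[i]),
             if (length(dag$parents[[id]]))
               paste0("is_a: ", dag$parents[[id]], " ! ",
                      name_of[dag$parents[[id]]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Propagate term assignments up the DAG and count per category
#'
#' Reporting categories are the terms at depth `report_depth` below their
#' namespace root (depth 1, the default, are the broad categories directly
#' under each root). Following the true-path rule, a product annotated to
#' any descendant of a category counts toward that category, but each
#' product is counted at most once per category no matter how many of its
#' terms fall below it. Percentages are per namespace over the sum of that
#' namespace's category counts (a product spanning k categories
#' contributes k to the denominator).
#'
#' @param assignments Data frame with columns `product_id`, `term_id`.
#' @param dag An [ontology_dag] object.
#' @param report_depth Depth of the reporting categories below the roots.
#' @return Data frame (`namespace`, `term_id`, `name`, `count`,
#'   `percent`), with attributes `skipped` (assignments to unknown terms,
#'   dropped with a warning) and `root_only` (per-namespace counts of
#'   products whose closure reaches the root but no reporting category).
#' @export
propagate_counts <- function(assignments, dag, report_depth = 1L) {
  if (report_depth < 1) stop("'report_depth' must be >= 1", call. = FALSE)
  known <- assignments$term_id %in% dag$terms$id
  skipped <- sum(!known)
  if (skipped > 0)
    warning(sprintf("skipped %d assignment(s) to unknown terms", skipped),
            call. = FALSE)
  assignments <- assignments[known, , drop = FALSE]

  depth <- term_depths(dag)
  cats <- dag$terms$id[depth[dag$terms$id] == report_depth]
  ns_of <- setNames(dag$terms$namespace, dag$terms$id)
  anc <- dag_ancestors(dag)

  counts <- setNames(numeric(length(cats)), cats)
  root_only <- setNames(numeric(length(dag$roots)),
                        ns_of[dag$roots])
  by_prod <- split(assignments$term_id, assignments$product_id)
  for (terms in by_prod) {
    closure <- unique(c(terms, unlist(anc[unique(terms)],
                                      use.names = FALSE)))
    hit_cats <- intersect(closure, cats)
    counts[hit_cats] <- counts[hit_cats] + 1
    for (r in intersect(closure, dag$roots)) {
      ns <- ns_of[[r]]
      if (!any(ns_of[hit_cats] == ns))
        root_only[ns] <- root_only[ns] + 1
    }
  }

  ns_cat <- ns_of[cats]
  percent <- rep(NA_real_, length(cats))
  for (ns in unique(ns_cat)) {
    tot <- sum(counts[ns_cat == ns])
    if (tot > 0)
      percent[ns_cat == ns] <- round_half_up(100 * counts[ns_cat == ns] / tot, 1)
  }
  out <- data.frame(namespace = unname(ns_cat), term_id = cats,
                    name = setNames(dag$terms$name, dag$terms$id)[cats],
                    count = unname(counts), percent = percent,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$namespace, -out$count, out$term_id), ]
  row.names(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "root_only") <- root_only
  out
}

#' Annotation accounting across evidence tables
#'
#' Counts translated products and how many of them carry a protein match
#' (homology frame tiers), a conserved-domain annotation, and at least one
#' ontology term.
#'
#' @param calls Frame-call data frame (see [run_cascade()]).
#' @param interpro Data frame keyed by `product_id` (domain annotations),
#'   or `NULL`.
#' @param go Data frame keyed by `product_id` (term assignments), or
#'   `NULL`.
#' @return Named list of counts.
#' @export
annotation_summary <- function(calls, interpro = NULL, go = NULL) {
  translated <- calls$contig_id[calls$tier != "unassigned"]
  n_domain <- if (is.null(interpro) || !nrow(interpro)) 0L
  else length(unique(interpro$product_id))
  n_go <- if (is.null(go) || !nrow(go)) 0L
  else length(unique(go$product_id))
  list(
    n_products = length(translated),
    n_protein_match = sum(calls$tier %in% c("strict", "relaxed")),
    n_domain = n_domain,
    n_go = n_go
  )
}
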