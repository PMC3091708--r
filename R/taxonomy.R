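#' Construct a taxonomy lookup table
#'
#' A rooted taxonomy as `taxid -> (parent_taxid, rank, name)`. The root is
#' self-parented; every parent chain must terminate at the root without
#' cycles, which is validated at construction.
#'
#' @param nodes Data frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`.
#' @return Object of class `taxonomy_table` (a validated data frame).
#' @export
taxonomy_table <- function(nodes) {
  req <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(req %in% names(nodes)))
    stop("taxonomy needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxids", call. = FALSE)
  unknown <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(unknown))
    stop("parent taxid(s) absent from table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  roots <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(roots) != 1)
    stop("taxonomy must have exactly one self-parented root", call. = FALSE)
  parent <- setNames(nodes$parent_taxid, nodes$taxid)
  for (t in nodes$taxid) {
    cur <- t
    for (step in seq_len(nrow(nodes) + 1L)) {
      if (cur == roots) break
      cur <- parent[[as.character(cur)]]
      if (step > nrow(nodes))
        stop("cycle detected in parent chain of taxid ", t, call. = FALSE)
    }
  }
  structure(as.data.frame(nodes, stringsAsFactors = FALSE),
            class = c("taxonomy_table", "data.frame"))
}

#' Simulate a rooted taxonomy
#'
#' Builds a root with the three superkingdoms Bacteria, Archaea and
#' Eukaryota, then a `breadth`-ary tree of `depth` levels (ranks phylum,
#' class, order, family, genus, species) under Bacteria and Eukaryota.
#'
#' @param depth Levels below each populated superkingdom (at most 6).
#' @param breadth Children per internal node.
#' @param seed Integer seed (kept for interface symmetry; the tree is
#'   deterministic given `depth` and `breadth`).
#' @return A [taxonomy_table].
#' @export
simulate_taxonomy <- function(depth = 4L, breadth = 3L, seed = 1L) {
  if (depth < 1 || depth > 6) stop("'depth' must be in 1..6", call. = FALSE)
  if (breadth < 1) stop("'breadth' must be >= 1", call. = FALSE)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  rows <- data.frame(
    taxid = c(1L, 2L, 2157L, 2759L),
    parent_taxid = c(1L, 1L, 1L, 1L),
    rank = c("no rank", "superkingdom", "superkingdom", "superkingdom"),
    name = c("root", "Bacteria", "Archaea", "Eukaryota"),
    stringsAsFactors = FALSE
  )
  next_id <- 10000L
  for (sk in c(2L, 2759L)) {
    skname <- rows$name[rows$taxid == sk]
    frontier <- sk
    for (d in seq_len(depth)) {
      new_frontier <- integer(0)
      for (p in frontier) {
        kids <- next_id + seq_len(breadth) - 1L
        next_id <- next_id + breadth
        rows <- rbind(rows, data.frame(
          taxid = kids, parent_taxid = p, rank = ranks[d],
          name = sprintf("%s %s %d", skname, ranks[d], kids),
          stringsAsFactors = FALSE
        ))
        new_frontier <- c(new_frontier, kids)
      }
      frontier <- new_frontier
    }
  }
  taxonomy_table(rows)
}

# Leaf taxids whose lineage passes through the named superkingdom.
taxonomy_tips <- function(taxonomy, superkingdom) {
  tips <- setdiff(taxonomy$taxid, taxonomy$parent_taxid)
  sk <- superkingdom_of(tips, taxonomy)
  tips[!is.na(sk) & sk == superkingdom]
}

#' Superkingdom of a taxon
#'
#' Walks each taxid's parent chain and returns the name of the ancestor
#' (or the taxon itself) holding rank `superkingdom`; `NA` when the chain
#' reaches the root without one. Unknown taxids are an error; a guard
#' against chains longer than the table aborts with a format error.
#'
#' @param taxid Vector of taxon identifiers.
#' @param taxonomy A [taxonomy_table].
#' @return Character vector of superkingdom names (or `NA`).
#' @export
superkingdom_of <- function(taxid, taxonomy) {
  parent <- setNames(taxonomy$parent_taxid, taxonomy$taxid)
  rank <- setNames(taxonomy$rank, taxonomy$taxid)
  name <- setNames(taxonomy$name, taxonomy$taxid)
  vapply(taxid, function(t) {
    key <- as.character(t)
    if (!key %in% names(parent))
      stop("unknown taxid: ", t, call. = FALSE)
    for (step in seq_len(nrow(taxonomy) + 1L)) {
      if (rank[[key]] == "superkingdom") return(name[[key]])
      up <- as.character(parent[[key]])
      if (up == key) return(NA_character_)
      key <- up
      if (step > nrow(taxonomy))
        stop("parent chain exceeds taxonomy size (cycle?)", call. = FALSE)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Is a taxon bacterial?
#'
#' @inheritParams superkingdom_of
#' @return Logical vector: lineage reaches the superkingdom Bacteria.
#' @export
is_bacterial <- function(taxid, taxonomy) {
  sk <- superkingdom_of(taxid, taxonomy)
  !is.na(sk) & sk == "Bacteria"
}

#' Cumulative bacterial-hit-by-rank curve
#'
#' For queries with ranked hits, `f(r)` counts the queries whose best
#' (lowest-rank) bacterial hit sits at rank `<= r`, for `r = 1..max_rank`.
#' Queries with no bacterial hit never contribute. Hits whose `staxid` is
#' absent from the taxonomy are skipped and logged (skip-and-log policy;
#' the count is reported in the result).
#'
#' @param hits Hit data frame with `qseqid`, `staxid` and a `rank` column
#'   (as from [read_hit_table()] or [simulate_hits()]).
#' @param taxonomy A [taxonomy_table].
#' @param max_rank Deepest hit rank examined (default 20).
#' @return Object of class `rank_curve`: list with `f` (length
#'   `max_rank`), `increments`, `total_queries`, `max_rank`,
#'   `skipped_taxids`.
#' @export
bacterial_rank_curve <- function(hits, taxonomy, max_rank = 20L) {
  if (!"rank" %in% names(hits))
    stop("hit table must carry a 'rank' column", call. = FALSE)
  total <- length(unique(hits$qseqid))
  ut <- unique(hits$staxid)
  sk <- setNames(rep(NA_character_, length(ut)), as.character(ut))
  skipped <- character(0)
  for (t in ut) {
    res <- tryCatch(superkingdom_of(t, taxonomy), error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, as.character(t))
    else sk[[as.character(t)]] <- res
  }
  bac <- !is.na(sk[as.character(hits$staxid)]) &
    sk[as.character(hits$staxid)] == "Bacteria"
  f <- integer(max_rank)
  if (any(bac)) {
    best <- tapply(hits$rank[bac], hits$qseqid[bac], min)
    for (r in seq_len(max_rank)) f[r] <- sum(best <= r)
  }
  structure(list(f = f, increments = diff(c(0L, f)),
                 total_queries = total, max_rank = as.integer(max_rank),
                 skipped_taxids = unique(skipped)),
            class = "rank_curve")
}

#' @export
print.rank_curve <- function(x, ...) {
  cat(sprintf("rank_curve over %d queries (max rank %d): f(%d) = %d\n",
              x$total_queries, x$max_rank, x$max_rank, x$f[x$max_rank]))
  invisible(x)
}

#' Detect convergence of a rank curve
#'
#' Finds the earliest rank `r` whose next `window - 1` increments are all
#' `<= tol`; the plateau value is always `f(max_rank)`. A curve still
#' rising at the deepest rank is flagged non-converged.
#'
#' @param curve A `rank_curve` from [bacterial_rank_curve()].
#' @param tol Maximum increment treated as flat (default 0).
#' @param window Number of consecutive ranks that must be flat
#'   (default 5, minimum 2).
#' @return List with `plateau_value`, `plateau_rank` (`NA` if never
#'   flat), and `converged`.
#' @export
detect_plateau <- function(curve, tol = 0L, window = 5L) {
  stopifnot(inherits(curve, "rank_curve"))
  if (window < 2) stop("'window' must be >= 2", call. = FALSE)
  if (tol < 0) stop("'tol' must be >= 0", call. = FALSE)
  f <- curve$f
  mr <- length(f)
  plateau_rank <- NA_integer_
  if (mr >= window) {
    for (r in seq_len(mr - window + 1L)) {
      inc <- f[(r + 1L):(r + window - 1L)] - f[r:(r + window - 2L)]
      if (all(inc <= tol)) {
        plateau_rank <- r
        break
      }
    }
  }
  list(plateau_value = f[mr], plateau_rank = plateau_rank,
       converged = !is.na(plateau_rank))
}

#' Read and write the taxonomy dump dialect
#'
#' `nodes.dmp` rows are `taxid | parent | rank |` and `names.dmp` rows
#' `taxid | name | unique name | scientific name |`, pipe-delimited with
#' tab padding as in the NCBI taxonomy dump. Only scientific names are
#' read.
#'
#' @param taxonomy A [taxonomy_table] (for writing).
#' @param nodes_path,names_path File paths.
#' @return `read_taxdump` returns a [taxonomy_table]; `write_taxdump`
#'   returns `nodes_path` invisibly.
#' @export
write_taxdump <- function(taxonomy, nodes_path, names_path) {
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", taxonomy$taxid,
                     taxonomy$parent_taxid, taxonomy$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     taxonomy$taxid, taxonomy$name), names_path)
  invisible(nodes_path)
}

#' @rdname write_taxdump
#' @export
read_taxdump <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nodes <- parse_dmp(nodes_path)
  names_rows <- parse_dmp(names_path)
  sci <- Filter(function(x) length(x) >= 4 && x[4] == "scientific name",
                names_rows)
  name_of <- setNames(vapply(sci, `[`, character(1), 2),
                      vapply(sci, `[`, character(1), 1))
  taxonomy_table(data.frame(
    taxid = as.integer(vapply(nodes, `[`, character(1), 1)),
    parent_taxid = as.integer(vapply(nodes, `[`, character(1), 2)),
    rank = vapply(nodes, `[`, character(1), 3),
    name = unname(name_of[vapply(nodes, `[`, character(1), 1)]),
    stringsAsFactors = FALSE
  ))
}
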