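#' Directed acyclic graphs with designated selection nodes
#'
#' A `dag` object encodes a causal diagram: a set of named variables, a set
#' of directed cause-to-effect edges, and an optional subset of
#' *selection nodes*, i.e. variables that are conditioned on by design
#' (typically "inclusion into the analysis"). Selection nodes are implicitly
#' added to every conditioning set in [d_separated()],
#' [implied_independencies()] and [blocks_selection_path()]: callers never
#' pass them explicitly.
#'
#' @param edges character vector of edges in `"A -> B"` form, or a
#'   two-column character matrix (from, to).
#' @param nodes character vector of node names; defaults to the union of
#'   edge endpoints. Isolated nodes must be declared here.
#' @param selection character vector of selection-node names (may be empty).
#' @return an object of class `dag` with elements `nodes`, `parents`
#'   (named list), and `selection`.
#' @examples
#' g <- dag(c("Age -> PTA", "PTA -> PC"))
#' d_separated(g, "Age", "PC", "PTA")
#' @export
dag <- function(edges = character(), nodes = NULL, selection = character()) {
  if (is.character(edges) && !is.matrix(edges)) {
    edges <- edges[nzchar(trimws(edges))]
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed edge(s): ", paste(edges[bad], collapse = ", "))
    em <- cbind(trimws(vapply(parts, `[`, "", 1L)),
                trimws(vapply(parts, `[`, "", 2L)))
  } else {
    em <- as.matrix(edges)
    if (length(em) && ncol(em) != 2L) stop("edge matrix must have two columns")
  }
  nodes <- sort(unique(c(nodes, as.vector(em))))
  if (length(selection) && !all(selection %in% nodes)) {
    stop("selection node(s) not declared: ",
         paste(setdiff(selection, nodes), collapse = ", "))
  }
  if (length(em) && anyDuplicated(paste(em[, 1], em[, 2]))) {
    em <- em[!duplicated(paste(em[, 1], em[, 2])), , drop = FALSE]
  }
  if (length(em) && any(em[, 1] == em[, 2])) stop("self-loop edge not allowed")
  parents <- lapply(stats::setNames(nodes, nodes), function(v) {
    if (length(em)) sort(em[em[, 2] == v, 1]) else character()
  })
  g <- structure(list(nodes = nodes, parents = parents,
                      selection = sort(unique(selection))),
                 class = "dag")
  if (is.null(topological_order(g))) stop("graph contains a directed cycle")
  g
}

#' @export
print.dag <- function(x, ...) {
  cat("Causal DAG:", length(x$nodes), "nodes,", nrow(dag_edges(x)), "edges\n")
  e <- dag_edges(x)
  if (nrow(e)) cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  if (length(x$selection))
    cat("Selection (always conditioned):",
        paste(x$selection, collapse = ", "), "\n")
  invisible(x)
}

#' Edge list of a dag
#' @param g a [dag()].
#' @return two-column character matrix (from, to).
#' @export
dag_edges <- function(g) {
  e <- do.call(rbind, lapply(g$nodes, function(v) {
    if (length(g$parents[[v]])) cbind(g$parents[[v]], v) else NULL
  }))
  if (is.null(e)) e <- matrix(character(), 0, 2)
  colnames(e) <- c("from", "to")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

topological_order <- function(g) {
  indeg <- vapply(g$parents, length, 0L)
  order <- character()
  pending <- g$nodes
  while (length(pending)) {
    free <- pending[indeg[pending] == 0L]
    if (!length(free)) return(NULL)  # cycle
    v <- free[1L]
    order <- c(order, v)
    pending <- setdiff(pending, v)
    for (w in pending) {
      if (v %in% g$parents[[w]]) indeg[w] <- indeg[w] - 1L
    }
  }
  order
}

dag_children <- function(g, v) g$nodes[vapply(g$nodes, function(w) v %in% g$parents[[w]], TRUE)]

#' @keywords internal
dag_ancestors <- function(g, vs) {
  # ancestors of vs, including vs themselves
  out <- unique(vs)
  repeat {
    more <- setdiff(unique(unlist(g$parents[out])), out)
    if (!length(more)) return(sort(out))
    out <- c(out, more)
  }
}

#' @keywords internal
dag_descendants <- function(g, v) {
  # descendants of v, including v itself
  out <- v
  repeat {
    more <- setdiff(unique(unlist(lapply(out, dag_children, g = g))), out)
    if (!length(more)) return(sort(out))
    out <- c(out, more)
  }
}

check_nodes <- function(g, vs, what = "node") {
  bad <- setdiff(vs, g$nodes)
  if (length(bad)) stop("unknown ", what, "(s): ", paste(bad, collapse = ", "))
}

#' The causal diagram of the presbycusis consonant-identification study
#'
#' Six variables: Age, Gender, PTA (pure-tone average, dB HL), Cond
#' (listening condition, quiet vs noise), PC (percent/probability of correct
#' consonant identification) and Inclusion (inclusion into the analysis).
#' Age and Gender drive PTA; Age, PTA and Cond drive PC; Age and Gender
#' drive Inclusion, which is a selection node: the analyzed sample is
#' conditioned on it by construction, so the collider path
#' Age -> Inclusion <- Gender is open unless Gender (or Age) is controlled.
#'
#' The study's PTA-percentile inclusion criterion can optionally be drawn as
#' an explicit PTA -> Inclusion edge; the default diagram encodes inclusion
#' as depending on Age and Gender only, which is the structure needed to
#' reason about the Age/Gender collider.
#'
#' @param pta_inclusion logical; add a PTA -> Inclusion edge.
#' @return a [dag()].
#' @examples
#' g <- presbycusis_dag()
#' d_separated(g, "Gender", "PC", c("Age", "PTA"))
#' @export
presbycusis_dag <- function(pta_inclusion = FALSE) {
  edges <- c("Age -> PTA", "Age -> PC", "Age -> Inclusion",
             "Gender -> PTA", "Gender -> Inclusion",
             "PTA -> PC", "Cond -> PC")
  if (pta_inclusion) edges <- c(edges, "PTA -> Inclusion")
  dag(edges, selection = "Inclusion")
}

#' d-separation under design-based selection
#'
#' Tests whether `x` and `y` are d-separated given `z` plus the graph's
#' selection nodes, using the moralization criterion: restrict to the
#' ancestral graph of `{x, y} U z U selection`, marry co-parents, drop the
#' conditioning nodes, and test undirected connectivity.
#'
#' @param g a [dag()].
#' @param x,y single node names.
#' @param z character vector of conditioning nodes (selection nodes are
#'   added automatically).
#' @return logical: `TRUE` iff every path between `x` and `y` is blocked.
#' @export
d_separated <- function(g, x, y, z = character()) {
  check_nodes(g, c(x, y, z))
  if (length(x) != 1L || length(y) != 1L) stop("x and y must be single nodes")
  z <- union(z, g$selection)
  z <- setdiff(z, c(x, y))
  if (x == y) return(FALSE)
  anc <- dag_ancestors(g, c(x, y, z))
  # moral graph on ancestral set: adjacency matrix
  n <- length(anc)
  adj <- matrix(FALSE, n, n, dimnames = list(anc, anc))
  for (v in anc) {
    pa <- intersect(g$parents[[v]], anc)
    adj[pa, v] <- TRUE
    adj[v, pa] <- TRUE
    if (length(pa) > 1L) adj[pa, pa] <- TRUE  # marry parents
  }
  diag(adj) <- FALSE
  keep <- setdiff(anc, z)
  adj <- adj[keep, keep, drop = FALSE]
  # BFS from x
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nb <- keep[colSums(adj[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nb, seen)
    if (y %in% frontier) return(FALSE)
    seen <- c(seen, frontier)
  }
  TRUE
}

#' Implied conditional independencies among observed variables
#'
#' Enumerates, for every pair of observed nodes, the minimal subset of the
#' remaining observed nodes (smallest cardinality, ties broken
#' lexicographically) that d-separates the pair, with selection nodes
#' implicitly conditioned throughout. Pairs that cannot be separated are
#' omitted. Results are ordered lexicographically by the node pair.
#'
#' @param g a [dag()].
#' @param observed character vector of observed nodes (must exclude
#'   selection nodes).
#' @return a list of triples `list(x, y, z)`.
#' @export
implied_independencies <- function(g, observed = setdiff(g$nodes, g$selection)) {
  check_nodes(g, observed)
  if (length(intersect(observed, g$selection)))
    stop("observed set must exclude selection nodes")
  observed <- sort(observed)
  out <- list()
  if (length(observed) < 2L) return(out)
  pairs <- utils::combn(observed, 2L)
  for (j in seq_len(ncol(pairs))) {
    x <- pairs[1L, j]; y <- pairs[2L, j]
    rest <- setdiff(observed, c(x, y))
    found <- NULL
    for (k in 0:length(rest)) {
      subs <- if (k == 0L) list(character()) else
        apply(utils::combn(rest, k), 2L, identity, simplify = FALSE)
      # combn already yields lexicographic order for sorted input
      for (s in subs) {
        if (d_separated(g, x, y, s)) { found <- s; break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) out[[length(out) + 1L]] <- list(x = x, y = y, z = found)
  }
  out
}

#' Does a control set block all non-causal paths under selection?
#'
#' Checks whether `controls` (plus the implicit selection nodes) closes
#' every non-causal path between exposure and outcome, leaving only the
#' causal routes. Because conditioning on a selection collider can open
#' paths that *leave* the exposure (e.g. exposure -> inclusion <- cause of
#' outcome), the classic "delete all edges out of the exposure" back-door
#' construction is insufficient; instead the generalized adjustment
#' construction is used: only the first edge of every proper causal path
#' from exposure to outcome is removed, and d-separation given
#' `controls` plus selection nodes is tested in the resulting graph.
#'
#' @param g a [dag()].
#' @param exposure,outcome single node names (must differ).
#' @param controls character vector of adjustment variables.
#' @return logical: `TRUE` iff no non-causal path remains open.
#' @export
blocks_selection_path <- function(g, exposure, outcome, controls = character()) {
  check_nodes(g, c(exposure, outcome, controls))
  if (exposure == outcome) stop("exposure and outcome must differ")
  # first edges of proper causal paths: exposure -> w with outcome in de(w)
  kids <- dag_children(g, exposure)
  causal_first <- kids[vapply(kids, function(w) outcome %in% dag_descendants(g, w), TRUE)]
  e <- dag_edges(g)
  drop <- e[, 1] == exposure & e[, 2] %in% causal_first
  g2 <- dag(e[!drop, , drop = FALSE], nodes = g$nodes, selection = g$selection)
  d_separated(g2, exposure, outcome, controls)
}

#' Read / write a dag as a plain edge-list file
#'
#' Format: one `"A -> B"` edge per line; lines of the form
#' `"selection: NAME"` declare selection nodes; lines `"node: NAME"`
#' declare isolated nodes; `#` starts a comment.
#'
#' @param path file path.
#' @rdname dag_io
#' @return `read_dag` returns a [dag()]; `write_dag` returns `path`
#'   invisibly.
#' @export
read_dag <- function(path) {
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(lines)]
  sel <- sub("^selection:\\s*", "", lines[grepl("^selection:", lines)])
  iso <- sub("^node:\\s*", "", lines[grepl("^node:", lines)])
  edges <- lines[!grepl("^(selection|node):", lines)]
  dag(edges, nodes = c(iso, sel), selection = sel)
}

#' @param g a [dag()].
#' @rdname dag_io
#' @export
write_dag <- function(g, path) {
  e <- dag_edges(g)
  iso <- setdiff(g$nodes, c(e[, 1], e[, 2], g$selection))
  writeLines(c(paste(e[, 1], "->", e[, 2]),
               if (length(iso)) paste("node:", iso),
               if (length(g$selection)) paste("selection:", g$selection)),
             path)
  invisible(path)
}

#' DOT export for visualization
#' @param g a [dag()].
#' @return a character scalar with Graphviz DOT source; selection nodes are
#'   drawn as boxes.
#' @export
dag_to_dot <- function(g) {
  e <- dag_edges(g)
  paste0("digraph {\n",
         paste0("  ", g$nodes,
                ifelse(g$nodes %in% g$selection, " [shape=box]", ""),
                ";\n", collapse = ""),
         paste0("  ", e[, 1], " -> ", e[, 2], ";\n", collapse = ""),
         "}\n")
}
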