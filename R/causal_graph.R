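# Causal DAG representation, d-separation and backdoor adjustment-set search.
#
# The graph is deliberately small and clinical (tens of nodes), so the
# algorithms favour transparency over asymptotics: d-separation by the
# moralised-ancestral-graph construction, backdoor search by exhaustive
# subset enumeration over observed non-descendants of the exposure.

#' Construct and validate a causal DAG
#'
#' @param nodes Either a character vector of node names (all observed, role
#'   `"covariate"` unless named in `exposure`/`outcome`) or a data frame with
#'   columns `name`, `observed` (logical), `role` (one of `"exposure"`,
#'   `"outcome"`, `"intermediary"`, `"covariate"`).
#' @param edges Two-column data frame or matrix of `(parent, child)` pairs, or
#'   a character vector of `"parent -> child"` strings.
#' @param exposure,outcome Optional node names; when given they override (or
#'   set) the corresponding roles. Exactly one exposure and at least one
#'   outcome are required.
#' @return An object of class `causal_dag`.
#' @examples
#' g <- causal_dag(c("X", "T", "Y"),
#'                 c("X -> T", "X -> Y", "T -> Y"),
#'                 exposure = "T", outcome = "Y")
#' @export
causal_dag <- function(nodes, edges, exposure = NULL, outcome = NULL) {
  if (is.character(nodes)) {
    nodes <- data.frame(name = nodes, observed = TRUE, role = "covariate",
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "observed", "role") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$name)) {
    stop("causal_dag: duplicate node(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "),
         call. = FALSE)
  }
  ok_roles <- c("exposure", "outcome", "intermediary", "covariate")
  if (!all(nodes$role %in% ok_roles)) {
    stop("causal_dag: unknown role(s): ",
         paste(setdiff(nodes$role, ok_roles), collapse = ", "), call. = FALSE)
  }
  edges <- parse_edges(edges)
  missing_nodes <- setdiff(unique(c(edges$parent, edges$child)), nodes$name)
  if (length(missing_nodes)) {
    stop("causal_dag: edges reference unknown node(s): ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    stop("causal_dag: self-loop detected", call. = FALSE)
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    edges <- unique(edges)
  }
  if (!is.null(exposure)) {
    stopifnot(exposure %in% nodes$name)
    nodes$role[nodes$role == "exposure"] <- "covariate"
    nodes$role[nodes$name == exposure] <- "exposure"
  }
  if (!is.null(outcome)) {
    stopifnot(all(outcome %in% nodes$name))
    nodes$role[nodes$name %in% outcome] <- "outcome"
  }
  if (sum(nodes$role == "exposure") != 1L) {
    stop("causal_dag: exactly one exposure node is required", call. = FALSE)
  }
  if (sum(nodes$role == "outcome") < 1L) {
    stop("causal_dag: at least one outcome node is required", call. = FALSE)
  }
  dag <- structure(
    list(nodes = nodes, edges = edges,
         parents = adjacency_list(edges$child, edges$parent, nodes$name),
         children = adjacency_list(edges$parent, edges$child, nodes$name)),
    class = "causal_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("causal_dag: cycle detected: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  dag
}

parse_edges <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("causal_dag: malformed edge string (expect 'parent -> child')",
           call. = FALSE)
    }
    edges <- data.frame(parent = trimws(vapply(parts, `[`, "", 1L)),
                        child = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L && nrow(edges) > 0L) {
    stop("causal_dag: edges need (parent, child) columns", call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  names(edges)[1:2] <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges[, c("parent", "child")]
}

adjacency_list <- function(keys, values, all_nodes) {
  adj <- split(values, factor(keys, levels = all_nodes))
  lapply(adj, unique)
}

# Returns one directed cycle as a node sequence, or NULL if acyclic.
find_cycle <- function(dag) {
  state <- stats::setNames(rep(0L, nrow(dag$nodes)), dag$nodes$name) # 0 new, 1 open, 2 done
  path <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (ch in dag$children[[v]]) {
      if (!is.null(cycle)) return()
      if (state[ch] == 1L) {
        i <- match(ch, path)
        cycle <<- c(path[i:length(path)], ch)
        return()
      }
      if (state[ch] == 0L) visit(ch)
    }
    path <<- path[-length(path)]
    state[v] <<- 2L
  }
  for (v in dag$nodes$name) if (state[v] == 0L) visit(v)
  cycle
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal_dag:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  exposure:", dag_exposure(x), "\n")
  cat("  outcome(s):", paste(dag_outcomes(x), collapse = ", "), "\n")
  latent <- x$nodes$name[!x$nodes$observed]
  if (length(latent)) cat("  unobserved:", paste(latent, collapse = ", "), "\n")
  invisible(x)
}

#' Accessors for causal_dag objects
#' @param dag A `causal_dag`.
#' @return `dag_nodes()` the node table; `dag_edges()` the edge table;
#'   `dag_exposure()`/`dag_outcomes()` role-tagged node names;
#'   `observed_nodes()` names of observed nodes.
#' @export
dag_nodes <- function(dag) dag$nodes

#' @rdname dag_nodes
#' @export
dag_edges <- function(dag) dag$edges

#' @rdname dag_nodes
#' @export
dag_exposure <- function(dag) dag$nodes$name[dag$nodes$role == "exposure"]

#' @rdname dag_nodes
#' @export
dag_outcomes <- function(dag) dag$nodes$name[dag$nodes$role == "outcome"]

#' @rdname dag_nodes
#' @export
observed_nodes <- function(dag) dag$nodes$name[dag$nodes$observed]

reach <- function(adj, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

#' Ancestors / descendants of a node set
#'
#' @param dag A `causal_dag`.
#' @param nodes Character vector of node names.
#' @param inclusive Include the query nodes themselves (default `TRUE`).
#' @return Character vector of node names.
#' @export
dag_ancestors <- function(dag, nodes, inclusive = TRUE) {
  check_nodes(dag, nodes)
  out <- reach(dag$parents, nodes)
  if (!inclusive) out <- setdiff(out, nodes)
  out
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, nodes, inclusive = TRUE) {
  check_nodes(dag, nodes)
  out <- reach(dag$children, nodes)
  if (!inclusive) out <- setdiff(out, nodes)
  out
}

check_nodes <- function(dag, nodes) {
  unknown <- setdiff(nodes, dag$nodes$name)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Test d-separation
#'
#' Decides whether node sets `a` and `b` are d-separated by `given` using the
#' moralised ancestral graph construction: restrict to ancestors of
#' `a`, `b` and `given`; marry co-parents; drop edge directions; delete the
#' conditioning set; then `a` and `b` are d-separated iff no undirected path
#' connects them. Unobserved nodes take part as latent structure and may also
#' appear in `given` (the backdoor search never conditions on them, but the
#' primitive itself is agnostic).
#'
#' @param dag A `causal_dag`.
#' @param a,b Node names (disjoint from `given`).
#' @param given Character vector of conditioning nodes (possibly empty).
#' @return `TRUE` if every path between `a` and `b` is blocked.
#' @export
d_separated <- function(dag, a, b, given = character(0)) {
  check_nodes(dag, c(a, b, given))
  if (any(c(a, b) %in% given)) {
    stop("d_separated: query nodes must not be in the conditioning set",
         call. = FALSE)
  }
  anc <- dag_ancestors(dag, unique(c(a, b, given)))
  # undirected adjacency of the moral graph restricted to anc
  adj <- stats::setNames(vector("list", length(anc)), anc)
  add_und <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v)
    adj[[v]] <<- c(adj[[v]], u)
  }
  e <- dag$edges[dag$edges$parent %in% anc & dag$edges$child %in% anc, ,
                 drop = FALSE]
  for (i in seq_len(nrow(e))) add_und(e$parent[i], e$child[i])
  for (v in anc) {
    pa <- intersect(dag$parents[[v]], anc)
    if (length(pa) > 1L) {
      cmb <- utils::combn(sort(pa), 2L)
      for (j in seq_len(ncol(cmb))) add_und(cmb[1L, j], cmb[2L, j])
    }
  }
  keep <- setdiff(anc, given)
  adj <- lapply(adj[keep], function(x) setdiff(unique(x), given))
  reached <- reach(adj, intersect(a, keep))
  !any(b %in% reached)
}

#' Check a candidate set against the backdoor criterion
#'
#' A set `z` satisfies the backdoor criterion relative to
#' (`exposure`, `outcome`) if no member is a descendant of the exposure and
#' `z` d-separates exposure from outcome in the graph with the exposure's
#' outgoing edges removed.
#'
#' @param dag A `causal_dag`.
#' @param z Character vector (may be empty).
#' @param exposure,outcome Node names; default to the DAG's tagged roles.
#' @return Logical scalar.
#' @export
is_valid_backdoor_set <- function(dag, z, exposure = dag_exposure(dag),
                                  outcome = dag_outcomes(dag)[1L]) {
  check_nodes(dag, c(z, exposure, outcome))
  if (length(z) && any(z %in% dag_descendants(dag, exposure))) return(FALSE)
  g2 <- remove_outgoing(dag, exposure)
  d_separated(g2, exposure, outcome, z)
}

remove_outgoing <- function(dag, node) {
  e <- dag$edges[dag$edges$parent != node, , drop = FALSE]
  structure(
    list(nodes = dag$nodes, edges = e,
         parents = adjacency_list(e$child, e$parent, dag$nodes$name),
         children = adjacency_list(e$parent, e$child, dag$nodes$name)),
    class = "causal_dag")
}

#' Enumerate backdoor adjustment sets
#'
#' Exhaustively enumerates subsets of observed non-descendants of the
#' exposure (sizes ascending, lexicographic within size) and keeps those
#' satisfying the backdoor criterion. With `minimal_only = TRUE` only sets
#' with no valid proper subset are returned; supersets of known valid sets
#' are pruned without testing. Exhaustive search is deliberate: the clinical
#' graphs involved have few observed nodes and no heuristics are wanted.
#'
#' @param dag A `causal_dag`.
#' @param exposure,outcome Node names; default to the tagged roles.
#' @param minimal_only Return only minimal sets (default `TRUE`).
#' @param max_size Cap on candidate subset size (default: all candidates).
#' @return Object of class `adjustment_sets`: a list whose elements are
#'   `adjustment_set` objects (fields `variables`, `query`, `minimal`).
#'   If no observed set is valid, an error of class
#'   `ventcausal_not_identifiable` is thrown (distinct from a valid empty
#'   set, which is returned as `character(0)`).
#' @export
backdoor_sets <- function(dag, exposure = dag_exposure(dag),
                          outcome = dag_outcomes(dag)[1L],
                          minimal_only = TRUE, max_size = Inf) {
  check_nodes(dag, c(exposure, outcome))
  cand <- sort(setdiff(observed_nodes(dag),
                       c(outcome, dag_descendants(dag, exposure))))
  g2 <- remove_outgoing(dag, exposure)
  valid <- list()
  max_size <- min(max_size, length(cand))
  for (k in 0:max_size) {
    subsets <- if (k == 0L) list(character(0)) else {
      m <- utils::combn(cand, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }
    for (z in subsets) {
      if (minimal_only && length(valid) &&
          any(vapply(valid, function(v) all(v %in% z), TRUE))) next
      if (d_separated(g2, exposure, outcome, z)) valid <- c(valid, list(z))
    }
    if (minimal_only && k == 0L && length(valid)) break
  }
  if (!length(valid)) {
    stop(structure(
      class = c("ventcausal_not_identifiable", "error", "condition"),
      list(message = paste0("no observed backdoor adjustment set exists for ",
                            exposure, " -> ", outcome,
                            " (unblockable unobserved confounding)"),
           call = NULL)))
  }
  if (minimal_only) {
    is_min <- vapply(valid, function(z) {
      !any(vapply(valid, function(v)
        length(v) < length(z) && all(v %in% z), TRUE))
    }, TRUE)
    valid <- valid[is_min]
  }
  sets <- lapply(valid, function(z) {
    structure(list(variables = z, query = c(exposure = exposure,
                                            outcome = outcome),
                   minimal = minimal_only),
              class = "adjustment_set")
  })
  structure(sets, class = "adjustment_sets")
}

#' @export
print.adjustment_set <- function(x, ...) {
  v <- if (length(x$variables)) paste(x$variables, collapse = ", ") else "{}"
  cat("adjustment_set {", v, "} for", x$query[["exposure"]], "->",
      x$query[["outcome"]], if (isTRUE(x$minimal)) "(minimal)" else "", "\n")
  invisible(x)
}

#' @export
print.adjustment_sets <- function(x, ...) {
  cat(length(x), "adjustment set(s):\n")
  for (s in x) print(s)
  invisible(x)
}

#' Read / write the plain-text graph file format
#'
#' One declaration per line. Node lines: `node <name> observed|unobserved
#' <role>`; edge lines: `parent -> child`. Blank lines and `#` comments are
#' ignored. The round trip `write_dag_file()` then `read_dag_file()` is
#' lossless up to comments.
#'
#' @param path File path.
#' @return `read_dag_file()` returns a `causal_dag`.
#' @export
read_dag_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  node_lines <- grepl("^node\\s", lines)
  nd <- strsplit(lines[node_lines], "\\s+")
  if (any(lengths(nd) != 4L)) {
    stop("read_dag_file: malformed node line (expect 'node <name> ",
         "observed|unobserved <role>')", call. = FALSE)
  }
  nodes <- data.frame(
    name = vapply(nd, `[`, "", 2L),
    observed = vapply(nd, `[`, "", 3L) == "observed",
    role = vapply(nd, `[`, "", 4L),
    stringsAsFactors = FALSE)
  causal_dag(nodes, lines[!node_lines])
}

#' @rdname read_dag_file
#' @param dag A `causal_dag` to serialise.
#' @export
write_dag_file <- function(dag, path) {
  node_lines <- sprintf("node %s %s %s", dag$nodes$name,
                        ifelse(dag$nodes$observed, "observed", "unobserved"),
                        dag$nodes$role)
  edge_lines <- sprintf("%s -> %s", dag$edges$parent, dag$edges$child)
  writeLines(c(node_lines, edge_lines), path)
  invisible(path)
}

#' The packaged default ventilation DAG
#'
#' Loads the graph shipped with the package: clinical labs and vitals feed a
#' latent disease-severity score that drives both the oxygenation trajectory
#' (P/F) and ventilator-free days; clinicians titrate respiratory rate and
#' peak pressure to severity, and those settings (with latent lung
#' compliance) determine mechanical power, the exposure. Compliance and the
#' severity score are unobserved; compliance affects outcomes only through
#' mechanical power, so the effect remains backdoor-identifiable.
#'
#' @return A `causal_dag`.
#' @export
default_vent_dag <- function() {
  read_dag_file(system.file("extdata", "vent_dag.txt",
                            package = "ventcausal", mustWork = TRUE))
}
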