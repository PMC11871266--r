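# Independent oracles used across the suite. These deliberately take routes
# different from the package implementation: d-separation by exhaustive
# simple-path enumeration with per-path blocking rules (vs the moralised
# ancestral graph), argmin paths by an explicit per-column scan, order
# statistics by plain sorting.

# Descendants (inclusive) by direct BFS on the edge list.
oracle_descendants <- function(edges, node) {
  seen <- node
  frontier <- node
  while (length(frontier)) {
    nxt <- setdiff(unique(edges$child[edges$parent %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# d-separation by enumerating every simple undirected path and applying the
# blocking rules: a non-collider blocks iff it is conditioned on; a collider
# blocks iff neither it nor any descendant is conditioned on.
oracle_d_separated <- function(dag, a, b, given = character(0)) {
  edges <- dag$edges
  nbrs <- function(v) unique(c(edges$child[edges$parent == v],
                               edges$parent[edges$child == v]))
  is_edge <- function(p, c) any(edges$parent == p & edges$child == c)
  path_open <- function(path) {
    if (length(path) >= 3L) {
      for (i in 2:(length(path) - 1L)) {
        v <- path[i]
        collider <- is_edge(path[i - 1L], v) && is_edge(path[i + 1L], v)
        if (collider) {
          if (!any(oracle_descendants(edges, v) %in% given)) return(FALSE)
        } else if (v %in% given) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  open_found <- FALSE
  dfs <- function(v, path) {
    if (open_found) return(invisible())
    for (w in nbrs(v)) {
      if (w %in% path) next
      if (w == b) {
        if (path_open(c(path, w))) open_found <<- TRUE
      } else {
        dfs(w, c(path, w))
      }
    }
  }
  if (a == b) return(FALSE)
  dfs(a, a)
  !open_found
}

# All valid backdoor sets by brute force: every subset of observed
# non-descendants, validity checked with the path-enumeration d-separation
# oracle on the graph with the exposure's outgoing edges removed.
oracle_backdoor_sets <- function(dag, exposure, outcome,
                                 minimal_only = FALSE) {
  obs <- dag$nodes$name[dag$nodes$observed]
  de <- oracle_descendants(dag$edges, exposure)
  cand <- sort(setdiff(obs, c(outcome, de)))
  e2 <- dag$edges[dag$edges$parent != exposure, , drop = FALSE]
  dag2 <- list(nodes = dag$nodes, edges = e2)
  valid <- list()
  for (k in 0:length(cand)) {
    subsets <- if (k == 0L) list(character(0)) else {
      m <- utils::combn(cand, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }
    for (z in subsets) {
      if (oracle_d_separated(dag2, exposure, outcome, z)) {
        valid <- c(valid, list(z))
      }
    }
  }
  if (minimal_only && length(valid)) {
    keep <- vapply(valid, function(z) {
      !any(vapply(valid, function(v)
        length(v) < length(z) && all(v %in% z), TRUE))
    }, TRUE)
    valid <- valid[keep]
  }
  valid
}

canon_sets <- function(sets) {
  sort(vapply(sets, function(z) paste(sort(z), collapse = "|"), ""))
}

# Random DAG on <= n_max nodes: random topological order, Bernoulli edges,
# random latent flags; exposure and outcome always observed and distinct.
random_dag <- function(n_nodes, p_edge = 0.3, p_latent = 0.25, seed = 1L) {
  set.seed(seed)
  nm <- paste0("v", seq_len(n_nodes))
  eds <- list()
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (stats::runif(1) < p_edge) {
        eds[[length(eds) + 1L]] <- c(nm[i], nm[j])
      }
    }
  }
  edges <- if (length(eds)) {
    data.frame(parent = vapply(eds, `[`, "", 1L),
               child = vapply(eds, `[`, "", 2L), stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0))
  xy <- sample(nm, 2L)
  observed <- stats::runif(n_nodes) >= p_latent
  observed[match(xy, nm)] <- TRUE
  nodes <- data.frame(name = nm, observed = observed, role = "covariate",
                      stringsAsFactors = FALSE)
  causal_dag(nodes, edges, exposure = xy[1L], outcome = xy[2L])
}

# Random synthetic effect surface with a controlled masked fraction.
random_grid <- function(n_hours = 41, n_thresholds = 41, p_masked = 0.1,
                        seed = 1L) {
  set.seed(seed)
  est <- matrix(stats::rnorm(n_hours * n_thresholds), n_hours, n_thresholds)
  mask <- matrix(stats::runif(n_hours * n_thresholds) < p_masked,
                 n_hours, n_thresholds)
  # keep at least one open cell per hour
  for (i in which(rowSums(!mask) == 0L)) mask[i, 1L] <- FALSE
  est[mask] <- NA_real_
  cate_grid(seq_len(n_hours) - 1L, seq_len(n_thresholds) - 1L, est,
            mask = mask, estimator_tag = "synthetic", seed = seed)
}

# Per-column argmin scan, lowest threshold on ties.
oracle_argmin_path <- function(grid) {
  out <- numeric(length(grid$hours))
  for (i in seq_along(grid$hours)) {
    best <- NA_real_
    best_th <- NA_real_
    for (j in seq_along(grid$thresholds)) {
      e <- grid$estimates[i, j]
      if (!is.na(e) && (is.na(best) || e < best)) {
        best <- e
        best_th <- grid$thresholds[j]
      }
    }
    out[i] <- best_th
  }
  out
}
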