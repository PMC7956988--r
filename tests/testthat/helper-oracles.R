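# Independent oracles used across tests.

# --- d-separation by exhaustive undirected-path enumeration ----------------
# Works directly on the edge matrix; shares no code with the package's
# moralization-based implementation.

oracle_descendants <- function(em, v) {
  out <- v
  repeat {
    more <- setdiff(em[em[, 1] %in% out, 2], out)
    if (!length(more)) return(out)
    out <- c(out, more)
  }
}

# enumerate all simple undirected paths between x and y
oracle_paths <- function(em, nodes, x, y) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    nb <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
    for (w in setdiff(nb, path)) walk(c(path, w))
  }
  walk(x)
  paths
}

oracle_dsep <- function(g, x, y, z) {
  em <- dag_edges(g)
  z <- setdiff(union(z, g$selection), c(x, y))
  for (path in oracle_paths(em, g$nodes, x, y)) {
    if (length(path) == 2L) return(FALSE)  # direct edge, never blocked
    open <- TRUE
    for (i in 2:(length(path) - 1L)) {
      m <- path[i]
      into_left <- any(em[, 1] == path[i - 1L] & em[, 2] == m)
      into_right <- any(em[, 1] == path[i + 1L] & em[, 2] == m)
      if (into_left && into_right) {           # collider
        if (!length(intersect(oracle_descendants(em, m), z))) {
          open <- FALSE; break
        }
      } else if (m %in% z) {                   # chain or fork
        open <- FALSE; break
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

# minimal separating subsets by brute force over all conditioning sets
oracle_independencies <- function(g, observed) {
  observed <- sort(observed)
  out <- list()
  pairs <- utils::combn(observed, 2L)
  for (j in seq_len(ncol(pairs))) {
    x <- pairs[1L, j]; y <- pairs[2L, j]
    rest <- setdiff(observed, c(x, y))
    found <- NULL
    for (k in 0:length(rest)) {
      subs <- if (k == 0L) list(character()) else
        apply(utils::combn(rest, k), 2L, identity, simplify = FALSE)
      for (s in subs) if (oracle_dsep(g, x, y, s)) { found <- s; break }
      if (!is.null(found)) break
    }
    if (!is.null(found)) out[[length(out) + 1L]] <- list(x = x, y = y, z = found)
  }
  out
}

# random DAG on <= 7 nodes: edges respect a random topological order
random_dag <- function(n_nodes, p_edge = 0.4, n_selection = 0) {
  nodes <- LETTERS[seq_len(n_nodes)]
  ord <- sample(nodes)
  em <- NULL
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    if (stats::runif(1) < p_edge) em <- rbind(em, c(ord[i], ord[j]))
  }
  if (is.null(em)) em <- matrix(character(), 0, 2)
  sel <- if (n_selection > 0) sample(nodes, n_selection) else character()
  dag(em, nodes = nodes, selection = sel)
}

# --- small synthetic fixtures ---------------------------------------------

tiny_cohort <- function(n_hi = 60, n_nh = 0, seed = 1, ...) {
  simulate_cohort(cohort_config(n_hi = n_hi, n_nh = n_nh, ...), seed = seed)
}

# minimal hand-built psychfit-shaped object for deterministic method tests
mock_fit <- function(y, n_trials, cond, X, beta, beta0 = 0, sigma0 = 0,
                     pmiss = 0, spec = psych_model_spec("pta_only"),
                     n_draws = 2, group = rep("HI", length(y)),
                     standardization = list(
                       age = c(mean = 0, sd = 1), pta = c(mean = 0, sd = 1))) {
  stopifnot(identical(colnames(X), spec$terms))
  S <- 1L
  draws <- cbind(beta0 = rep(beta0, n_draws),
                 matrix(rep(beta, each = n_draws), n_draws,
                        dimnames = list(NULL, names(beta))),
                 sigma0 = sigma0, pmiss = pmiss, `z[1]` = 0)
  fit <- structure(list(
    draws = draws, spec = spec,
    diagnostics = data.frame(parameter = colnames(draws), rhat = 1, ess = Inf),
    divergences = 0L,
    standardization = standardization,
    data = list(y = y, n_trials = n_trials, cond = cond, X = X,
                site_idx = rep(1L, length(y)), site_levels = "S1",
                n_sites = S, group = group,
                participant_id = paste0("P", seq_along(y)),
                censored = rep(FALSE, length(y)),
                standardize = standardization),
    settings = list(chains = 1, iter = n_draws, warmup = 0, seed = 0),
    loglik = NULL), class = "psychfit")
  fit$loglik <- presbyfit:::pointwise_loglik(fit)
  fit
}
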