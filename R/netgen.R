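#' @title Random benchmark networks and tables
#' @name netgen
#' @keywords internal
NULL

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random benchmark network
#'
#' Produces signed networks with the structural features of biologically
#' motivated regulatory networks used for benchmarking: exactly
#' `round(edge_ratio * n)` edges, every node with in- and out-degree at
#' least 1, at most `max_in` incoming edges per node, and no simple
#' mediator nodes (exactly one incoming and one outgoing edge).  Edge signs
#' are independent uniform draws.
#'
#' The construction first places a random permutation cycle of edges (one
#' in- and one out-edge per node), then spends the remaining edges first on
#' nodes that are still mediators and finally uniformly at random, subject
#' to the in-degree cap and one-edge-per-ordered-pair; whole attempts that
#' cannot satisfy all constraints are rejected and retried.
#'
#' @param n node count.
#' @param edge_ratio target ratio of edges to nodes (default 2.5).
#' @param max_in maximum in-degree (default 6).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param max_retries whole-network rejection budget.
#' @return An `interaction_network` with nodes `n1`, ..., `n<n>`.
#' @export
random_network <- function(n, edge_ratio = 2.5, max_in = 6L, seed = NULL,
                           max_retries = 1000L) {
  stopifnot(n >= 2L, edge_ratio >= 1, max_in >= 1L)
  e_target <- round(edge_ratio * n)
  if (e_target > n * max_in)
    stop("infeasible configuration: ", e_target, " edges cannot satisfy ",
         "max in-degree ", max_in, " over ", n, " nodes")
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      net <- generate_attempt(n, e_target, max_in)
      if (!is.null(net)) return(net)
    }
    stop("random_network: max_retries exhausted")
  })
}

generate_attempt <- function(n, e_target, max_in) {
  perm <- sample.int(n)
  from <- seq_len(n); to <- perm
  present <- matrix(FALSE, n, n)
  present[cbind(from, to)] <- TRUE
  in_deg <- rep(1L, n); out_deg <- rep(1L, n)
  add_edge <- function(f, t) {
    from <<- c(from, f); to <<- c(to, t)
    present[f, t] <<- TRUE
    in_deg[t] <<- in_deg[t] + 1L; out_deg[f] <<- out_deg[f] + 1L
  }
  extra <- e_target - n
  while (extra > 0L) {
    mediators <- which(in_deg == 1L & out_deg == 1L)
    if (length(mediators) > 0L) {
      m <- mediators[sample.int(length(mediators), 1L)]
      # give the mediator a second incoming or outgoing edge
      placed <- FALSE
      for (dir in sample(c("in", "out"))) {
        if (dir == "in" && in_deg[m] < max_in) {
          srcs <- which(!present[, m])
          if (length(srcs)) {
            add_edge(srcs[sample.int(length(srcs), 1L)], m)
            placed <- TRUE; break
          }
        } else if (dir == "out") {
          tgts <- which(!present[m, ] & in_deg < max_in)
          if (length(tgts)) {
            add_edge(m, tgts[sample.int(length(tgts), 1L)])
            placed <- TRUE; break
          }
        }
      }
      if (!placed) return(NULL)
    } else {
      f <- sample.int(n, 1L)
      tgts <- which(!present[f, ] & in_deg < max_in)
      if (length(tgts) == 0L) {
        ok <- which(rowSums(!present & rep(in_deg < max_in, each = n)) > 0L)
        if (length(ok) == 0L) return(NULL)
        f <- ok[sample.int(length(ok), 1L)]
        tgts <- which(!present[f, ] & in_deg < max_in)
      }
      add_edge(f, tgts[sample.int(length(tgts), 1L)])
    }
    extra <- extra - 1L
  }
  if (any(in_deg == 1L & out_deg == 1L)) return(NULL)   # mediators remain
  sgn <- ifelse(stats::runif(length(from)) < 0.5, SIGN_ACTIVATING,
                SIGN_INHIBITING)
  nodes <- paste0("n", seq_len(n))
  make_network(nodes[from], nodes[to], sgn, nodes = nodes)
}

#' Random fully specified logical function table
#'
#' Draws every free logical parameter independently and uniformly from the
#' node's value range; the two mandatory boundary entries per node are kept
#' at their forced values, so single-input nodes are unaffected by the
#' draw.
#'
#' @param net an `interaction_network`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @inheritParams free_table
#' @return A fully specified `logic_table`.
#' @export
random_table <- function(net, seed = NULL, levels = rep(2L, net$n),
                         frozen = NULL) {
  tab <- free_table(net, levels = levels, frozen = frozen)
  with_seed(seed, {
    for (i in seq_len(net$n)) {
      img <- tab$funs[[i]]$images
      nf <- which(is.na(img))
      if (length(nf))
        tab$funs[[i]]$images[nf] <- sample.int(levels[i], length(nf),
                                               replace = TRUE) - 1L
    }
    tab
  })
}

#' Monte-Carlo estimate of the discontent-count distribution
#'
#' Samples states uniformly from the full state space and reports the
#' fraction with at most `kmax` discontent nodes — the relative size of the
#' subspace that the cycle search at bound `kmax` would enumerate.
#'
#' @param net an `interaction_network`.
#' @param table a fully specified `logic_table`.
#' @param kmax discontent bound.
#' @param n_samples number of uniform samples (>= 1).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A list with `fraction`, `ci_half_width` (normal-approximation
#'   95\% binomial half-width), `n_samples`, and `kmax`.
#' @export
estimate_discontent_fraction <- function(net, table, kmax, n_samples,
                                         seed = NULL) {
  stopifnot(n_samples >= 1L)
  if (!is_fully_specified(table))
    stop("discontent counts require a fully specified table")
  with_seed(seed, {
    states <- vapply(seq_len(net$n), function(i)
      sample.int(table$levels[i], n_samples, replace = TRUE) - 1L,
      integer(n_samples))
    if (n_samples == 1L) states <- matrix(states, nrow = 1L)
    img <- image_matrix(net, table, states)
    ndisc <- rowSums(img != states)
    p <- mean(ndisc <= kmax)
    list(fraction = p,
         ci_half_width = 1.96 * sqrt(p * (1 - p) / n_samples),
         n_samples = n_samples, kmax = kmax)
  })
}
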