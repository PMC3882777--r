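#' @title Stable-cycle detection in the k-discontent subspace
#' @description Cycle attractors cannot appear in the fixed-state subspace:
#'   every member of a cycle is at least 1-discontent.  Relaxing the
#'   build-up pruning to tolerate up to `kmax` discontent nodes per state
#'   yields a subspace that provably contains every j-cycle with
#'   `j <= kmax`; the asynchronous transition graph restricted to that
#'   subspace is then searched for closed cycles.
#' @name cycles
#' @keywords internal
NULL

#' Enumerate all states with at most kmax discontent nodes
#'
#' Incremental build-up identical to the fixed-state search, except that a
#' row is removed only when its count of evaluated discontent nodes exceeds
#' `kmax` (a node's content status is final as soon as it is evaluable, so
#' the count can only grow — the pruning is exact).  With `kmax = 0` this
#' reduces to the fixed-state search.  All fixed states of the network are
#' contained in the result and labeled 0.
#'
#' @param net an `interaction_network`.
#' @param table a fully specified `logic_table`.
#' @param kmax discontent bound (>= 0).
#' @param k0 initial group size.
#' @param row_limit memory guard, as in [find_fixed_states()].
#' @param verbose per-iteration log lines.
#' @return A `subspace_enumeration`: `states` (matrix ordered by state
#'   key), `disc` (per-state discontent count), `keys`, `kmax`,
#'   `peak_row_count`, `trace`.
#' @export
enumerate_subspace <- function(net, table, kmax, k0 = 10L, row_limit = 5e7,
                               verbose = FALSE) {
  stopifnot(kmax >= 0L)
  if (!is_fully_specified(table))
    stop("subspace enumeration requires a fully specified table ",
         "(discontent counts are undefined under FREE parameters)")
  psm <- build_up_enumeration(net, table, kmax = kmax, k0 = k0,
                              row_limit = row_limit, verbose = verbose)
  keys <- state_keys(psm$vals, state_weights(table$levels))
  o <- order(keys)
  structure(list(states = psm$vals[o, , drop = FALSE], disc = psm$disc[o],
                 keys = keys[o], kmax = kmax, levels = table$levels,
                 peak_row_count = psm$peak_row_count, trace = psm$trace),
            class = "subspace_enumeration")
}

#' @export
print.subspace_enumeration <- function(x, ...) {
  cat(sprintf("Subspace enumeration: %d state(s) with <= %d discontent node(s)\n",
              nrow(x$states), x$kmax))
  invisible(x)
}

#' Asynchronous transition graph over an enumerated subspace
#'
#' Records, for every enumerated state, its successors and predecessors
#' within the set.  A state with at least one successor escaping the set is
#' flagged as a boundary state: its full fate cannot be assessed inside the
#' subspace, so it is barred from attractor membership (it may still belong
#' to basins).
#'
#' @param enum a `subspace_enumeration`.
#' @param net an `interaction_network`.
#' @param table the fully specified `logic_table` used for the enumeration.
#' @return A `transition_graph`: `states`, `keys`, `disc`, `succ`/`pred`
#'   (adjacency lists of in-set state indices), `boundary` (logical), and
#'   `n_succ_total` (the discontent count, equal to the number of
#'   successors including escaping ones).
#' @export
build_graph <- function(enum, net, table) {
  states <- enum$states
  S <- nrow(states)
  img <- image_matrix(net, table, states)
  disc <- img != states
  wts <- state_weights(table$levels)
  keys <- enum$keys
  efrom <- integer(0); eto <- integer(0)
  boundary <- logical(S)
  for (i in seq_len(net$n)) {
    rows <- which(disc[, i])
    if (!length(rows)) next
    step <- sign(img[rows, i] - states[rows, i])
    tokey <- keys[rows] + step * wts[i]
    toidx <- match(tokey, keys)
    out <- is.na(toidx)
    boundary[rows[out]] <- TRUE
    efrom <- c(efrom, rows[!out])
    eto <- c(eto, toidx[!out])
  }
  fct <- function(v) factor(v, levels = seq_len(S))
  structure(list(states = states, keys = keys, disc = rowSums(disc),
                 succ = split(eto, fct(efrom)), pred = split(efrom, fct(eto)),
                 boundary = boundary, n_succ_total = rowSums(disc),
                 levels = table$levels),
            class = "transition_graph")
}

#' Basins of attraction of the fixed states
#'
#' Walks the predecessor relation "uphill" from every 0-discontent state,
#' labeling and counting all states of the enumerated set from which that
#' fixed state is reachable.  A state may belong to several basins.
#'
#' @param graph a `transition_graph`.
#' @return A list with `fixed_idx` (state indices of the fixed states),
#'   `basins` (per fixed state, the indices of its basin members, the fixed
#'   state included), and `labeled` (logical over all states: member of at
#'   least one fixed-state basin).
#' @export
fixed_state_basins <- function(graph) {
  fixed_idx <- which(graph$disc == 0L)
  basins <- lapply(fixed_idx, function(f) reverse_reach(graph$pred, f))
  labeled <- logical(length(graph$keys))
  for (b in basins) labeled[b] <- TRUE
  list(fixed_idx = fixed_idx, basins = basins, labeled = labeled)
}

#' Detect stable cycles in the restricted transition graph
#'
#' Searches the states that are neither in a fixed-state basin nor on the
#' subspace boundary.  A stable cycle is a set of two or more mutually
#' reachable states all of whose successors (recomputed over the full
#' successor lists) remain inside the set — "closed", in other words: the
#' system cannot escape it.  Candidate member sets are the strongly
#' connected components of the restricted graph; a component with any
#' successor escaping to a basin, to the boundary, or to another component
#' is discarded as unstable.  Each cycle is classified by
#' `k = max` member discontent count (`simple` iff `k == 1`, every member
#' then having exactly one successor; `mixed` otherwise, with branching)
#' and its basin is computed by reverse reachability.
#'
#' @param graph a `transition_graph`.
#' @param basins result of [fixed_state_basins()] on the same graph.
#' @return A list of attractor records (members, `k`, shape, basin size).
#' @export
find_stable_cycles <- function(graph, basins) {
  cand <- which(!basins$labeled & !graph$boundary & graph$disc > 0L)
  if (length(cand) == 0L) return(list())
  pos <- match(seq_along(graph$keys), cand)     # graph idx -> candidate idx
  efrom <- integer(0); eto <- integer(0)
  for (u in cand) {
    vs <- graph$succ[[u]]
    vs <- vs[!is.na(pos[vs])]
    efrom <- c(efrom, rep(pos[u], length(vs)))
    eto <- c(eto, pos[vs])
  }
  comp <- if (length(efrom)) {
    g <- igraph::make_graph(rbind(efrom, eto), n = length(cand),
                            directed = TRUE)
    igraph::components(g, mode = "strong")$membership
  } else seq_along(cand)
  out <- list()
  for (cid in unique(comp)) {
    members <- cand[comp == cid]
    if (length(members) < 2L) next
    allsucc <- unique(unlist(graph$succ[members], use.names = FALSE))
    if (!all(allsucc %in% members)) next        # leaks: unstable
    k <- max(graph$disc[members])
    out[[length(out) + 1L]] <- list(
      id = NA_integer_, kind = "cycle",
      members = graph$states[members, , drop = FALSE],
      member_keys = sort(graph$keys[members]),
      k = k, shape = if (k == 1L) "simple" else "mixed",
      basin_size = length(reverse_reach(graph$pred, members)),
      constraints = NULL)
  }
  out
}

#' Full attractor analysis within the kmax-discontent subspace
#'
#' Two-stage procedure: (i) enumerate all states with at most `kmax`
#' discontent nodes and build the asynchronous transition graph restricted
#' to them; (ii) compute the fixed states and their basins by reverse
#' reachability, then search the remaining unlabeled, non-boundary states
#' for stable (closed) cycles.  Every j-cycle with `j <= kmax` whose
#' members' successors all lie in the subspace is found; larger `kmax`
#' enumerates more states and finds more cycles, up to `kmax = n`, which is
#' an exhaustive analysis of the whole state space.
#'
#' @param net an `interaction_network`.
#' @param table a fully specified `logic_table`.
#' @param kmax discontent bound (default 1: fixed states plus simple
#'   cycles).
#' @param k0 initial group size of the build-up enumeration.
#' @param row_limit memory guard.
#' @param verbose per-iteration log lines.
#' @return An `attractor_set` (fixed states first, ordered by state key,
#'   then cycles by smallest member key) with `peak_row_count` and `trace`
#'   from the enumeration; basin sizes are counted within the enumerated
#'   subspace.
#' @export
run_cycle_analysis <- function(net, table, kmax = 1L, k0 = 10L,
                               row_limit = 5e7, verbose = FALSE) {
  enum <- enumerate_subspace(net, table, kmax = kmax, k0 = k0,
                             row_limit = row_limit, verbose = verbose)
  graph <- build_graph(enum, net, table)
  fb <- fixed_state_basins(graph)
  attractors <- lapply(seq_along(fb$fixed_idx), function(j) {
    f <- fb$fixed_idx[j]
    list(id = NA_integer_, kind = "fixed_state",
         members = graph$states[f, , drop = FALSE],
         member_keys = graph$keys[f], k = 0L, shape = NA,
         basin_size = length(fb$basins[[j]]), constraints = NULL)
  })
  attractors <- c(attractors, find_stable_cycles(graph, fb))
  res <- new_attractor_set(order_attractors(attractors),
                           n_states = nrow(enum$states),
                           levels = table$levels)
  res$kmax <- kmax
  res$peak_row_count <- enum$peak_row_count
  res$trace <- enum$trace
  res
}
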