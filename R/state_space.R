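#' @title State space primitives and the brute-force oracle
#' @name state_space
#' @keywords internal
NULL

# node i contributes value * prod(levels of nodes before i) to the integer
# key of a state; node 1 is the least significant digit
state_weights <- function(levels) {
  n <- length(levels)
  cumprod(c(1, as.numeric(levels[-n])))
}

state_keys <- function(states, weights) {
  as.numeric(states %*% weights)
}

key_to_state <- function(key, levels) {
  n <- length(levels)
  v <- integer(n)
  r <- key
  for (i in seq_len(n)) {
    v[i] <- r %% levels[i]
    r <- r %/% levels[i]
  }
  v
}

# S x n matrix of node images for every row-state; NA where the relevant
# logical parameter is FREE
image_matrix <- function(net, table, states) {
  S <- nrow(states)
  img <- matrix(NA_integer_, S, net$n)
  for (i in seq_len(net$n)) {
    f <- table$funs[[i]]
    if (length(f$inputs) == 0L) {
      img[, i] <- f$images
    } else {
      w <- cumprod(c(1, as.numeric(f$input_levels[-length(f$input_levels)])))
      idx <- as.numeric(states[, f$inputs, drop = FALSE] %*% w) + 1
      img[, i] <- f$images[idx]
    }
  }
  img
}

#' Asynchronous successors of a state
#'
#' Under general asynchronous updating, a k-discontent state has exactly k
#' successors: each one updates a single discontent node, setting it one
#' level towards its image (for binary nodes, flipping it).  Content nodes
#' never change.
#'
#' @param net an `interaction_network`.
#' @param table a fully specified `logic_table`.
#' @param state integer vector of length n.
#' @return An integer matrix with one successor state per row (zero rows
#'   for a fixed state).
#' @export
successors <- function(net, table, state) {
  img <- image_matrix(net, table, matrix(state, nrow = 1L))[1L, ]
  if (anyNA(img))
    stop("successor generation requires a fully specified table ",
         "(FREE image encountered)")
  disc <- which(img != state)
  if (length(disc) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = net$n,
                  dimnames = list(NULL, net$nodes)))
  out <- matrix(state, nrow = length(disc), ncol = net$n, byrow = TRUE)
  for (j in seq_along(disc)) {
    i <- disc[j]
    out[j, i] <- state[i] + sign(img[i] - state[i])
  }
  out
}

new_attractor_set <- function(attractors, n_states, levels) {
  structure(list(attractors = attractors, n_states = n_states,
                 levels = levels),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("Attractor set: %d attractor(s) over %s enumerated state(s)\n",
              length(x$attractors), format(x$n_states, big.mark = ",")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.attractor_set <- function(x, ...) {
  do.call(rbind, c(lapply(x$attractors, function(a)
    data.frame(id = a$id, kind = a$kind, k = a$k,
               shape = if (is.na(a$shape)) NA_character_ else a$shape,
               member_count = nrow(a$members),
               basin_size = a$basin_size)),
    list(make.row.names = FALSE)))
}

# order: fixed states by state key, then cycles by smallest member key
order_attractors <- function(attractors) {
  if (length(attractors) == 0L) return(attractors)
  fixed <- vapply(attractors, function(a) a$kind == "fixed_state", TRUE)
  firstkey <- vapply(attractors, function(a) min(a$member_keys), 0)
  attractors <- attractors[order(!fixed, firstkey)]
  for (j in seq_along(attractors)) attractors[[j]]$id <- j
  attractors
}

reverse_reach <- function(pred, start) {
  visited <- logical(length(pred))
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(pred[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  which(visited)
}

#' Brute-force attractor detection over the full state space
#'
#' Independent reference method for small networks: enumerates every state,
#' builds the complete asynchronous state transition graph, and returns the
#' fixed states (0-discontent states) together with the terminal strongly
#' connected components (components without outgoing edges) as cycle
#' attractors.  The basin of an attractor is the set of all states from
#' which it is reachable.
#'
#' @param net an `interaction_network`.
#' @param table a fully specified `logic_table`.
#' @param max_states guard on the full state-space size (default `2^20`).
#' @return An `attractor_set`; each attractor carries its member states,
#'   its discontent bound `k`, its shape (`simple` iff `k == 1`), and its
#'   basin size.
#' @export
brute_force_attractors <- function(net, table, max_states = 2^20) {
  if (!is_fully_specified(table))
    stop("brute-force search requires a fully specified table")
  levels <- table$levels
  S <- prod(as.numeric(levels))
  if (S > max_states)
    stop("state space too large for brute force (", S, " states)")
  S <- as.integer(S)
  n <- net$n
  states <- matrix(0L, S, n, dimnames = list(NULL, net$nodes))
  w <- 1L
  for (i in seq_len(n)) {
    states[, i] <- rep(rep(0:(levels[i] - 1L), each = w), length.out = S)
    w <- w * levels[i]
  }
  img <- image_matrix(net, table, states)
  disc <- img != states
  ndisc <- rowSums(disc)
  wts <- state_weights(levels)
  keys <- state_keys(states, wts)       # keys == 0:(S-1); index = key + 1
  efrom <- integer(0); eto <- integer(0)
  for (i in seq_len(n)) {
    rows <- which(disc[, i])
    if (!length(rows)) next
    step <- sign(img[rows, i] - states[rows, i])
    efrom <- c(efrom, rows)
    eto <- c(eto, as.integer(keys[rows] + step * wts[i]) + 1L)
  }
  comp <- if (length(efrom)) {
    g <- igraph::make_graph(rbind(efrom, eto), n = S, directed = TRUE)
    igraph::components(g, mode = "strong")$membership
  } else rep(seq_len(S))
  leaving <- unique(comp[efrom][comp[efrom] != comp[eto]])
  terminal <- setdiff(unique(comp), leaving)
  pred <- split(efrom, factor(eto, levels = seq_len(S)))
  attractors <- list()
  for (cid in terminal) {
    members <- which(comp == cid)
    if (length(members) == 1L && ndisc[members] > 0L) next  # transient singleton
    kind <- if (length(members) == 1L) "fixed_state" else "cycle"
    k <- max(ndisc[members])
    attractors[[length(attractors) + 1L]] <- list(
      id = NA_integer_, kind = kind,
      members = states[members, , drop = FALSE],
      member_keys = sort(keys[members]),
      k = k,
      shape = if (kind == "cycle") { if (k == 1L) "simple" else "mixed" } else NA,
      basin_size = length(reverse_reach(pred, members)),
      constraints = NULL)
  }
  new_attractor_set(order_attractors(attractors), S, levels)
}
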