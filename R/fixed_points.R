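#' @title Incremental build-up fixed-state search
#' @description The search enumerates partial value assignments over a
#'   growing subset of nodes, pruning every row in which an already
#'   evaluable node violates its logical function.  Removing a row removes
#'   all of its exponentially many full-state extensions at once, which is
#'   what keeps the enumerated set orders of magnitude below `2^n`.
#' @name fixed_points
#' @keywords internal
NULL

#' Initial node group for the build-up search
#'
#' Selects the `k0` nodes with the highest out-degree (ties broken by node
#' order).  High out-degree nodes feed many others, which maximizes the
#' chance that subsequently added nodes have all their inputs already in
#' the matrix and can be evaluated (and pruned on) immediately.
#'
#' @param net an `interaction_network`.
#' @param k0 size of the initial group, `1 <= k0 <= n`.
#' @return Integer vector of node indices, in selection order.
#' @export
choose_initial_nodes <- function(net, k0) {
  stopifnot(k0 >= 1L, k0 <= net$n)
  order(-net$out_deg, seq_len(net$n))[seq_len(k0)]
}

#' Next node to add to the partial state matrix
#'
#' Prefers a node all of whose inputs are already included (it can be
#' evaluated, and rows pruned, as soon as it is added); among several such
#' nodes the one with the highest out-degree wins, then node order.  If no
#' node is fully fed by the matrix, the not-yet-included node with maximal
#' out-degree is chosen.
#'
#' @param net an `interaction_network`.
#' @param included integer vector of node indices already in the matrix.
#' @return A single node index.
#' @export
next_node <- function(net, included) {
  remaining <- setdiff(seq_len(net$n), included)
  if (length(remaining) == 0L) stop("all nodes already included")
  ready <- remaining[vapply(remaining, function(i)
    all(net$in_nbrs[[i]] %in% included), TRUE)]
  pool <- if (length(ready)) ready else remaining
  pool[order(-net$out_deg[pool], pool)][1L]
}

#' Empty partial state matrix
#'
#' The bootstrap object of the build-up search: a single row over zero
#' nodes, extended node by node with [expand()] and [prune()].
#'
#' @param track_constraints record per-row parameter constraints (needed
#'   when the table has FREE entries).
#' @return A `partial_state_matrix` with one row and no columns.
#' @export
new_partial_matrix <- function(track_constraints = FALSE) {
  structure(list(node_order = integer(0),
                 vals = matrix(0L, 1L, 0L),
                 evaluated = integer(0),
                 disc = 0L,
                 constraints = if (track_constraints) list(list()) else NULL,
                 peak_row_count = 1L),
            class = "partial_state_matrix")
}

#' Extend a partial state matrix by one node
#'
#' Replicates the matrix `m` times (once per level of the added node) and
#' appends the new column; accumulated constraints and discontent counts
#' are copied to the replicates.
#'
#' @param psm a `partial_state_matrix`.
#' @param node node index to add (must not already be included).
#' @param m number of levels of the node (2 for binary).
#' @return The extended matrix with `m` times as many rows.
#' @export
expand <- function(psm, node, m = 2L) {
  if (node %in% psm$node_order) stop("node already included")
  stopifnot(m >= 2L)
  nr <- nrow(psm$vals)
  rep_idx <- rep(seq_len(nr), m)
  psm$vals <- cbind(psm$vals[rep_idx, , drop = FALSE],
                    rep(0:(m - 1L), each = nr))
  psm$node_order <- c(psm$node_order, node)
  psm$disc <- psm$disc[rep_idx]
  if (!is.null(psm$constraints)) psm$constraints <- psm$constraints[rep_idx]
  psm$peak_row_count <- max(psm$peak_row_count, nrow(psm$vals))
  psm
}

#' Evaluate newly evaluable nodes and prune violating rows
#'
#' A node becomes evaluable once all its inputs are included in the matrix;
#' its content status in a row is then final.  For every row and every
#' newly evaluable node: a DISCONTENT node increments the row's discontent
#' count, and rows whose count exceeds `kmax` are removed (with the default
#' `kmax = 0`, any violation removes the row — the fixed-state contract);
#' an UNDETERMINED node (FREE parameter) appends the constraint "parameter
#' at this pattern must equal the row's value" to the row; a CONTENT node
#' leaves the row unchanged.
#'
#' @param psm a `partial_state_matrix`.
#' @param net an `interaction_network`.
#' @param table a `logic_table` (must be fully specified when `kmax > 0`).
#' @param kmax maximum tolerated discontent count per row (default 0).
#' @return The pruned matrix with its evaluated set updated.
#' @export
prune <- function(psm, net, table, kmax = 0L) {
  if (kmax > 0L && !is_fully_specified(table))
    stop("discontent-bounded enumeration requires a fully specified table")
  included <- psm$node_order
  newly <- setdiff(included[vapply(included, function(i)
    all(net$in_nbrs[[i]] %in% included), TRUE)], psm$evaluated)
  col_of <- match(seq_len(net$n), psm$node_order)
  for (i in newly) {
    if (nrow(psm$vals) == 0L) break
    f <- table$funs[[i]]
    if (length(f$inputs) == 0L) {
      img <- rep(f$images, nrow(psm$vals))
    } else {
      w <- cumprod(c(1, as.numeric(f$input_levels[-length(f$input_levels)])))
      idx <- as.numeric(psm$vals[, col_of[f$inputs], drop = FALSE] %*% w) + 1
      img <- f$images[idx]
    }
    cur <- psm$vals[, col_of[i]]
    und <- is.na(img)
    psm$disc <- psm$disc + as.integer(!und & img != cur)
    keep <- und | psm$disc <= kmax
    if (any(und)) {
      if (is.null(psm$constraints))
        stop("FREE image encountered but constraints are not tracked")
      for (r in which(und)) {
        psm$constraints[[r]] <- c(psm$constraints[[r]],
                                  list(list(node = i, pattern = idx[r],
                                            value = cur[r])))
      }
    }
    if (!all(keep)) {
      psm$vals <- psm$vals[keep, , drop = FALSE]
      psm$disc <- psm$disc[keep]
      if (!is.null(psm$constraints)) psm$constraints <- psm$constraints[keep]
    }
  }
  psm$evaluated <- c(psm$evaluated, newly)
  psm
}

abort_row_limit <- function(trace, rows, row_limit) {
  stop(structure(class = c("row_limit_error", "error", "condition"),
                 list(message = sprintf(
                   "row limit exceeded (%d rows > limit %d) after including %d node(s)",
                   rows, row_limit, nrow(trace)),
                   call = NULL, trace = trace)))
}

# shared driver for the fixed-state search (kmax = 0) and the k-discontent
# subspace enumeration (kmax > 0)
build_up_enumeration <- function(net, table, kmax, k0, row_limit,
                                 verbose = FALSE) {
  n <- net$n
  k0 <- max(1L, min(k0, n))
  stopifnot(row_limit >= 1L)
  track <- !is_fully_specified(table)
  psm <- new_partial_matrix(track)
  plan <- choose_initial_nodes(net, k0)
  trace <- data.frame(iter = integer(0), nodes = integer(0),
                      rows_expanded = integer(0), rows = integer(0))
  iter <- 0L
  while (length(psm$node_order) < n) {
    iter <- iter + 1L
    node <- if (iter <= length(plan)) plan[iter] else
      next_node(net, psm$node_order)
    psm <- expand(psm, node, table$levels[node])
    expanded <- nrow(psm$vals)
    if (expanded > row_limit)
      abort_row_limit(trace, expanded, row_limit)
    psm <- prune(psm, net, table, kmax = kmax)
    trace <- rbind(trace, data.frame(iter = iter,
                                     nodes = length(psm$node_order),
                                     rows_expanded = expanded,
                                     rows = nrow(psm$vals)))
    if (verbose)
      message(sprintf("iter=%d nodes=%d rows=%d", iter,
                      length(psm$node_order), nrow(psm$vals)))
  }
  # reorder columns from inclusion order to network node order
  perm <- match(seq_len(n), psm$node_order)
  psm$vals <- psm$vals[, perm, drop = FALSE]
  colnames(psm$vals) <- net$nodes
  psm$node_order <- seq_len(n)
  psm$trace <- trace
  psm
}

#' Find all fixed states, with logical-parameter constraints
#'
#' Runs the incremental build-up search: start from all value combinations
#' of the `k0` highest-out-degree nodes, then repeatedly add one node
#' (preferring nodes whose inputs are all present), duplicate the matrix,
#' and remove every row in which an evaluable node is discontent.  When all
#' nodes have been processed, the surviving rows are exactly the fixed
#' states.  Under a partially specified table a row survives if the node
#' can be content for *some* choice of the free parameters; the required
#' parameter values are accumulated per row and reported, so the result
#' covers all fixed states of every completion of the table.
#'
#' @param net an `interaction_network`.
#' @param table a `logic_table` (free, default, or custom).
#' @param k0 initial group size (default 10, clamped to `n`).
#' @param row_limit abort threshold on the row count of the partial matrix
#'   (memory guard); exceeding it raises an error of class
#'   `row_limit_error` carrying the per-iteration trace.
#' @param verbose emit one `iter=… nodes=… rows=…` log line per iteration.
#' @return An object of class `fixed_state_search`: `states` (matrix, one
#'   fixed state per row, columns in node order, rows ordered by state
#'   key), `constraints` (per state, a data frame of required free-parameter
#'   values, zero rows when the table is fully specified),
#'   `peak_row_count`, and `trace`.
#' @export
find_fixed_states <- function(net, table, k0 = 10L, row_limit = 5e7,
                              verbose = FALSE) {
  psm <- build_up_enumeration(net, table, kmax = 0L, k0 = k0,
                              row_limit = row_limit, verbose = verbose)
  keys <- state_keys(psm$vals, state_weights(table$levels))
  o <- order(keys)
  states <- psm$vals[o, , drop = FALSE]
  constraints <- lapply(seq_len(nrow(states)), function(j) {
    cs <- if (is.null(psm$constraints)) list() else psm$constraints[[o[j]]]
    if (length(cs) == 0L)
      return(data.frame(node = character(0), pattern = character(0),
                        value = integer(0), display = character(0)))
    do.call(rbind, lapply(cs, function(co) data.frame(
      node = net$nodes[co$node],
      pattern = paste(index_to_pattern(co$pattern,
                                       table$funs[[co$node]]$input_levels),
                      collapse = ""),
      value = co$value,
      display = format_constraint(table, co))))
  })
  structure(list(states = states, constraints = constraints,
                 peak_row_count = psm$peak_row_count, trace = psm$trace,
                 nodes = net$nodes),
            class = "fixed_state_search")
}

#' @export
print.fixed_state_search <- function(x, ...) {
  cat(sprintf("Fixed-state search: %d fixed state(s), peak %s enumerated row(s)\n",
              nrow(x$states), format(x$peak_row_count, big.mark = ",")))
  for (j in seq_len(nrow(x$states))) {
    cond <- if (nrow(x$constraints[[j]]) > 0L)
      paste0("  if ", paste(x$constraints[[j]]$display, collapse = " and "))
    else ""
    cat("  (", paste(x$states[j, ], collapse = ","), ")", cond, "\n", sep = "")
  }
  invisible(x)
}
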