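#' boolattract: attractor detection in asynchronous Boolean networks
#'
#' Detects fixed states and stable cycles of asynchronously updated Boolean
#' regulatory networks by exhaustive enumeration of pruned subspaces of the
#' state space.  Logical functions follow the Thomas positive-influence
#' parameterization and may be partially specified; fixed states found under
#' a partially specified table carry the constraints on the free logical
#' parameters that realize them.
#'
#' @keywords internal
"_PACKAGE"

SIGN_ACTIVATING <- 1L
SIGN_INHIBITING <- -1L

#' Build a signed interaction network from an edge list
#'
#' Nodes are ordered by first appearance (sources before targets, in edge
#' order) unless an explicit `nodes` vector is given; that order is the
#' tie-breaking order used throughout the package.
#'
#' @param from,to character vectors of source and target node labels.
#' @param sign integer vector, `+1` for activation, `-1` for inhibition.
#' @param nodes optional character vector fixing node order; must contain
#'   every edge endpoint.
#' @return An object of class `interaction_network` with elements `nodes`,
#'   `n`, `edges` (data frame with integer columns `from`, `to`, `sign`),
#'   `in_nbrs`/`in_signs` (per-node input lists, inputs sorted in node
#'   order), `in_deg`, and `out_deg`.
#' @export
make_network <- function(from, to, sign, nodes = NULL) {
  stopifnot(length(from) == length(to), length(sign) == length(from))
  if (!all(sign %in% c(SIGN_ACTIVATING, SIGN_INHIBITING)))
    stop("edge signs must be +1 (activating) or -1 (inhibiting)")
  if (is.null(nodes)) {
    nodes <- unique(as.vector(rbind(as.character(from), as.character(to))))
  }
  if (length(nodes) < 1L) stop("empty network")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  if (anyNA(fi) || anyNA(ti)) stop("edge endpoint not among declared nodes")
  pair <- paste0(fi, ":", ti)
  if (anyDuplicated(pair)) {
    d <- duplicated(pair)
    # identical duplicates collapse; opposite-sign duplicates are rejected
    for (p in unique(pair[d])) {
      s <- unique(sign[pair == p])
      if (length(s) > 1L)
        stop("dual-sign pair: ", from[match(p, pair)], " both activates and inhibits ",
             to[match(p, pair)])
    }
    warning("duplicate edges collapsed")
    keep <- !d
    fi <- fi[keep]; ti <- ti[keep]; sign <- sign[keep]
  }
  n <- length(nodes)
  edges <- data.frame(from = fi, to = ti, sign = as.integer(sign))
  in_nbrs <- vector("list", n)
  in_signs <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(edges$to == i)
    o <- order(edges$from[idx])            # inputs in network node order
    in_nbrs[[i]] <- edges$from[idx][o]
    in_signs[[i]] <- edges$sign[idx][o]
  }
  net <- list(nodes = nodes, n = n, edges = edges,
              in_nbrs = in_nbrs, in_signs = in_signs,
              in_deg = lengths(in_nbrs),
              out_deg = tabulate(edges$from, nbins = n))
  class(net) <- "interaction_network"
  net
}

#' Parse a signed interaction network from text lines
#'
#' One interaction per line: `SRC -> TGT` for activation, `SRC -| TGT` for
#' inhibition, whitespace-separated (the plain-text format also used by
#' GenYsis).  Lines starting with `#` are comments; blank lines are ignored.
#' Duplicate identical lines are collapsed with a warning; a pair of nodes
#' carrying both an activating and an inhibiting edge is rejected.
#'
#' @param lines character vector of input lines.
#' @return An `interaction_network`; node order is first-appearance order.
#' @examples
#' net <- parse_network(c("A -> B", "B -| A"))
#' net$n
#' @export
parse_network <- function(lines) {
  stripped <- sub("#.*$", "", lines)
  stripped <- trimws(stripped)
  keep <- nzchar(stripped)
  if (!any(keep)) stop("empty network: no interactions found")
  lineno <- which(keep)
  toks <- strsplit(stripped[keep], "[[:space:]]+")
  from <- character(0); to <- character(0); sgn <- integer(0)
  for (j in seq_along(toks)) {
    tk <- toks[[j]]
    if (length(tk) != 3L || !(tk[2] %in% c("->", "-|")))
      stop(sprintf("line %d: expected '<src> -> <tgt>' or '<src> -| <tgt>', got '%s'",
                   lineno[j], stripped[keep][j]))
    from <- c(from, tk[1]); to <- c(to, tk[3])
    sgn <- c(sgn, if (tk[2] == "->") SIGN_ACTIVATING else SIGN_INHIBITING)
  }
  make_network(from, to, sgn)
}

#' Read a network from a text file
#' @param file path to a network file in the line-oriented text format.
#' @return An `interaction_network`.
#' @export
read_network <- function(file) parse_network(readLines(file))

#' Write a network in the line-oriented text format
#' @param net an `interaction_network`.
#' @param file output path or connection.
#' @export
write_network <- function(net, file) {
  op <- ifelse(net$edges$sign == SIGN_ACTIVATING, "->", "-|")
  writeLines(paste(net$nodes[net$edges$from], op, net$nodes[net$edges$to]), file)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              x$n, nrow(x$edges), sum(x$edges$sign == SIGN_ACTIVATING),
              sum(x$edges$sign == SIGN_INHIBITING)))
  invisible(x)
}

#' Structural summary of a network
#'
#' Reports the quantities used to characterize benchmark networks: the
#' edge-to-node ratio, the maximum in-degree, the presence of nodes with
#' zero in- or out-degree, and the list of mediator nodes (exactly one
#' incoming and one outgoing edge).
#'
#' @param net an `interaction_network`.
#' @return A list with elements `edge_to_node_ratio`, `max_in_degree`,
#'   `has_zero_in_degree`, `has_zero_out_degree`, `mediator_nodes`.
#' @export
network_report <- function(net) {
  list(edge_to_node_ratio = nrow(net$edges) / net$n,
       max_in_degree = max(net$in_deg),
       has_zero_in_degree = any(net$in_deg == 0L),
       has_zero_out_degree = any(net$out_deg == 0L),
       mediator_nodes = net$nodes[net$in_deg == 1L & net$out_deg == 1L])
}

#' Enumerate signed feedback loops
#'
#' Finds all elementary directed circuits of length at most `max_length`.
#' The sign of a circuit is the parity of its inhibiting edges: an even
#' count gives a positive loop (switch-like/differentiation behaviour), an
#' odd count a negative loop (homeostasis/oscillation).
#'
#' Circuits are reported in canonical rotation (starting at the member that
#' appears earliest in node order) and ordered by length, then
#' lexicographically by member indices.
#'
#' @param net an `interaction_network`.
#' @param max_length maximum number of edges in a circuit (>= 1).
#' @return A data frame with columns `circuit` (comma-joined labels),
#'   `length`, `inhibiting_edge_count`, `sign` (`"positive"`/`"negative"`).
#' @export
find_feedback_loops <- function(net, max_length = net$n) {
  stopifnot(max_length >= 1L)
  n <- net$n
  out_adj <- vector("list", n)
  sign_of <- new.env(hash = TRUE)
  for (e in seq_len(nrow(net$edges))) {
    f <- net$edges$from[e]; t <- net$edges$to[e]
    out_adj[[f]] <- c(out_adj[[f]], t)
    assign(paste0(f, ":", t), net$edges$sign[e], envir = sign_of)
  }
  for (i in seq_len(n)) out_adj[i] <- list(sort(out_adj[[i]]))
  circuits <- list()
  # elementary circuits: only start each circuit at its smallest-index member
  walk <- function(start, path, visited) {
    v <- path[length(path)]
    for (w in out_adj[[v]]) {
      if (w == start && length(path) <= max_length) {
        circuits[[length(circuits) + 1L]] <<- path
      } else if (w > start && !visited[w] && length(path) < max_length) {
        visited[w] <- TRUE
        walk(start, c(path, w), visited)
        visited[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- logical(n); visited[s] <- TRUE
    walk(s, s, visited)
  }
  if (length(circuits) == 0L)
    return(data.frame(circuit = character(0), length = integer(0),
                      inhibiting_edge_count = integer(0), sign = character(0)))
  len <- lengths(circuits)
  keystr <- vapply(circuits, function(p) paste(sprintf("%06d", p), collapse = ","), "")
  o <- order(len, keystr)
  circuits <- circuits[o]
  inh <- vapply(circuits, function(p) {
    nxt <- c(p[-1], p[1])
    sum(vapply(seq_along(p), function(i)
      get(paste0(p[i], ":", nxt[i]), envir = sign_of), 0L) == SIGN_INHIBITING)
  }, 0L)
  data.frame(
    circuit = vapply(circuits, function(p) paste(net$nodes[p], collapse = ","), ""),
    length = lengths(circuits),
    inhibiting_edge_count = inh,
    sign = ifelse(inh %% 2L == 0L, "positive", "negative"))
}
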