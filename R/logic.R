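#' @title Logical function tables
#' @description Internal helpers plus the exported constructors for the
#'   Thomas-style pattern-table parameterization of node logical functions.
#' @name logic
#' @keywords internal
NULL

FREE <- NA_integer_

# mixed-radix index of an input pattern; the node's first input (in network
# node order) is the least significant digit.  1-based.
pattern_index <- function(values, radices) {
  if (length(values) == 0L) return(1L)
  w <- cumprod(c(1L, radices[-length(radices)]))
  as.integer(1L + sum(values * w))
}

index_to_pattern <- function(idx, radices) {
  k <- length(radices)
  if (k == 0L) return(integer(0))
  v <- integer(k)
  r <- idx - 1L
  for (j in seq_len(k)) {
    v[j] <- r %% radices[j]
    r <- r %/% radices[j]
  }
  v
}

# the two mandatory boundary patterns of a node: "optimal" (all activators
# at their maximum level, all inhibitors absent) and its opposite
boundary_patterns <- function(signs, input_levels) {
  opt <- ifelse(signs == SIGN_ACTIVATING, input_levels - 1L, 0L)
  pes <- ifelse(signs == SIGN_ACTIVATING, 0L, input_levels - 1L)
  list(optimal = opt, pessimal = pes)
}

new_logic_table <- function(net, levels, funs) {
  tab <- list(nodes = net$nodes, n = net$n, levels = as.integer(levels),
              funs = funs)
  class(tab) <- "logic_table"
  tab
}

table_skeleton <- function(net, levels, frozen) {
  n <- net$n
  funs <- vector("list", n)
  frozen_idx <- integer(0)
  if (!is.null(frozen)) {
    frozen_idx <- match(names(frozen), net$nodes)
    if (anyNA(frozen_idx)) stop("unknown frozen node label")
  }
  for (i in seq_len(n)) {
    ins <- net$in_nbrs[[i]]
    if (length(ins) == 0L) {
      if (!(i %in% frozen_idx))
        stop("node '", net$nodes[i], "' has in-degree 0; declare it a frozen ",
             "external input via the 'frozen' argument")
      val <- as.integer(frozen[[match(i, frozen_idx)]])
      if (val < 0L || val >= levels[i]) stop("frozen value out of range")
      funs[[i]] <- list(inputs = ins, signs = integer(0),
                        input_levels = integer(0), images = val)
      next
    }
    il <- levels[ins]
    img <- rep(FREE, prod(il))
    bp <- boundary_patterns(net$in_signs[[i]], il)
    img[pattern_index(bp$optimal, il)] <- levels[i] - 1L
    img[pattern_index(bp$pessimal, il)] <- 0L
    funs[[i]] <- list(inputs = ins, signs = net$in_signs[[i]],
                      input_levels = il, images = img)
  }
  new_logic_table(net, levels, funs)
}

#' Minimally constrained ("free") logical function table
#'
#' Builds the table in which every logical parameter is left FREE except the
#' two mandatory boundary entries per node: under optimal conditions (all
#' activators present, all inhibitors absent) a node takes its maximum
#' value, and under the opposite conditions it takes 0.  These minimum
#' assumptions guarantee that every node can in principle switch.
#' Single-input nodes are fully determined, since both of their patterns are
#' boundary patterns.
#'
#' @param net an `interaction_network`.
#' @param levels integer vector of per-node level counts (default binary).
#' @param frozen optional named vector giving the permanent value of each
#'   zero-in-degree node (frozen external inputs).  Nodes with in-degree 0
#'   that are not listed here raise an error.
#' @return A `logic_table`: per node, a mapping from input patterns to an
#'   image value in `{0, ..., m - 1}` or `NA` (FREE).
#' @export
free_table <- function(net, levels = rep(2L, net$n), frozen = NULL) {
  table_skeleton(net, levels, frozen)
}

#' Inhibitor-dominant default logical function table
#'
#' The fully specified table under the widely used convention that any
#' present inhibitor inactivates a node regardless of activators, while in
#' the absence of inhibitors a single present activator suffices for full
#' activation.  It is a completion of [free_table()]: the two boundary
#' entries are satisfied by construction.
#'
#' @inheritParams free_table
#' @return A fully specified `logic_table`.
#' @export
default_table <- function(net, levels = rep(2L, net$n), frozen = NULL) {
  tab <- table_skeleton(net, levels, frozen)
  for (i in seq_len(net$n)) {
    f <- tab$funs[[i]]
    if (length(f$inputs) == 0L) next
    has_act <- any(f$signs == SIGN_ACTIVATING)
    for (p in seq_along(f$images)) {
      v <- index_to_pattern(p, f$input_levels)
      inh_present <- any(f$signs == SIGN_INHIBITING & v > 0L)
      act_present <- any(f$signs == SIGN_ACTIVATING & v > 0L)
      on <- !inh_present && (act_present || !has_act)
      tab$funs[[i]]$images[p] <- if (on) tab$levels[i] - 1L else 0L
    }
  }
  tab
}

#' @export
print.logic_table <- function(x, ...) {
  nfree <- sum(vapply(x$funs, function(f) sum(is.na(f$images)), 0L))
  cat(sprintf("Logical function table: %d nodes, %d FREE parameters%s\n",
              x$n, nfree, if (nfree == 0L) " (fully specified)" else ""))
  invisible(x)
}

#' Is every logical parameter specified?
#' @param table a `logic_table`.
#' @return `TRUE` iff no table entry is FREE.
#' @export
is_fully_specified <- function(table) {
  !any(vapply(table$funs, function(f) anyNA(f$images), TRUE))
}

node_index <- function(table, node) {
  if (is.character(node)) {
    i <- match(node, table$nodes)
    if (is.na(i)) stop("unknown node '", node, "'")
    i
  } else as.integer(node)
}

#' Image of a node under an input pattern
#'
#' The image is the value towards which a node tends under a given pattern
#' of its inputs; a node whose current value equals its image is *content*,
#' otherwise *discontent*.
#'
#' @param table a `logic_table`.
#' @param node node label or index.
#' @param pattern integer vector of input values, one per in-neighbor of the
#'   node in network node order.
#' @return The image value, or `NA` if the corresponding parameter is FREE.
#' @export
image <- function(table, node, pattern) {
  i <- node_index(table, node)
  f <- table$funs[[i]]
  if (length(pattern) != length(f$inputs))
    stop("pattern length ", length(pattern), " does not match in-degree ",
         length(f$inputs), " of node '", table$nodes[i], "'")
  f$images[pattern_index(as.integer(pattern), f$input_levels)]
}

#' Content/discontent status of a node in a state
#'
#' A node is CONTENT when its value equals its image for the current input
#' pattern, DISCONTENT when the image is a concrete different value, and
#' UNDETERMINED when the relevant logical parameter is FREE — in which case
#' the constraint "this parameter must equal the current value" is returned:
#' it is exactly the condition under which the node would be content.
#'
#' @param table a `logic_table`.
#' @param node node label or index.
#' @param state integer vector of length n, the full network state in node
#'   order.
#' @return A list with `status` in `"content"`, `"discontent"`,
#'   `"undetermined"`, and for the undetermined case a `constraint` list
#'   `(node, pattern, value)` where `pattern` is the 1-based mixed-radix
#'   pattern index.
#' @export
node_status <- function(table, node, state) {
  i <- node_index(table, node)
  f <- table$funs[[i]]
  idx <- pattern_index(state[f$inputs], f$input_levels)
  img <- f$images[idx]
  if (is.na(img))
    return(list(status = "undetermined",
                constraint = list(node = i, pattern = idx, value = state[i])))
  list(status = if (img == state[i]) "content" else "discontent",
       constraint = NULL)
}

#' Display a parameter constraint in positive-influence notation
#'
#' Thomas-style K parameters are written with a subscript listing the inputs
#' that exert positive influence: an activator that is present or an
#' inhibitor that is absent.  `K_3{1}` therefore denotes the image of node 3
#' under the positive influence of input 1 alone.
#'
#' @param table a `logic_table`.
#' @param constraint a constraint list as returned by [node_status()].
#' @return A single string such as `"K_3{1}=0"`.
#' @export
format_constraint <- function(table, constraint) {
  f <- table$funs[[constraint$node]]
  v <- index_to_pattern(constraint$pattern, f$input_levels)
  pos <- (f$signs == SIGN_ACTIVATING & v > 0L) |
         (f$signs == SIGN_INHIBITING & v == 0L)
  sub <- paste(table$nodes[f$inputs[pos]], collapse = ",")
  sprintf("K_%s{%s}=%d", table$nodes[constraint$node], sub, constraint$value)
}

# compact machine form: node@pattern=value with the pattern as a digit
# string in input order
constraint_tag <- function(table, constraint) {
  f <- table$funs[[constraint$node]]
  v <- index_to_pattern(constraint$pattern, f$input_levels)
  sprintf("%s@%s=%d", table$nodes[constraint$node],
          paste(v, collapse = ""), constraint$value)
}

#' Write a logical function table as TSV
#'
#' Columns: `node`, `inputs` (comma-joined in-neighbor labels in node
#' order), `pattern` (digit string in input order), `image`.  Only non-FREE
#' entries are written; on reading, omitted entries default to FREE and the
#' two boundary entries per node are always implied.
#'
#' @param table a `logic_table`.
#' @param file output path.
#' @export
write_table_tsv <- function(table, file) {
  rows <- list()
  for (i in seq_len(table$n)) {
    f <- table$funs[[i]]
    if (length(f$inputs) == 0L) next
    given <- which(!is.na(f$images))
    for (p in given) {
      v <- index_to_pattern(p, f$input_levels)
      rows[[length(rows) + 1L]] <- data.frame(
        node = table$nodes[i],
        inputs = paste(table$nodes[f$inputs], collapse = ","),
        pattern = paste(v, collapse = ""),
        image = f$images[p])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), inputs = character(0),
               pattern = character(0), image = integer(0))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a logical function table from TSV
#'
#' @param file TSV path as written by [write_table_tsv()].
#' @param net the `interaction_network` the table refers to.
#' @inheritParams free_table
#' @return A `logic_table`; entries not present in the file remain FREE
#'   (boundary entries are implied).
#' @export
read_table_tsv <- function(file, net, levels = rep(2L, net$n), frozen = NULL) {
  tab <- free_table(net, levels = levels, frozen = frozen)
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "integer"))
  for (r in seq_len(nrow(df))) {
    i <- match(df$node[r], net$nodes)
    if (is.na(i)) stop("table row ", r, ": unknown node '", df$node[r], "'")
    f <- tab$funs[[i]]
    v <- as.integer(strsplit(df$pattern[r], "")[[1]])
    if (length(v) != length(f$inputs))
      stop("table row ", r, ": pattern length mismatch for node '",
           df$node[r], "'")
    idx <- pattern_index(v, f$input_levels)
    img <- df$image[r]
    if (img < 0L || img >= tab$levels[i])
      stop("table row ", r, ": image out of range")
    cur <- f$images[idx]
    if (!is.na(cur) && cur != img)
      stop("table row ", r, ": entry conflicts with a boundary constraint")
    tab$funs[[i]]$images[idx] <- img
  }
  tab
}
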