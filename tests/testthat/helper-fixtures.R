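# Shared fixtures: the two in-paper example networks and small oracles.

# 3-node example: node 2 activates 1, 1 activates 3, 2 inhibits 3,
# 3 inhibits 2.  Node order fixed to 1,2,3 so states read (v1,v2,v3).
fig2_net <- function() {
  make_network(from = c("2", "1", "2", "3"), to = c("1", "3", "3", "2"),
               sign = c(1L, 1L, -1L, -1L), nodes = c("1", "2", "3"))
}

# lines in the GenYsis text format for the same network
fig2_lines <- function() c("2 -> 1", "1 -> 3", "2 -| 3", "3 -| 2")

# the completion that renders both candidate states fixed:
# K of node 3 at pattern (1,1) = 0 and at pattern (0,0) = 1
fig2_completed_table <- function(net = fig2_net()) {
  tab <- free_table(net)
  tab$funs[[3]]$images[1L] <- 1L   # pattern (0,0)
  tab$funs[[3]]$images[4L] <- 0L   # pattern (1,1)
  tab
}

# two-node negative feedback: A activates B, B inhibits A
toggle_net <- function() parse_network(c("A -> B", "B -| A"))

# canonical, order-insensitive signatures for attractor comparison
att_sig <- function(aset) {
  sort(vapply(aset$attractors,
              function(a) paste(a$member_keys, collapse = ","), ""))
}

att_basin_by_sig <- function(aset) {
  s <- vapply(aset$attractors,
              function(a) paste(a$member_keys, collapse = ","), "")
  stats::setNames(vapply(aset$attractors, function(a) a$basin_size, 0L), s)[order(s)]
}

fixed_state_strings <- function(states) {
  if (nrow(states) == 0L) return(character(0))
  sort(apply(states, 1L, paste, collapse = ","))
}

oracle_fixed_strings <- function(aset) {
  fx <- Filter(function(a) a$kind == "fixed_state", aset$attractors)
  sort(vapply(fx, function(a) paste(a$members[1L, ], collapse = ","), ""))
}

# independent elementary-circuit oracle: enumerate every k-permutation of
# the nodes, keep those that close into a circuit, deduplicate rotations
brute_circuits <- function(net, max_length) {
  has_edge <- matrix(FALSE, net$n, net$n)
  has_edge[cbind(net$edges$from, net$edges$to)] <- TRUE
  found <- character(0)
  perms <- function(pool, path) {
    if (length(path) >= 1L && length(path) <= max_length &&
        has_edge[path[length(path)], path[1L]]) {
      rot <- which.min(path)
      canon <- if (rot == 1L) path else c(path[rot:length(path)],
                                          path[seq_len(rot - 1L)])
      found <<- union(found, paste(canon, collapse = ","))
    }
    if (length(path) < max_length) {
      for (v in pool) {
        if (length(path) == 0L || has_edge[path[length(path)], v])
          perms(setdiff(pool, v), c(path, v))
      }
    }
  }
  perms(seq_len(net$n), integer(0))
  sort(found)
}

# small random instance shared by several property tests
random_instance <- function(n, seed) {
  net <- random_network(n, seed = seed)
  list(net = net, tab = random_table(net, seed = seed + 100000L))
}
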