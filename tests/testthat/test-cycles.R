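test_that("subspace enumeration keeps exactly the <= kmax-discontent states", {
  tg <- toggle_net()
  en <- enumerate_subspace(tg, default_table(tg), kmax = 1L)
  expect_equal(nrow(en$states), 4L)
  expect_equal(en$disc, rep(1L, 4L))

  net <- fig2_net()
  en3 <- enumerate_subspace(net, fig2_completed_table(net), kmax = 1L)
  got <- apply(en3$states, 1L, paste, collapse = ",")
  expect_setequal(got[en3$disc == 0L], c("1,1,0", "0,0,1"))
  expect_setequal(got[en3$disc == 1L], c("0,1,0", "1,0,1"))
  expect_equal(nrow(en3$states), 4L)
})

test_that("subspace discontent labels match direct per-state evaluation", {
  for (seed in 1:8) {
    inst <- random_instance(sample(5:9, 1L), 1400L + seed)
    kmax <- sample(0:3, 1L)
    en <- enumerate_subspace(inst$net, inst$tab, kmax = kmax)
    for (r in seq_len(nrow(en$states))) {
      k <- sum(vapply(seq_len(inst$net$n), function(i)
        node_status(inst$tab, i, en$states[r, ])$status == "discontent", TRUE))
      expect_equal(en$disc[r], k)
      expect_lte(k, kmax)
    }
    # completeness: every in-bound state of the full space is present
    n <- inst$net$n
    expected <- sum(vapply(seq_len(2^n) - 1L, function(key) {
      st <- as.integer(intToBits(key)[seq_len(n)])
      sum(vapply(seq_len(n), function(i)
        node_status(inst$tab, i, st)$status == "discontent", TRUE)) <= kmax
    }, TRUE))
    expect_equal(nrow(en$states), expected)
  }
})

test_that("kmax = 0 reduces to the fixed-state search", {
  for (seed in 1:6) {
    inst <- random_instance(8L, 1500L + seed)
    en <- enumerate_subspace(inst$net, inst$tab, kmax = 0L)
    fs <- find_fixed_states(inst$net, inst$tab)
    expect_equal(fixed_state_strings(en$states), fixed_state_strings(fs$states))
  }
})

test_that("subspace enumeration refuses partially specified tables", {
  net <- fig2_net()
  expect_error(enumerate_subspace(net, free_table(net), kmax = 1L),
               "fully specified")
})

test_that("transition graph records in-set successors and boundary states", {
  tg <- toggle_net()
  g <- build_graph(enumerate_subspace(tg, default_table(tg), 1L),
                   tg, default_table(tg))
  expect_equal(sum(lengths(g$succ)), 4L)
  expect_false(any(g$boundary))
  expect_equal(g$n_succ_total, rep(1L, 4L))

  net <- fig2_net()
  tab <- fig2_completed_table(net)
  g3 <- build_graph(enumerate_subspace(net, tab, 1L), net, tab)
  st <- apply(g3$states, 1L, paste, collapse = ",")
  succ_of <- function(s) st[g3$succ[[match(s, st)]]]
  expect_equal(succ_of("0,1,0"), "1,1,0")
  expect_equal(succ_of("1,0,1"), "0,0,1")
  expect_false(any(g3$boundary))
})

test_that("states whose successors escape the subspace are flagged boundary", {
  # mutual activation: (0,1) and (1,0) are 2-discontent, so at kmax = 2 the
  # fixed states' 1-step predecessors are present but their own successors
  # stay in-set; at kmax = 1 only the fixed states are enumerated.  A
  # boundary case needs a 1-discontent state with a 2-discontent successor:
  # chain A -> B -> C with A inhibited by C (negative loop) provides one.
  net <- parse_network(c("A -> B", "B -> C", "C -| A"))
  tab <- default_table(net)
  full <- enumerate_subspace(net, tab, kmax = net$n)
  gfull <- build_graph(full, net, tab)
  en1 <- enumerate_subspace(net, tab, kmax = 1L)
  g1 <- build_graph(en1, net, tab)
  keys1 <- en1$keys
  stfull <- apply(gfull$states, 1L, paste, collapse = ",")
  for (r in seq_len(nrow(en1$states))) {
    rf <- match(paste(en1$states[r, ], collapse = ","), stfull)
    esc <- any(!(gfull$keys[gfull$succ[[rf]]] %in% keys1))
    expect_equal(g1$boundary[r], esc)
    expect_equal(length(g1$succ[[r]]) + sum(!(gfull$keys[gfull$succ[[rf]]]
                                              %in% keys1)),
                 g1$n_succ_total[r])
  }
})

test_that("fixed-state basins are found by walking predecessors uphill", {
  net <- fig2_net()
  tab <- fig2_completed_table(net)
  g <- build_graph(enumerate_subspace(net, tab, 1L), net, tab)
  fb <- fixed_state_basins(g)
  expect_length(fb$basins, 2L)
  st <- apply(g$states, 1L, paste, collapse = ",")
  basin_of <- function(s) sort(st[fb$basins[[match(s, st[fb$fixed_idx])]]])
  expect_equal(basin_of("0,0,1"), c("0,0,1", "1,0,1"))
  expect_equal(basin_of("1,1,0"), c("0,1,0", "1,1,0"))
  expect_true(all(fb$labeled))

  tg <- toggle_net()
  gtg <- build_graph(enumerate_subspace(tg, default_table(tg), 1L),
                     tg, default_table(tg))
  fbtg <- fixed_state_basins(gtg)
  expect_length(fbtg$basins, 0L)
  expect_false(any(fbtg$labeled))
})

test_that("a shared predecessor belongs to both fixed-state basins", {
  mut <- parse_network(c("A -> B", "B -> A"))
  tab <- default_table(mut)
  g <- build_graph(enumerate_subspace(mut, tab, 2L), mut, tab)
  fb <- fixed_state_basins(g)
  st <- apply(g$states, 1L, paste, collapse = ",")
  both <- which(st == "0,1")
  expect_true(all(vapply(fb$basins, function(b) both %in% b, TRUE)))
})

test_that("the toggle yields one simple 4-state cycle with full basin", {
  tg <- toggle_net()
  res <- run_cycle_analysis(tg, default_table(tg), kmax = 1L)
  expect_length(res$attractors, 1L)
  a <- res$attractors[[1L]]
  expect_equal(a$kind, "cycle")
  expect_equal(nrow(a$members), 4L)
  expect_equal(a$k, 1L)
  expect_equal(a$shape, "simple")
  expect_equal(a$basin_size, 4L)
})

test_that("the completed 3-node example has only its two fixed states", {
  net <- fig2_net()
  res <- run_cycle_analysis(net, fig2_completed_table(net), kmax = 1L)
  expect_length(res$attractors, 2L)
  expect_true(all(vapply(res$attractors, function(a) a$kind, "") ==
                    "fixed_state"))
  expect_equal(sort(vapply(res$attractors, function(a)
    paste(a$members[1L, ], collapse = ","), "")), c("0,0,1", "1,1,0"))
})

test_that("cycle analysis at kmax = n equals the brute-force oracle", {
  for (seed in 1:25) {
    inst <- random_instance(sample(5:10, 1L), 1600L + seed)
    res <- run_cycle_analysis(inst$net, inst$tab, kmax = inst$net$n)
    bf <- brute_force_attractors(inst$net, inst$tab)
    expect_equal(att_sig(res), att_sig(bf))
    expect_equal(att_basin_by_sig(res), att_basin_by_sig(bf))
  }
})

test_that("attractor sets grow monotonically with the discontent bound", {
  for (seed in 1:10) {
    inst <- random_instance(sample(5:8, 1L), 1700L + seed)
    prev <- character(0)
    for (kmax in 0:inst$net$n) {
      cur <- att_sig(run_cycle_analysis(inst$net, inst$tab, kmax = kmax))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("returned cycles pass an independent closure and simplicity check", {
  for (seed in 1:12) {
    inst <- random_instance(sample(5:9, 1L), 1800L + seed)
    res <- run_cycle_analysis(inst$net, inst$tab, kmax = 2L)
    for (a in res$attractors) {
      if (a$kind != "cycle") next
      sigs <- apply(a$members, 1L, paste, collapse = ",")
      for (r in seq_len(nrow(a$members))) {
        succ <- successors(inst$net, inst$tab, a$members[r, ])
        expect_true(all(apply(succ, 1L, paste, collapse = ",") %in% sigs))
        if (a$shape == "simple") expect_equal(nrow(succ), 1L)
      }
    }
  }
})

test_that("every j-cycle with j <= kmax is found when its flow stays in-set", {
  # completeness bound, checked against the oracle across all kmax values
  for (seed in 1:8) {
    inst <- random_instance(sample(5:8, 1L), 1900L + seed)
    bf <- brute_force_attractors(inst$net, inst$tab)
    for (kmax in 0:inst$net$n) {
      res <- run_cycle_analysis(inst$net, inst$tab, kmax = kmax)
      want <- Filter(function(a) a$k <= kmax, bf$attractors)
      expect_true(all(vapply(want, function(a)
        paste(a$member_keys, collapse = ","), "") %in% att_sig(res)))
    }
  }
})
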