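# dynamics_engine: synchronous step, trajectories, exhaustive enumeration,
# oracle equivalence, conservation, determinism.

toggle <- parse_rules("targets, factors\nA, !B\nB, !A")

test_that("synchronous step matches hand evaluation on fixtures", {
  expect_equal(bn_step(toggle, 0), 3)  # 00 -> 11
  expect_equal(bn_step(toggle, 3), 0)  # 11 -> 00
  expect_equal(bn_step(toggle, 1), 1)  # 10 fixed
  expect_equal(bn_step(toggle, 2), 2)  # 01 fixed
  idn <- parse_rules("targets, factors\nA, A\nB, B\nC, C")
  expect_equal(bn_step(idn, 0:7), 0:7)
  cst <- parse_rules("targets, factors\nA, 0\nB, 0")
  expect_equal(bn_step(cst, 0:3), rep(0, 4))
})

test_that("step agrees with the naive oracle on random networks", {
  for (i in 1:10) {
    net <- parse_rules(random_rules_text(2 + (i %% 6), seed = 2000 + i))
    n <- n_nodes(net)
    for (s in 0:(2^n - 1))
      expect_equal(bn_step(net, s), naive_step(net, s),
                   info = sprintf("net %d state %d", i, s))
  }
})

test_that("trajectory_to_attractor finds cycles and transients", {
  t1 <- trajectory_to_attractor(toggle, 2)
  expect_equal(t1$attractor$states, 2)
  expect_equal(t1$transient, 0L)
  t2 <- trajectory_to_attractor(toggle, 0)
  expect_equal(t2$attractor$states, c(0, 3))
  expect_equal(t2$attractor$period, 2L)
  expect_equal(t2$transient, 0L)
  cst <- parse_rules("targets, factors\nA, 0\nB, 0\nC, 0")
  t3 <- trajectory_to_attractor(cst, 5)
  expect_equal(t3$attractor$states, 0)
  expect_equal(t3$transient, 1L)
  t4 <- trajectory_to_attractor(cst, 0)
  expect_equal(t4$transient, 0L)
})

test_that("exhaustive enumeration on the textbook fixtures", {
  idn <- parse_rules("targets, factors\nA, A")
  L <- exhaustive_attractors(idn)
  expect_length(L$attractors, 2L)
  expect_equal(vapply(L$attractors, function(a) a$basin_size, numeric(1)),
               c(1, 1))
  L2 <- exhaustive_attractors(toggle)
  expect_length(L2$attractors, 3L)
  df <- as.data.frame(L2)
  expect_equal(df$states, c("0/3", "1", "2"))
  expect_equal(df$basin_size, c(2, 1, 1))
})

test_that("engine equals the naive oracle exactly on random networks", {
  # expression-based nets and truth-table (N-K) nets, both clamped and not;
  # sizes straddle the scalar/bit-parallel switchover at 6 free nodes
  for (i in 1:12) {
    net <- parse_rules(random_rules_text(3 + (i %% 6), seed = 3000 + i))
    expect_identical(landscape_as_plain(exhaustive_attractors(net)),
                     naive_landscape(net), info = paste("expr net", i))
  }
  for (i in 1:8) {
    net <- random_network(4 + (i %% 5), k = 1 + (i %% 3), p = 0.5,
                          seed = 4000 + i)
    expect_identical(landscape_as_plain(exhaustive_attractors(net)),
                     naive_landscape(net), info = paste("NK net", i))
  }
  for (i in 1:5) {
    net0 <- parse_rules(random_rules_text(7, seed = 5000 + i))
    net <- apply_clamps(net0, stats::setNames(i %% 2, net0$node_names[[1]]))
    expect_identical(landscape_as_plain(exhaustive_attractors(net)),
                     naive_landscape(net), info = paste("clamped net", i))
  }
})

test_that("basin conservation and determinism hold on random networks", {
  for (i in 1:10) {
    net <- random_network(6 + (i %% 9), k = 2, p = 0.5, seed = 6000 + i)
    L <- exhaustive_attractors(net)
    expect_equal(sum(vapply(L$attractors, function(a) a$basin_size,
                            numeric(1))), L$total_states)
    for (a in L$attractors) {
      expect_gte(a$basin_size, a$period)
      # applying one step to states[k] yields states[k+1 mod period]
      expect_equal(bn_step(net, a$states),
                   c(a$states[-1], a$states[[1]]))
    }
    L2 <- exhaustive_attractors(net)
    expect_identical(as.data.frame(L), as.data.frame(L2))
  }
})

test_that("clamped enumeration halves the state space per clamp", {
  net <- random_network(10, k = 2, p = 0.5, seed = 99)
  L0 <- exhaustive_attractors(net)
  expect_equal(L0$total_states, 2^10)
  L1 <- exhaustive_attractors(apply_clamps(net, c(G1 = 1)))
  expect_equal(L1$total_states, 2^9)
  expect_true(all(state_respects <- vapply(L1$attractors, function(a)
    all((a$states %/% 1) %% 2 == 1), logical(1))))  # bit 1 (G1) always on
})

test_that("the free-node cap refuses oversized enumerations with guidance", {
  net <- random_network(12, k = 1, p = 0.5, seed = 1)
  expect_error(exhaustive_attractors(net, cap = 10), "exceeds the cap")
})

test_that("landscape exports are written and self-consistent", {
  L <- exhaustive_attractors(toggle)
  tsv <- tempfile(fileext = ".tsv")
  export_landscape(L, tsv)
  lines <- readLines(tsv)
  expect_true(any(grepl("bit order", lines)))
  body <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(nrow(body), 4L)  # 2 cycle states + 2 fixed points
  js <- jsonlite::fromJSON(landscape_to_json(L))
  expect_equal(js$total_states, 4)
  expect_equal(length(js$attractors$id), 3)
})
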