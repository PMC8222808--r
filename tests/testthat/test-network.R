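# network_model: parsing, validation, serialization, clamps, reduction,
# bundled model structure.

test_that("parser handles the dialect, precedence, and trivial networks", {
  net1 <- parse_rules("targets, factors\nA, A")
  expect_equal(n_nodes(net1), 1L)
  expect_equal(bn_step(net1, 1), 1)

  toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
  expect_equal(toggle$node_names, c("A", "B"))
  expect_equal(bn_step(toggle, 0), 3)  # 00 -> 11

  # NOT > AND > OR; parentheses override
  net <- parse_rules("targets, factors\nA, A & B | C\nB, !A & C\nC, A & (B | C)")
  # A&B|C is (A&B)|C: state C=1 only (enc 4) -> A next = 1
  expect_equal(unname(decode_state(bn_step(net, 4), net)[1, "A"]), 1L)
  # !A & C is (!A)&C, not !(A&C): state A=1,C=1 (enc 5) -> B next = 0
  expect_equal(unname(decode_state(bn_step(net, 5), net)[1, "B"]), 0L)
  # A&(B|C): state A=1,C=1 -> C next = 1
  expect_equal(unname(decode_state(bn_step(net, 5), net)[1, "C"]), 1L)

  # whitespace-insensitive
  expect_true(expr_equivalent(
    parse_rules("targets, factors\nA,!B&A\nB,  A |B"),
    parse_rules("targets, factors\nA, ! B & A\nB, A|B")))
})

test_that("parser reports undeclared nodes, duplicates, and empty input", {
  expect_error(parse_rules("targets, factors\nA, B"), "undeclared.*B")
  expect_error(parse_rules("targets, factors\nA, A\nA, !A"), "duplicate.*A")
  expect_error(parse_rules(""), "empty")
  expect_error(parse_rules("targets, factors"), "no rules")
  expect_error(parse_rules("wrong header\nA, A"), "header")
  expect_error(parse_rules("targets, factors\nA, (B & "), ".")
})

test_that("serialize -> parse round-trips logical equivalence (50 random nets)", {
  for (i in 1:50) {
    n <- 2 + (i %% 7)
    net <- parse_rules(random_rules_text(n, seed = 1000 + i))
    back <- parse_rules(serialize_rules(net))
    expect_true(expr_equivalent(net, back), info = paste("net", i))
  }
})

test_that("clamping replaces functions, preserves the original, and validates", {
  toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
  cl <- apply_clamps(toggle, c(A = 1))
  expect_equal(free_nodes(cl), "B")
  expect_equal(cl$functions$A$op, "const")
  expect_equal(bexpr_deparse(cl$functions$B), "!A")
  expect_equal(toggle$clamps, integer(0))  # original untouched
  expect_error(apply_clamps(toggle, c(Z = 1)), "unknown node")
  expect_error(apply_clamps(cl, c(A = 0)), "conflicting")
  # idempotent and order-independent for disjoint sets
  a_then_b <- apply_clamps(apply_clamps(toggle, c(A = 1)), c(B = 0))
  b_then_a <- apply_clamps(apply_clamps(toggle, c(B = 0)), c(A = 1))
  expect_equal(sort(names(a_then_b$clamps)), sort(names(b_then_a$clamps)))
  expect_identical(apply_clamps(cl, c(A = 1))$clamps, cl$clamps)
  # clamp all nodes: single fixed point equal to the clamp vector
  all_cl <- apply_clamps(toggle, c(A = 1, B = 0))
  Lc <- exhaustive_attractors(all_cl)
  expect_length(Lc$attractors, 1L)
  expect_equal(Lc$attractors[[1]]$states, 1)  # A=1, B=0
  expect_equal(bn_step(all_cl, encode_state(c(A = 1, B = 0), all_cl)), 1)
})

test_that("reduce_low_degree_nodes drops degree<2 nodes once, or errors", {
  # every node degree >= 2: unchanged
  net <- parse_rules("targets, factors\nA, B\nB, A")
  expect_identical(reduce_low_degree_nodes(net)$node_names, c("A", "B"))
  # chain A->B->C, C unreferenced: C has degree 1, safely removable
  chain <- parse_rules("targets, factors\nA, A\nB, A & B\nC, B")
  red <- reduce_low_degree_nodes(chain)
  expect_identical(red$node_names, c("A", "B"))
  # star: hub referenced by leaves; removing leaves orphans the hub's rule
  star <- parse_rules(paste("targets, factors", "H, L1 | L2 | L3 | L4",
                            "L1, H", "L2, H", "L3, H", "L4, H", sep = "\n"))
  # every leaf has degree 2 here (in from H, out to H), so unchanged
  expect_identical(reduce_low_degree_nodes(star)$node_names, star$node_names)
  # pure sink leaves with degree 1 that the hub still references -> error
  star2 <- parse_rules(paste("targets, factors", "H, L1 | L2 | H",
                             "L1, 0", "L2, 0", sep = "\n"))
  expect_error(reduce_low_degree_nodes(star2), "orphan.*H")
})

test_that("node name normalization maps Greek and hyphens to ASCII", {
  expect_equal(normalize_node_name("HIF1-α"), "HIF1A")
  expect_equal(normalize_node_name("NFκB"), "NFKB")
  expect_equal(normalize_node_name("TGF-β"), "TGFB")
})

test_that("bundled macrophage model has the published structure", {
  net <- load_macrophage_model()
  expect_equal(n_nodes(net), 29L)
  expect_equal(nrow(network_edges(net)), 60L)
  roster <- c("TLR4", "NFKB", "STAT1", "STAT3", "STAT6", "SOCS1", "KLF4",
              "AP1", "ERK", "HIF1A", "FRA1", "TNFA", "TGFB", "IL10", "IL6",
              "IL4", "IL1B", "IFNG", "IFNB", "IGG", "GCGCR", "A2A",
              "HYPOXIA", "MCSF")
  expect_true(all(roster %in% net$node_names))
  # the bundled network is already reduced: no node below degree 2
  expect_identical(reduce_low_degree_nodes(net)$node_names, net$node_names)
  # round-trip
  expect_true(expr_equivalent(
    parse_rules("targets, factors\nTLR4, HMGB1 | FRA1 | TLR4\nHMGB1, HMGB1\nFRA1, FRA1"),
    parse_rules(serialize_rules(parse_rules(
      "targets, factors\nTLR4, HMGB1 | FRA1 | TLR4\nHMGB1, HMGB1\nFRA1, FRA1")))))
  # TGEM clamp leaves 27 free nodes
  expect_length(free_nodes(apply_clamps(net, c(NFKB = 1, HIF1A = 0))), 27L)
})
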