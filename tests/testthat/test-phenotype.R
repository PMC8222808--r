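# phenotype_labeling: marker rules, state/attractor labels, census,
# embedding + clustering.

test_that("default rules match the published marker logic", {
  rules <- default_phenotype_rules()
  expect_length(rules, 5L)
  expect_equal(names(rules), c("M1", "M2a", "M2b", "M2c", "M2d"))
  expect_equal(macboolnet:::bexpr_vars(rules$M2a$expr), "STAT6")
  net <- load_macrophage_model()
  # M2d fires on HIF1A alone regardless of TLR4/A2A
  expect_equal(label_state(encode_state(c(HIF1A = 1), net), net), "M2d")
  expect_equal(label_state(encode_state(c(TLR4 = 1), net), net), "M0")
  expect_equal(label_state(encode_state(c(TLR4 = 1, A2A = 1), net), net), "M2d")
})

test_that("label_state composes hybrid labels in fixed order", {
  net <- load_macrophage_model()
  expect_equal(label_state(0, net), "M0")
  expect_equal(label_state(encode_state(c(STAT6 = 1), net), net), "M2a")
  expect_equal(label_state(encode_state(c(NFKB = 1, STAT3 = 1), net), net),
               "M1M2c")
  # order invariance: never M2c before M1, whatever the bit pattern
  s <- encode_state(c(STAT3 = 1, NFKB = 1, STAT6 = 1), net)
  expect_equal(label_state(s, net), "M1M2aM2c")
  expect_error(label_state(0, parse_rules("targets, factors\nA, A")),
               "missing node")
})

test_that("label_attractor joins cyclic per-state labels from canonical start", {
  net <- load_macrophage_model()
  a1 <- macboolnet:::new_attractor(encode_state(c(NFKB = 1), net), 10)
  expect_equal(label_attractor(a1, net)$label, "M1")
  # synthetic 2-cycle alternating M0 / M1 states
  a2 <- macboolnet:::new_attractor(c(0, encode_state(c(STAT1 = 1), net)), 4)
  expect_equal(label_attractor(a2, net)$label, "M0/M1")
  # consecutive duplicates collapse
  a3 <- macboolnet:::new_attractor(c(0, encode_state(c(IFNB = 1), net)), 4)
  expect_equal(label_attractor(a3, net)$label, "M0")
})

test_that("census partitions attractors and conserves basins", {
  toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
  rules <- list(M1 = phenotype_rule("M1", "A"))
  L <- label_landscape(exhaustive_attractors(toggle), rules)
  cen <- phenotype_census(L, rules)
  expect_setequal(cen$label, c("M1", "M0", "M0/M1"))
  expect_equal(sum(cen$n_attractors), 3L)
  expect_equal(sum(cen$basin_size), 4)
  # labels are a pure function of states: permuting attractors changes nothing
  Lp <- L
  Lp$attractors <- rev(Lp$attractors)
  cenp <- phenotype_census(Lp, rules)
  expect_equal(cen[order(cen$label), ], cenp[order(cenp$label), ],
               ignore_attr = TRUE)
})

test_that("restricted macrophage census has the experimentally pure labels", {
  L <- labeled_landscape(restricted_macrophage())
  cen <- phenotype_census(L)
  expect_equal(sum(cen$basin_size), L$total_states)
  expect_true(all(c("M0", "M1", "M2b", "M2d") %in% cen$label))
  # pure M2a / M2c do not occur in the wild-type landscape
  expect_false(any(c("M2a", "M2c") %in% cen$label))
})

test_that("embedding recovers planted well-separated groups", {
  # three Hamming-distant blocks of duplicated patterns, presented as a
  # landscape of fixed points over a 24-node scaffold
  scaffold <- parse_rules(paste(c("targets, factors",
                                  paste0("B", 1:24, ", B", 1:24)),
                                collapse = "\n"))
  block_state <- function(which, noise_bit) {
    bits <- rep(0, 24)
    bits[(which - 1) * 8 + 1:8] <- 1
    bits[noise_bit] <- 1 - bits[noise_bit]  # one-bit within-block variation
    encode_state(stats::setNames(bits, paste0("B", 1:24)), scaffold)
  }
  set.seed(4)
  atts <- lapply(1:30, function(i) {
    g <- (i - 1) %% 3 + 1
    a <- macboolnet:::new_attractor(block_state(g, (g - 1) * 8 +
                                                  ((i - 1) %/% 3 %% 8) + 1), 1)
    a$id <- i
    a$label <- paste0("G", g)
    a
  })
  L <- structure(list(attractors = atts, free_node_count = 24L,
                      total_states = 2^24, net = scaffold, labeled = TRUE),
                 class = "Landscape")
  ca <- embed_and_cluster(L, k_range = 2:6, seed = 11)
  expect_equal(ca$k, 3L)
  # blocks map 1:1 onto clusters
  split_by_group <- split(ca$points$cluster, ca$points$label)
  for (g in split_by_group) expect_length(unique(g), 1L)
  expect_length(unique(vapply(split_by_group, unique, integer(1))), 3L)
  # same seed -> same assignment
  ca2 <- embed_and_cluster(L, k_range = 2:6, seed = 11)
  expect_identical(ca$points, ca2$points)
  expect_error(embed_and_cluster(L, k_range = 40:45, seed = 1),
               "admissible|attractors")
})

test_that("identical duplicated patterns land in the same cluster", {
  scaffold <- parse_rules(paste(c("targets, factors",
                                  paste0("B", 1:12, ", B", 1:12)),
                                collapse = "\n"))
  pattern <- function(which) sum(2^((which - 1) * 4 + 0:3))
  atts <- lapply(1:12, function(i) {
    a <- macboolnet:::new_attractor(pattern((i - 1) %% 3 + 1), 1)
    a$id <- i
    a$label <- paste0("P", (i - 1) %% 3 + 1)
    a
  })
  L <- structure(list(attractors = atts, free_node_count = 12L,
                      total_states = 2^12, net = scaffold, labeled = TRUE),
                 class = "Landscape")
  ca <- embed_and_cluster(L, k_range = 2:3, seed = 5)
  for (g in split(ca$points$cluster, ca$points$label))
    expect_length(unique(g), 1L)
})
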