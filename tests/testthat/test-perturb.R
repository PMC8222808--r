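# perturbation_analysis: fold-change semantics, scans, microenvironments,
# TGEM/STGEM, scenarios (small/restricted state spaces; the full-scale runs
# live in test-acceptance.R).

rules2 <- list(M1 = phenotype_rule("M1", "A"), M2 = phenotype_rule("M2", "B"))

test_that("fold-change: zeros on identical landscapes, exact ratios, flags", {
  toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
  L <- label_landscape(exhaustive_attractors(toggle), rules2)
  fc <- basin_log2_foldchange(L, L)
  expect_true(all(fc$status == "ok"))
  expect_true(all(fc$log2fc == 0))
  # wt basin 4 vs pert basin 8 for one label -> +1
  net3 <- parse_rules("targets, factors\nA, A\nB, B\nC, C")
  Lw <- label_landscape(exhaustive_attractors(net3), rules2)
  Lp <- label_landscape(exhaustive_attractors(apply_clamps(net3, c(C = 1))),
                        rules2)
  # A-label mass halves with one fewer free node
  a_row <- function(f) f[f$label == "M1", ]
  fc2 <- basin_log2_foldchange(Lw, Lp)
  expect_equal(a_row(fc2)$log2fc, log2(2 / 4))
  # lost and gained flags
  kb <- label_landscape(exhaustive_attractors(apply_clamps(net3, c(A = 0))),
                        rules2)
  fc3 <- basin_log2_foldchange(Lw, kb)
  expect_true(any(fc3$status == "lost"))
  lost_labels <- fc3$label[fc3$status == "lost"]
  expect_true(all(grepl("M1", lost_labels)))
})

test_that("fold-change antisymmetry under reference swap", {
  net <- random_network(8, k = 2, p = 0.5, seed = 77)
  rules <- list(M1 = phenotype_rule("M1", "G1 | G2"),
                M2 = phenotype_rule("M2", "G3"))
  A <- label_landscape(exhaustive_attractors(net), rules)
  B <- label_landscape(exhaustive_attractors(apply_clamps(net, c(G5 = 1))),
                       rules)
  ab <- basin_log2_foldchange(A, B)
  ba <- basin_log2_foldchange(B, A)
  m <- merge(ab, ba, by = "label")
  ok <- m$status.x == "ok"
  expect_true(all(m$status.y[ok] == "ok"))
  expect_equal(m$log2fc.x[ok], -m$log2fc.y[ok])
  expect_true(all(m$status.y[m$status.x == "lost"] == "gained"))
  expect_true(all(m$status.y[m$status.x == "gained"] == "lost"))
  # per-attractor mode shows the same antisymmetry
  abA <- basin_log2_foldchange(A, B, by = "attractor")
  baA <- basin_log2_foldchange(B, A, by = "attractor")
  m2 <- merge(abA, baA, by = "label")
  ok2 <- m2$status.x == "ok"
  expect_equal(m2$log2fc.x[ok2], -m2$log2fc.y[ok2])
})

test_that("single-node scan covers every node with the right clamp", {
  net <- random_network(6, k = 2, p = 0.5, seed = 5)
  rules <- list(M1 = phenotype_rule("M1", "G1"))
  wt <- label_landscape(exhaustive_attractors(net), rules)
  wt$labeled <- TRUE
  ko <- single_node_scan(net, "knockout", rules = rules, wt = wt)
  oe <- single_node_scan(net, "overexpress", rules = rules, wt = wt)
  expect_length(ko, 6L)
  expect_length(oe, 6L)
  for (nm in names(ko)) {
    expect_equal(ko[[nm]]$landscape$total_states, 2^5)
    expect_equal(ko[[nm]]$landscape$net$clamps[[nm]], 0L)
    expect_equal(oe[[nm]]$landscape$net$clamps[[nm]], 1L)
  }
  # overexpressing an already-overexpressed node is idempotent
  oe1 <- apply_clamps(net, c(G2 = 1))
  again <- single_node_scan(oe1, "overexpress", nodes = "G2", rules = rules,
                            wt = wt)
  expect_equal(again$G2$landscape$total_states, 2^5)
  # knockout of a node absent from every attractor leaves labels unchanged:
  # G_sink reads others but regulates nothing and is 0 in all attractors
  fix <- parse_rules(paste("targets, factors", "A, A", "B, B",
                           "SINK, A & !A", sep = "\n"))
  rs <- list(M1 = phenotype_rule("M1", "A"), M2 = phenotype_rule("M2", "B"))
  wt2 <- label_landscape(exhaustive_attractors(fix), rs)
  ko2 <- single_node_scan(fix, "knockout", nodes = "SINK", rules = rs, wt = wt2)
  fc <- ko2$SINK$foldchange
  # the label set is unchanged (nothing lost, nothing gained) and every
  # label keeps its share of the (halved) state space
  expect_true(all(fc$status == "ok"))
  expect_true(all(fc$pert_basin / 2^2 == fc$wt_basin / 2^3))
})

test_that("microenvironments carry the published clamp sets", {
  envs <- microenvironments()
  expect_setequal(names(envs), c("Pro-M0", "Pro-M1", "Pro-M2a", "Pro-M2b",
                                 "Pro-M2c", "Pro-M2d"))
  expect_length(envs[["Pro-M0"]]$assignments, 0L)
  expect_equal(envs[["Pro-M1"]]$assignments, c(IFNG = 1L, IFNB = 1L))
  expect_equal(envs[["Pro-M2a"]]$assignments, c(IL4 = 1L, TGFB = 1L))
  expect_equal(envs[["Pro-M2b"]]$assignments, c(IGG = 1L, GCGCR = 1L))
  expect_equal(envs[["Pro-M2c"]]$assignments,
               c(IL10 = 1L, IL6 = 1L, MCSF = 1L))
  expect_equal(envs[["Pro-M2d"]]$assignments,
               c(A2A = 1L, HYPOXIA = 1L, GCGCR = 1L))
  net <- restricted_macrophage(c(HMGB1 = 0, IL13 = 0, IL1B = 0, IL4 = 0,
                                 IGG = 0, GCGCR = 0, MCSF = 0, HYPOXIA = 0))
  expect_error(microenvironment_landscape(net, "Pro-M9"), "Pro-M1")
  # Pro-M0 is the unclamped wild-type landscape itself
  wt <- labeled_landscape(net)
  m0 <- microenvironment_landscape(net, "Pro-M0", wt = wt)
  expect_identical(m0$landscape, wt)
  expect_true(all(m0$foldchange$log2fc == 0))
  # two clamps knock two nodes out of the free set
  m1 <- microenvironment_landscape(net, "Pro-M1", wt = wt)
  expect_equal(m1$landscape$free_node_count, length(free_nodes(net)) - 2L)
})

test_that("TGEM/STGEM validate nodes and layer scenario clamps safely", {
  small <- parse_rules("targets, factors\nA, A\nB, B")
  expect_error(build_tgem(small), "lacks node")
  net <- restricted_macrophage(c(HMGB1 = 0, IL13 = 0, IL1B = 0, IFNB = 0))
  tg <- build_tgem(net)
  expect_equal(tg$landscape$free_node_count, length(free_nodes(net)) - 2L)
  expect_equal(tg$perturbation$assignments, c(NFKB = 1L, HIF1A = 0L))
  sg <- build_stgem(net)
  expect_equal(sg$perturbation$assignments, c(STAT1 = 1L, HIF1A = 0L))
  # scenario layering demands the TGEM clamps and forbids conflicts
  expect_error(breast_cancer_scenarios(net), "TGEM")
  tnet <- apply_clamps(net, c(NFKB = 1, HIF1A = 0))
  conflicted <- apply_clamps(tnet, c(IGG = 0))
  expect_error(breast_cancer_scenarios(conflicted), "conflicting")
})
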