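# Independent naive oracle: pure-R, one-state-at-a-time simulation using the
# recursive expression evaluator. Deliberately shares no code with the
# compiled engine path (no bytecode, no bit-parallel blocks).

naive_step <- function(net, s) {
  bits <- decode_state(s, net)[1, ]
  vals <- as.list(as.integer(bits))
  names(vals) <- net$node_names
  nb <- vapply(net$node_names, function(nd)
    as.integer(macboolnet:::bexpr_eval(net$functions[[nd]], vals)), integer(1))
  sum(nb * 2^(seq_along(nb) - 1))
}

# Full landscape by naive per-state simulation with memoized successors.
# Returns attractors sorted by smallest state: list(states = <canonical
# cycle, full encodings>, basin = <count>).
naive_landscape <- function(net) {
  free <- free_nodes(net)
  pos <- match(free, net$node_names)
  clamp_value <- if (length(net$clamps))
    sum(net$clamps * 2^(match(names(net$clamps), net$node_names) - 1)) else 0
  nf <- length(free)
  total <- 2^nf
  expand <- function(fe) {
    out <- clamp_value
    for (k in seq_along(pos))
      out <- out + ((fe %/% 2^(k - 1)) %% 2) * 2^(pos[k] - 1)
    out
  }
  compress <- function(s) {
    out <- 0
    for (k in seq_along(pos))
      out <- out + ((s %/% 2^(pos[k] - 1)) %% 2) * 2^(k - 1)
    out
  }
  succ <- rep(NA_real_, total)
  labels <- integer(total)
  cycles <- list()
  basins <- numeric(0)
  for (s0 in 0:(total - 1)) {
    if (labels[s0 + 1] != 0L) next
    path <- numeric(0)
    v <- s0
    while (labels[v + 1] == 0L) {
      labels[v + 1] <- -(length(path) + 1L)
      path <- c(path, v)
      if (is.na(succ[v + 1])) succ[v + 1] <- compress(naive_step(net, expand(v)))
      v <- succ[v + 1]
    }
    if (labels[v + 1] < 0L) {
      p <- -labels[v + 1]
      cyc <- path[p:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      basins <- c(basins, 0)
      id <- length(cycles)
    } else id <- labels[v + 1]
    basins[id] <- basins[id] + length(path)
    labels[path + 1] <- id
  }
  out <- lapply(seq_along(cycles), function(i) {
    states <- expand(cycles[[i]])
    k <- which.min(states)
    if (k > 1) states <- c(states[k:length(states)], states[seq_len(k - 1)])
    list(states = states, basin = basins[i])
  })
  out[order(vapply(out, function(a) a$states[1], numeric(1)))]
}

# Landscape object -> comparable plain list in the oracle's format.
landscape_as_plain <- function(L) {
  lapply(L$attractors, function(a) list(states = a$states, basin = a$basin_size))
}

# Random expression-based network text for parser/dynamics fuzzing.
random_rules_text <- function(n, seed, depth = 3) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n))
  gen <- function(d) {
    if (d == 0 || runif(1) < 0.3) return(sample(nodes, 1))
    op <- sample(c("&", "|", "!"), 1)
    if (op == "!") return(paste0("!(", gen(d - 1), ")"))
    paste0("(", gen(d - 1), " ", op, " ", gen(d - 1), ")")
  }
  paste(c("targets, factors",
          vapply(nodes, function(nd) paste0(nd, ", ", gen(depth)), character(1))),
        collapse = "\n")
}

# Expression truth-table equality over all assignments of the referenced nodes.
expr_equivalent <- function(net1, net2) {
  if (!identical(sort(net1$node_names), sort(net2$node_names))) return(FALSE)
  n <- n_nodes(net1)
  if (n > 12) stop("truth-table comparison capped at 12 nodes")
  for (s in 0:(2^n - 1)) {
    if (naive_step(net1, s) !=
        naive_step(net2, encode_state(decode_state(s, net1)[1, net2$node_names],
                                      net2)))
      return(FALSE)
  }
  TRUE
}

# The macrophage model restricted to a small free space, for quick tests.
restricted_macrophage <- function(extra = c(HMGB1 = 0, IFNB = 0, IL4 = 0,
                                            IL13 = 0, IL1B = 0, IGG = 0,
                                            GCGCR = 0, MCSF = 0)) {
  apply_clamps(load_macrophage_model(), clamp_set(extra, "restriction"))
}
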