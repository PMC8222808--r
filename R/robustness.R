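# Robustness: Derrida curves with regime classification, and per-rule
# sensitivity analysis.

# Uniform random full states over the free nodes of `net` (clamped bits are
# held at their clamp values), as encodings.
#' @noRd
random_states <- function(net, m) {
  free_pos <- match(free_nodes(net), net$node_names)
  clamp_value <- if (length(net$clamps))
    sum(net$clamps * 2^(match(names(net$clamps), net$node_names) - 1)) else 0
  out <- rep(clamp_value, m)
  for (p in free_pos)
    out <- out + stats::rbinom(m, 1L, 0.5) * 2^(p - 1)
  out
}

#' Derrida curve of a network
#'
#' Samples pairs of initial states stratified by initial Hamming distance
#' d = 1..N over the free nodes (a uniform random state plus d random
#' distinct bit flips), advances each pair one synchronous step, and averages
#' the normalized Hamming distance after the step within each
#' initial-distance bin. The point (0, 0) is always included: identical
#' states remain identical under a deterministic update.
#'
#' @param net A `BooleanNetwork`.
#' @param n_pairs Total number of sampled pairs (default 10000).
#' @param seed Integer seed.
#' @return A `DerridaCurve`: data.frame `points` with `h_t`, `mean_h_t1`,
#'   `n_pairs`, plus fields `N` (free-node count) and `seed`.
#' @export
derrida_curve <- function(net, n_pairs = 10000L, seed = 1L) {
  stopifnot(n_pairs >= 1L)
  set.seed(seed)
  cn <- compile_network(net)
  N <- cn$n_free
  free_pos <- cn$positions
  d <- rep(seq_len(N), length.out = n_pairs)  # stratified over distances
  x1 <- random_states(net, n_pairs)
  x2 <- x1
  for (k in seq_len(n_pairs)) {
    flips <- sample(free_pos, d[[k]])
    for (p in flips) x2[[k]] <- flip_bit(x2[[k]], p)
  }
  s1 <- .bn_step_cpp(cn$code, cn$offsets, N, compress_state(x1, free_pos))
  s2 <- .bn_step_cpp(cn$code, cn$offsets, N, compress_state(x2, free_pos))
  h1 <- .bn_hamming_cpp(s1, s2) / N
  mean_by_d <- tapply(h1, d, mean)
  count_by_d <- tapply(h1, d, length)
  dd <- as.integer(names(mean_by_d))
  points <- data.frame(
    h_t = c(0, dd / N),
    mean_h_t1 = c(0, as.numeric(mean_by_d)),
    n_pairs = c(NA_integer_, as.integer(count_by_d)))
  structure(list(points = points, N = N, seed = seed), class = "DerridaCurve")
}

#' @export
print.DerridaCurve <- function(x, ...) {
  slope <- derrida_slope(x)
  cat(sprintf("DerridaCurve: N = %d, %d bins, initial slope ~ %.3f, seed %d\n",
              x$N, nrow(x$points) - 1L, slope, x$seed))
  invisible(x)
}

#' Initial slope of a Derrida curve
#'
#' The mean one-step distance at the smallest nonzero initial distance,
#' divided by that distance: the finite-difference slope at the origin,
#' which estimates the network's one-step perturbation expansion rate.
#'
#' @param curve A `DerridaCurve`.
#' @return Numeric slope estimate.
#' @export
derrida_slope <- function(curve) {
  p <- curve$points[curve$points$h_t > 0, , drop = FALSE]
  p$mean_h_t1[[1]] / p$h_t[[1]]
}

#' Classify the dynamical regime from a Derrida curve
#'
#' Applies a chi-squared goodness-of-fit comparison of the observed mean
#' one-step distances against the identity line (expected = h_t) on the bins
#' before the first crossing of the identity line. No significant deviation
#' means the curve tracks the diagonal: critical; a significant deficit means
#' perturbations shrink: ordered; a significant excess: chaotic. A curve that
#' is identically zero is classified ordered without a test.
#'
#' Note the test inherits the source procedure's treatment of averaged
#' distances as goodness-of-fit counts; it is reproduced as stated rather
#' than replaced by a formally calibrated test.
#'
#' @param curve A `DerridaCurve`.
#' @param alpha Significance level (default 0.05).
#' @return A list with `regime` (`"ordered"`, `"critical"`, `"chaotic"`),
#'   `p_value`, `statistic`, and the number of bins used.
#' @export
classify_regime <- function(curve, alpha = 0.05) {
  pts <- curve$points[curve$points$h_t > 0, , drop = FALSE]
  if (all(pts$mean_h_t1 == 0))
    return(list(regime = "ordered", p_value = NA_real_,
                statistic = NA_real_, bins_used = 0L))
  dev <- pts$mean_h_t1 - pts$h_t
  crossing <- which(sign(dev) != sign(dev[[1]]))
  cut <- if (length(crossing)) crossing[[1]] - 1L else nrow(pts)
  cut <- max(cut, 3L)  # need at least 3 bins for a meaningful comparison
  # compare on the un-normalized (bit count) scale: with normalized
  # distances the expected values are << 1 and the statistic degenerates
  obs <- pts$mean_h_t1[seq_len(cut)] * curve$N
  exp <- pts$h_t[seq_len(cut)] * curve$N
  stat <- sum((obs - exp)^2 / exp)
  p <- stats::pchisq(stat, df = cut - 1L, lower.tail = FALSE)
  regime <- if (p >= alpha) "critical"
    else if (sum(obs) < sum(exp)) "ordered" else "chaotic"
  list(regime = regime, p_value = p, statistic = stat, bins_used = cut)
}

#' Sensitivity of one node's update rule
#'
#' Estimates the probability that flipping one uniformly chosen node bit of a
#' uniform random state changes the node's update-function output. By
#' default the flipped bit is chosen among all N nodes (so a rule that copies
#' a single input has sensitivity 1/N and a constant rule 0); with
#' `inputs_only = TRUE` the flip is restricted to the rule's own inputs.
#'
#' @param net A `BooleanNetwork`.
#' @param node Node name.
#' @param n_samples Number of sampled states (default 50000).
#' @param seed Integer seed.
#' @param inputs_only Restrict flips to the function's referenced nodes.
#' @return Estimated sensitivity in `[0, 1]`.
#' @export
rule_sensitivity <- function(net, node, n_samples = 50000L, seed = 1L,
                             inputs_only = FALSE) {
  stopifnot(n_samples >= 1L)
  if (!node %in% net$node_names) stop("unknown node: ", node, call. = FALSE)
  set.seed(seed)
  N <- n_nodes(net)
  index <- stats::setNames(as.list(seq_len(N) - 1L), net$node_names)
  code <- bexpr_compile(net$functions[[node]], index)
  pool <- if (inputs_only) {
    vars <- bexpr_vars(net$functions[[node]])
    if (length(vars) == 0L) return(0)
    match(vars, net$node_names)
  } else seq_len(N)
  x <- numeric(n_samples)
  for (p in seq_len(N))
    x <- x + stats::rbinom(n_samples, 1L, 0.5) * 2^(p - 1)
  pos <- pool[sample.int(length(pool), n_samples, replace = TRUE)]
  bit <- (x %/% 2^(pos - 1)) %% 2
  y <- x + (1 - 2 * bit) * 2^(pos - 1)
  f1 <- .bn_eval_node_cpp(code, x)
  f2 <- .bn_eval_node_cpp(code, y)
  mean(f1 != f2)
}

#' Sensitivity profile of a whole network
#'
#' [rule_sensitivity()] for every node, the arithmetic network mean, and the
#' N-scaled mean (`N * mean`), which estimates the expected one-step spread
#' of a single-bit perturbation -- the quantity whose position relative to 1
#' separates ordered (< 1) from chaotic (> 1) dynamics.
#'
#' @param net A `BooleanNetwork`.
#' @param n_samples Samples per node (default 50000).
#' @param seed Integer seed.
#' @param inputs_only Passed to [rule_sensitivity()].
#' @return A `SensitivityProfile`: `per_node` (named numeric),
#'   `network_mean`, `expected_spread`, `n_samples`, `seed`.
#' @export
network_sensitivity <- function(net, n_samples = 50000L, seed = 1L,
                                inputs_only = FALSE) {
  per_node <- vapply(seq_along(net$node_names), function(i)
    rule_sensitivity(net, net$node_names[[i]], n_samples = n_samples,
                     seed = seed + i, inputs_only = inputs_only),
    numeric(1))
  names(per_node) <- net$node_names
  structure(list(per_node = per_node,
                 network_mean = mean(per_node),
                 expected_spread = n_nodes(net) * mean(per_node),
                 n_samples = n_samples, seed = seed,
                 inputs_only = inputs_only),
            class = "SensitivityProfile")
}

#' @export
print.SensitivityProfile <- function(x, ...) {
  cat(sprintf(paste0("SensitivityProfile: network mean %.4f ",
                     "(expected one-step spread %.3f), n = %d, seed %d\n"),
              x$network_mean, x$expected_spread, x$n_samples, x$seed))
  top <- sort(x$per_node, decreasing = TRUE)[seq_len(min(5, length(x$per_node)))]
  cat("  highest:", paste(sprintf("%s=%.4f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}
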