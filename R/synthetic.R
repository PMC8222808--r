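# Synthetic networks: random Boolean network ensembles (N, K, bias p) and a
# catalog of tiny fixture networks with analytically known landscapes.

# Truth table (length 2^k, row r = output for input bits of r) -> expression
# over the given input names, as a disjunction of minterms (or a negated
# disjunction when that is smaller).
#' @noRd
truth_table_to_expr <- function(inputs, table) {
  k <- length(inputs)
  stopifnot(length(table) == 2^k)
  if (all(table == 0L)) return(bexpr_const(0L))
  if (all(table == 1L)) return(bexpr_const(1L))
  ones <- which(table == 1L) - 1L
  negate <- length(ones) > 2^(k - 1)
  rows <- if (negate) setdiff(0:(2^k - 1L), ones) else ones
  minterm <- function(r) {
    bexpr_and(lapply(seq_len(k), function(i) {
      v <- bexpr_var(inputs[[i]])
      if ((r %/% 2^(i - 1)) %% 2 == 1) v else bexpr_not(v)
    }))
  }
  e <- bexpr_or(lapply(rows, minterm))
  if (negate) bexpr_not(e) else e
}

#' Generate a random Boolean network
#'
#' Classic N-K random Boolean network ensemble: every node receives `k`
#' distinct inputs chosen uniformly among all nodes (self-inputs allowed, as
#' in the ensembles underlying Derrida/annealed-approximation theory) and an
#' independent random truth table whose rows are 1 with probability `p`.
#' With `k = 2, p = 0.5` the annealed prediction `2 K p (1 - p) = 1` puts
#' the ensemble at criticality.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param k In-degree (0 <= k <= n_nodes).
#' @param p Truth-table bias (probability of output 1).
#' @param seed Integer seed; the same seed gives the identical network.
#' @return A `BooleanNetwork` with nodes `G1..Gn`.
#' @export
random_network <- function(n_nodes, k = 2L, p = 0.5, seed = 1L) {
  stopifnot(n_nodes >= 1L, p >= 0, p <= 1)
  if (k > n_nodes) stop("in-degree k cannot exceed n_nodes", call. = FALSE)
  set.seed(seed)
  nodes <- paste0("G", seq_len(n_nodes))
  functions <- stats::setNames(lapply(seq_len(n_nodes), function(i) {
    if (k == 0L) return(bexpr_const(stats::rbinom(1L, 1L, p)))
    inputs <- nodes[sample.int(n_nodes, k)]
    truth_table_to_expr(inputs, stats::rbinom(2^k, 1L, p))
  }), nodes)
  boolean_network(nodes, functions,
                  metadata = sprintf("random N-K network: n=%d K=%d p=%g seed=%d",
                                     n_nodes, k, p, seed))
}

#' Catalog of fixture networks with known landscapes
#'
#' Tiny networks whose complete synchronous landscapes are known by hand
#' enumeration, shipped with their expected attractors and basins as test
#' vectors:
#' \describe{
#'   \item{identity1}{one self-copying node: fixed points 0 and 1, basins 1/1.}
#'   \item{toggle}{two mutually repressing nodes: fixed points 01 and 10
#'     (encodings 2 and 1), plus the 2-cycle \{00, 11\} with basin 2.}
#'   \item{negring3}{three-node negation ring: synchronously, a 2-cycle
#'     \{000, 111\} with basin 2 and a 6-cycle through the remaining states.}
#'   \item{const3}{three constant-0 nodes: the single fixed point 0 absorbs
#'     all 8 states.}
#' }
#'
#' @return Named list; each entry has `net` (a `BooleanNetwork`) and
#'   `expected`, a list of `list(states =, basin =)` in canonical order.
#' @export
fixture_catalog <- function() {
  list(
    identity1 = list(
      net = parse_rules("targets, factors\nA, A"),
      expected = list(list(states = 0, basin = 1),
                      list(states = 1, basin = 1))),
    toggle = list(
      net = parse_rules("targets, factors\nA, !B\nB, !A"),
      expected = list(list(states = c(0, 3), basin = 2),
                      list(states = 1, basin = 1),
                      list(states = 2, basin = 1))),
    negring3 = list(
      net = parse_rules("targets, factors\nA, !C\nB, !A\nC, !B"),
      expected = list(list(states = c(0, 7), basin = 2),
                      list(states = c(1, 5, 4, 6, 2, 3), basin = 6))),
    const3 = list(
      net = parse_rules("targets, factors\nA, 0\nB, 0\nC, 0"),
      expected = list(list(states = 0, basin = 8))))
}
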