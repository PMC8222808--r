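# Synchronous dynamics: single step, trajectories, exhaustive attractor and
# basin enumeration over the free-state space.

# Compile a network for the C++ engine: substitute clamp constants into every
# free node's expression and emit one bytecode program per free node, indexed
# over free nodes in declared order.
#' @noRd
compile_network <- function(net) {
  free <- free_nodes(net)
  if (length(free) == 0L)
    stop("network has no free nodes (everything is clamped)", call. = FALSE)
  index <- stats::setNames(as.list(seq_along(free) - 1L), free)
  clamp_list <- as.list(net$clamps)
  programs <- lapply(free, function(node) {
    e <- bexpr_substitute(net$functions[[node]], clamp_list)
    bexpr_compile(e, index)
  })
  offsets <- c(0L, cumsum(lengths(programs)))
  positions <- match(free, net$node_names)
  clamp_value <- if (length(net$clamps))
    sum(net$clamps * 2^(match(names(net$clamps), net$node_names) - 1)) else 0
  list(code = as.integer(unlist(programs)), offsets = as.integer(offsets),
       n_free = length(free), free = free, positions = positions,
       clamp_value = clamp_value)
}

#' Advance a state by one synchronous step
#'
#' Every node is updated simultaneously from the same input state; clamped
#' nodes keep their clamp values.
#'
#' @param net A `BooleanNetwork`.
#' @param s Numeric vector of full-state encodings (see [encode_state()]).
#' @return Numeric vector of successor encodings.
#' @examples
#' toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
#' bn_step(toggle, 0)  # 00 -> 11
#' @export
bn_step <- function(net, s) {
  if (!all(state_respects_clamps(s, net)))
    stop("state does not respect the network's clamps", call. = FALSE)
  if (length(free_nodes(net)) == 0L) return(s)  # fully determined
  cn <- compile_network(net)
  free_s <- compress_state(s, cn$positions)
  free_t <- .bn_step_cpp(cn$code, cn$offsets, cn$n_free, free_s)
  expand_state(free_t, cn$positions, cn$clamp_value)
}

# Canonical cycle form: rotate so the smallest encoding comes first.
#' @noRd
canonical_cycle <- function(states) {
  k <- which.min(states)
  if (k > 1L) states <- c(states[k:length(states)], states[seq_len(k - 1L)])
  states
}

#' @noRd
new_attractor <- function(states, basin_size, id = NA_integer_) {
  structure(list(states = states, period = length(states),
                 basin_size = basin_size, id = id),
            class = "Attractor")
}

#' @export
print.Attractor <- function(x, ...) {
  cat(sprintf("Attractor%s: period %d, basin %s, states {%s}\n",
              if (is.na(x$id)) "" else paste0(" #", x$id),
              x$period, format(x$basin_size, big.mark = ","),
              paste(format(x$states, scientific = FALSE), collapse = ", ")))
  invisible(x)
}

#' Follow a trajectory to its attractor
#'
#' Iterates the synchronous update from `s` until a state repeats, then
#' returns the attractor (canonical rotation, smallest encoding first) and
#' the number of steps taken before entering the cycle.
#'
#' @param net A `BooleanNetwork`.
#' @param s A single full-state encoding respecting the clamps.
#' @return A list with elements `attractor` (an `Attractor` whose
#'   `basin_size` is `NA`) and `transient` (integer >= 0).
#' @export
trajectory_to_attractor <- function(net, s) {
  stopifnot(length(s) == 1L)
  if (!state_respects_clamps(s, net))
    stop("state does not respect the network's clamps", call. = FALSE)
  if (length(free_nodes(net)) == 0L)
    return(list(attractor = new_attractor(s, 1), transient = 0L))
  cn <- compile_network(net)
  res <- .bn_trajectory_cpp(cn$code, cn$offsets, cn$n_free,
                            compress_state(s, cn$positions))
  states <- canonical_cycle(expand_state(res$cycle, cn$positions, cn$clamp_value))
  list(attractor = new_attractor(states, NA_real_),
       transient = as.integer(res$transient))
}

#' Enumerate all attractors and exact basins exhaustively
#'
#' Evaluates the synchronous successor of every one of the
#' `2^length(free_nodes(net))` initial states with a bit-parallel block
#' evaluator, then identifies every cycle and exact basin size on the
#' successor mapping. Deterministic: no sampling is involved, and attractors
#' are returned sorted by their smallest state encoding.
#'
#' @param net A `BooleanNetwork`.
#' @param cap Refuse to enumerate when the free-node count exceeds this
#'   (default 30). A 29-node run needs roughly 4.5 GB of working memory and
#'   a few minutes of CPU; shrink the space by clamping inputs if that is
#'   more than the machine can give.
#' @return A `Landscape`: list of `Attractor`s plus `free_node_count` and
#'   `total_states`. Basin sizes sum to `total_states`.
#' @examples
#' toggle <- parse_rules("targets, factors\nA, !B\nB, !A")
#' exhaustive_attractors(toggle)
#' @export
exhaustive_attractors <- function(net, cap = 30L) {
  if (length(free_nodes(net)) == 0L) {
    # fully clamped: a single fixed point equal to the clamp vector
    clamp_value <- sum(net$clamps * 2^(match(names(net$clamps),
                                             net$node_names) - 1))
    a <- new_attractor(clamp_value, 1)
    a$id <- 1L
    return(structure(list(attractors = list(a), free_node_count = 0L,
                          total_states = 1, net = net),
                     class = "Landscape"))
  }
  cn <- compile_network(net)
  if (cn$n_free > cap)
    stop(sprintf(paste0("free-node count %d exceeds the cap (%d); clamp more ",
                        "nodes or raise `cap` if you have the memory for ",
                        "2^%d states"),
                 cn$n_free, cap, cn$n_free), call. = FALSE)
  raw <- .bn_exhaustive_cpp(cn$code, cn$offsets, cn$n_free)
  atts <- lapply(seq_along(raw$states), function(a) {
    states <- canonical_cycle(expand_state(raw$states[[a]], cn$positions,
                                           cn$clamp_value))
    new_attractor(states, raw$basin_sizes[[a]])
  })
  ord <- order(vapply(atts, function(a) a$states[[1]], numeric(1)))
  atts <- atts[ord]
  for (k in seq_along(atts)) atts[[k]]$id <- k
  structure(list(attractors = atts,
                 free_node_count = cn$n_free,
                 total_states = 2^cn$n_free,
                 net = net),
            class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  periods <- vapply(x$attractors, function(a) a$period, integer(1))
  cat(sprintf(paste0("Landscape: %d attractors (%d cyclic) over %s states ",
                     "(%d free nodes)\n"),
              length(x$attractors), sum(periods > 1L),
              format(x$total_states, big.mark = ","), x$free_node_count))
  invisible(x)
}

#' Tabulate a landscape
#'
#' @param x A `Landscape`.
#' @param ... Unused.
#' @return A data.frame with one row per attractor: `id`, `period`,
#'   `basin_size`, and `states` (slash-separated encodings).
#' @export
as.data.frame.Landscape <- function(x, ...) {
  data.frame(
    id = vapply(x$attractors, function(a) a$id, integer(1)),
    period = vapply(x$attractors, function(a) a$period, integer(1)),
    basin_size = vapply(x$attractors, function(a) a$basin_size, numeric(1)),
    states = vapply(x$attractors, function(a)
      paste(format(a$states, scientific = FALSE, trim = TRUE), collapse = "/"),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Export a landscape as a tab-separated table
#'
#' One row per attractor state with the per-node binary pattern; a header
#' comment documents the bit order (bit i = node i in declared order).
#'
#' @param landscape A `Landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_landscape <- function(landscape, path) {
  net <- landscape$net
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# macboolnet landscape export",
               paste0("# bit order: bit i of the encoding = node i in ",
                      "declared order (", paste(net$node_names, collapse = ","),
                      ")"),
               paste(c("attractor", "period", "basin_size", "state",
                       net$node_names), collapse = "\t")), con)
  for (a in landscape$attractors) {
    bits <- decode_state(a$states, net)
    for (k in seq_along(a$states))
      writeLines(paste(c(a$id, a$period, a$basin_size,
                         format(a$states[[k]], scientific = FALSE),
                         bits[k, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Structured (JSON) landscape dump
#'
#' @param landscape A `Landscape`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
landscape_to_json <- function(landscape, path = NULL) {
  obj <- list(
    free_node_count = landscape$free_node_count,
    total_states = landscape$total_states,
    node_order = landscape$net$node_names,
    attractors = lapply(landscape$attractors, function(a)
      list(id = a$id, period = a$period, basin_size = a$basin_size,
           states = a$states)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
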