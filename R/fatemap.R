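# Single-bit-flip cell-fate mapping between labeled attractors, with
# reversibility classification at the phenotype-label level.

# Flip bit `node_pos` (1-based, full encoding) of states `s`.
#' @noRd
flip_bit <- function(s, node_pos) {
  bit <- (s %/% 2^(node_pos - 1)) %% 2
  s + (1 - 2 * bit) * 2^(node_pos - 1)
}

#' One-bit neighborhood of an attractor
#'
#' Deterministic, exhaustive version of random single-bit-flip probing: for
#' every state of the attractor and every free (unclamped) node, flips that
#' node's bit, follows the trajectory to its attractor, and records a
#' transition whenever the reached attractor differs from the source. For an
#' attractor of period p in a network with f free nodes, exactly `p * f`
#' flips are evaluated.
#'
#' @param net A `BooleanNetwork`.
#' @param a An `Attractor` of `net`'s dynamics.
#' @param rules Phenotype rules used to label source and target.
#' @return A data.frame of transitions: `source_label`, `target_label`,
#'   `node`, `direction` (`"+"` = bit was off and was turned on, `"-"` =
#'   turned off), `source_state`, `flipped_state`, `target_key` (canonical
#'   first state of the reached attractor).
#' @export
one_bit_neighbors <- function(net, a, rules = default_phenotype_rules()) {
  cn <- compile_network(net)
  source_key <- min(a$states)
  source_label <- if (!is.null(a$label)) a$label else
    label_attractor(a, net, rules)$label
  rows <- list()
  for (s in a$states) {
    for (k in seq_along(cn$free)) {
      pos <- cn$positions[[k]]
      flipped <- flip_bit(s, pos)
      res <- .bn_trajectory_cpp(cn$code, cn$offsets, cn$n_free,
                                compress_state(flipped, cn$positions))
      cycle <- canonical_cycle(expand_state(res$cycle, cn$positions,
                                            cn$clamp_value))
      if (cycle[[1]] == source_key) next
      bit_was <- (s %/% 2^(pos - 1)) %% 2
      target <- new_attractor(cycle, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        source_label = source_label,
        target_label = label_attractor(target, net, rules)$label,
        node = cn$free[[k]],
        direction = if (bit_was == 0) "+" else "-",
        source_state = s, flipped_state = flipped,
        source_key = source_key, target_key = cycle[[1]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(source_label = character(0), target_label = character(0),
                      node = character(0), direction = character(0),
                      source_state = numeric(0), flipped_state = numeric(0),
                      source_key = numeric(0), target_key = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cell-fate map of a landscape
#'
#' Runs [one_bit_neighbors()] over every attractor, aggregates transitions by
#' (source label, target label, node, direction), and classifies an edge as
#' reversible when some single-bit flip on a reached target attractor leads
#' back to an attractor carrying the source's label. Each edge keeps one
#' concrete witness flip; each reversible edge keeps a witness return flip.
#'
#' @param landscape A labeled `Landscape` (labeled on the fly if not).
#' @param rules Phenotype rules.
#' @param max_attractors Safety limit on the number of attractors to probe
#'   (the full landscape of a large model can have tens of thousands);
#'   increase deliberately for full runs.
#' @return A data.frame of label-level edges: `source_label`, `target_label`,
#'   `node`, `direction`, `n_flips` (number of witnessing flips),
#'   `reversible`, `witness_state`, `witness_flip`, `return_node`,
#'   `return_direction`.
#' @export
fate_graph <- function(landscape, rules = default_phenotype_rules(),
                       max_attractors = 5000L) {
  if (!isTRUE(landscape$labeled)) landscape <- label_landscape(landscape, rules)
  atts <- landscape$attractors
  if (length(atts) > max_attractors)
    stop(sprintf(paste0("landscape has %d attractors, above max_attractors = %d; ",
                        "raise the limit deliberately for a full run"),
                 length(atts), max_attractors), call. = FALSE)
  net <- landscape$net
  trans <- do.call(rbind, lapply(atts, one_bit_neighbors, net = net,
                                 rules = rules))
  if (is.null(trans) || nrow(trans) == 0L)
    return(data.frame(source_label = character(0), target_label = character(0),
                      node = character(0), direction = character(0),
                      n_flips = integer(0), reversible = logical(0),
                      stringsAsFactors = FALSE))
  # drop self-label transitions between distinct attractors of the same label
  trans <- trans[trans$source_label != trans$target_label, , drop = FALSE]
  if (nrow(trans) == 0L)
    return(data.frame(source_label = character(0), target_label = character(0),
                      node = character(0), direction = character(0),
                      n_flips = integer(0), reversible = logical(0),
                      stringsAsFactors = FALSE))
  grp <- paste(trans$source_label, trans$target_label, trans$node,
               trans$direction, sep = "\r")
  first <- !duplicated(grp)
  edges <- trans[first, c("source_label", "target_label", "node", "direction",
                          "source_state", "flipped_state"), drop = FALSE]
  names(edges)[names(edges) == "source_state"] <- "witness_state"
  names(edges)[names(edges) == "flipped_state"] <- "witness_flip"
  edges$n_flips <- as.integer(table(grp)[grp[first]])
  # reversibility: some flip applied on one of the attractors actually
  # reached by this label pair leads back to an attractor with the source's
  # label; every reached attractor is itself in the landscape, so its
  # outgoing flips are all in `trans`, keyed by canonical first state.
  edges$reversible <- FALSE
  edges$return_node <- NA_character_
  edges$return_direction <- NA_character_
  pair <- paste(trans$source_label, trans$target_label, sep = "\r")
  for (i in seq_len(nrow(edges))) {
    p <- paste(edges$source_label[[i]], edges$target_label[[i]], sep = "\r")
    tkeys <- unique(trans$target_key[pair == p])
    back <- trans[trans$source_key %in% tkeys &
                    trans$target_label == edges$source_label[[i]], ,
                  drop = FALSE]
    if (nrow(back)) {
      edges$reversible[[i]] <- TRUE
      edges$return_node[[i]] <- back$node[[1]]
      edges$return_direction[[i]] <- back$direction[[1]]
    }
  }
  rownames(edges) <- NULL
  edges[, c("source_label", "target_label", "node", "direction", "n_flips",
            "reversible", "witness_state", "witness_flip", "return_node",
            "return_direction")]
}

#' Export a fate graph in DOT format
#'
#' @param edges A fate-graph edge table from [fate_graph()].
#' @param path Optional output path; when `NULL` the DOT string is returned.
#' @return The DOT string (invisibly when written).
#' @export
fate_graph_dot <- function(edges, path = NULL) {
  lab <- sprintf("  \"%s\" -> \"%s\" [label=\"%s(%s)\"%s];",
                 edges$source_label, edges$target_label, edges$node,
                 edges$direction,
                 ifelse(edges$reversible, ", style=bold", ""))
  out <- paste(c("digraph fate_map {", "  rankdir=LR;", lab, "}"),
               collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
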