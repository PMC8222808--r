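# BooleanNetwork: named nodes, one update expression per node, optional clamps.

#' Construct a BooleanNetwork object
#'
#' Low-level constructor; most users will call [parse_rules()] or
#' [load_macrophage_model()] instead. A `BooleanNetwork` holds an ordered node
#' roster, one Boolean update expression per node, and an optional set of
#' clamps (nodes permanently fixed to 0 or 1).
#'
#' @param node_names Character vector of unique node identifiers; their order
#'   defines the bit order of state encodings (bit `i` = node `i`).
#' @param functions Named list of expression trees (one per node, same order).
#' @param clamps Named integer vector of 0/1 clamp values (possibly empty).
#' @param metadata Free-text provenance string.
#' @return An object of class `BooleanNetwork`.
#' @export
boolean_network <- function(node_names, functions, clamps = integer(0),
                            metadata = "") {
  net <- structure(
    list(node_names = as.character(node_names),
         functions = functions,
         clamps = clamps,
         metadata = metadata),
    class = "BooleanNetwork")
  validate_network(net)
  net
}

#' @noRd
validate_network <- function(net) {
  nn <- net$node_names
  if (length(nn) < 1L) stop("a BooleanNetwork needs at least one node", call. = FALSE)
  if (anyDuplicated(nn)) stop("duplicate node names: ",
                              paste(unique(nn[duplicated(nn)]), collapse = ", "),
                              call. = FALSE)
  if (!identical(sort(names(net$functions)), sort(nn)) ||
      length(net$functions) != length(nn))
    stop("every node needs exactly one update function", call. = FALSE)
  for (node in nn) {
    refs <- bexpr_vars(net$functions[[node]])
    bad <- setdiff(refs, nn)
    if (length(bad))
      stop(sprintf("rule for %s references undeclared node(s): %s",
                   node, paste(bad, collapse = ", ")), call. = FALSE)
  }
  cl <- net$clamps
  if (length(cl)) {
    if (is.null(names(cl)) || any(!nzchar(names(cl))))
      stop("clamps must be a named vector", call. = FALSE)
    bad <- setdiff(names(cl), nn)
    if (length(bad)) stop("clamped node(s) not in network: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(cl))) stop("node clamped twice", call. = FALSE)
    if (!all(cl %in% c(0L, 1L))) stop("clamp values must be 0 or 1", call. = FALSE)
  }
  invisible(net)
}

#' Number of nodes in a network
#' @param net A `BooleanNetwork`.
#' @return Integer node count.
#' @export
n_nodes <- function(net) length(net$node_names)

#' Free (unclamped) nodes of a network
#' @param net A `BooleanNetwork`.
#' @return Character vector of node names not held fixed by a clamp.
#' @export
free_nodes <- function(net) setdiff(net$node_names, names(net$clamps))

#' Regulator-to-target edge list
#'
#' An edge is a distinct (regulator, target) pair in which the regulator
#' appears in the target's update expression; self-loops count. Clamped nodes
#' keep their original expressions for topology purposes.
#'
#' @param net A `BooleanNetwork`.
#' @return A data.frame with columns `regulator` and `target`.
#' @export
network_edges <- function(net) {
  regs <- lapply(net$node_names, function(node)
    bexpr_vars(net$functions[[node]]))
  data.frame(
    regulator = unlist(regs, use.names = FALSE),
    target = rep(net$node_names, lengths(regs)),
    stringsAsFactors = FALSE)
}

#' @export
print.BooleanNetwork <- function(x, ...) {
  cat(sprintf("BooleanNetwork: %d nodes, %d interactions\n",
              n_nodes(x), nrow(network_edges(x))))
  if (length(x$clamps))
    cat("  clamps: ", paste(sprintf("%s=%d", names(x$clamps), x$clamps),
                            collapse = ", "), "\n", sep = "")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

# --- rule-file dialect -------------------------------------------------------

#' Normalize node identifiers to the ASCII roster convention
#'
#' Maps Greek letters to Latin transliterations, strips hyphens and
#' whitespace, and upper-cases, so e.g. `HIF1-α` becomes `HIF1A`.
#' @param x Character vector of raw names.
#' @return Normalized names.
#' @export
normalize_node_name <- function(x) {
  x <- gsub("α|Α", "A", x)
  x <- gsub("β|Β", "B", x)
  x <- gsub("γ|Γ", "G", x)
  x <- gsub("κ|Κ", "K", x)
  x <- gsub("[-\\s]+", "", x, perl = TRUE)
  toupper(x)
}

#' Parse a Boolean network from rule text
#'
#' The dialect is a header line `targets, factors` followed by one rule per
#' line, `NODE, <expression>`, with operators `&` (AND), `|` (OR), `!` (NOT),
#' parentheses, and the constants 0/1. Operator precedence is NOT > AND > OR;
#' whitespace is insignificant. Lines that are empty or start with `#` are
#' skipped.
#'
#' @param text Rule-file content: a single string or a character vector of
#'   lines.
#' @param metadata Provenance string attached to the network.
#' @return A validated `BooleanNetwork`.
#' @examples
#' net <- parse_rules("targets, factors\nA, !B\nB, !A")
#' n_nodes(net)
#' @export
parse_rules <- function(text, metadata = "") {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else as.character(text)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty rule file", call. = FALSE)
  header <- tolower(gsub("\\s+", "", lines[[1]]))
  if (header != "targets,factors")
    stop("expected header line 'targets, factors', found: ", lines[[1]], call. = FALSE)
  lines <- lines[-1]
  lineno <- lineno[-1]
  if (length(lines) == 0L) stop("rule file has a header but no rules", call. = FALSE)

  targets <- character(0)
  functions <- list()
  for (k in seq_along(lines)) {
    parts <- regmatches(lines[[k]], regexpr(",", lines[[k]]), invert = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d is not of the form 'NODE, expression': %s",
                   lineno[[k]], lines[[k]]), call. = FALSE)
    target <- trimws(parts[[1]])
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", target))
      stop(sprintf("invalid target name '%s' on line %d", target, lineno[[k]]),
           call. = FALSE)
    if (target %in% targets)
      stop(sprintf("duplicate target '%s' on line %d", target, lineno[[k]]),
           call. = FALSE)
    targets <- c(targets, target)
    functions[[target]] <- bexpr_parse(parts[[2]], line = lineno[[k]])
  }
  # undeclared references are reported with the offending rule's line
  for (k in seq_along(targets)) {
    bad <- setdiff(bexpr_vars(functions[[targets[[k]]]]), targets)
    if (length(bad))
      stop(sprintf("rule for %s (line %d) references undeclared node(s): %s",
                   targets[[k]], lineno[[k]], paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  boolean_network(targets, functions, metadata = metadata)
}

#' Read a rule file from disk
#' @param path Path to a rule file in the `targets, factors` dialect.
#' @return A `BooleanNetwork`.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  parse_rules(readLines(path, warn = FALSE),
              metadata = paste0("loaded from ", basename(path)))
}

#' Serialize a network to the rule dialect
#'
#' @param net A `BooleanNetwork`.
#' @return A single string; `parse_rules()` of it reproduces a logically
#'   equivalent network. Clamps are not part of the dialect and are dropped.
#' @export
serialize_rules <- function(net) {
  body <- vapply(net$node_names, function(node)
    paste0(node, ", ", bexpr_deparse(net$functions[[node]])), character(1))
  paste(c("targets, factors", body), collapse = "\n")
}

#' Write a network to a rule file
#' @param net A `BooleanNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(net, path) {
  writeLines(serialize_rules(net), path)
  invisible(path)
}

# --- clamps ------------------------------------------------------------------

#' Create a clamp set
#'
#' A clamp permanently fixes a node at 0 (knockout / gene deletion) or 1
#' (overexpression / constitutive signal) for the whole simulation.
#'
#' @param assignments Named vector or list of 0/1 values, e.g.
#'   `c(NFKB = 1, HIF1A = 0)`.
#' @param label Short display name (e.g. `"TGEM"`, `"Pro-M1"`).
#' @return An object of class `ClampSet`.
#' @export
clamp_set <- function(assignments, label = "") {
  a <- unlist(assignments)
  if (length(a) && (is.null(names(a)) || any(!nzchar(names(a)))))
    stop("clamp assignments must be named", call. = FALSE)
  if (anyDuplicated(names(a)))
    stop("node assigned twice in clamp set", call. = FALSE)
  if (length(a) && !all(a %in% c(0, 1)))
    stop("clamp values must be 0 or 1", call. = FALSE)
  structure(list(assignments = stats::setNames(as.integer(a), names(a)),
                 label = label),
            class = "ClampSet")
}

#' @export
print.ClampSet <- function(x, ...) {
  cat(sprintf("ClampSet%s: %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              if (length(x$assignments))
                paste(sprintf("%s=%d", names(x$assignments), x$assignments),
                      collapse = ", ") else "(none)"))
  invisible(x)
}

#' Apply clamps to a network
#'
#' Returns a new network in which each clamped node's update function is
#' replaced by the constant clamp value; the original network is unmodified.
#' Clamps accumulate across calls; re-clamping a node to a conflicting value
#' is an error.
#'
#' @param net A `BooleanNetwork`.
#' @param clamps A `ClampSet`, or a named 0/1 vector.
#' @return A clamped `BooleanNetwork` with `length(free_nodes())` equal to
#'   `n_nodes(net) - length(clamps)` (for previously unclamped nodes).
#' @export
apply_clamps <- function(net, clamps) {
  if (!inherits(clamps, "ClampSet")) clamps <- clamp_set(clamps)
  a <- clamps$assignments
  if (length(a) == 0L) return(net)
  bad <- setdiff(names(a), net$node_names)
  if (length(bad)) stop("unknown node(s) in clamp set: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  overlap <- intersect(names(a), names(net$clamps))
  if (length(overlap)) {
    conflict <- overlap[a[overlap] != net$clamps[overlap]]
    if (length(conflict))
      stop("conflicting clamp for node(s): ", paste(conflict, collapse = ", "),
           call. = FALSE)
  }
  merged <- net$clamps
  merged[names(a)] <- a
  functions <- net$functions
  for (node in names(a)) functions[[node]] <- bexpr_const(a[[node]])
  boolean_network(net$node_names, functions, clamps = merged,
                  metadata = net$metadata)
}

# --- reduction ---------------------------------------------------------------

#' Drop nodes with fewer than two interactions
#'
#' Removes, in a single (non-iterated) pass, every node whose total degree
#' (in + out over distinct regulator-to-target pairs, self-loops counted once
#' in each direction) is below 2. Removed nodes are not substituted into the
#' surviving rules: if a surviving rule still references a removed node the
#' reduction fails with an error listing the affected rules, because silently
#' rewiring logic would change the dynamics.
#'
#' @param net A `BooleanNetwork`.
#' @return The reduced `BooleanNetwork` (possibly identical).
#' @export
reduce_low_degree_nodes <- function(net) {
  edges <- network_edges(net)
  degree <- vapply(net$node_names, function(node)
    sum(edges$regulator == node) + sum(edges$target == node), integer(1))
  drop <- net$node_names[degree < 2L]
  if (length(drop) == 0L) return(net)
  keep <- setdiff(net$node_names, drop)
  if (length(keep) == 0L)
    stop("reduction would remove every node", call. = FALSE)
  orphaned <- keep[vapply(keep, function(node)
    length(intersect(bexpr_vars(net$functions[[node]]), drop)) > 0L, logical(1))]
  if (length(orphaned))
    stop("removing low-degree node(s) would orphan references in rule(s) for: ",
         paste(orphaned, collapse = ", "), call. = FALSE)
  boolean_network(keep, net$functions[keep],
                  clamps = net$clamps[intersect(names(net$clamps), keep)],
                  metadata = net$metadata)
}

# --- bundled model -----------------------------------------------------------

#' Load the bundled macrophage polarization network
#'
#' Returns the 29-node, 60-interaction transcriptional regulatory network of
#' macrophage polarization in a tumor microenvironment that ships with the
#' package. The bundled file is a reconstruction transcribed from the source
#' article's narrative description of the signaling cascades (see the file's
#' provenance note and the methods vignette); it reproduces the published
#' node and interaction counts and the qualitative transition behavior, but
#' it is not the authors' original supplementary rule file.
#'
#' @return A `BooleanNetwork` with 29 nodes and 60 regulator-to-target pairs.
#' @examples
#' net <- load_macrophage_model()
#' n_nodes(net)
#' @export
load_macrophage_model <- function() {
  path <- system.file("extdata", "models", "macrophage_tme_synthetic.txt",
                      package = "macboolnet")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled macrophage model file is missing or the package is corrupt",
         call. = FALSE)
  net <- read_rules(path)
  net$metadata <- paste("macrophage polarization TRN (synthetic reconstruction;",
                        "29 nodes / 60 interactions)")
  net
}
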