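# State encodings: a network state is a non-negative integer with bit i
# (LSB = bit 1 here in R terms) holding the 0/1 state of node i in declared
# order. Encodings are carried as doubles, exact for networks up to 53 nodes.

#' Encode a per-node state vector as an integer state encoding
#'
#' @param bits 0/1 vector in node order, or a named 0/1 vector whose names are
#'   matched against `net$node_names` (missing nodes default to 0).
#' @param net A `BooleanNetwork` giving node order.
#' @return A numeric (double) encoding with bit `i` = node `i`.
#' @examples
#' net <- parse_rules("targets, factors\nA, !B\nB, !A")
#' encode_state(c(B = 1), net)
#' @export
encode_state <- function(bits, net) {
  nn <- net$node_names
  if (!is.null(names(bits)) && any(nzchar(names(bits)))) {
    bad <- setdiff(names(bits), nn)
    if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    full <- stats::setNames(numeric(length(nn)), nn)
    full[names(bits)] <- bits
    bits <- full
  }
  if (length(bits) != length(nn))
    stop("state vector length must equal node count", call. = FALSE)
  if (!all(bits %in% c(0, 1))) stop("states are 0/1", call. = FALSE)
  sum(as.numeric(bits) * 2^(seq_along(nn) - 1))
}

#' Decode state encodings to a 0/1 matrix
#'
#' @param enc Numeric vector of state encodings.
#' @param net A `BooleanNetwork` (or an integer node count).
#' @return An integer matrix, one row per encoding, one named column per node.
#' @export
decode_state <- function(enc, net) {
  n <- if (inherits(net, "BooleanNetwork")) n_nodes(net) else as.integer(net)
  out <- matrix(0L, nrow = length(enc), ncol = n)
  for (i in seq_len(n))
    out[, i] <- as.integer((enc %/% 2^(i - 1)) %% 2)
  if (inherits(net, "BooleanNetwork")) colnames(out) <- net$node_names
  out
}

# Extract the free-node bits of full encodings (positions are 1-based in
# declared order), producing encodings over the free subspace.
#' @noRd
compress_state <- function(enc, positions) {
  out <- numeric(length(enc))
  for (k in seq_along(positions))
    out <- out + ((enc %/% 2^(positions[k] - 1)) %% 2) * 2^(k - 1)
  out
}

# Inverse of compress_state: place free bits back and add the clamp bits.
#' @noRd
expand_state <- function(enc, positions, clamp_value) {
  out <- rep(clamp_value, length.out = length(enc))
  for (k in seq_along(positions))
    out <- out + ((enc %/% 2^(k - 1)) %% 2) * 2^(positions[k] - 1)
  out
}

#' @noRd
state_respects_clamps <- function(enc, net) {
  if (length(net$clamps) == 0L) return(rep(TRUE, length(enc)))
  pos <- match(names(net$clamps), net$node_names)
  ok <- rep(TRUE, length(enc))
  for (k in seq_along(pos))
    ok <- ok & ((enc %/% 2^(pos[k] - 1)) %% 2) == net$clamps[[k]]
  ok
}
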