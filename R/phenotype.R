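# Phenotype labeling of attractors (M1/M2a/M2b/M2c/M2d marker logic),
# landscape census, and 2D embedding + clustering of attractor patterns.

#' Create a phenotype rule
#'
#' @param label Phenotype name (e.g. `"M1"`).
#' @param expression Boolean marker expression over node names, in the same
#'   dialect as the rule files.
#' @return A `PhenotypeRule`.
#' @export
phenotype_rule <- function(label, expression) {
  structure(list(label = label, expr = bexpr_parse(expression)),
            class = "PhenotypeRule")
}

#' Default macrophage phenotype rules
#'
#' The marker logic used to name attractors: a state is called M1 when NFKB
#' or STAT1 is active, or TNFA together with AP1; M2a when STAT6 is active;
#' M2b when AP1 or ERK; M2c when STAT3; M2d when TLR4 together with A2A, or
#' HIF1A. A state matching no rule is labeled M0 (monocyte). Hybrid labels
#' concatenate all matching phenotypes in the fixed order M1, M2a, M2b, M2c,
#' M2d (e.g. `"M1M2b"`).
#'
#' @return Named list of five `PhenotypeRule`s in label order.
#' @export
default_phenotype_rules <- function() {
  list(
    M1 = phenotype_rule("M1", "NFKB | STAT1 | (TNFA & AP1)"),
    M2a = phenotype_rule("M2a", "STAT6"),
    M2b = phenotype_rule("M2b", "AP1 | ERK"),
    M2c = phenotype_rule("M2c", "STAT3"),
    M2d = phenotype_rule("M2d", "(TLR4 & A2A) | HIF1A"))
}

#' @noRd
check_rules_against <- function(rules, net) {
  for (r in rules) {
    bad <- setdiff(bexpr_vars(r$expr), net$node_names)
    if (length(bad))
      stop(sprintf("phenotype rule %s references missing node(s): %s",
                   r$label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(rules)
}

#' Label network states with phenotype names
#'
#' Evaluates every rule on each state and concatenates the labels of all
#' satisfied rules in the order the rules are given; states satisfying no
#' rule are labeled `"M0"`.
#'
#' @param s Numeric vector of full-state encodings.
#' @param net The `BooleanNetwork` the states belong to.
#' @param rules List of `PhenotypeRule`s (default [default_phenotype_rules()]).
#' @return Character vector of labels, one per state.
#' @examples
#' net <- load_macrophage_model()
#' label_state(0, net)  # all-off state is a monocyte
#' @export
label_state <- function(s, net, rules = default_phenotype_rules()) {
  check_rules_against(rules, net)
  cn_index <- stats::setNames(as.list(seq_along(net$node_names) - 1L),
                              net$node_names)
  hit <- vapply(rules, function(r)
    .bn_eval_node_cpp(bexpr_compile(r$expr, cn_index), as.numeric(s)),
    logical(length(s)))
  hit <- matrix(hit, nrow = length(s))
  labels <- vapply(rules, function(r) r$label, character(1))
  out <- apply(hit, 1L, function(row)
    if (any(row)) paste(labels[row], collapse = "") else "M0")
  as.character(out)
}

# Collapse consecutive duplicates around a cycle of per-state labels.
#' @noRd
dedup_cycle_labels <- function(lab) {
  if (length(lab) > 1L) {
    keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
    lab <- lab[keep]
    if (length(lab) > 1L && lab[[1L]] == lab[[length(lab)]])
      lab <- lab[-length(lab)]
  }
  lab
}

#' Label a single attractor
#'
#' Fixed points get the label of their single state; cyclic attractors get
#' the per-state labels in cycle order from the canonical start, consecutive
#' duplicates collapsed, joined with `"/"`.
#'
#' @param a An `Attractor`.
#' @param net The `BooleanNetwork`.
#' @param rules Phenotype rules.
#' @return The attractor with a `label` field set (class `LabeledAttractor`
#'   prepended).
#' @export
label_attractor <- function(a, net, rules = default_phenotype_rules()) {
  lab <- dedup_cycle_labels(label_state(a$states, net, rules))
  a$label <- paste(lab, collapse = "/")
  class(a) <- unique(c("LabeledAttractor", class(a)))
  a
}

#' Label every attractor of a landscape
#'
#' @param landscape A `Landscape`.
#' @param rules Phenotype rules.
#' @return The landscape with labeled attractors and a `labeled = TRUE` flag.
#' @export
label_landscape <- function(landscape, rules = default_phenotype_rules()) {
  landscape$attractors <- lapply(landscape$attractors, label_attractor,
                                 net = landscape$net, rules = rules)
  landscape$labeled <- TRUE
  landscape
}

#' Phenotype census of a landscape
#'
#' Partitions the attractors by label and totals their basins. The counts
#' sum to the number of attractors and the basins to `total_states`.
#'
#' @param landscape A `Landscape` (labeled on the fly if needed).
#' @param rules Phenotype rules.
#' @return A data.frame with columns `label`, `n_attractors`, `basin_size`,
#'   sorted by decreasing basin mass.
#' @export
phenotype_census <- function(landscape, rules = default_phenotype_rules()) {
  if (!isTRUE(landscape$labeled))
    landscape <- label_landscape(landscape, rules)
  labels <- vapply(landscape$attractors, function(a) a$label, character(1))
  basins <- vapply(landscape$attractors, function(a) a$basin_size, numeric(1))
  agg <- stats::aggregate(
    data.frame(n_attractors = 1L, basin_size = basins),
    by = list(label = labels), FUN = sum)
  agg <- agg[order(-agg$basin_size, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# --- embedding and clustering ------------------------------------------------

# Exact (dense) t-SNE on a small pattern matrix; seeded and deterministic.
#' @noRd
tsne_embed <- function(X, perplexity = 30, max_iter = 700, seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  # per-point precision via bisection on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  lr <- max(50, n / 12)  # van der Maaten's auto learning rate, floored
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1   # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    momentum <- if (iter > 20) 0.8 else 0.5
    G <- momentum * G - lr * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Internal cluster-validity indices on a 2D embedding. Larger is better for
# silhouette / Calinski-Harabasz / Dunn; Davies-Bouldin is negated so every
# index votes by maximization.
#' @noRd
validity_indices <- function(Y, assign_by_k) {
  D <- as.matrix(stats::dist(Y))
  n <- nrow(Y)
  score <- function(cl) {
    k <- length(unique(cl))
    if (k < 2L) return(c(sil = NA, ch = NA, db = NA, dunn = NA))
    cent <- do.call(rbind, lapply(split(seq_len(n), cl), function(ix)
      colMeans(Y[ix, , drop = FALSE])))
    sizes <- tabulate(cl)
    gmean <- colMeans(Y)
    B <- sum(sizes * rowSums(sweep(cent, 2, gmean)^2))
    W <- sum(vapply(seq_len(n), function(i)
      sum((Y[i, ] - cent[cl[i], ])^2), numeric(1)))
    ch <- (B / (k - 1)) / (W / max(n - k, 1))
    # silhouette
    sil <- mean(vapply(seq_len(n), function(i) {
      a <- if (sizes[cl[i]] > 1)
        sum(D[i, cl == cl[i]]) / (sizes[cl[i]] - 1) else 0
      b <- min(vapply(setdiff(seq_len(k), cl[i]), function(j)
        mean(D[i, cl == j]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
    # Davies-Bouldin
    sbar <- vapply(seq_len(k), function(j)
      mean(sqrt(rowSums(sweep(Y[cl == j, , drop = FALSE], 2, cent[j, ])^2))),
      numeric(1))
    dbj <- vapply(seq_len(k), function(j) {
      others <- setdiff(seq_len(k), j)
      max((sbar[j] + sbar[others]) /
            sqrt(rowSums(sweep(cent[others, , drop = FALSE], 2, cent[j, ])^2)))
    }, numeric(1))
    db <- mean(dbj)
    # Dunn
    diam <- max(vapply(seq_len(k), function(j) {
      ix <- which(cl == j)
      if (length(ix) < 2) 0 else max(D[ix, ix])
    }, numeric(1)))
    sep <- min(vapply(seq_len(k - 1), function(j) {
      min(vapply((j + 1):k, function(l)
        min(D[cl == j, cl == l]), numeric(1)))
    }, numeric(1)))
    dunn <- if (diam == 0) Inf else sep / diam
    c(sil = sil, ch = ch, db = -db, dunn = dunn)
  }
  t(vapply(assign_by_k, score, numeric(4)))
}

#' Embed attractor patterns in 2D and cluster them
#'
#' Period-1 attractors are embedded from their binary node patterns with a
#' seeded stochastic-neighbor embedding (exact t-SNE; a PCA embedding is used
#' above `max_tsne` points, where the dense t-SNE becomes impractical), then
#' k-means is run for every k in `k_range` and a consensus k is chosen by
#' majority vote of a battery of internal validity indices (silhouette,
#' Calinski-Harabasz, Davies-Bouldin, Dunn).
#'
#' @param landscape A labeled or unlabeled `Landscape`.
#' @param k_range Candidate cluster counts (default `10:30`).
#' @param seed Integer seed controlling the embedding and k-means.
#' @param rules Phenotype rules used to annotate the result.
#' @param method `"tsne"`, `"pca"`, or `"auto"` (default).
#' @param max_tsne Point count above which `"auto"` falls back to PCA.
#' @return A `ClusterAssignment`: data.frame `points` (attractor id, x, y,
#'   cluster, label), consensus `k`, per-index `votes`, and `seed`.
#' @export
embed_and_cluster <- function(landscape, k_range = 10:30, seed = 1L,
                              rules = default_phenotype_rules(),
                              method = c("auto", "tsne", "pca"),
                              max_tsne = 2000L) {
  method <- match.arg(method)
  if (!isTRUE(landscape$labeled)) landscape <- label_landscape(landscape, rules)
  simple <- Filter(function(a) a$period == 1L, landscape$attractors)
  if (length(simple) < 2L)
    stop("need at least two period-1 attractors to embed", call. = FALSE)
  if (length(simple) <= min(k_range))
    stop(sprintf("only %d attractors but smallest k is %d",
                 length(simple), min(k_range)), call. = FALSE)
  X <- decode_state(vapply(simple, function(a) a$states[[1]], numeric(1)),
                    landscape$net)
  # embed unique patterns only: identical patterns share coordinates (and
  # therefore always share a cluster), and t-SNE is spared degenerate
  # zero-distance neighborhoods
  key <- apply(X, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  Xu <- X[uniq, , drop = FALSE]
  if (method == "auto")
    method <- if (nrow(Xu) <= max_tsne) "tsne" else "pca"
  Yu <- if (method == "tsne" && nrow(Xu) > 4L) {
    tsne_embed(Xu, seed = seed)
  } else {
    p <- stats::prcomp(Xu, center = TRUE, scale. = FALSE)
    cbind(p$x[, 1], if (ncol(p$x) > 1) p$x[, 2] else 0)
  }
  Y <- Yu[match(key, key[uniq]), , drop = FALSE]
  k_range <- k_range[k_range < nrow(X) & k_range <= nrow(Xu)]
  if (length(k_range) == 0L)
    stop("no admissible k below the number of (distinct) attractors",
         call. = FALSE)
  assigns <- lapply(k_range, function(k) {
    # several seeded starts from distinct embedded points (plain nstart can
    # draw duplicated rows as coincident centers and fail)
    set.seed(seed + k)
    best <- NULL
    for (r in 1:10) {
      fit <- stats::kmeans(Y, centers = Yu[sample.int(nrow(Yu), k), ,
                                           drop = FALSE], iter.max = 50)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best$cluster
  })
  names(assigns) <- as.character(k_range)
  idx <- validity_indices(Y, assigns)
  votes <- apply(idx, 2, function(col) k_range[which.max(col)])
  tab <- table(votes)
  k <- as.integer(names(tab)[which.max(tab)])
  cl <- assigns[[as.character(k)]]
  structure(list(
    points = data.frame(
      id = vapply(simple, function(a) a$id, integer(1)),
      x = Y[, 1], y = Y[, 2], cluster = cl,
      label = vapply(simple, function(a) a$label, character(1)),
      stringsAsFactors = FALSE),
    k = k, votes = votes, seed = seed, method = method),
    class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d attractors, consensus k = %d (%s), seed %d\n",
              nrow(x$points), x$k, x$method, x$seed))
  cat("  index votes:", paste(sprintf("%s=%s", names(x$votes), x$votes),
                              collapse = ", "), "\n")
  invisible(x)
}
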