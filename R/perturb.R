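# Knockout/overexpression scans, log2 basin fold-change, microenvironment
# simulations, TGEM/STGEM construction, and breast cancer scenarios.

# Session-level landscape cache keyed by (rule digest, clamp signature), so a
# scan can reuse the expensive wild-type enumeration.
.landscape_cache <- new.env(parent = emptyenv())

#' @noRd
landscape_cache_key <- function(net, rules = list()) {
  sig <- paste(serialize_rules(net),
               paste(sprintf("%s=%d", names(net$clamps), net$clamps),
                     collapse = ";"),
               paste(vapply(rules, function(r)
                 paste(r$label, bexpr_deparse(r$expr)), character(1)),
                 collapse = ";"),
               sep = "\n--\n")
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(sig, tf)
  as.character(tools::md5sum(tf))
}

#' Enumerate and label, with session caching
#'
#' [exhaustive_attractors()] + [label_landscape()], memoized on the rule text
#' and clamp set so repeated perturbation scans reuse the reference landscape.
#'
#' @param net A `BooleanNetwork`.
#' @param rules Phenotype rules.
#' @param cap Free-node cap passed to [exhaustive_attractors()].
#' @return A labeled `Landscape`.
#' @export
labeled_landscape <- function(net, rules = default_phenotype_rules(),
                              cap = 30L) {
  key <- landscape_cache_key(net, rules)
  hit <- .landscape_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- label_landscape(exhaustive_attractors(net, cap = cap), rules)
  .landscape_cache[[key]] <- out
  out
}

#' @noRd
label_basins <- function(landscape) {
  labels <- vapply(landscape$attractors, function(a) a$label, character(1))
  basins <- vapply(landscape$attractors, function(a) a$basin_size, numeric(1))
  tapply(basins, labels, sum)
}

#' Per-label log2 basin fold-change between two landscapes
#'
#' Aggregates basin mass by phenotype label in each landscape and reports
#' `log2(perturbed / reference)` per label. Labels with reference mass but no
#' perturbed mass are flagged `"lost"`; labels appearing only in the
#' perturbed landscape are flagged `"gained"`. A per-attractor mode (match by
#' identical state sets) is also available.
#'
#' @param wt Reference (wild-type) labeled `Landscape`.
#' @param pert Perturbed labeled `Landscape`.
#' @param by `"label"` (default, the heatmap semantics) or `"attractor"`.
#' @return A data.frame with columns `label`, `wt_basin`, `pert_basin`,
#'   `log2fc` (NA when flagged), `status` (`"ok"`, `"lost"`, `"gained"`).
#' @export
basin_log2_foldchange <- function(wt, pert, by = c("label", "attractor")) {
  by <- match.arg(by)
  stopifnot(isTRUE(wt$labeled), isTRUE(pert$labeled))
  if (by == "label") {
    wb <- label_basins(wt)
    pb <- label_basins(pert)
    keys <- sort(union(names(wb), names(pb)))
    w <- ifelse(keys %in% names(wb), wb[keys], 0)
    p <- ifelse(keys %in% names(pb), pb[keys], 0)
  } else {
    wk <- vapply(wt$attractors, function(a)
      paste(a$states, collapse = "/"), character(1))
    pk <- vapply(pert$attractors, function(a)
      paste(a$states, collapse = "/"), character(1))
    keys <- sort(union(wk, pk))
    w <- vapply(keys, function(k) {
      i <- match(k, wk)
      if (is.na(i)) 0 else wt$attractors[[i]]$basin_size
    }, numeric(1))
    p <- vapply(keys, function(k) {
      i <- match(k, pk)
      if (is.na(i)) 0 else pert$attractors[[i]]$basin_size
    }, numeric(1))
  }
  status <- ifelse(w > 0 & p > 0, "ok", ifelse(w > 0, "lost", "gained"))
  data.frame(label = keys,
             wt_basin = as.numeric(w), pert_basin = as.numeric(p),
             log2fc = ifelse(status == "ok", log2(p / w), NA_real_),
             status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @noRd
new_perturbation_result <- function(perturbation, landscape, wt, reference) {
  structure(list(perturbation = perturbation,
                 landscape = landscape,
                 foldchange = basin_log2_foldchange(wt, landscape),
                 reference = reference),
            class = "PerturbationResult")
}

#' @export
print.PerturbationResult <- function(x, ...) {
  cat(sprintf("PerturbationResult '%s' vs %s: %d attractors\n",
              x$perturbation$label, x$reference,
              length(x$landscape$attractors)))
  print(utils::head(x$foldchange, 15))
  invisible(x)
}

#' Scan single-node knockouts or overexpressions
#'
#' For every node (or the subset in `nodes`), clamps it at 0 (`knockout`) or
#' 1 (`overexpress`), exhaustively enumerates the clamped landscape over its
#' `2^(N-1)` free states, labels it, and reports per-label basin fold-changes
#' against the wild-type landscape.
#'
#' @param net A `BooleanNetwork` (typically unclamped).
#' @param mode `"knockout"` or `"overexpress"`.
#' @param nodes Nodes to scan (default: all free nodes).
#' @param rules Phenotype rules.
#' @param wt Optional precomputed labeled wild-type `Landscape`.
#' @param cap Free-node cap.
#' @return Named list of `PerturbationResult`, one per node.
#' @export
single_node_scan <- function(net, mode = c("knockout", "overexpress"),
                             nodes = NULL, rules = default_phenotype_rules(),
                             wt = NULL, cap = 30L) {
  mode <- match.arg(mode)
  value <- if (mode == "knockout") 0L else 1L
  if (is.null(nodes)) nodes <- free_nodes(net)
  if (is.null(wt)) wt <- labeled_landscape(net, rules, cap = cap)
  out <- lapply(nodes, function(node) {
    cs <- clamp_set(stats::setNames(value, node),
                    label = sprintf("%s %s", node, mode))
    pl <- labeled_landscape(apply_clamps(net, cs), rules, cap = cap)
    new_perturbation_result(cs, pl, wt, reference = "wild-type")
  })
  stats::setNames(out, nodes)
}

#' Long-format fold-change table from scan results
#'
#' @param results List of `PerturbationResult` (e.g. from
#'   [single_node_scan()]).
#' @return A heatmap-ready data.frame: `perturbation`, `label`, `wt_basin`,
#'   `pert_basin`, `log2fc`, `status`.
#' @export
foldchange_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    cbind(perturbation = r$perturbation$label, r$foldchange,
          stringsAsFactors = FALSE)))
}

#' Microenvironment clamp sets
#'
#' The six cytokine milieus associated with macrophage subtypes: Pro-M0 has
#' no external stimuli; Pro-M1 clamps IFNG and IFNB on; Pro-M2a IL4 and TGFB;
#' Pro-M2b IGG and GCGCR (glucocorticoids); Pro-M2c IL10, IL6 and MCSF;
#' Pro-M2d A2A (adenosines), HYPOXIA and GCGCR.
#'
#' @return Named list of `ClampSet`s.
#' @export
microenvironments <- function() {
  defs <- list(
    "Pro-M0" = integer(0),
    "Pro-M1" = c(IFNG = 1L, IFNB = 1L),
    "Pro-M2a" = c(IL4 = 1L, TGFB = 1L),
    "Pro-M2b" = c(IGG = 1L, GCGCR = 1L),
    "Pro-M2c" = c(IL10 = 1L, IL6 = 1L, MCSF = 1L),
    "Pro-M2d" = c(A2A = 1L, HYPOXIA = 1L, GCGCR = 1L))
  stats::setNames(lapply(names(defs), function(nm) clamp_set(defs[[nm]], nm)),
                  names(defs))
}

#' Simulate a cytokine microenvironment
#'
#' Applies the named microenvironment's clamps (see [microenvironments()]),
#' enumerates and labels the clamped landscape, and compares it to the
#' wild-type by per-label basin fold-change.
#'
#' @param net A `BooleanNetwork`.
#' @param env_name One of `"Pro-M0"`, `"Pro-M1"`, `"Pro-M2a"`, `"Pro-M2b"`,
#'   `"Pro-M2c"`, `"Pro-M2d"`.
#' @param rules Phenotype rules.
#' @param wt Optional precomputed labeled wild-type `Landscape`.
#' @param cap Free-node cap.
#' @return A `PerturbationResult`.
#' @export
microenvironment_landscape <- function(net, env_name,
                                       rules = default_phenotype_rules(),
                                       wt = NULL, cap = 30L) {
  envs <- microenvironments()
  if (!env_name %in% names(envs))
    stop("unknown microenvironment '", env_name, "'; valid names: ",
         paste(names(envs), collapse = ", "), call. = FALSE)
  if (is.null(wt)) wt <- labeled_landscape(net, rules, cap = cap)
  cs <- envs[[env_name]]
  pl <- if (length(cs$assignments) == 0L) wt else
    labeled_landscape(apply_clamps(net, cs), rules, cap = cap)
  new_perturbation_result(cs, pl, wt, reference = "wild-type")
}

#' Theoretical genetically modified macrophages
#'
#' `build_tgem()` clamps NFKB on and HIF1A off; `build_stgem()` clamps STAT1
#' on and HIF1A off. Both enumerate and label the constrained landscape and
#' compare it to the wild-type.
#'
#' @param net A `BooleanNetwork` containing NFKB, STAT1 and HIF1A.
#' @param rules Phenotype rules.
#' @param wt Optional precomputed labeled wild-type `Landscape`.
#' @param cap Free-node cap.
#' @return A `PerturbationResult`.
#' @export
build_tgem <- function(net, rules = default_phenotype_rules(), wt = NULL,
                       cap = 30L) {
  build_gem(net, c(NFKB = 1L, HIF1A = 0L), "TGEM", rules, wt, cap)
}

#' @rdname build_tgem
#' @export
build_stgem <- function(net, rules = default_phenotype_rules(), wt = NULL,
                        cap = 30L) {
  build_gem(net, c(STAT1 = 1L, HIF1A = 0L), "STGEM", rules, wt, cap)
}

#' @noRd
build_gem <- function(net, assignments, label, rules, wt, cap) {
  missing_nodes <- setdiff(names(assignments), net$node_names)
  if (length(missing_nodes))
    stop("network lacks node(s): ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  if (is.null(wt)) wt <- labeled_landscape(net, rules, cap = cap)
  cs <- clamp_set(assignments, label)
  pl <- labeled_landscape(apply_clamps(net, cs), rules, cap = cap)
  new_perturbation_result(cs, pl, wt, reference = "wild-type")
}

#' Breast cancer microenvironment scenarios for a TGEM
#'
#' Layers four simplified breast cancer milieus on top of an already
#' TGEM-clamped network, each activating two extracellular components:
#' IGG & A2A, IL10 & TGFB, IL1B & IL6, and HYPOXIA & GCGCR. A scenario clamp
#' conflicting with an existing clamp is an error.
#'
#' @param tgem_net The TGEM-clamped `BooleanNetwork` (e.g.
#'   `apply_clamps(net, c(NFKB = 1, HIF1A = 0))`).
#' @param rules Phenotype rules.
#' @param reference Optional labeled `Landscape` used as fold-change
#'   reference (default: the TGEM landscape itself).
#' @param cap Free-node cap.
#' @return Named list of four `PerturbationResult`s.
#' @export
breast_cancer_scenarios <- function(tgem_net,
                                    rules = default_phenotype_rules(),
                                    reference = NULL, cap = 30L) {
  required <- c(NFKB = 1L, HIF1A = 0L)
  have <- tgem_net$clamps[names(required)]
  if (any(is.na(have)) || !all(have == required))
    stop("expected a network with the TGEM clamps NFKB=1, HIF1A=0", call. = FALSE)
  scen <- list(
    "IgG+A2a" = c(IGG = 1L, A2A = 1L),
    "IL10+TGFb" = c(IL10 = 1L, TGFB = 1L),
    "IL1b+IL6" = c(IL1B = 1L, IL6 = 1L),
    "Hypoxia+GC" = c(HYPOXIA = 1L, GCGCR = 1L))
  if (is.null(reference))
    reference <- labeled_landscape(tgem_net, rules, cap = cap)
  out <- lapply(names(scen), function(nm) {
    cs <- clamp_set(scen[[nm]], nm)
    pl <- labeled_landscape(apply_clamps(tgem_net, cs), rules, cap = cap)
    new_perturbation_result(cs, pl, reference, reference = "TGEM")
  })
  stats::setNames(out, names(scen))
}
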