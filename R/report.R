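# End-to-end reproduction workflow: configuration, staged execution, table
# exports, and a summary with headline counts and provenance.

#' Read a run configuration
#'
#' The configuration is a single JSON file (keys below); every omitted key
#' takes its default from [default_run_config()].
#'
#' @param path Path to a JSON config, or `NULL` for pure defaults.
#' @return A named list (class `RunConfig`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  if (is.null(cfg$seed)) stop("a seed is mandatory (stochastic stages)", call. = FALSE)
  structure(cfg, class = c("RunConfig", "list"))
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    model_path = NULL,          # NULL = bundled macrophage model
    seed = 1L,
    output_dir = "macboolnet_run",
    stages = c("landscape", "census", "cluster", "scan", "microenv",
               "tgem", "scenarios", "fatemap", "robustness"),
    k_range = c(10L, 30L),
    n_pairs = 10000L,
    n_samples = 50000L,
    scan_nodes = NULL,          # NULL = all nodes
    extra_clamps = NULL,        # named 0/1 list: restrict the state space
    max_fate_attractors = 5000L,
    cap = 30L)
}

#' Run the full analysis workflow
#'
#' Executes, in order: exhaustive wild-type landscape; phenotype census;
#' 2D embedding + clustering; knockout and overexpression scans;
#' microenvironment simulations; TGEM and STGEM; breast cancer scenarios on
#' the TGEM; cell-fate maps (wild-type restricted landscape and TGEM); and
#' Derrida + sensitivity robustness analysis. All tables are written under
#' `config$output_dir`, and a `summary.json` records headline counts, the
#' model checksum, the seed, and the parameter block of every stage.
#'
#' The unrestricted workflow on the bundled 29-node model enumerates 2^29
#' states for the wild-type and 2^28 per scanned node; expect on the order
#' of an hour of CPU for everything. `config$extra_clamps` (e.g. clamping a
#' few extracellular inputs to 0) shrinks the space for quicker, partial
#' runs and is recorded in the provenance block.
#'
#' @param config A `RunConfig` from [read_run_config()], or `NULL`.
#' @return Invisibly, the summary list.
#' @export
run_full_reproduction <- function(config = NULL) {
  cfg <- if (is.null(config)) read_run_config(NULL) else config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  net <- if (is.null(cfg$model_path)) load_macrophage_model() else
    read_rules(cfg$model_path)
  model_file <- if (is.null(cfg$model_path))
    system.file("extdata", "models", "macrophage_tme_synthetic.txt",
                package = "macboolnet") else cfg$model_path
  checksum <- as.character(tools::md5sum(model_file))
  if (!is.null(cfg$extra_clamps))
    net <- apply_clamps(net, clamp_set(unlist(cfg$extra_clamps), "restriction"))
  rules <- default_phenotype_rules()
  summary <- list(model = basename(model_file), md5 = checksum,
                  seed = cfg$seed, free_nodes = length(free_nodes(net)),
                  config = cfg[setdiff(names(cfg), "stages")])
  out <- function(...) file.path(cfg$output_dir, paste0(...))
  stage <- function(s) s %in% cfg$stages
  partial_manifest <- function(err, done) {
    jsonlite::write_json(list(error = conditionMessage(err), stages_done = done),
                         out("partial_manifest.json"), auto_unbox = TRUE)
    stop(err)
  }
  done <- character(0)
  wt <- NULL
  tryCatch({
    if (stage("landscape")) {
      wt <- labeled_landscape(net, rules, cap = cfg$cap)
      periods <- vapply(wt$attractors, function(a) a$period, integer(1))
      labels <- vapply(wt$attractors, function(a) a$label, character(1))
      summary$wt <- list(
        attractors = length(wt$attractors),
        cyclic = sum(periods > 1L),
        simple_labels = length(unique(labels[periods == 1L])),
        total_states = wt$total_states)
      export_landscape(wt, out("wt_landscape.tsv"))
      done <- c(done, "landscape")
    }
    if (stage("census") && !is.null(wt)) {
      census <- phenotype_census(wt, rules)
      utils::write.table(census, out("wt_census.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$census_labels <- nrow(census)
      done <- c(done, "census")
    }
    if (stage("cluster") && !is.null(wt)) {
      ca <- embed_and_cluster(wt, k_range = seq(cfg$k_range[[1]],
                                                cfg$k_range[[2]]),
                              seed = cfg$seed, rules = rules)
      utils::write.table(ca$points, out("wt_clusters.csv"), sep = ",",
                         quote = TRUE, row.names = FALSE)
      summary$cluster <- list(k = ca$k, method = ca$method,
                              votes = as.list(ca$votes))
      done <- c(done, "cluster")
    }
    if (stage("scan")) {
      for (mode in c("knockout", "overexpress")) {
        res <- single_node_scan(net, mode, nodes = cfg$scan_nodes,
                                rules = rules, wt = wt, cap = cfg$cap)
        utils::write.table(foldchange_table(res),
                           out("scan_", mode, ".tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      done <- c(done, "scan")
    }
    if (stage("microenv")) {
      for (env in names(microenvironments())) {
        r <- microenvironment_landscape(net, env, rules, wt = wt,
                                        cap = cfg$cap)
        utils::write.table(cbind(environment = env, r$foldchange),
                           out("microenv_", gsub("[^A-Za-z0-9]", "_", env),
                               ".tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      done <- c(done, "microenv")
    }
    tgem <- NULL
    if (stage("tgem")) {
      tgem <- build_tgem(net, rules, wt = wt, cap = cfg$cap)
      stgem <- build_stgem(net, rules, wt = wt, cap = cfg$cap)
      summary$tgem <- list(attractors = length(tgem$landscape$attractors),
                           labels = sort(unique(vapply(tgem$landscape$attractors,
                                                       function(a) a$label,
                                                       character(1)))))
      summary$stgem <- list(attractors = length(stgem$landscape$attractors),
                            labels = sort(unique(vapply(stgem$landscape$attractors,
                                                        function(a) a$label,
                                                        character(1)))))
      utils::write.table(tgem$foldchange, out("tgem_foldchange.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(stgem$foldchange, out("stgem_foldchange.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      done <- c(done, "tgem")
    }
    if (stage("scenarios")) {
      tnet <- apply_clamps(net, clamp_set(c(NFKB = 1L, HIF1A = 0L), "TGEM"))
      scen <- breast_cancer_scenarios(tnet, rules, cap = cfg$cap)
      utils::write.table(foldchange_table(scen), out("scenarios.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$scenarios <- lapply(scen, function(r)
        sort(unique(vapply(r$landscape$attractors, function(a) a$label,
                           character(1)))))
      done <- c(done, "scenarios")
    }
    if (stage("fatemap")) {
      maps <- list()
      if (!is.null(wt) &&
          length(wt$attractors) <= cfg$max_fate_attractors)
        maps$wt <- fate_graph(wt, rules,
                              max_attractors = cfg$max_fate_attractors)
      tnet <- apply_clamps(net, clamp_set(c(NFKB = 1L, HIF1A = 0L), "TGEM"))
      maps$tgem <- fate_graph(labeled_landscape(tnet, rules, cap = cfg$cap),
                              rules,
                              max_attractors = cfg$max_fate_attractors)
      for (nm in names(maps)) {
        utils::write.table(maps[[nm]], out("fatemap_", nm, ".tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        fate_graph_dot(maps[[nm]], out("fatemap_", nm, ".dot"))
      }
      done <- c(done, "fatemap")
    }
    if (stage("robustness")) {
      dc <- derrida_curve(net, n_pairs = cfg$n_pairs, seed = cfg$seed)
      reg <- classify_regime(dc)
      sp <- network_sensitivity(net, n_samples = cfg$n_samples,
                                seed = cfg$seed)
      utils::write.table(dc$points, out("derrida_curve.csv"), sep = ",",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(node = names(sp$per_node), sensitivity = sp$per_node),
        out("sensitivity.csv"), sep = ",", quote = FALSE, row.names = FALSE)
      summary$robustness <- list(regime = reg$regime, p_value = reg$p_value,
                                 derrida_slope = derrida_slope(dc),
                                 network_mean_sensitivity = sp$network_mean,
                                 expected_spread = sp$expected_spread)
      done <- c(done, "robustness")
    }
  }, error = function(e) partial_manifest(e, done))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
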