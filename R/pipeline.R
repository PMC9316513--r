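#' Analysis configuration
#'
#' Validated settings for [run_pipeline()]. Exactly one input source must
#' be given: a cohort CSV path (with its metadata sidecar) or a synthetic
#' cohort specification. A seed is mandatory because synthetic generation
#' and both bootstraps are stochastic.
#'
#' @param input Path to a cohort CSV written by [write_cohort_csv()], or
#'   `NULL` to simulate.
#' @param synthetic List of arguments for [simulate_cohort()] (e.g.
#'   `list(n = 146)`); defaults applied for omitted entries.
#' @param seed Integer seed (required).
#' @param mode Correlation mode: `"mixed"` or `"pearson"`.
#' @param gamma,grid_size,min_ratio EBIC-glasso settings.
#' @param stability Run the bootstrap stages.
#' @param B_edges Edge-bootstrap replicates.
#' @param B_drop Case-dropping replicates per proportion.
#' @param proportions Case-dropping proportion grid.
#' @param cor_threshold,confidence CS-coefficient settings.
#' @param out_dir Output directory for file artifacts, or `NULL` to skip
#'   writing files.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, synthetic = list(), seed = NULL,
                            mode = c("mixed", "pearson"),
                            gamma = 0.5, grid_size = 100, min_ratio = 0.01,
                            stability = FALSE, B_edges = 1000, B_drop = 250,
                            proportions = seq(0.05, 0.75, by = 0.05),
                            cor_threshold = 0.7, confidence = 0.95,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("analysis_config: a single integer `seed` is required")
  }
  if (!is.null(input) && length(synthetic) > 0) {
    stop("analysis_config: give either `input` or `synthetic`, not both")
  }
  stopifnot(gamma >= 0, grid_size >= 2, min_ratio > 0, min_ratio < 1,
            B_edges >= 1, B_drop >= 1, all(proportions >= 0),
            all(proportions < 1), cor_threshold > 0, cor_threshold <= 1,
            confidence > 0, confidence <= 1)
  structure(
    list(input = input, synthetic = synthetic, seed = as.integer(seed),
         mode = mode, gamma = gamma, grid_size = grid_size,
         min_ratio = min_ratio, stability = stability, B_edges = B_edges,
         B_drop = B_drop, proportions = proportions,
         cor_threshold = cor_threshold, confidence = confidence,
         out_dir = out_dir),
    class = "analysis_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-analysis pipeline
#'
#' Orchestrates cohort acquisition (file or synthetic), complete-case
#' filtering, the mixed correlation matrix, EBIC-glasso network selection,
#' centrality indices, and (optionally) the edge-weight and case-dropping
#' bootstraps with the CS coefficient. All stochastic stages derive their
#' seeds from the config seed, so identical configs give identical
#' reports. When `out_dir` is set, writes the network (GraphML + labeled
#' adjacency CSV), the centrality table (CSV), the stability report
#' (JSON), and the full analysis report (JSON).
#'
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report`: `dropped`, `n`,
#'   `selected_lambda`, `edges` (edge list data frame), `centrality`,
#'   `top_nodes` (highest-ranked node per index), `stability` (or `NULL`),
#'   `provenance` (effective settings, seed, package version, config
#'   hash), plus the underlying `network` object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- stage("input", {
    if (!is.null(config$input)) {
      read_cohort_csv(config$input)
    } else {
      args <- config$synthetic
      args$seed <- config$seed
      do.call(simulate_cohort, args)
    }
  })
  filtered <- stage("complete_case_filter", complete_case_filter(cohort))
  S <- stage("mixed_matrix", mixed_matrix(filtered$table, mode = config$mode))
  sel <- stage("select_network",
               select_network(S, gamma = config$gamma,
                              grid_size = config$grid_size,
                              min_ratio = config$min_ratio))
  net <- sel$network
  cent <- stage("centrality", centrality_table(net))
  top_nodes <- list(
    strength = cent$node[which.max(cent$strength)],
    closeness = cent$node[which.max(cent$closeness)],
    betweenness = cent$node[which.max(cent$betweenness)]
  )
  stab <- NULL
  if (isTRUE(config$stability)) {
    eb <- stage("bootstrap_edges",
                bootstrap_edges(filtered$table, B = config$B_edges,
                                seed = config$seed + 1L, mode = config$mode,
                                gamma = config$gamma,
                                grid_size = config$grid_size,
                                min_ratio = config$min_ratio))
    cd <- stage("case_dropping",
                case_dropping(filtered$table,
                              proportions = config$proportions,
                              B = config$B_drop, seed = config$seed + 2L,
                              mode = config$mode, gamma = config$gamma,
                              grid_size = config$grid_size,
                              min_ratio = config$min_ratio))
    cs <- cs_coefficient(cd, cor_threshold = config$cor_threshold,
                         confidence = config$confidence)
    stab <- stability_report(eb, cd, cs)
  }
  provenance <- list(
    seed = config$seed, mode = config$mode, gamma = config$gamma,
    grid_size = config$grid_size, min_ratio = config$min_ratio,
    stability = config$stability, B_edges = config$B_edges,
    B_drop = config$B_drop, proportions = config$proportions,
    cor_threshold = config$cor_threshold, confidence = config$confidence,
    input = config$input %||% "synthetic",
    synthetic = config$synthetic,
    package_version = as.character(utils::packageVersion("painnet")),
    config_hash = config_hash(config)
  )
  report <- structure(
    list(dropped = filtered$dropped, n = nrow(filtered$table),
         selected_lambda = net$lambda, ebic = net$ebic,
         edges = as_edge_list(net), centrality = as.data.frame(cent),
         top_nodes = top_nodes, stability = stab, provenance = provenance,
         network = net),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) write_report_files(report, config$out_dir)
  report
}

# Deterministic fingerprint of the scientific settings (the output
# directory is excluded: where artifacts land must not change the
# analysis identity): serialize canonically and hash with a rolling hash.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_network_graphml(report$network, file.path(out_dir, "network.graphml"))
  write_network_csv(report$network, file.path(out_dir, "network_adjacency.csv"))
  write.csv(report$centrality, file.path(out_dir, "centrality.csv"),
            row.names = FALSE)
  if (!is.null(report$stability)) {
    write_stability_json(report$stability, file.path(out_dir, "stability.json"))
  }
  write_report_json(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Serialize an analysis report as JSON
#'
#' The JSON contains no timestamps, so identical configs (and seeds)
#' produce byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$network <- NULL          # matrices live in the CSV/GraphML exports
  if (!is.null(out$stability)) out$stability <- unclass(out$stability)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d (%d dropped), lambda = %s, %d edges\n",
              x$n, x$dropped, signif(x$selected_lambda, 4), nrow(x$edges)))
  cat(sprintf("  top nodes - strength: %s, closeness: %s, betweenness: %s\n",
              x$top_nodes$strength, x$top_nodes$closeness,
              x$top_nodes$betweenness))
  if (!is.null(x$stability) && !is.null(x$stability$cs)) {
    cat(sprintf("  CS(0.7) - strength %g, closeness %g, betweenness %g\n",
                x$stability$cs$strength, x$stability$cs$closeness,
                x$stability$cs$betweenness))
  }
  invisible(x)
}

#' Simulate a cohort and write it straight to CSV
#'
#' Convenience wrapper chaining [simulate_cohort()] and
#' [write_cohort_csv()]; deterministic under the seed.
#'
#' @param path Output CSV path (metadata sidecar written alongside).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()].
#' @return `path`, invisibly.
#' @export
simulate_cohort_csv <- function(path, seed, ...) {
  tab <- simulate_cohort(seed = seed, ...)
  write_cohort_csv(tab, path)
}
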