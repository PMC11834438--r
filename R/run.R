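# Workflow entry points mirrored by the command-line script in
# inst/cli/codetect.R. Each writes its outputs plus a JSON log of the
# parameters and seed, so every run is reproducible from its log.

write_run_log <- function(out_dir, command, params) {
  path <- file.path(out_dir, paste0(command, "-params.json"))
  jsonlite::write_json(c(list(command = command), params), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  path
}

#' Build one network and write its artifacts
#'
#' Writes an edge-list TSV, a GraphML file, a centrality report and a
#' parameter log into `out_dir`.
#'
#' @param input Path to an abundance table (TSV/CSV) or an abundance tibble.
#' @param out_dir Output directory (created if missing).
#' @param method `"pbcdm"`, `"pearson"`, `"spearman"` or `"sparcc"`.
#' @param min_prev,k_sd,alpha,detection_threshold Model parameters; defaults
#'   mirror the co-detection workflow (10% prevalence filter, 1-SD band,
#'   p < 0.05 retention).
#' @param seed Seed for the stochastic SparCC builder.
#' @param method_params Extra arguments for the SparCC builder.
#' @return The built `coexist_network`, invisibly.
#' @export
run_network <- function(input, out_dir, method = "pbcdm", min_prev = 0.10,
                        k_sd = 1, alpha = 0.05, detection_threshold = 0,
                        seed = NULL, method_params = list()) {
  table <- if (is.character(input)) read_abundance_table(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (method == "sparcc") method_params$seed <- method_params$seed %||% seed
  net <- build_network(table, method, min_prev, k_sd, alpha,
                       detection_threshold, method_params)
  write_edge_list(net, file.path(out_dir, paste0(method, "-edges.tsv")))
  write_graphml(net, file.path(out_dir, paste0(method, "-network.graphml")))
  write_centrality_report(net, file.path(out_dir, paste0(method, "-centrality.tsv")))
  write_run_log(out_dir, "network", list(
    input = if (is.character(input)) input else "in-memory table",
    method = method, min_prev = min_prev, k_sd = k_sd, alpha = alpha,
    detection_threshold = detection_threshold, seed = seed
  ))
  invisible(net)
}

#' Shear a network and write the trajectory and core network
#'
#' Builds the network in-line (default method `"pbcdm"`), runs the full
#' shearing trajectory, selects the stop step under `stop_rule`, and writes
#' the trajectory TSV, core edge list, core GraphML and a parameter log.
#'
#' @inheritParams run_network
#' @param stop_rule Stop rule passed to [select_stop_step()].
#' @return Invisibly, a list with `trajectory`, `stop_step` and `core`.
#' @export
run_shear <- function(input, out_dir, method = "pbcdm",
                      stop_rule = "normalized-product", min_prev = 0.10,
                      k_sd = 1, alpha = 0.05, detection_threshold = 0,
                      seed = NULL, method_params = list()) {
  table <- if (is.character(input)) read_abundance_table(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (method == "sparcc") method_params$seed <- method_params$seed %||% seed
  net <- build_network(table, method, min_prev, k_sd, alpha,
                       detection_threshold, method_params)
  traj <- shear_trajectory(net)
  stop_step <- select_stop_step(traj, stop_rule)
  core <- core_network(traj, stop_step)
  write_trajectory(traj, file.path(out_dir, "shear-trajectory.tsv"), stop_step)
  write_edge_list(core, file.path(out_dir, "core-edges.tsv"))
  write_graphml(core, file.path(out_dir, "core-network.graphml"))
  write_run_log(out_dir, "shear", list(
    input = if (is.character(input)) input else "in-memory table",
    method = method, stop_rule = stop_rule, stop_step = as.integer(stop_step),
    min_prev = min_prev, k_sd = k_sd, alpha = alpha, seed = seed
  ))
  invisible(list(trajectory = traj, stop_step = stop_step, core = core))
}

#' Run the sample-size stability workflow and write its reports
#'
#' For each requested method, subsamples the pool across the size grid,
#' records the three network attributes per replicate, and writes a
#' long-format report, a minimum-stable-size summary (method x attribute;
#' NA when no size stabilises), a normality screen and a parameter log.
#'
#' @inheritParams run_network
#' @inheritParams attribute_trajectories
#' @param methods Character vector of methods to benchmark.
#' @return Invisibly, a list with `report` (long tibble over all methods)
#'   and `summary`.
#' @export
run_stability <- function(input, out_dir, methods = c("pbcdm", "pearson", "spearman"),
                          sizes = default_size_grid, max_iter = 20, seed = 1L,
                          min_prev = 0.10, k_sd = 1, alpha = 0.05,
                          detection_threshold = 0, method_params = list()) {
  if (!length(sizes)) abort("Empty size grid.")
  table <- if (is.character(input)) read_abundance_table(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- purrr::map(methods, function(m) {
    suppressWarnings(attribute_trajectories(
      table, method = m, sizes = sizes, max_iter = max_iter, seed = seed,
      min_prev = min_prev, k_sd = k_sd, alpha = alpha,
      detection_threshold = detection_threshold, method_params = method_params
    ))
  })
  long <- dplyr::bind_rows(purrr::map(reports, tibble::as_tibble))
  summary <- dplyr::bind_rows(purrr::map(reports, glance))
  screen <- dplyr::bind_rows(purrr::map2(reports, methods, function(r, m) {
    dplyr::mutate(normality_screen(r), method = m, .before = 1L)
  }))
  readr::write_tsv(long, file.path(out_dir, "stability-report.tsv"))
  readr::write_tsv(summary, file.path(out_dir, "stability-summary.tsv"))
  readr::write_tsv(screen, file.path(out_dir, "normality-screen.tsv"))
  write_run_log(out_dir, "stability", list(
    input = if (is.character(input)) input else "in-memory table",
    methods = methods, sizes = sizes, max_iter = max_iter, seed = seed,
    min_prev = min_prev, k_sd = k_sd, alpha = alpha
  ))
  invisible(list(report = long, summary = summary, normality = screen))
}
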