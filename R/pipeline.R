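# End-to-end orchestration and report writing: census, pair rates,
# aggregate rates, pathways, with a resolved-config snapshot for
# auditability.

.fmt6 <- function(d) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) signif(x, 6))
  d
}

#' Write a data frame report as CSV
#'
#' Floats are serialized with 6 significant digits; an empty result yields a
#' header-only file.
#'
#' @param d Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(d, path) {
  utils::write.csv(.fmt6(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a census report (CSV + JSON with ratios)
#'
#' @param census A `pigment_census` or named list of them.
#' @param path_csv CSV path (columns: selection, class, count).
#' @param path_json JSON path (counts and ratios per selection).
#' @return Invisibly, the CSV path.
#' @export
write_census_report <- function(census, path_csv, path_json = NULL) {
  if (inherits(census, "pigment_census")) census <- list(census)
  rows <- do.call(rbind, lapply(census, function(cn)
    data.frame(selection = cn$selection, class = names(cn$counts),
               count = unname(cn$counts), stringsAsFactors = FALSE)))
  utils::write.csv(rows, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_json)) {
    payload <- lapply(census, function(cn)
      list(counts = as.list(cn$counts),
           ratios = list(chl_a_c = cn$ratios$chl_a_c,
                         chl_car = cn$ratios$chl_car)))
    names(payload) <- vapply(census, `[[`, "", "selection")
    jsonlite::write_json(list(schema = "excitonet-census/1",
                              census = payload),
                         path_json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path_csv)
}

#' Run the EET analysis pipeline
#'
#' Runs the requested stages in dependency order (a missing dependency stage
#' is auto-included with a message): `census`; `pair_rates` (charges
#' assigned, full inter-pigment rate matrix, binned edge table);
#' `aggregate_rates` (generalized Forster rates between assigned
#' aggregates); `pathways` (ranked aggregate routes into `sink`).
#' When `out_dir` is given, reports are written (census CSV/JSON, rate
#' CSVs, network edge CSV and GraphML, pathway JSON, resolved-config
#' snapshot).
#'
#' @param cx A `pigment_complex` or a structure file path.
#' @param config [eet_config()].
#' @param stages Subset of `c("census", "pair_rates", "aggregate_rates",
#'   "pathways")`.
#' @param aggregate_mapping Chain -> aggregate mapping for
#'   [assign_aggregates()] (required for aggregate stages unless already
#'   assigned).
#' @param layer_axis Membrane normal for [assign_layers()], or `NULL` to
#'   keep existing layers.
#' @param sink Aggregate id(s) treated as the EET sink for the pathway
#'   stage (default `"CORE"`).
#' @param n_paths Paths reported per source aggregate.
#' @param out_dir Output directory (created), or `NULL` for no files.
#' @return A `eet_report` bundle with the computed stages, invisibly
#'   when `out_dir` is set.
#' @export
run_pipeline <- function(cx, config = eet_config(),
                         stages = c("census", "pair_rates",
                                    "aggregate_rates", "pathways"),
                         aggregate_mapping = NULL, layer_axis = c(0, 0, 1),
                         sink = "CORE", n_paths = 3, out_dir = NULL) {
  stages <- match.arg(stages, c("census", "pair_rates", "aggregate_rates",
                                "pathways"), several.ok = TRUE)
  if ("pathways" %in% stages && !"aggregate_rates" %in% stages) {
    message("stage 'pathways' requires 'aggregate_rates'; auto-included")
    stages <- c(stages, "aggregate_rates")
  }
  if (is.character(cx)) cx <- load_structure(cx)
  stopifnot(inherits(cx, "pigment_complex"))
  if (!is.null(aggregate_mapping))
    cx <- assign_aggregates(cx, aggregate_mapping)
  if (!is.null(layer_axis) && length(chlorins(cx)))
    cx <- assign_layers(cx, axis = layer_axis)
  bundle <- list(config = resolved_config(config))

  if ("census" %in% stages) {
    bundle$census <- pigment_census(cx)
    if (length(cx$aggregates))
      bundle$census_by_aggregate <- lapply(
        stats::setNames(nm = names(cx$aggregates)), function(a)
          pigment_census(cx, selection = function(p)
            identical(p$aggregate, a), label = a))
  }
  needs_rates <- any(c("pair_rates", "aggregate_rates") %in% stages)
  if (needs_rates) cx <- charge_pigments(cx, config$charge_lib,
                                         config$include_pheo)
  if ("pair_rates" %in% stages) {
    bundle$pair_rates <- all_pair_rates(cx, config)
    bundle$pair_table <- rate_table(bundle$pair_rates)
    bundle$binned <- bin_time_constants(bundle$pair_rates)
    bundle$network <- build_graph(bundle$pair_rates, config$tau_cutoff)
  }
  if ("aggregate_rates" %in% stages) {
    bundle$aggregate_rates <- all_aggregate_rates(cx, config)
    bundle$aggregate_network <- build_graph(bundle$aggregate_rates,
                                            config$tau_cutoff)
  }
  if ("pathways" %in% stages) {
    net <- bundle$aggregate_network
    sinks <- intersect(sink, igraph::V(net$graph)$name)
    sources <- setdiff(igraph::V(net$graph)$name, sinks)
    bundle$pathways <- lapply(stats::setNames(nm = sources), function(s)
      best_pathways(net, s, sinks, n_paths = n_paths))
  }
  bundle$complex <- cx
  class(bundle) <- "eet_report"
  if (!is.null(out_dir)) {
    write_report(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write an analysis report bundle to disk
#'
#' @param bundle An `eet_report` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "eet_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(f) written[length(written) + 1L] <<- f
  jsonlite::write_json(list(schema = "excitonet-config/1",
                            config = bundle$config),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  emit(file.path(out_dir, "resolved_config.json"))
  if (!is.null(bundle$census)) {
    all_census <- c(list(bundle$census), bundle$census_by_aggregate)
    write_census_report(all_census, file.path(out_dir, "census.csv"),
                        file.path(out_dir, "census.json"))
    emit(file.path(out_dir, "census.csv"))
    emit(file.path(out_dir, "census.json"))
  }
  if (!is.null(bundle$pair_table)) {
    write_report_csv(bundle$pair_table,
                     file.path(out_dir, "pair_rates.csv"))
    emit(file.path(out_dir, "pair_rates.csv"))
  }
  if (!is.null(bundle$network)) {
    write_report_csv(network_edges(bundle$network),
                     file.path(out_dir, "network_edges.csv"))
    emit(file.path(out_dir, "network_edges.csv"))
    igraph::write_graph(bundle$network$graph,
                        file.path(out_dir, "network.graphml"),
                        format = "graphml")
    emit(file.path(out_dir, "network.graphml"))
  }
  if (!is.null(bundle$aggregate_rates)) {
    write_report_csv(bundle$aggregate_rates$table,
                     file.path(out_dir, "aggregate_rates.csv"))
    emit(file.path(out_dir, "aggregate_rates.csv"))
  }
  if (!is.null(bundle$pathways)) {
    payload <- lapply(bundle$pathways, function(paths)
      lapply(paths, function(p)
        list(nodes = p$nodes, total_tau_ps = signif(p$total_tau, 6),
             bottleneck_tau_ps = signif(p$bottleneck_tau, 6))))
    jsonlite::write_json(list(schema = "excitonet-pathways/1",
                              pathways = payload),
                         file.path(out_dir, "pathways.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(file.path(out_dir, "pathways.json"))
  }
  invisible(written)
}
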