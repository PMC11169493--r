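# Directed EET networks: graph construction, dominant pathways,
# layer-resolved maps, symmetry diagnostics.

#' Build a directed EET network
#'
#' Turns a pigment-level rate matrix or an aggregate rate table into a
#' directed graph whose edges carry rate `k` (ps^-1), time constant `tau`
#' (ps) and bin label. Edges with `tau >= tau_cutoff` are omitted.
#'
#' @param x A `rate_matrix`, or the result (or `table`) of
#'   [all_aggregate_rates()].
#' @param tau_cutoff Edge cutoff, ps (default 20; `Inf` keeps all nonzero
#'   rates).
#' @return A `rate_network` wrapping an igraph object (`$graph`).
#' @examples
#' cx <- charge_pigments(make_dimer(separation = 12))
#' net <- build_graph(all_pair_rates(cx))
#' network_edges(net)
#' @export
build_graph <- function(x, tau_cutoff = 20) {
  if (inherits(x, "rate_matrix")) {
    idx <- which(!is.na(x$k) & x$k > 0, arr.ind = TRUE)
    edges <- data.frame(from = x$ids[idx[, 1]], to = x$ids[idx[, 2]],
                        k = x$k[idx], tau = x$tau[idx],
                        stringsAsFactors = FALSE)
    nodes <- data.frame(name = x$ids, layer = unname(x$layer),
                        subunit = unname(x$subunit),
                        aggregate = unname(x$aggregate),
                        stringsAsFactors = FALSE)
  } else {
    tab <- if (is.data.frame(x)) x else x$table
    edges <- data.frame(from = tab$donor_agg, to = tab$acceptor_agg,
                        k = tab$k_per_ps, tau = tab$tau_ps,
                        stringsAsFactors = FALSE)
    edges <- edges[is.finite(edges$tau) & edges$k > 0, , drop = FALSE]
    nodes <- data.frame(name = unique(c(tab$donor_agg, tab$acceptor_agg)),
                        layer = "unassigned", subunit = NA_character_,
                        aggregate = NA_character_, stringsAsFactors = FALSE)
  }
  edges <- edges[edges$tau < tau_cutoff, , drop = FALSE]
  edges$bin <- .bin_tau(edges$tau)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, tau_cutoff = tau_cutoff),
            class = "rate_network")
}

#' Edge list of a rate network
#' @param net A `rate_network`.
#' @return Data frame with `from`, `to`, `k`, `tau`, `bin`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "rate_network"))
  igraph::as_data_frame(net$graph, what = "edges")
}

#' @export
print.rate_network <- function(x, ...) {
  cat("EET network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (tau <", x$tau_cutoff, "ps)\n")
  invisible(x)
}

#' Rank EET pathways from a source to a sink set
#'
#' Enumerates simple directed paths (up to `max_hops` edges) from `source`
#' to any node of `sinks` and ranks them by total time constant (sum of edge
#' tau; `cost = "bottleneck"` ranks by the slowest edge instead). Paths tying
#' within 1e-9 relative are ordered lexicographically by their node ids for
#' determinism.
#'
#' @param net A `rate_network`.
#' @param source Source node id (must be in the network).
#' @param sinks Character vector of sink node ids.
#' @param n_paths Number of top paths to return (`Inf` for all).
#' @param max_hops Maximum number of edges per path.
#' @param cost `"sum"` or `"bottleneck"`.
#' @return List of paths, each with `nodes`, `total_tau`, `bottleneck_tau`;
#'   empty when no sink is reachable.
#' @export
best_pathways <- function(net, source, sinks, n_paths = 3, max_hops = 8,
                          cost = c("sum", "bottleneck")) {
  stopifnot(inherits(net, "rate_network"))
  cost <- match.arg(cost)
  g <- net$graph
  vn <- igraph::V(g)$name
  if (!source %in% vn) stop("source node '", source, "' not in network")
  sinks <- intersect(sinks, vn)
  if (!length(sinks)) return(list())
  taus <- igraph::E(g)$tau
  paths <- list()
  for (s in sinks) {
    ps <- igraph::all_simple_paths(g, from = source, to = s,
                                   mode = "out", cutoff = max_hops)
    paths <- c(paths, ps)
  }
  if (!length(paths)) return(list())
  scored <- lapply(paths, function(p) {
    ids <- names(p)
    eid <- igraph::get_edge_ids(g, as.vector(rbind(ids[-length(ids)],
                                                   ids[-1])))
    et <- taus[eid]
    list(nodes = ids,
         total_tau = if (cost == "sum") sum(et) else max(et),
         bottleneck_tau = max(et))
  })
  totals <- vapply(scored, `[[`, 0, "total_tau")
  keys <- vapply(scored, function(s) paste(s$nodes, collapse = " "), "")
  ord <- order(totals, keys)
  scored <- scored[ord]; totals <- totals[ord]; keys <- keys[ord]
  # re-sort lexicographically inside tie groups (1e-9 relative)
  if (length(scored) > 1) {
    grp <- cumsum(c(TRUE, diff(totals) > 1e-9 * pmax(abs(totals[-1]), 1e-300)))
    ord2 <- order(grp, keys)
    scored <- scored[ord2]
  }
  utils::head(scored, n_paths)
}

#' Partition network edges by membrane layer
#'
#' @param net A `rate_network` whose nodes carry layer annotations.
#' @return Named list of edge data frames: `stromal-stromal`,
#'   `lumenal-lumenal`, `inter-layer`, and (with a warning) `unassigned`
#'   for edges touching unannotated nodes.
#' @export
layer_resolved_map <- function(net) {
  stopifnot(inherits(net, "rate_network"))
  e <- igraph::as_data_frame(net$graph, what = "edges")
  v <- igraph::as_data_frame(net$graph, what = "vertices")
  lay <- stats::setNames(v$layer, v$name)
  lf <- lay[e$from]; lt <- lay[e$to]
  part <- ifelse(is.na(lf) | is.na(lt) | lf == "unassigned" |
                   lt == "unassigned", "unassigned",
          ifelse(lf == "stromal" & lt == "stromal", "stromal-stromal",
          ifelse(lf == "lumenal" & lt == "lumenal", "lumenal-lumenal",
                 "inter-layer")))
  if (any(part == "unassigned"))
    warning("edges touching layer-unannotated nodes placed in 'unassigned'")
  out <- split(e, factor(part, levels = c("stromal-stromal",
                                          "lumenal-lumenal", "inter-layer",
                                          "unassigned")))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Symmetry residual of a network under a node permutation
#'
#' Maximum relative time-constant deviation between each edge and its image
#' under the permutation: max over edges of |tau(e) - tau(perm(e))| /
#' tau(e). Exactly symmetric networks (e.g. a C2 supercomplex with its
#' recorded pairing) give 0; a missing image edge gives `Inf`.
#'
#' @param net A `rate_network`.
#' @param permutation Named character vector, node -> image node; must be a
#'   bijection on the network's nodes.
#' @return Maximum relative deviation (0 for exact symmetry).
#' @export
symmetry_residual <- function(net, permutation) {
  stopifnot(inherits(net, "rate_network"))
  g <- net$graph
  vn <- igraph::V(g)$name
  perm <- permutation[vn]
  if (any(is.na(perm)) || anyDuplicated(perm) || !all(perm %in% vn))
    stop("permutation must be a bijection on the network's nodes")
  e <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(e)) return(0)
  img <- igraph::get_edge_ids(g, as.vector(rbind(unname(perm[e$from]),
                                                 unname(perm[e$to]))))
  tau_all <- igraph::E(g)$tau
  tau_img <- rep(Inf, length(img))
  tau_img[img > 0] <- tau_all[img[img > 0]]
  max(abs(e$tau - tau_img) / e$tau)
}
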