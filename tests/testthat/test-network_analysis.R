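# Graph construction, pathway ranking, layer partitions, symmetry.

# hand-built aggregate-style rate table
toy_table <- function(edges) {
  data.frame(donor_agg = edges$from, acceptor_agg = edges$to,
             k_per_ps = 1 / edges$tau, tau_ps = edges$tau,
             stringsAsFactors = FALSE)
}

test_that("graph building honours the time-constant cutoff", {
  cx <- prepared_supercomplex()
  rm_ <- all_pair_rates(cx)
  net_all <- build_graph(rm_, tau_cutoff = Inf)
  expect_equal(igraph::ecount(net_all$graph), sum(rm_$k > 0, na.rm = TRUE))
  net_none <- build_graph(rm_, tau_cutoff = 0)
  expect_equal(igraph::ecount(net_none$graph), 0)
  # three-node chain with tau = 2 and 30 ps: one edge survives default 20
  tab <- toy_table(data.frame(from = c("A", "B"), to = c("B", "C"),
                              tau = c(2, 30)))
  net <- build_graph(tab)
  e <- network_edges(net)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "A")
  # no self-edges, tau = 1/k
  expect_true(all(e$from != e$to))
  expect_equal(e$tau, 1 / e$k)
})

test_that("pathway ranking follows total time and reports ties", {
  # linear chain
  tab <- toy_table(data.frame(from = c("A", "B"), to = c("B", "C"),
                              tau = c(2, 3)))
  p <- best_pathways(build_graph(tab), "A", "C")
  expect_length(p, 1)
  expect_equal(p[[1]]$nodes, c("A", "B", "C"))
  expect_equal(p[[1]]$total_tau, 5)
  # symmetric diamond: two equal-arm paths, deterministic order
  tab2 <- toy_table(data.frame(from = c("A", "A", "B", "C"),
                               to = c("B", "C", "D", "D"),
                               tau = c(2, 2, 3, 3)))
  p2 <- best_pathways(build_graph(tab2), "A", "D", n_paths = 5)
  expect_length(p2, 2)
  expect_equal(p2[[1]]$total_tau, p2[[2]]$total_tau)
  expect_equal(p2[[1]]$nodes, c("A", "B", "D"))   # lexicographic tie-break
  expect_equal(p2[[2]]$nodes, c("A", "C", "D"))
  # unreachable sink and absent source
  expect_length(best_pathways(build_graph(tab), "C", "A"), 0)
  expect_error(best_pathways(build_graph(tab), "Z", "C"), "not in network")
})

test_that("ranking matches exhaustive enumeration on a random 6-node graph", {
  set.seed(17)
  nodes <- LETTERS[1:6]
  edges <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, ]
  edges <- edges[runif(nrow(edges)) < 0.5, ]
  edges$tau <- round(runif(nrow(edges), 0.5, 15), 3)
  net <- build_graph(toy_table(edges), tau_cutoff = Inf)
  got <- best_pathways(net, "A", "F", n_paths = Inf, max_hops = 6)
  ref <- brute_all_paths(edges, "A", "F", max_hops = 6)
  expect_equal(length(got), length(ref))
  ref_totals <- sort(vapply(ref, `[[`, 0, "total_tau"))
  got_totals <- vapply(got, `[[`, 0, "total_tau")
  expect_equal(got_totals, ref_totals, tolerance = 1e-12)
  expect_true(all(diff(got_totals) >= -1e-12))    # non-decreasing in rank
})

test_that("bottleneck cost ranks by slowest edge", {
  tab <- toy_table(data.frame(from = c("A", "B", "A", "C"),
                              to = c("B", "D", "C", "D"),
                              tau = c(1, 10, 5, 6)))
  p <- best_pathways(build_graph(tab), "A", "D", cost = "bottleneck")
  expect_equal(p[[1]]$nodes, c("A", "C", "D"))    # max edge 6 < 10
  expect_equal(p[[1]]$bottleneck_tau, 6)
})

test_that("layer partition conserves edges and flags unassigned nodes", {
  cx <- prepared_supercomplex()
  cx <- assign_layers(cx, c(0, 0, 1), origin = 0)
  net <- build_graph(all_pair_rates(cx), tau_cutoff = Inf)
  parts <- layer_resolved_map(net)
  expect_equal(sum(vapply(parts, nrow, 0L)), igraph::ecount(net$graph))
  expect_equal(nrow(parts$unassigned), 0L)
  # all-stromal network has only stromal-stromal edges
  slab <- assign_layers(charge_pigments(make_slab(4, gap = 20, seed = 2)),
                        c(0, 0, 1), origin = -100)
  pnet <- build_graph(all_pair_rates(slab), tau_cutoff = Inf)
  sparts <- layer_resolved_map(pnet)
  expect_equal(nrow(sparts[["stromal-stromal"]]),
               igraph::ecount(pnet$graph))
  # an unannotated node collects its edges under "unassigned", conserved
  cx2 <- cx
  cx2$pigments[[1]]$layer <- "unassigned"
  net2 <- build_graph(all_pair_rates(cx2), tau_cutoff = Inf)
  expect_warning(parts2 <- layer_resolved_map(net2), "unannotated")
  expect_equal(sum(vapply(parts2, nrow, 0L)), igraph::ecount(net2$graph))
  expect_gt(nrow(parts2$unassigned), 0)
})

test_that("symmetry residual is zero for identity and exact C2, positive when perturbed", {
  cx <- prepared_supercomplex()
  gt <- attr(cx, "ground_truth")
  net <- build_graph(all_pair_rates(cx), tau_cutoff = Inf)
  ids <- igraph::V(net$graph)$name
  expect_equal(symmetry_residual(net, setNames(ids, ids)), 0)
  expect_lt(symmetry_residual(net, gt$pigment_pairing), 1e-9)
  # 0.5 Angstrom coordinate noise breaks the symmetry measurably
  cxj <- prepared_supercomplex(jitter = 0.5, seed = 4)
  gtj <- attr(cxj, "ground_truth")
  netj <- build_graph(all_pair_rates(cxj), tau_cutoff = Inf)
  expect_gt(symmetry_residual(netj, gtj$pigment_pairing), 1e-6)
  expect_error(symmetry_residual(net, setNames(ids, rev(ids))[c(1, 1)]),
               "bijection")
})
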