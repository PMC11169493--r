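# Parsing, pigment classification, census, distances, layers, aggregates.

test_that("a hand-written single-residue PDB yields one classified pigment", {
  lines <- c(
    "HETATM    1 MG   CLA A 301      10.000  20.000  30.000  1.00  0.00          MG",
    "HETATM    2  NA  CLA A 301      12.050  20.000  30.000  1.00  0.00           N",
    "HETATM    3  NB  CLA A 301      10.000  22.050  30.000  1.00  0.00           N",
    "HETATM    4  NC  CLA A 301       7.950  20.000  30.000  1.00  0.00           N",
    "HETATM    5  ND  CLA A 301      10.000  17.950  30.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- load_structure(f)
  expect_equal(n_pigments(cx), 1L)
  p <- cx$pigments[[1]]
  expect_equal(p$class, "CHL_A")
  expect_equal(p$center, c(10, 20, 30))         # Mg position
  expect_equal(sort(p$atoms$name)[1:2], c("MG", "NA"))
  expect_length(cx$aggregates, 0)
})

test_that("unreadable or unknown-format input fails with a clear error", {
  f <- tempfile(fileext = ".pdb")
  writeLines("not a structure at all", f)
  expect_error(load_structure(f))
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
  g <- tempfile(fileext = ".xyz")
  writeLines("x", g)
  expect_error(load_structure(g), "format")
})

test_that("census counts selections, is additive and permutation-invariant", {
  cx <- make_supercomplex()
  cn_all <- pigment_census(cx)
  expect_equal(unname(cn_all$counts[["CHL_A"]]), 20L)  # 2*(2*3 + 4)
  cn_a <- pigment_census(cx, selection = c("A", "B", "C"))
  cn_b <- pigment_census(cx, selection = function(p) !p$chain %in% c("A", "B", "C"))
  expect_equal(cn_a$counts + cn_b$counts, cn_all$counts)
  # permutation invariance
  cx_perm <- cx
  cx_perm$pigments <- rev(cx_perm$pigments)
  expect_equal(pigment_census(cx_perm)$counts, cn_all$counts)
  # empty complex and empty selection
  empty <- pigment_census(make_supercomplex(), selection = "nonexistent") |>
    expect_warning("matched no pigments")
  expect_true(all(empty$counts == 0L))
})

test_that("ratios follow the census and guard zero denominators", {
  r <- compute_ratios(c(CHL_A = 133, CHL_C = 14, CAR_ALX = 48,
                        CAR_CRO = 8, CAR_ACAR = 4))
  expect_equal(r$chl_a_c, 9.5)
  expect_equal(r$chl_car, 2.45)
  r2 <- compute_ratios(c(CHL_A = 1, CHL_C = 1, CAR_ALX = 1))
  expect_equal(r2$chl_a_c, 1)
  expect_equal(r2$chl_car, 2)
  r3 <- compute_ratios(c(CHL_A = 5, CHL_C = 0))
  expect_true(is.na(r3$chl_a_c))
  expect_true(is.na(r3$chl_car))
})

test_that("pigment distances are symmetric and match the brute-force oracle", {
  cx <- make_dimer(separation = 10)
  p <- cx$pigments[[1]]; q <- cx$pigments[[2]]
  expect_equal(pigment_distance(p, p), 0)
  expect_equal(pigment_distance(p, p, "min_atom"), 0)
  expect_equal(pigment_distance(p, q), 10)
  expect_equal(pigment_distance(p, q), pigment_distance(q, p))
  # randomized pair vs exhaustive double loop
  set.seed(42)
  for (rep in 1:5) {
    sc <- make_supercomplex(jitter = 2, seed = rep)
    ids <- sample(names(sc$pigments), 2)
    a <- sc$pigments[[ids[1]]]; b <- sc$pigments[[ids[2]]]
    expect_equal(pigment_distance(a, b, "min_atom"),
                 brute_min_atom_distance(a, b), tolerance = 1e-12)
    expect_lte(pigment_distance(a, b, "min_atom"), pigment_distance(a, b))
  }
})

test_that("round-trip write/load preserves ids, classes and centers", {
  cx <- make_supercomplex()
  for (fmt in c("pdb", "cif")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_structure(cx, f)
    cx2 <- load_structure(f)
    expect_equal(names(cx2$pigments), names(cx$pigments))
    expect_equal(vapply(cx2$pigments, `[[`, "", "class"),
                 vapply(cx$pigments, `[[`, "", "class"))
    dc <- max(vapply(names(cx$pigments), function(i)
      max(abs(cx2$pigments[[i]]$center - cx$pigments[[i]]$center)), 0))
    expect_lt(dc, 1e-3)
  }
})

test_that("layer assignment follows the sign rule and recovers slab labels", {
  sc <- make_slab(n_per_layer = 8, gap = 20, seed = 7)
  gt <- attr(sc, "ground_truth")
  sc <- assign_layers(sc, axis = c(0, 0, 1), origin = 0)
  expect_equal(vapply(sc$pigments, `[[`, "", "layer"), gt$layers)
  # tie: projection exactly at the origin counts as stromal
  cx <- make_dimer(separation = 10)
  cx <- assign_layers(cx, axis = c(0, 0, 1), origin = 0)
  expect_true(all(vapply(cx$pigments, `[[`, "", "layer") == "stromal"))
  expect_error(assign_layers(cx, axis = c(0, 0, 0)), "degenerate")
})

test_that("layer assignment is invariant under a rigid rotation", {
  sc <- make_slab(n_per_layer = 6, gap = 20, seed = 3)
  before <- vapply(assign_layers(sc, c(0, 0, 1), 0)$pigments, `[[`, "",
                   "layer")
  th <- 0.7
  Rm <- matrix(c(1, 0, 0,
                 0, cos(th), sin(th),
                 0, -sin(th), cos(th)), 3, 3)
  sc$pigments <- lapply(sc$pigments, function(p) {
    xyz <- as.matrix(p$atoms[, c("x", "y", "z")]) %*% t(Rm)
    p$atoms$x <- xyz[, 1]; p$atoms$y <- xyz[, 2]; p$atoms$z <- xyz[, 3]
    p$center <- as.numeric(Rm %*% p$center)
    p
  })
  after <- vapply(assign_layers(sc, as.numeric(Rm %*% c(0, 0, 1)),
                                0)$pigments, `[[`, "", "layer")
  expect_equal(after, before)
})

test_that("aggregate assignment partitions pigments and rejects conflicts", {
  cx <- make_supercomplex()
  gt <- attr(cx, "ground_truth")
  cx2 <- assign_aggregates(cx, gt$aggregate_mapping)
  expect_length(cx2$aggregates, 14)  # (6 antennae + core) x 2 monomers
  expect_equal(sort(unlist(cx2$aggregates, use.names = FALSE)),
               sort(names(cx2$pigments)))
  # many chains -> one aggregate
  cx3 <- assign_aggregates(cx, c(A = "ANT", B = "ANT", C = "ANT",
                                 D = "ANT", E = "ANT", F = "ANT",
                                 X = "CORE"))
  expect_equal(length(cx3$aggregates[["ANT"]]), 6L)
  # unmapped chains excluded; empty mapping refuses aggregate rates
  expect_false("unassigned" %in% names(cx3$aggregates))
  cx4 <- cx
  cx4$aggregates <- list()
  expect_error(all_aggregate_rates(cx4), "no aggregates")
  expect_error(assign_aggregates(cx, c(A = "X1", A = "X2")),
               "more than one aggregate")
})
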