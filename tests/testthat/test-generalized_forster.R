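# Exciton systems, thermal weights, exciton couplings, aggregate rates.

test_that("thermal weights normalize and reproduce closed-form splittings", {
  tw <- thermal_weights(14925)
  expect_equal(tw$weights, 1)
  expect_equal(tw$Z, 1)
  tw2 <- thermal_weights(c(500, 500))
  expect_equal(tw2$weights, c(0.5, 0.5))
  # states split by exactly kB*T
  kT <- 0.69504 * 300
  tw3 <- thermal_weights(c(0, kT))
  expect_equal(tw3$weights, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(tw3$weights, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(sum(tw3$weights), 1)
})

test_that("exciton systems diagonalize correctly", {
  cx <- prepared_supercomplex()
  # single-pigment aggregate: one state at the site energy
  s1 <- build_exciton_system(cx, "ACPII-1")
  expect_equal(s1$eigenvalues, 14925)
  expect_equal(as.numeric(s1$coefficients), 1)
  expect_equal(s1$weights, 1)
  # degenerate dimer splits as omega0 +/- v with (1, +/-1)/sqrt(2)
  dim2 <- charge_pigments(make_dimer(separation = 10))
  dim2 <- assign_aggregates(dim2, c(A = "D", B = "D"))
  v <- screened_coupling(dim2$pigments[[1]], dim2$pigments[[2]])$V
  sys <- build_exciton_system(dim2, "D")
  expect_equal(sys$eigenvalues, 14925 + c(-abs(v), abs(v)), tolerance = 1e-9)
  expect_equal(abs(sys$coefficients),
               matrix(1 / sqrt(2), 2, 2, dimnames = dimnames(sys$coefficients)),
               tolerance = 1e-12)
  # orthonormal coefficients, ascending eigenvalues, spectral reconstruction
  core <- build_exciton_system(cx, "CORE")
  C <- core$coefficients
  expect_equal(C %*% t(C), diag(nrow(C)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(core$eigenvalues) >= 0))
  H_rec <- t(C) %*% diag(core$eigenvalues) %*% C
  expect_equal(H_rec, core$H, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(build_exciton_system(cx, "nope"), "not present")
})

test_that("exciton couplings match the explicit double sum", {
  set.seed(5)
  cx <- prepared_supercomplex(pigments_per_site = 2, core_size = 3)
  D <- build_exciton_system(cx, "ACPII-2")
  A <- build_exciton_system(cx, "CORE")
  Vsite <- matrix(runif(length(D$site_ids) * length(A$site_ids), -20, 20),
                  length(D$site_ids), length(A$site_ids))
  Vab <- exciton_coupling(D, A, Vsite)
  for (a in seq_along(D$eigenvalues)) for (b in seq_along(A$eigenvalues)) {
    acc <- 0
    for (m in seq_along(D$site_ids)) for (n in seq_along(A$site_ids))
      acc <- acc + D$coefficients[a, m] * A$coefficients[b, n] * Vsite[m, n]
    expect_equal(Vab[a, b], acc, tolerance = 1e-12)
  }
  # closed form: symmetric dimer state against an equally coupled acceptor
  expect_error(exciton_coupling(D, A, Vsite[, 1, drop = FALSE]), "x")
})

test_that("symmetric donor dimer state couples as sqrt(2) v", {
  # degenerate two-site donor, single acceptor coupled v to both sites
  dimer <- charge_pigments(make_dimer(separation = 10))
  dimer <- assign_aggregates(dimer, c(A = "D", B = "D"))
  sys <- build_exciton_system(dimer, "D")
  v <- 7.3
  Vab <- exciton_coupling(sys,
                          structure(list(site_ids = "s", eigenvalues = 1,
                                         coefficients = matrix(1, 1, 1)),
                                    class = "exciton_system"),
                          matrix(c(v, v), 2, 1))
  expect_equal(sort(abs(as.numeric(Vab))), c(0, sqrt(2) * v),
               tolerance = 1e-9)
})

test_that("1x1 aggregate rates reduce exactly to the pairwise rate", {
  for (sep in c(9, 14, 22)) {
    cx <- charged_dimer(sep)
    cx <- assign_aggregates(cx, c(A = "D", B = "A"))
    D <- build_exciton_system(cx, "D")
    A <- build_exciton_system(cx, "A")
    ar <- aggregate_rate(D, A)
    V <- screened_coupling(cx$pigments[[1]], cx$pigments[[2]])$V
    J <- resolve_overlap("CHL_A", "CHL_A")
    expect_equal(ar$k_DA, pair_rate(V, J), tolerance = 1e-14)
  }
})

test_that("aggregate rates match an independent brute-force implementation", {
  cx <- prepared_supercomplex(pigments_per_site = 2, core_size = 2)
  cfg <- eet_config()
  D <- build_exciton_system(cx, "ACPII-3", cfg)
  A <- build_exciton_system(cx, "ACPII-4", cfg)
  ar <- aggregate_rate(D, A, cfg)
  Vsite <- matrix(0, 2, 2)
  for (m in 1:2) for (n in 1:2)
    Vsite[m, n] <- screened_coupling(D$pigments[[m]], A$pigments[[n]])$V
  sig <- 240 / (2 * sqrt(2 * log(2)))
  k_brute <- brute_generalized_forster(
    omega_D = c(14925, 14925), V_D = D$H[1, 2],
    stokes_D = rep(160, 2), sigma_D = rep(sig, 2),
    omega_A = c(14925, 14925), V_A = A$H[1, 2], sigma_A = rep(sig, 2),
    site_couplings = Vsite)
  expect_equal(ar$k_DA, k_brute, tolerance = 1e-8)
  # bookkeeping invariants
  expect_equal(sum(ar$contributions$partial), ar$k_DA)
  expect_gte(ar$k_DA, 0)
  expect_error(aggregate_rate(D, D), "share pigment")
})

test_that("a common site-energy shift leaves the aggregate rate unchanged", {
  cx <- prepared_supercomplex(pigments_per_site = 2, core_size = 2)
  cfg1 <- eet_config()
  shift <- 500
  sp <- default_spectra()
  sp$CHL_A$omega0 <- sp$CHL_A$omega0 + shift
  cfg2 <- eet_config(spectra = sp)
  k1 <- aggregate_rate(build_exciton_system(cx, "ACPII-1", cfg1),
                       build_exciton_system(cx, "ACPII-2", cfg1), cfg1)$k_DA
  k2 <- aggregate_rate(build_exciton_system(cx, "ACPII-1", cfg2),
                       build_exciton_system(cx, "ACPII-2", cfg2), cfg2)$k_DA
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("aggregate rate is invariant under site reordering", {
  cx <- prepared_supercomplex(pigments_per_site = 2, core_size = 2)
  k1 <- aggregate_rate(build_exciton_system(cx, "ACPII-2"),
                       build_exciton_system(cx, "CORE"))$k_DA
  cx2 <- cx
  ids <- cx2$aggregates[["ACPII-2"]]
  cx2$aggregates[["ACPII-2"]] <- rev(ids)
  k2 <- aggregate_rate(build_exciton_system(cx2, "ACPII-2"),
                       build_exciton_system(cx2, "CORE"))$k_DA
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("weak intra-aggregate coupling recovers weighted pairwise rates", {
  # two stacked donors barely coupled to each other, one distant acceptor:
  # k_DA approaches the Boltzmann-weighted sum of site-level rates
  p1 <- excitonet:::.place_chlorin("A", 1L, "CHL_A", c(0, 0, 0), 0)
  p2 <- excitonet:::.place_chlorin("A", 2L, "CHL_A", c(0, 0, 200), 0)
  p3 <- excitonet:::.place_chlorin("B", 1L, "CHL_A", c(25, 0, 0), 0)
  cx <- excitonet:::new_pigment_complex(list(p1, p2, p3))
  cx <- charge_pigments(cx)
  cx <- assign_aggregates(cx, c(A = "D", B = "A"))
  k_agg <- aggregate_rate(build_exciton_system(cx, "D"),
                          build_exciton_system(cx, "A"))$k_DA
  J <- resolve_overlap("CHL_A", "CHL_A")
  k_pair <- vapply(1:2, function(i)
    pair_rate(screened_coupling(cx$pigments[[i]], cx$pigments[[3]])$V, J), 0)
  expect_equal(k_agg, mean(k_pair), tolerance = 1e-3)
})
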