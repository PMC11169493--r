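# Aggregate-to-aggregate EET rates by generalized Forster theory:
# exciton Hamiltonians, Boltzmann-weighted donor states, exciton couplings.

#' Boltzmann weights over exciton states
#'
#' Energies are shifted by the lowest eigenvalue before exponentiation (the
#' weight ratio is invariant, and the shift prevents underflow):
#' Z = sum_a exp(-(eps_a - eps_min)/kB T), w_a = exp(...)/Z.
#'
#' @param eps Exciton eigenvalues, cm^-1.
#' @param consts [eet_constants()].
#' @return List with `Z` and `weights` (summing to 1).
#' @examples
#' thermal_weights(c(0, 0.69504 * 300))   # split by exactly kB*T
#' @export
thermal_weights <- function(eps, consts = eet_constants()) {
  stopifnot(length(eps) >= 1, all(is.finite(eps)))
  e <- exp(-(eps - min(eps)) / (consts$kB * consts$temperature))
  Z <- sum(e)
  list(Z = Z, weights = e / Z)
}

#' Build the exciton system of one aggregate
#'
#' Assembles the Frenkel exciton Hamiltonian of an aggregate: site energies
#' (per-class omega0 from the spectra) on the diagonal, screened TrEsp
#' couplings off the diagonal (unscreened Coulomb couplings when
#' `config$screen_intra` is `FALSE`). Diagonalizes it, orders states by
#' ascending energy and attaches thermal weights. Each exciton state
#' inherits participation-weighted (|c|^2) Stokes shift and width from its
#' member sites.
#'
#' @param cx A `pigment_complex` with aggregates assigned and chlorins
#'   charged.
#' @param aggregate_id Name of the aggregate in `cx$aggregates`.
#' @param config [eet_config()].
#' @return An `exciton_system`: `aggregate_id`, `site_ids`, `H`,
#'   `eigenvalues` (ascending), `coefficients` (rows = states, orthonormal),
#'   `Z`, `weights`, per-state `stokes` and `fwhm`, and the member pigments.
#' @export
build_exciton_system <- function(cx, aggregate_id, config = eet_config()) {
  stopifnot(inherits(cx, "pigment_complex"), inherits(config, "eet_config"))
  if (!aggregate_id %in% names(cx$aggregates))
    stop("aggregate '", aggregate_id, "' not present; run assign_aggregates()")
  ids <- cx$aggregates[[aggregate_id]]
  pig <- cx$pigments[ids]
  pig <- Filter(function(p) is_chlorin(p$class) &&
                  (config$include_pheo || p$class != "PHEO"), pig)
  if (!length(pig)) stop("aggregate '", aggregate_id, "' has no chlorins")
  nch <- names(which(!vapply(pig, `[[`, TRUE, "charged")))
  if (length(nch))
    stop("uncharged pigment(s) in aggregate '", aggregate_id, "': ",
         paste(nch, collapse = ", "))
  n <- length(pig)
  cls <- vapply(pig, `[[`, "", "class")
  missing_sp <- setdiff(unique(cls), names(config$spectra))
  if (length(missing_sp))
    stop("no spectral parameters for class(es): ",
         paste(missing_sp, collapse = ", "))
  omega0 <- vapply(cls, function(cl) config$spectra[[cl]]$omega0, 0)
  H <- diag(omega0, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cr <- screened_coupling(pig[[i]], pig[[j]], config$screening)
      H[i, j] <- H[j, i] <- if (config$screen_intra) cr$V else cr$V_coulomb
    }
  }
  dimnames(H) <- list(names(pig), names(pig))
  ev <- eigen(H, symmetric = TRUE)
  ord <- order(ev$values)
  eps <- ev$values[ord]
  # rows = exciton states alpha, columns = sites
  C <- t(ev$vectors[, ord, drop = FALSE])
  tw <- thermal_weights(eps, config$constants)
  part <- C^2
  stokes_site <- vapply(cls, function(cl) config$spectra[[cl]]$stokes, 0)
  sigma_site <- vapply(cls, function(cl)
    .sigma_of(config$spectra[[cl]]$fwhm, config$spectra[[cl]]$width_mode), 0)
  structure(list(aggregate_id = aggregate_id, site_ids = names(pig),
                 site_classes = cls, H = H, eigenvalues = eps,
                 coefficients = C, Z = tw$Z, weights = tw$weights,
                 stokes = as.numeric(part %*% stokes_site),
                 sigma = as.numeric(part %*% sigma_site),
                 pigments = pig),
            class = "exciton_system")
}

#' @export
print.exciton_system <- function(x, ...) {
  cat("Exciton system '", x$aggregate_id, "': ", length(x$site_ids),
      " sites\n", sep = "")
  cat("eigenvalues (cm^-1):", paste(signif(x$eigenvalues, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exciton-state couplings between two aggregates
#'
#' V_ab = sum_{m in D} sum_{n in A} c_{a,m} c_{b,n} V_mn, rotating the
#' inter-aggregate site coupling matrix into the exciton bases.
#'
#' @param D,A `exciton_system` objects (donor, acceptor).
#' @param site_couplings Matrix of site couplings V_mn, cm^-1, dimensions
#'   |D sites| x |A sites|.
#' @return Matrix of exciton couplings, rows = donor states.
#' @export
exciton_coupling <- function(D, A, site_couplings) {
  stopifnot(inherits(D, "exciton_system"), inherits(A, "exciton_system"))
  if (!all(dim(site_couplings) == c(length(D$site_ids), length(A$site_ids))))
    stop("site coupling matrix must be |D sites| x |A sites|")
  D$coefficients %*% site_couplings %*% t(A$coefficients)
}

# Screened site couplings between the members of two aggregates (screening
# always applies between aggregates).
.inter_site_couplings <- function(D, A, config) {
  V <- matrix(0, length(D$site_ids), length(A$site_ids),
              dimnames = list(D$site_ids, A$site_ids))
  for (i in seq_along(D$pigments)) for (j in seq_along(A$pigments))
    V[i, j] <- screened_coupling(D$pigments[[i]], A$pigments[[j]],
                                 config$screening)$V
  V
}

#' Generalized Forster rate between two aggregates
#'
#' k_DA = (2 pi / hbar) sum_a sum_b w_a |V_ab|^2 J_ab, where w_a are the
#' donor Boltzmann weights, V_ab the exciton couplings, and J_ab the overlap
#' of a Gaussian donor emission lineshape centered at eps_a - S_a (exciton
#' Stokes shift) with a Gaussian acceptor absorption lineshape centered at
#' eps_b, widths inherited from the sites by participation.
#'
#' @param D,A `exciton_system` objects built from the same complex; sharing
#'   a pigment is an error.
#' @param config [eet_config()].
#' @return An `aggregate_rate` record: `donor`, `acceptor`, `k_DA` (ps^-1),
#'   `tau` (ps), and per-state `contributions`.
#' @export
aggregate_rate <- function(D, A, config = eet_config()) {
  stopifnot(inherits(D, "exciton_system"), inherits(A, "exciton_system"))
  shared <- intersect(D$site_ids, A$site_ids)
  if (length(shared))
    stop("aggregates '", D$aggregate_id, "' and '", A$aggregate_id,
         "' share pigment(s): ", paste(shared, collapse = ", "))
  Vab <- exciton_coupling(D, A, .inter_site_couplings(D, A, config))
  nD <- length(D$eigenvalues); nA <- length(A$eigenvalues)
  contrib <- expand.grid(alpha = seq_len(nD), beta = seq_len(nA))
  rate1 <- function(a, b) {
    Fe <- structure(list(kind = "emission",
                         center = D$eigenvalues[a] - D$stokes[a],
                         sigma = D$sigma[a]), class = "lineshape")
    Ab <- structure(list(kind = "absorption", center = A$eigenvalues[b],
                         sigma = A$sigma[b]), class = "lineshape")
    J <- overlap_integral(Fe, Ab)
    c(J = J,
      partial = D$weights[a] *
        pair_rate(Vab[a, b], J, config$constants))
  }
  jp <- mapply(rate1, contrib$alpha, contrib$beta)
  contrib$w_alpha <- D$weights[contrib$alpha]
  contrib$V_ab <- Vab[cbind(contrib$alpha, contrib$beta)]
  contrib$J <- jp["J", ]
  contrib$partial <- jp["partial", ]
  k <- sum(contrib$partial)
  structure(list(donor = D$aggregate_id, acceptor = A$aggregate_id,
                 k_DA = k, tau = 1 / k, contributions = contrib),
            class = "aggregate_rate")
}

#' @export
print.aggregate_rate <- function(x, ...) {
  cat("Aggregate EET ", x$donor, " -> ", x$acceptor, ": k = ",
      signif(x$k_DA, 4), " ps^-1 (tau = ", signif(x$tau, 4), " ps)\n",
      sep = "")
  invisible(x)
}

#' Generalized Forster rates between all assigned aggregates
#'
#' @param cx A `pigment_complex` with aggregates assigned and chlorins
#'   charged; refuses to run when no aggregates are assigned.
#' @param config [eet_config()].
#' @return List with `table` (data frame: donor_agg, acceptor_agg, k_per_ps,
#'   tau_ps, n_donor_states, n_acceptor_states) and `records` (the
#'   `aggregate_rate` objects, named "donor->acceptor").
#' @examples
#' cx <- make_supercomplex()
#' cx <- assign_aggregates(cx, attr(cx, "ground_truth")$aggregate_mapping)
#' cx <- charge_pigments(cx)
#' head(all_aggregate_rates(cx)$table)
#' @export
all_aggregate_rates <- function(cx, config = eet_config()) {
  stopifnot(inherits(cx, "pigment_complex"))
  if (!length(cx$aggregates))
    stop("no aggregates assigned; run assign_aggregates() first")
  systems <- lapply(names(cx$aggregates), function(a)
    build_exciton_system(cx, a, config))
  names(systems) <- names(cx$aggregates)
  pairs <- expand.grid(donor = names(systems), acceptor = names(systems),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$donor != pairs$acceptor, , drop = FALSE]
  records <- Map(function(d, a) aggregate_rate(systems[[d]], systems[[a]],
                                               config),
                 pairs$donor, pairs$acceptor)
  names(records) <- paste0(pairs$donor, "->", pairs$acceptor)
  tab <- data.frame(
    donor_agg = pairs$donor, acceptor_agg = pairs$acceptor,
    k_per_ps = vapply(records, `[[`, 0, "k_DA"),
    tau_ps = vapply(records, `[[`, 0, "tau"),
    n_donor_states = vapply(records, function(r)
      length(unique(r$contributions$alpha)), 0L),
    n_acceptor_states = vapply(records, function(r)
      length(unique(r$contributions$beta)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, records = records, systems = systems)
}
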