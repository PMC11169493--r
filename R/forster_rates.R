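# Pairwise Forster rates, the inter-pigment time-constant matrix, and
# time-constant binning.

#' Pairwise Forster transfer rate
#'
#' k = (2 pi / hbar) |V|^2 J. With hbar in cm^-1 ps, V in cm^-1 and the
#' spectral overlap J in (cm^-1)^-1, the rate is in ps^-1.
#'
#' @param V Electronic coupling, cm^-1.
#' @param J Donor-emission/acceptor-absorption spectral overlap, (cm^-1)^-1.
#' @param consts [eet_constants()].
#' @return Rate in ps^-1.
#' @examples
#' pair_rate(V = 100, J = 1e-3)   # ~11.8 ps^-1
#' @export
pair_rate <- function(V, J, consts = eet_constants()) {
  stopifnot(inherits(consts, "eet_constants"))
  if (any(J < 0)) stop("spectral overlap J must be >= 0")
  (2 * pi / consts$hbar) * V^2 * J
}

# Coupling between two charged pigments under the configured mode.
.pair_coupling <- function(m, n, config) {
  if (config$coupling_mode == "dipole") {
    R <- sqrt(sum((m$center - n$center)^2))
    f <- screening_factor(R, config$screening)
    Vc <- point_dipole_coupling(transition_dipole(m)$vector_D, m$center,
                                transition_dipole(n)$vector_D, n$center)
    list(R = R, f = f, V_coulomb = Vc, V = f * Vc)
  } else {
    cr <- screened_coupling(m, n, config$screening)
    list(R = cr$R, f = cr$f, V_coulomb = cr$V_coulomb, V = cr$V)
  }
}

#' Inter-pigment rate matrix for a whole complex
#'
#' For every ordered chlorin pair within the configured distance cutoff, the
#' rate is assembled from the screened coupling, the resolved spectral
#' overlap and [pair_rate()]. Carotenoids never enter; pheophytins enter when
#' `config$include_pheo` is set. Row i / column j is the donor i -> acceptor
#' j rate.
#'
#' @param cx A `pigment_complex` whose chlorins carry transition charges
#'   (see [charge_pigments()]); an uncharged chlorin is an error naming the
#'   pigment.
#' @param config [eet_config()].
#' @return A `rate_matrix`: `ids`, matrices `k` (ps^-1), `tau` (ps), `V`,
#'   `R`, `f`, `J`, and per-pigment metadata.
#' @examples
#' cx <- charge_pigments(make_dimer(separation = 15))
#' all_pair_rates(cx)$k
#' @export
all_pair_rates <- function(cx, config = eet_config()) {
  stopifnot(inherits(cx, "pigment_complex"), inherits(config, "eet_config"))
  pig <- chlorins(cx, include_pheo = config$include_pheo)
  nch <- names(which(!vapply(pig, `[[`, TRUE, "charged")))
  if (length(nch))
    stop("pigment(s) without transition charges: ",
         paste(nch, collapse = ", "), "; run charge_pigments() first")
  n <- length(pig)
  ids <- names(pig)
  k <- V <- R <- f <- J <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(k) <- diag(V) <- diag(R) <- diag(f) <- diag(J) <- NA_real_
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      Rij <- sqrt(sum((pig[[i]]$center - pig[[j]]$center)^2))
      if (Rij > config$distance_cutoff) { R[i, j] <- R[j, i] <- Rij; next }
      cp <- .pair_coupling(pig[[i]], pig[[j]], config)
      V[i, j] <- V[j, i] <- cp$V
      R[i, j] <- R[j, i] <- cp$R
      f[i, j] <- f[j, i] <- cp$f
      J[i, j] <- resolve_overlap(pig[[i]], pig[[j]], config$overlap_tab,
                                 config$spectra)
      J[j, i] <- resolve_overlap(pig[[j]], pig[[i]], config$overlap_tab,
                                 config$spectra)
      k[i, j] <- pair_rate(cp$V, J[i, j], config$constants)
      k[j, i] <- pair_rate(cp$V, J[j, i], config$constants)
    }
  }
  structure(list(ids = ids, k = k, tau = 1 / k, V = V, R = R, f = f, J = J,
                 layer = vapply(pig, `[[`, "", "layer"),
                 subunit = vapply(pig, `[[`, "", "subunit"),
                 aggregate = vapply(pig, function(p)
                   if (is.null(p$aggregate)) "unassigned" else p$aggregate,
                   "")),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  n <- length(x$ids)
  kk <- x$k[!is.na(x$k)]
  cat("Rate matrix:", n, "pigments,", sum(kk > 0), "nonzero directed rates\n")
  if (any(kk > 0))
    cat("tau range:", signif(1 / max(kk), 3), "-",
        signif(1 / min(kk[kk > 0]), 3), "ps\n")
  invisible(x)
}

.BIN_LABELS <- c("fast", "medium", "slow")

# Half-open binning [0,1) fast, [1,10) medium, [10,20) slow; tau >= 20
# omitted.
.bin_tau <- function(tau, breaks = c(1, 10, 20)) {
  i <- findInterval(tau, c(0, breaks))
  ifelse(i >= length(breaks) + 1 | tau <= 0, NA_character_, .BIN_LABELS[i])
}

#' Bin inter-pigment time constants into the map categories
#'
#' Directed edges are labelled by time constant: `[0, 1)` ps "fast",
#' `[1, 10)` ps "medium", `[10, 20)` ps "slow" (intervals half-open at the
#' upper edge); pairs at or slower than 20 ps are omitted.
#'
#' @param rm A `rate_matrix`.
#' @param breaks Upper bin edges, ps.
#' @return Data frame of surviving directed edges with columns `donor`,
#'   `acceptor`, `R_angstrom`, `k_per_ps`, `tau_ps`, `bin`.
#' @export
bin_time_constants <- function(rm, breaks = c(1, 10, 20)) {
  stopifnot(inherits(rm, "rate_matrix"), length(breaks) == 3)
  idx <- which(!is.na(rm$k) & rm$k > 0, arr.ind = TRUE)
  tau <- rm$tau[idx]
  bin <- .bin_tau(tau, breaks)
  keep <- !is.na(bin)
  data.frame(donor = rm$ids[idx[keep, 1]],
             acceptor = rm$ids[idx[keep, 2]],
             R_angstrom = rm$R[idx[keep, , drop = FALSE]],
             k_per_ps = rm$k[idx[keep, , drop = FALSE]],
             tau_ps = tau[keep], bin = bin[keep],
             stringsAsFactors = FALSE)
}

#' Full per-pair rate table
#'
#' One row per ordered pigment pair with a nonzero rate, in the column
#' layout used by the CSV reports.
#'
#' @param rm A `rate_matrix`.
#' @return Data frame with donor/acceptor ids, distance, screening factor,
#'   coupling, overlap, rate, time constant, bin, and layers.
#' @export
rate_table <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  idx <- which(!is.na(rm$k) & rm$k > 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(donor_id = character(), acceptor_id = character(),
                      R_angstrom = numeric(), f = numeric(),
                      V_cm1 = numeric(), J_per_cm1 = numeric(),
                      k_per_ps = numeric(), tau_ps = numeric(),
                      bin = character(), donor_layer = character(),
                      acceptor_layer = character(),
                      stringsAsFactors = FALSE))
  tau <- rm$tau[idx]
  data.frame(donor_id = rm$ids[idx[, 1]], acceptor_id = rm$ids[idx[, 2]],
             R_angstrom = rm$R[idx], f = rm$f[idx], V_cm1 = rm$V[idx],
             J_per_cm1 = rm$J[idx], k_per_ps = rm$k[idx], tau_ps = tau,
             bin = .bin_tau(tau),
             donor_layer = unname(rm$layer[idx[, 1]]),
             acceptor_layer = unname(rm$layer[idx[, 2]]),
             stringsAsFactors = FALSE)
}
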