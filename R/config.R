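# Central run configuration: every constant the rate theory needs in one
# auditable object.

#' Configuration for an EET rate calculation
#'
#' Collects all tunable physics parameters and flags. Every default is
#' recorded into the resolved-config snapshot written by [run_pipeline()].
#'
#' @param charge_lib A `charge_library` (default: bundled synthetic set).
#' @param screening [screening_params()].
#' @param spectra Named list of per-class [spectral_params()].
#' @param overlap_tab An [overlap_table()] of class-pair overrides, or `NULL`.
#' @param constants [eet_constants()].
#' @param include_pheo Include pheophytins in the pigment set.
#' @param screen_intra Apply the screening factor to couplings inside an
#'   aggregate's exciton Hamiltonian as well as between aggregates.
#' @param coupling_mode `"tresp"` (atomic transition charges) or `"dipole"`
#'   (point-dipole approximation from the rescaled transition dipoles).
#' @param distance_cutoff Skip pigment pairs whose center distance exceeds
#'   this, Angstrom (`Inf`: all pairs).
#' @param tau_cutoff Network edge cutoff: time constants at or above this
#'   (ps) are omitted from graphs and binned output.
#' @return An object of class `eet_config`.
#' @examples
#' cfg <- eet_config(screen_intra = FALSE)
#' @export
eet_config <- function(charge_lib = read_charge_library(),
                       screening = screening_params(),
                       spectra = default_spectra(),
                       overlap_tab = NULL,
                       constants = eet_constants(),
                       include_pheo = TRUE,
                       screen_intra = TRUE,
                       coupling_mode = c("tresp", "dipole"),
                       distance_cutoff = Inf,
                       tau_cutoff = 20) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(inherits(screening, "screening_params"),
            inherits(constants, "eet_constants"),
            is.list(spectra), length(spectra) >= 1,
            distance_cutoff > 0, tau_cutoff >= 0)
  structure(list(charge_lib = charge_lib, screening = screening,
                 spectra = spectra, overlap_tab = overlap_tab,
                 constants = constants,
                 include_pheo = isTRUE(include_pheo),
                 screen_intra = isTRUE(screen_intra),
                 coupling_mode = coupling_mode,
                 distance_cutoff = distance_cutoff,
                 tau_cutoff = tau_cutoff),
            class = "eet_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys mirror the [eet_config()] arguments; `spectra` is a map
#' class -> {omega0, stokes, fwhm, width_mode}, `screening` a map of
#' [screening_params()] fields, `overlap_table` a map "DONOR->ACCEPTOR" ->
#' J, `constants` a map of [eet_constants()] fields, and `charge_library` a
#' file path. Missing keys keep package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `eet_config`.
#' @export
read_eet_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$charge_library))
    args$charge_lib <- read_charge_library(raw$charge_library)
  if (!is.null(raw$screening))
    args$screening <- do.call(screening_params, raw$screening)
  if (!is.null(raw$spectra))
    args$spectra <- lapply(raw$spectra, function(s)
      do.call(spectral_params, s))
  if (!is.null(raw$overlap_table))
    args$overlap_tab <- do.call(overlap_table, as.list(unlist(raw$overlap_table)))
  if (!is.null(raw$constants))
    args$constants <- do.call(eet_constants, raw$constants)
  for (k in c("include_pheo", "screen_intra", "coupling_mode",
              "distance_cutoff", "tau_cutoff"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(eet_config, args)
}

#' Flatten a configuration for the resolved-config snapshot
#' @param config An `eet_config`.
#' @return Plain nested list suitable for JSON serialization.
#' @export
resolved_config <- function(config) {
  stopifnot(inherits(config, "eet_config"))
  list(screening = unclass(config$screening),
       spectra = lapply(config$spectra, unclass),
       overlap_table = if (is.null(config$overlap_tab)) list()
                       else as.list(unclass(config$overlap_tab)),
       constants = unclass(config$constants),
       charge_library = lapply(unclass(config$charge_lib), function(e)
         list(target_dipole_D = e$target_dipole_D,
              provenance = e$provenance,
              n_atoms = length(e$atoms))),
       include_pheo = config$include_pheo,
       screen_intra = config$screen_intra,
       coupling_mode = config$coupling_mode,
       distance_cutoff = config$distance_cutoff,
       tau_cutoff = config$tau_cutoff)
}
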