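# Synthetic pigment geometries with recorded ground truth: pseudo-chlorin
# dimers, linear antenna belts, and C2-symmetric two-belt supercomplexes.

# Minimal planar pseudo-chlorin covering the bundled charge library:
# Mg + 4 pyrrole N + methine bridges + 8 ring carbons. The transition
# dipole of the charged template points along +y.
.chlorin_template <- function() {
  data.frame(
    name = c("MG", "NA", "NB", "NC", "ND",
             "CHA", "CHB", "CHC", "CHD",
             "C1A", "C4A", "C1B", "C4B", "C1C", "C4C", "C1D", "C4D"),
    elem = c("MG", rep("N", 4), rep("C", 12)),
    x = c(0, 2.05, 0, -2.05, 0, 2.40, -2.40, -2.40, 2.40,
          3.10, 3.10, 0.90, -0.90, -3.10, -3.10, -0.90, 0.90),
    y = c(0, 0, 2.05, 0, -2.05, 2.40, 2.40, -2.40, -2.40,
          0.90, -0.90, 3.10, 3.10, 0.90, -0.90, -3.10, -3.10),
    z = 0, q = 0, stringsAsFactors = FALSE)
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Place one pseudo-chlorin: rotate the template about z by `angle_deg`
# (dipole +y -> tangent direction), then translate to `center`.
.place_chlorin <- function(chain, resno, class, center, angle_deg = 0,
                           ligand = NULL) {
  tmpl <- .chlorin_template()
  if (identical(class, "PHEO")) tmpl <- tmpl[tmpl$name != "MG", ]
  if (is.null(ligand))
    ligand <- c(CHL_A = "CLA", CHL_C = "KC1", PHEO = "PHO")[[class]]
  xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(.rot_z(angle_deg))
  tmpl$x <- xyz[, 1] + center[1]
  tmpl$y <- xyz[, 2] + center[2]
  tmpl$z <- xyz[, 3] + center[3]
  new_pigment(chain = chain, resno = resno, ligand = ligand, class = class,
              atoms = tmpl)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Synthetic pseudo-chlorin dimer
#'
#' Two planar pseudo-chlorins separated along x. By default both transition
#' dipoles point along +y (parallel, perpendicular to the separation
#' vector); the second pigment can be rotated in-plane. The recorded ground
#' truth contains the analytic point-dipole coupling for the library's
#' effective dipoles, the expected screening factor and the orientation
#' factor kappa.
#'
#' @param separation Center-to-center distance, Angstrom (>= 3; smaller
#'   separations are rejected as clashes).
#' @param angle2_deg In-plane rotation of the second pigment's dipole.
#' @param classes Pigment classes of the two sites.
#' @param lib Charge library used for the ground-truth dipole magnitudes.
#' @param params Screening parameters for the ground-truth screened value.
#' @return A `pigment_complex` (chains "A" and "B") with attribute
#'   `ground_truth`: `kappa`, `V_dipole_unscreened_cm1`,
#'   `V_dipole_screened_cm1`, `f`, `mu_D`.
#' @examples
#' cx <- make_dimer(separation = 60)
#' attr(cx, "ground_truth")$V_dipole_unscreened_cm1
#' @export
make_dimer <- function(separation = 60, angle2_deg = 0,
                       classes = c("CHL_A", "CHL_A"),
                       lib = read_charge_library(),
                       params = screening_params()) {
  if (separation < 3) stop("separation < 3 Angstrom: pigments clash")
  p1 <- .place_chlorin("A", 1L, classes[1], c(0, 0, 0), 0)
  p2 <- .place_chlorin("B", 1L, classes[2], c(separation, 0, 0), angle2_deg)
  cx <- new_pigment_complex(list(p1, p2), source = "synthetic:dimer")
  mu1 <- .library_entry(lib, classes[1])$target_dipole_D
  mu2 <- .library_entry(lib, classes[2])$target_dipole_D
  u1 <- c(0, 1, 0)
  u2 <- as.numeric(.rot_z(angle2_deg) %*% c(0, 1, 0))
  Vd <- point_dipole_coupling(mu1 * u1, c(0, 0, 0), mu2 * u2,
                              c(separation, 0, 0))
  f <- screening_factor(separation, params)
  attr(cx, "ground_truth") <- list(
    kind = "dimer", separation = separation,
    kappa = sum(u1 * u2) - 3 * u1[1] * u2[1],
    mu_D = c(mu1, mu2),
    V_dipole_unscreened_cm1 = Vd,
    V_dipole_screened_cm1 = f * Vd, f = f)
  cx
}

#' Synthetic C2-symmetric two-belt supercomplex
#'
#' Emulates the antenna arrangement of a dimeric photosystem supercomplex:
#' per monomer, 2n antenna sites (two belts of n) on an arc around a linear
#' pseudo-core, with transition dipoles tangential to the arc (core dipoles
#' along the core row). The monomer is duplicated by an exact C2 rotation
#' about the z (membrane normal) axis, so all couplings and rates are
#' exactly symmetric under the recorded chain pairing. Antenna chains are
#' "A".."F" (belt 1: A..C outer arc half, belt 2: D..F) plus core "X" in
#' monomer 1, and the corresponding lower-case chains in monomer 2.
#'
#' Geometry defaults place nearest-neighbour sites ~15 Angstrom apart
#' (typical closest Mg-Mg distances between adjacent antenna subunits), the
#' arc ends ~13 Angstrom from the core ends, and the two z-planes (stromal
#' +z_offset for belt 1, lumenal -z_offset for belt 2; the core row
#' alternates) 2*z_offset apart.
#'
#' @param n_per_belt Antenna sites per belt (default 3: two linear trimers).
#' @param pigments_per_site Pigments per antenna site; for 2+, sites carry
#'   pigments stacked on both z-planes.
#' @param site_spacing Arc chord between adjacent antenna sites, Angstrom.
#' @param core_size Pigments in each monomer's pseudo-core.
#' @param core_spacing Spacing of the core row, Angstrom.
#' @param z_offset Half-distance between the two layer planes, Angstrom.
#' @param jitter Gaussian coordinate noise (Angstrom, sd) applied to pigment
#'   centers of both monomers independently; breaks the exact C2 symmetry.
#' @param seed RNG seed (only used when `jitter > 0`).
#' @return A `pigment_complex` with attribute `ground_truth`: the
#'   `aggregate_mapping` (chain -> ACPII-1..2n / CORE per monomer),
#'   `chain_pairing` and `pigment_pairing` under the C2 operation, and
#'   per-pigment `layers`.
#' @examples
#' cx <- make_supercomplex()
#' attr(cx, "ground_truth")$chain_pairing
#' @export
make_supercomplex <- function(n_per_belt = 3, pigments_per_site = 1,
                              site_spacing = 15, core_size = 4,
                              core_spacing = 10, z_offset = 8,
                              jitter = 0, seed = 1) {
  stopifnot(n_per_belt >= 1, pigments_per_site >= 1, core_size >= 1)
  ns <- 2L * n_per_belt
  if (ns > 26) stop("at most 13 sites per belt (single-letter chains)")
  dth <- 160 / (ns - 1)
  angles <- seq(170, 10, by = -dth)
  radius <- site_spacing / (2 * sin(dth / 2 * pi / 180))
  chains_upper <- c(LETTERS[seq_len(ns)], "X")
  chains_lower <- c(letters[seq_len(ns)], "x")
  core_x <- (seq_len(core_size) - (core_size + 1) / 2) * core_spacing
  core_z <- z_offset * (-1)^(seq_len(core_size) + 1)

  build_monomer <- function(chains, transform) {
    pigs <- list()
    for (s in seq_len(ns)) {
      th <- angles[s]
      cxy <- radius * c(cos(th * pi / 180), sin(th * pi / 180))
      zs <- if (pigments_per_site == 1) {
        if (s <= n_per_belt) z_offset else -z_offset
      } else {
        z_offset * (-1)^(seq_len(pigments_per_site) + 1)
      }
      for (pi_ in seq_len(pigments_per_site)) {
        ctr <- transform(c(cxy, zs[pi_]))
        ang <- th + attr(transform, "rot")
        pigs[[length(pigs) + 1L]] <-
          .place_chlorin(chains[s], 300L + pi_, "CHL_A", ctr, ang)
      }
    }
    for (j in seq_len(core_size)) {
      ctr <- transform(c(core_x[j], 0, core_z[j]))
      pigs[[length(pigs) + 1L]] <-
        .place_chlorin(chains[ns + 1L], 600L + j, "CHL_A", ctr,
                       -90 + attr(transform, "rot"))
    }
    pigs
  }
  ident <- function(v) v
  attr(ident, "rot") <- 0
  # exact C2: 180 degree rotation about the z axis through (0, -y_c)
  y_c <- radius + 2 * site_spacing
  c2 <- function(v) c(-v[1], -2 * y_c - v[2], v[3])
  attr(c2, "rot") <- 180

  pigs <- c(build_monomer(chains_upper, ident),
            build_monomer(chains_lower, c2))
  if (jitter > 0) {
    pigs <- .with_seed(seed, lapply(pigs, function(p) {
      d <- stats::rnorm(3, sd = jitter)
      p$atoms$x <- p$atoms$x + d[1]
      p$atoms$y <- p$atoms$y + d[2]
      p$atoms$z <- p$atoms$z + d[3]
      p$center <- pigment_center(p)
      p
    }))
  }
  cx <- new_pigment_complex(pigs, source = "synthetic:supercomplex")

  # antenna sites must not clash with the core
  ids_ant <- names(Filter(function(p) p$chain %in% LETTERS[seq_len(ns)],
                          cx$pigments))
  ids_core <- names(Filter(function(p) p$chain == "X", cx$pigments))
  dmin <- min(vapply(ids_ant, function(i) min(vapply(ids_core, function(j)
    pigment_distance(cx$pigments[[i]], cx$pigments[[j]], "min_atom"), 0)), 0))
  if (dmin < 3)
    stop("belt overlaps core: minimum atom distance ", signif(dmin, 3),
         " Angstrom")

  agg_names <- paste0("ACPII-", seq_len(ns))
  mapping <- c(stats::setNames(c(agg_names, "CORE"), chains_upper),
               stats::setNames(c(paste0(agg_names, "'"), "CORE'"),
                               chains_lower))
  pairing_chain <- c(stats::setNames(chains_lower, chains_upper),
                     stats::setNames(chains_upper, chains_lower))
  ids <- names(cx$pigments)
  pigment_pairing <- stats::setNames(vapply(cx$pigments, function(p)
    paste0(pairing_chain[[p$chain]], ":", p$resno), ""), ids)
  layers <- vapply(cx$pigments, function(p)
    if (p$center[3] >= 0) "stromal" else "lumenal", "")
  attr(cx, "ground_truth") <- list(
    kind = "supercomplex", n_per_belt = n_per_belt,
    aggregate_mapping = mapping,
    aggregate_pairing = c(stats::setNames(c(paste0(agg_names, "'"), "CORE'"),
                                          c(agg_names, "CORE")),
                          stats::setNames(c(agg_names, "CORE"),
                                          c(paste0(agg_names, "'"), "CORE'"))),
    chain_pairing = pairing_chain,
    pigment_pairing = pigment_pairing,
    layers = layers,
    z_planes = c(z_offset, -z_offset))
  cx
}

#' Synthetic two-layer slab
#'
#' Pigments on two parallel z-planes (a jittered in-plane grid), with the
#' generating layer labels recorded — a minimal fixture for layer
#' classification.
#'
#' @param n_per_layer Pigments per plane.
#' @param gap Distance between the planes, Angstrom.
#' @param seed RNG seed for the in-plane jitter.
#' @return A `pigment_complex` with attribute `ground_truth$layers`.
#' @export
make_slab <- function(n_per_layer = 6, gap = 20, seed = 1) {
  stopifnot(n_per_layer >= 1, gap > 0)
  cx <- .with_seed(seed, {
    pigs <- list()
    ncol_ <- ceiling(sqrt(n_per_layer))
    for (layer in 1:2) {
      z <- if (layer == 1) gap / 2 else -gap / 2
      ch <- c("S", "L")[layer]
      for (i in seq_len(n_per_layer)) {
        ctr <- c(((i - 1) %% ncol_) * 14 + stats::runif(1, -1, 1),
                 ((i - 1) %/% ncol_) * 14 + stats::runif(1, -1, 1), z)
        pigs[[length(pigs) + 1L]] <-
          .place_chlorin(ch, i, "CHL_A", ctr, stats::runif(1, 0, 360))
      }
    }
    new_pigment_complex(pigs, source = "synthetic:slab")
  })
  attr(cx, "ground_truth") <- list(
    kind = "slab",
    layers = vapply(cx$pigments, function(p)
      if (p$center[3] >= 0) "stromal" else "lumenal", ""))
  cx
}

#' Synthetic supercomplex carrying a published-style pigment inventory
#'
#' A synthetic stand-in emulating the pigment *inventory* of the deposited
#' cryptophyte PSII-ACPII model (it carries no realistic geometry): twelve
#' ACPII antenna chains holding 133 chlorophyll a, 14 chlorophyll c, 48
#' alloxanthin, 8 crocoxanthin and 4 alpha-carotene; two core chains with
#' the remaining 76 chlorophylls a (6 of them on the two linker chains), 4
#' pheophytins and 20 alpha-carotenes — 209 chlorophylls a in total.
#' Pigments are single-atom (Mg / pyrrole-N / C1) placeholders on a grid:
#' sufficient for parsing, classification and census, not for couplings.
#'
#' @return A `pigment_complex` with attribute `ground_truth` recording the
#'   ACPII chain set and expected counts.
#' @examples
#' cx <- make_inventory_supercomplex()
#' pigment_census(cx)$counts[["CHL_A"]]
#' @export
make_inventory_supercomplex <- function() {
  acpii_chains <- c("G", "H", "I", "J", "K", "L",
                    "g", "h", "i", "j", "k", "l")
  linker_chains <- c("N", "n")
  core_chains <- c("P", "p")
  spread <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + c(rep(1L, extra), rep(0L, k - extra))
  }
  counts <- list()
  add <- function(chain, lig, n_) {
    if (n_ > 0) counts[[length(counts) + 1L]] <<-
      list(chain = chain, lig = lig, n = n_)
  }
  cla_acpii <- spread(133L, 12L); kc_acpii <- spread(14L, 12L)
  alx <- spread(48L, 12L); cro <- spread(8L, 12L); acar <- spread(4L, 12L)
  for (i in seq_along(acpii_chains)) {
    add(acpii_chains[i], "CLA", cla_acpii[i])
    add(acpii_chains[i], "KC1", kc_acpii[i])
    add(acpii_chains[i], "ALX", alx[i])
    add(acpii_chains[i], "XCR", cro[i])
    add(acpii_chains[i], "ACR", acar[i])
  }
  for (ch in linker_chains) add(ch, "CLA", 3L)
  for (ch in core_chains) {
    add(ch, "CLA", 35L)
    add(ch, "PHO", 2L)
    add(ch, "ACR", 10L)
  }
  dict <- default_ligand_dict()
  pigs <- list()
  pos <- 0L
  next_resno <- new.env(parent = emptyenv())
  grid_xyz <- function(i) 12 * c(i %% 20, (i %/% 20) %% 20, i %/% 400)
  for (entry in counts) {
    for (j in seq_len(entry$n)) {
      pos <- pos + 1L
      n_prev <- if (is.null(next_resno[[entry$chain]])) 0L
                else next_resno[[entry$chain]]
      next_resno[[entry$chain]] <- n_prev + 1L
      ctr <- grid_xyz(pos)
      cls <- unname(dict[entry$lig])
      atoms <- if (cls == "PHEO") {
        data.frame(name = c("NA", "NB", "NC", "ND"), elem = "N",
                   x = ctr[1] + c(2.05, 0, -2.05, 0),
                   y = ctr[2] + c(0, 2.05, 0, -2.05),
                   z = ctr[3], q = 0, stringsAsFactors = FALSE)
      } else if (cls %in% c("CHL_A", "CHL_C")) {
        data.frame(name = "MG", elem = "MG", x = ctr[1], y = ctr[2],
                   z = ctr[3], q = 0, stringsAsFactors = FALSE)
      } else {
        data.frame(name = "C1", elem = "C", x = ctr[1], y = ctr[2],
                   z = ctr[3], q = 0, stringsAsFactors = FALSE)
      }
      pigs[[length(pigs) + 1L]] <-
        new_pigment(chain = entry$chain, resno = 300L + n_prev + 1L,
                    ligand = entry$lig, class = cls, atoms = atoms)
    }
  }
  cx <- new_pigment_complex(pigs, source = "synthetic:inventory")
  attr(cx, "ground_truth") <- list(
    kind = "inventory", acpii_chains = acpii_chains,
    expected_total_chl_a = 209L,
    expected_acpii = c(CHL_A = 133L, CHL_C = 14L, CAR_ALX = 48L,
                       CAR_CRO = 8L, CAR_ACAR = 4L))
  cx
}

#' Write a pigment complex to PDB or mmCIF
#'
#' Emits HETATM records (fixed-column PDB, or an `atom_site` loop in mmCIF)
#' that re-read with [load_structure()] to the same pigment ids, classes and
#' centers. PDB output requires single-character chain ids; use mmCIF for
#' longer chain names.
#'
#' @param cx A `pigment_complex`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(cx, path, format = c("auto", "pdb", "cif")) {
  stopifnot(inherits(cx, "pigment_complex"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", mmcif = "cif", pdb = "pdb",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  lines <- character(0)
  serial <- 0L
  if (format == "pdb") {
    for (p in cx$pigments) {
      if (nchar(p$chain) != 1L)
        stop("PDB output needs single-character chain ids (chain '",
             p$chain, "'); write mmCIF instead")
      for (i in seq_len(nrow(p$atoms))) {
        serial <- serial + 1L
        nm <- p$atoms$name[i]
        field <- if (nchar(nm) >= 4L) substr(nm, 1, 4)
                 else sprintf(" %-3s", nm)
        lines[length(lines) + 1L] <- sprintf(
          "HETATM%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, field, p$ligand, p$chain, p$resno %% 10000L,
          p$atoms$x[i], p$atoms$y[i], p$atoms$z[i], 1, 0,
          toupper(p$atoms$elem[i]))
      }
    }
    lines <- c(lines, "END")
  } else {
    hdr <- c("data_synthetic", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- character(0)
    for (p in cx$pigments) {
      for (i in seq_len(nrow(p$atoms))) {
        serial <- serial + 1L
        rows[length(rows) + 1L] <- paste(
          "HETATM", serial, toupper(p$atoms$elem[i]), p$atoms$name[i], ".",
          p$ligand, p$chain, 1, ".", "?",
          sprintf("%.3f", p$atoms$x[i]), sprintf("%.3f", p$atoms$y[i]),
          sprintf("%.3f", p$atoms$z[i]), "1.00", "0.00", "?",
          p$resno, p$ligand, p$chain, p$atoms$name[i], 1)
      }
    }
    lines <- c(hdr, rows, "#")
  }
  writeLines(lines, path)
  invisible(path)
}
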