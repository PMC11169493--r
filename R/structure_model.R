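# Structure parsing, pigment classification, census, distances, layer and
# aggregate assignment.

.PIGMENT_CLASSES <- c("CHL_A", "CHL_C", "PHEO",
                      "CAR_ALX", "CAR_CRO", "CAR_ACAR", "CAR_OTHER")

.CHLORIN_CLASSES <- c("CHL_A", "CHL_C", "PHEO")

.PYRROLE_N <- c("NA", "NB", "NC", "ND")

#' Default ligand-code dictionary
#'
#' Maps residue (ligand) codes found in structure files to pigment classes.
#' Chlorin codes follow the wwPDB chemical component dictionary (CLA/CHL for
#' chlorophyll a, KC1/KC2 for chlorophyll c, PHO for pheophytin a).
#' Carotenoid codes vary between depositions, so the dictionary is the single
#' point of configuration: pass an extended named vector to
#' [load_structure()] to classify additional codes. The carotenoid defaults
#' (ALX, XCR, ACR) are the codes emitted by this package's synthetic
#' structure writer.
#'
#' @return Named character vector: ligand code -> pigment class.
#' @examples
#' default_ligand_dict()
#' c(default_ligand_dict(), A86 = "CAR_ALX")
#' @export
default_ligand_dict <- function() {
  c(CLA = "CHL_A", CHL = "CHL_A",
    KC1 = "CHL_C", KC2 = "CHL_C",
    PHO = "PHEO",
    ALX = "CAR_ALX", XCR = "CAR_CRO", ACR = "CAR_ACAR",
    BCR = "CAR_OTHER")
}

#' @keywords internal
is_chlorin <- function(class) class %in% .CHLORIN_CLASSES

new_pigment <- function(chain, resno, ligand, class, atoms,
                        subunit = chain, layer = "unassigned") {
  stopifnot(nrow(atoms) >= 1L)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in pigment ", chain, ":", resno)
  p <- list(id = paste0(chain, ":", resno),
            chain = as.character(chain), resno = as.integer(resno),
            ligand = ligand, class = class,
            subunit = subunit, layer = layer,
            atoms = atoms, charged = FALSE)
  p$center <- pigment_center(p)
  class(p) <- "pigment"
  p
}

# Center convention: Mg when present, else centroid of the four pyrrole
# nitrogens (chlorins, e.g. pheophytin), else all-atom centroid.
pigment_center <- function(p) {
  a <- p$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  i <- which(a$name == "MG")
  if (length(i) == 1L) return(as.numeric(xyz[i, ]))
  if (is_chlorin(p$class)) {
    j <- which(a$name %in% .PYRROLE_N)
    if (length(j) >= 3L) return(colMeans(xyz[j, , drop = FALSE]))
  }
  colMeans(xyz)
}

new_pigment_complex <- function(pigments, aggregates = list(),
                                membrane_axis = NULL, source = NA_character_) {
  ids <- vapply(pigments, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate pigment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pigments) <- ids
  structure(list(pigments = pigments, aggregates = aggregates,
                 membrane_axis = membrane_axis, source = source),
            class = "pigment_complex")
}

#' @export
print.pigment_complex <- function(x, ...) {
  cls <- vapply(x$pigments, `[[`, "", "class")
  cat("Pigment complex:", length(x$pigments), "pigments\n")
  if (length(cls)) print(table(cls))
  if (length(x$aggregates))
    cat("Aggregates:", paste(names(x$aggregates), collapse = ", "), "\n")
  invisible(x)
}

#' Number of pigments in a complex
#' @param x A `pigment_complex`.
#' @return Integer count.
#' @export
n_pigments <- function(x) length(x$pigments)

#' Load pigment cofactors from a PDB or mmCIF structure file
#'
#' Parses an atomic structure (via bio3d) and extracts one pigment record per
#' residue whose ligand code appears in the class dictionary; all other
#' residues are ignored. For multi-model files only the first model is used.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param dict Ligand-code dictionary, see [default_ligand_dict()].
#' @return A `pigment_complex` with empty aggregates and unset membrane axis.
#' @examples
#' cx <- make_dimer(separation = 20)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(cx, f)
#' load_structure(f)
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"),
                           dict = default_ligand_dict()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", mmcif = "cif",
                     pdb = "pdb", ent = "pdb",
                     stop("cannot infer structure format from extension '.",
                          ext, "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no atom records parsed from '", path, "': ill-formed ", format,
         " file?")
  # bio3d coerces the literal pyrrole-nitrogen atom name "NA" to missing
  nm <- at$elety
  nm[is.na(nm)] <- "NA"
  elem <- if ("elesy" %in% names(at) && !all(is.na(at$elesy))) at$elesy
          else substr(gsub("[0-9']", "", nm), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(nm[is.na(elem) | elem == ""], 1, 1)
  keep <- at$resid %in% names(dict)
  if (!any(keep))
    return(new_pigment_complex(list(), source = path))
  at <- at[keep, , drop = FALSE]
  nm <- nm[keep]; elem <- elem[keep]
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  key <- paste(chain, at$resno, sep = ":")
  pigments <- lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                     function(i) {
    lig <- at$resid[i[1]]
    new_pigment(chain = chain[i[1]], resno = at$resno[i[1]], ligand = lig,
                class = unname(dict[lig]),
                atoms = data.frame(name = nm[i], elem = elem[i],
                                   x = at$x[i], y = at$y[i], z = at$z[i],
                                   q = 0, stringsAsFactors = FALSE))
  })
  new_pigment_complex(unname(pigments), source = path)
}

#' Pigment census over a selection
#'
#' Counts pigments per class, optionally restricted to a selection, and
#' derives the chlorophyll a/c and chlorophyll/carotenoid ratios.
#'
#' @param cx A `pigment_complex`.
#' @param selection `NULL` (all pigments), a character vector matched against
#'   subunit labels and chain ids, or a predicate `function(pigment)`.
#' @param label Name recorded for the selection in reports.
#' @return A `pigment_census` with `counts` (all classes, zero-filled) and
#'   `ratios`.
#' @examples
#' cx <- make_supercomplex()
#' pigment_census(cx)
#' pigment_census(cx, selection = c("A", "B"))
#' @export
pigment_census <- function(cx, selection = NULL, label = "all") {
  stopifnot(inherits(cx, "pigment_complex"))
  pig <- cx$pigments
  if (!is.null(selection)) {
    sel <- if (is.function(selection)) {
      vapply(pig, function(p) isTRUE(selection(p)), TRUE)
    } else {
      vapply(pig, function(p) p$subunit %in% selection ||
                              p$chain %in% selection, TRUE)
    }
    if (length(pig) && !any(sel))
      warning("selection matched no pigments")
    pig <- pig[sel]
  }
  cls <- vapply(pig, `[[`, "", "class")
  counts <- stats::setNames(integer(length(.PIGMENT_CLASSES)),
                            .PIGMENT_CLASSES)
  tab <- table(factor(cls, levels = .PIGMENT_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  census <- structure(list(counts = counts, selection = label),
                      class = "pigment_census")
  census$ratios <- compute_ratios(census)
  census
}

#' Chlorophyll ratios from a census
#'
#' @param census A `pigment_census` (or its `counts` vector).
#' @return List with `chl_a_c` (Chl a / Chl c) and `chl_car`
#'   ((Chl a + Chl c) / all carotenoids); a ratio is `NA` when its
#'   denominator is zero.
#' @examples
#' compute_ratios(c(CHL_A = 133, CHL_C = 14, CAR_ALX = 48, CAR_CRO = 8,
#'                  CAR_ACAR = 4))
#' @export
compute_ratios <- function(census) {
  counts <- if (inherits(census, "pigment_census")) census$counts else census
  get <- function(k) if (k %in% names(counts)) as.numeric(counts[[k]]) else 0
  chl_a <- get("CHL_A"); chl_c <- get("CHL_C")
  car <- sum(vapply(grep("^CAR_", names(counts), value = TRUE), get, 0))
  list(chl_a_c = if (chl_c > 0) chl_a / chl_c else NA_real_,
       chl_car = if (car > 0) (chl_a + chl_c) / car else NA_real_)
}

#' @export
print.pigment_census <- function(x, ...) {
  cat("Pigment census [", x$selection, "]\n", sep = "")
  print(x$counts[x$counts > 0 | names(x$counts) %in% c("CHL_A", "CHL_C")])
  r <- x$ratios
  cat("Chl a/c:", if (is.na(r$chl_a_c)) "NA" else signif(r$chl_a_c, 3),
      " Chl/Car:", if (is.na(r$chl_car)) "NA" else signif(r$chl_car, 3), "\n")
  invisible(x)
}

#' Distance between two pigments
#'
#' @param p,q `pigment` records.
#' @param mode `"center"` (distance between pigment centers) or `"min_atom"`
#'   (minimum over all interatomic pairs).
#' @return Distance in Angstrom; symmetric in its arguments.
#' @examples
#' cx <- make_dimer(separation = 15)
#' pigment_distance(cx$pigments[[1]], cx$pigments[[2]])
#' pigment_distance(cx$pigments[[1]], cx$pigments[[2]], mode = "min_atom")
#' @export
pigment_distance <- function(p, q, mode = c("center", "min_atom")) {
  mode <- match.arg(mode)
  if (nrow(p$atoms) < 1L || nrow(q$atoms) < 1L)
    stop("pigment with empty atom list")
  if (mode == "center") {
    sqrt(sum((p$center - q$center)^2))
  } else {
    a <- as.matrix(p$atoms[, c("x", "y", "z")])
    b <- as.matrix(q$atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(max(min(d2), 0))
  }
}

#' Assign stromal/lumenal layers by projection on the membrane normal
#'
#' Each chlorin is assigned to a layer by the sign of the projection of its
#' center on `axis` relative to `origin`: non-negative offsets are stromal
#' (projections exactly at the origin count as stromal), negative lumenal.
#' Carotenoids are left unassigned.
#'
#' @param cx A `pigment_complex`.
#' @param axis Membrane normal (need not be unit length; normalized here).
#' @param origin Scalar offset along the axis; default is the median
#'   projection of all chlorin centers.
#' @return The complex with pigment `layer` fields set and `membrane_axis`
#'   stored.
#' @examples
#' cx <- assign_layers(make_supercomplex(), axis = c(0, 0, 1))
#' table(vapply(cx$pigments, `[[`, "", "layer"))
#' @export
assign_layers <- function(cx, axis = c(0, 0, 1), origin = NULL) {
  stopifnot(inherits(cx, "pigment_complex"), length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-8) stop("degenerate membrane axis")
  axis <- axis / nrm
  chl <- vapply(cx$pigments, function(p) is_chlorin(p$class), TRUE)
  proj <- vapply(cx$pigments, function(p) sum(p$center * axis), 0)
  if (is.null(origin)) {
    if (!any(chl)) stop("no chlorins to define the default origin")
    origin <- stats::median(proj[chl])
  }
  cx$pigments <- lapply(cx$pigments, function(p) {
    p$layer <- if (!is_chlorin(p$class)) "unassigned"
               else if (sum(p$center * axis) - origin >= 0) "stromal"
               else "lumenal"
    p
  })
  cx$membrane_axis <- axis
  cx
}

#' Assign pigments to donor/acceptor aggregates
#'
#' Maps chains (or subunit labels) to aggregate ids, e.g. the six antenna
#' monomers and the photosystem core of one supercomplex half. Many chains
#' may map to one aggregate; a chain mapped to two aggregates is a
#' configuration error. Pigments whose chain is unmapped go to a reserved
#' `"unassigned"` group that is excluded from aggregate-level rates.
#'
#' @param cx A `pigment_complex`.
#' @param mapping Named character vector `chain -> aggregate_id`, or a
#'   data.frame with columns `chain` and `aggregate`.
#' @return The complex with `aggregates` set and per-pigment `aggregate`
#'   fields.
#' @examples
#' cx <- make_supercomplex()
#' cx <- assign_aggregates(cx, attr(cx, "ground_truth")$aggregate_mapping)
#' names(cx$aggregates)
#' @export
assign_aggregates <- function(cx, mapping) {
  stopifnot(inherits(cx, "pigment_complex"))
  if (is.data.frame(mapping))
    mapping <- stats::setNames(as.character(mapping$aggregate),
                               as.character(mapping$chain))
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("aggregate mapping must be named by chain/subunit")
  dup <- names(mapping)[duplicated(names(mapping))]
  conflict <- dup[vapply(dup, function(d)
    length(unique(mapping[names(mapping) == d])) > 1L, TRUE)]
  if (length(conflict))
    stop("chain(s) mapped to more than one aggregate: ",
         paste(unique(conflict), collapse = ", "))
  mapping <- mapping[!duplicated(names(mapping))]
  cx$pigments <- lapply(cx$pigments, function(p) {
    key <- if (p$chain %in% names(mapping)) p$chain
           else if (p$subunit %in% names(mapping)) p$subunit
           else NA_character_
    p$aggregate <- if (is.na(key)) "unassigned" else unname(mapping[key])
    p
  })
  agg <- vapply(cx$pigments, `[[`, "", "aggregate")
  ids <- vapply(cx$pigments, `[[`, "", "id")
  cx$aggregates <- split(ids, agg)
  cx$aggregates <- cx$aggregates[setdiff(names(cx$aggregates), "unassigned")]
  cx
}

#' Select chlorin pigments from a complex
#' @param cx A `pigment_complex`.
#' @param include_pheo Include pheophytins with the chlorophylls.
#' @return Named list of `pigment` records.
#' @export
chlorins <- function(cx, include_pheo = TRUE) {
  keep <- .CHLORIN_CLASSES
  if (!include_pheo) keep <- setdiff(keep, "PHEO")
  Filter(function(p) p$class %in% keep, cx$pigments)
}
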