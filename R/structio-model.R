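#' Van der Waals radius table
#'
#' Element radii (Angstrom) used when assigning per-atom radii at read time,
#' in the spirit of the Bondi compilation commonly used by pore-profiling
#' tools. The table is a named numeric vector and can be replaced or extended
#' by the caller.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, FE = 2.00, ZN = 1.39,
    MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75, X = 1.50)
}

#' Atomic model tibbles
#'
#' An `atomic_model` is a tibble of typed atom records: chain id, residue
#' index and name, atom name, element, coordinates in Angstrom, occupancy,
#' B-factor and van der Waals radius. `(chain, resid, atom)` must be unique.
#'
#' @param atoms a data frame with columns `chain`, `resid`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, and optionally `occupancy`, `b_factor`,
#'   `vdw`.
#' @param vdw_table named element -> radius table used to fill missing radii.
#' @param default_vdw radius assigned (with a warning) to unknown elements.
#' @return A tibble with class `atomic_model`.
#' @export
atomic_model <- function(atoms, vdw_table = vdw_radii(), default_vdw = 1.7) {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resid", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  if (!"vdw" %in% names(atoms)) {
    el <- toupper(atoms$element)
    r <- unname(vdw_table[el])
    unknown <- is.na(r)
    if (any(unknown)) {
      warn(paste0("unknown element(s) ",
                  paste(unique(el[unknown]), collapse = ", "),
                  "; assigning default vdW radius ", default_vdw, " A"))
      r[unknown] <- default_vdw
    }
    atoms$vdw <- r
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) abort("coordinates must be finite")
  if (any(atoms$vdw <= 0)) abort("vdW radii must be > 0")
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key)) abort("(chain, resid, atom) records must be unique")
  class(atoms) <- c("atomic_model", class(atoms))
  atoms
}

model_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Read a coordinate model from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; records are returned as an [atomic_model()]
#' tibble with van der Waals radii assigned per element from `vdw_table`.
#'
#' @param path a `.pdb` or `.cif` file.
#' @inheritParams atomic_model
#' @return An [atomic_model()].
#' @export
read_model <- function(path, vdw_table = vdw_radii(), default_vdw = 1.7) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    # fall back on the first letter of the atom name
    el <- sub("^[0-9]*", "", a$elety)
    el <- substr(el, 1, 1)
  }
  atomic_model(
    tibble(
      chain = a$chain, resid = a$resno, resname = a$resid, atom = a$elety,
      element = el, x = a$x, y = a$y, z = a$z,
      occupancy = ifelse(is.na(a$o), 1, a$o),
      b_factor = ifelse(is.na(a$b), 0, a$b)
    ),
    vdw_table = vdw_table, default_vdw = default_vdw
  )
}

#' Write an atomic model as PDB
#'
#' @param model an [atomic_model()].
#' @param path output path (PDB format).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  xyz <- as.vector(t(model_xyz(model)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = model$resid, resid = model$resname, chain = model$chain,
    elety = model$atom, o = model$occupancy, b = model$b_factor,
    elesy = model$element
  )
  invisible(NULL)
}
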