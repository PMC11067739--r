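#' Atomistic configuration (frame)
#'
#' One configuration of the system: element symbols, Cartesian coordinates in
#' Angstroms, an optional orthorhombic periodic cell, per-atom set labels and
#' molecule ids.  Labels partition the atoms into the sets the differential
#' formalism needs: \code{"solute"} and \code{"solvent"} in a solution frame,
#' with solvent atoms of a reference frame optionally refined into
#' \code{"excluded"} (droplet) and \code{"bulk"}.
#'
#' @param elements character vector of element symbols
#' @param xyz numeric n x 3 matrix of coordinates (A)
#' @param cell \code{NULL} (cluster mode) or the three orthorhombic edge
#'   lengths (A); general triclinic cells are not supported
#' @param labels per-atom tags in \code{c("solute","solvent","excluded","bulk")},
#'   or \code{NULL} when unset
#' @param mol_id integer molecule id per atom, or \code{NULL}
#' @return object of class \code{scat_frame}
#' @export
frame <- function(elements, xyz, cell = NULL, labels = NULL, mol_id = NULL) {
  elements <- as.character(elements)
  xyz <- as.matrix(xyz)
  if (length(elements) == 0L) stop("frame must contain at least one atom")
  if (!is.numeric(xyz) || ncol(xyz) != 3 || nrow(xyz) != length(elements))
    stop("xyz must be a numeric matrix with one row per atom and 3 columns")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) == 9) {
      m <- matrix(cell, 3, 3)
      if (any(abs(m[lower.tri(m) | upper.tri(m)]) > 1e-10))
        stop("only orthorhombic cells are supported (off-diagonal lattice ",
             "components must vanish)")
      cell <- diag(m)
    }
    if (length(cell) != 3 || any(!is.finite(cell)) || any(cell <= 0))
      stop("cell must be three positive orthorhombic edge lengths")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(elements))
      stop("labels must have one entry per atom")
    bad <- setdiff(unique(labels), c("solute", "solvent", "excluded", "bulk"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(mol_id)) {
    mol_id <- as.integer(mol_id)
    if (length(mol_id) != length(elements))
      stop("mol_id must have one entry per atom")
    if (!is.null(labels)) {
      per_mol <- tapply(labels, mol_id, function(l) length(unique(l)))
      if (any(per_mol > 1))
        stop("atoms sharing a molecule id must share a label")
    }
  }
  structure(list(elements = elements, xyz = xyz, cell = cell,
                 labels = labels, mol_id = mol_id),
            class = "scat_frame")
}

#' @export
print.scat_frame <- function(x, ...) {
  cat("<scat_frame>", length(x$elements), "atoms")
  if (!is.null(x$cell))
    cat("; cell", paste(format(x$cell, digits = 5), collapse = " x "), "A")
  else cat("; cluster (no cell)")
  if (!is.null(x$labels)) {
    tl <- table(x$labels)
    cat("; labels:", paste(names(tl), tl, sep = "=", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

n_atoms <- function(fr) length(fr$elements)

# resolve an atom-set selector to integer indices.
# set: "all", a label name, a logical mask or an integer index vector.
atom_indices <- function(fr, set) {
  n <- n_atoms(fr)
  if (is.character(set) && length(set) == 1L) {
    if (set == "all") return(seq_len(n))
    if (is.null(fr$labels))
      stop("frame carries no labels; cannot select set '", set, "'")
    if (set == "solvent")  # droplet refinement still belongs to the solvent
      return(which(fr$labels %in% c("solvent", "excluded", "bulk")))
    return(which(fr$labels == set))
  }
  if (is.logical(set)) {
    stopifnot(length(set) == n)
    return(which(set))
  }
  set <- as.integer(set)
  if (any(set < 1L | set > n)) stop("atom index out of range")
  set
}

#' Ordered collection of frames (ensemble)
#'
#' The thermal-average surface: an ordered list of frames sharing one element
#' list and label schema, with metadata.  Every ensemble-averaged quantity in
#' the differential framework is computed over such an object.
#'
#' @param frames list of [frame()] objects (at least one)
#' @param role declared experimental role, \code{"sample_A"} (solution) or
#'   \code{"sample_B"} (pure solvent reference)
#' @param metadata named list (name, temperature, seed, source, ...)
#' @param strict require identical element sequences across frames (default);
#'   with \code{FALSE}, frames may differ (e.g. overlap-rule constructions
#'   that delete a fluctuating number of solvent molecules)
#' @return object of class \code{scat_ensemble}
#' @export
ensemble <- function(frames, role = c("sample_A", "sample_B"),
                     metadata = list(), strict = TRUE) {
  role <- match.arg(role)
  if (!length(frames)) stop("ensemble needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "scat_frame")))
    stop("all frames must be scat_frame objects")
  if (strict) {
    ref <- frames[[1]]$elements
    same <- vapply(frames, function(f) identical(f$elements, ref), logical(1))
    if (!all(same))
      stop("inconsistent element lists across frames ",
           "(build with strict = FALSE to allow)")
  }
  structure(list(frames = frames, role = role, metadata = metadata,
                 strict = strict),
            class = "scat_ensemble")
}

#' @export
print.scat_ensemble <- function(x, ...) {
  cat("<scat_ensemble>", x$role, "-", length(x$frames), "frame(s),",
      n_atoms(x$frames[[1]]), "atoms in frame 1\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.scat_ensemble <- function(x) length(x$frames)
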