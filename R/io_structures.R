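# Structure file i/o: extended-XYZ (native) and PDB (via bio3d).

.known_elements <- function() {
  union(rownames(form_factor_table()), names(vdw_radii("ff")))
}

# parse key=value tokens of an extended-XYZ comment line (values may be
# double-quoted and contain spaces)
.parse_extxyz_header <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read frames from a structure file
#'
#' Reads an extended-XYZ file (possibly holding several concatenated frames)
#' or a PDB file into an ensemble.  Extended-XYZ carries the orthorhombic
#' cell in the \code{Lattice} header and per-atom set labels in the
#' \code{tag} property column (molecule ids in \code{mol}); PDB files carry
#' coordinates and elements only, with chain A read as solute and any other
#' chain as solvent.  Coordinates are taken as-is (no wrapping); periodic
#' wrapping is applied inside distance computations.
#'
#' @param path input file
#' @param format \code{"extxyz"} or \code{"pdb"} (default: by file extension)
#' @param role declared role of the resulting ensemble
#' @return a [ensemble()] object
#' @export
read_frames <- function(path, format = NULL,
                        role = c("sample_A", "sample_B")) {
  role <- match.arg(role)
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
              else "extxyz"
  }
  format <- match.arg(format, c("extxyz", "pdb"))
  if (format == "pdb") return(.read_pdb(path, role))
  lines <- readLines(path)
  known <- .known_elements()
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("line ", i, ": expected an atom count")
    nat <- as.integer(lines[i])
    if (i + 1L + nat > length(lines))
      stop("line ", i, ": file truncated (frame declares ", nat, " atoms)")
    hdr <- .parse_extxyz_header(lines[i + 1L])
    cell <- NULL
    if (!is.null(hdr$Lattice)) {
      lat <- as.numeric(strsplit(trimws(hdr$Lattice), "\\s+")[[1]])
      if (length(lat) != 9 || any(!is.finite(lat)))
        stop("line ", i + 1L, ": malformed Lattice header")
      cell <- lat  # frame() enforces orthorhombicity
    }
    props <- hdr$Properties
    cols <- c("species", "pos")
    if (!is.null(props)) {
      p <- strsplit(props, ":")[[1]]
      cols <- p[seq(1, length(p), by = 3)]
    }
    has_tag <- "tag" %in% cols
    has_mol <- "mol" %in% cols
    el <- character(nat); xyz <- matrix(NA_real_, nat, 3)
    tags <- if (has_tag) character(nat) else NULL
    mol <- if (has_mol) integer(nat) else NULL
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      need <- 4L + has_tag + has_mol
      if (length(tok) < need)
        stop("line ", ln, ": expected at least ", need, " fields")
      if (!tok[1] %in% known)
        stop("line ", ln, ": unknown element token '", tok[1], "'")
      el[k] <- tok[1]
      co <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(co))) stop("line ", ln, ": malformed coordinates")
      xyz[k, ] <- co
      at <- 5L
      if (has_tag) { tags[k] <- tok[at]; at <- at + 1L }
      if (has_mol) {
        mi <- suppressWarnings(as.integer(tok[at]))
        if (is.na(mi)) stop("line ", ln, ": malformed molecule id")
        mol[k] <- mi
      }
    }
    frames[[length(frames) + 1L]] <-
      frame(el, xyz, cell = cell, labels = tags, mol_id = mol)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  ensemble(frames, role = role, metadata = list(source = path))
}

.read_pdb <- function(path, role) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- trimws(at$elesy)
  el <- ifelse(el == "", substr(trimws(at$elety), 1, 1), el)
  known <- .known_elements()
  bad <- setdiff(unique(el), known)
  if (length(bad))
    stop("unknown element token(s) in PDB: ", paste(bad, collapse = ", "))
  labels <- ifelse(trimws(at$chain) == "A", "solute", "solvent")
  fr <- frame(el, cbind(at$x, at$y, at$z), labels = labels)
  ensemble(list(fr), role = role, metadata = list(source = path))
}

#' Write an ensemble (or frame) to extended-XYZ
#'
#' Writes frames with a \code{Lattice} header (periodic frames), per-atom
#' \code{tag} and \code{mol} columns when present, and a provenance key.
#'
#' @param x a [frame()] or [ensemble()]
#' @param path output file
#' @param extra named character vector merged into the comment line
#' @return \code{path}, invisibly
#' @export
write_xyz <- function(x, path, extra = NULL) {
  frames <- if (inherits(x, "scat_ensemble")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    nat <- n_atoms(fr)
    props <- "species:S:1:pos:R:3"
    if (!is.null(fr$labels)) props <- paste0(props, ":tag:S:1")
    if (!is.null(fr$mol_id)) props <- paste0(props, ":mol:I:1")
    hdr <- sprintf('Properties=%s provenance="solvscat %s"',
                   props, .pkg_version())
    if (!is.null(fr$cell))
      hdr <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" %s',
                     fr$cell[1], fr$cell[2], fr$cell[3], hdr)
    if (!is.null(extra))
      hdr <- paste(hdr, paste(names(extra), "=", '"', extra, '"',
                              sep = "", collapse = " "))
    writeLines(c(as.character(nat), hdr), con)
    for (k in seq_len(nat)) {
      ln <- sprintf("%-2s %.10g %.10g %.10g", fr$elements[k],
                    fr$xyz[k, 1], fr$xyz[k, 2], fr$xyz[k, 3])
      if (!is.null(fr$labels)) ln <- paste(ln, fr$labels[k])
      if (!is.null(fr$mol_id)) ln <- paste(ln, fr$mol_id[k])
      writeLines(ln, con)
    }
  }
  invisible(path)
}

#' Write a frame to PDB
#'
#' Minimal PDB export (coordinates and elements); solute atoms are written
#' as chain A, everything else as chain B.
#'
#' @param fr a [frame()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_pdb <- function(fr, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("writing PDB files requires the bio3d package")
  n <- n_atoms(fr)
  chain <- rep("B", n)
  if (!is.null(fr$labels)) chain[fr$labels == "solute"] <- "A"
  bio3d::write.pdb(file = path, xyz = as.vector(t(fr$xyz)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = fr$elements, resno = rep(1L, n),
                   resid = rep("MOL", n), chain = chain,
                   elesy = fr$elements)
  invisible(path)
}
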