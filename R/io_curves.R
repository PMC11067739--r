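# Q- and r-gridded curves with normalization provenance, and their
# two-column text format (.fq / .gr style).

#' Gridded scattering curve
#'
#' A curve on a strictly increasing abscissa grid: an intensity I(Q), a
#' reduced structure function F(Q) or a reduced PDF G(r).  The metadata list
#' records normalization provenance (which scattering power, which atom
#' count, transform parameters) and travels through file round trips.
#'
#' @param grid abscissa (Q in 1/A or r in A), strictly increasing
#' @param values ordinates, finite, same length as \code{grid}
#' @param kind one of \code{"intensity"}, \code{"structure_function"},
#'   \code{"pdf"}
#' @param meta named list of provenance entries (scalar character/numeric)
#' @param se optional standard errors (ensemble curves)
#' @return object of class \code{scat_curve}
#' @export
curve_record <- function(grid, values,
                         kind = c("intensity", "structure_function", "pdf"),
                         meta = list(), se = NULL) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) == 0L) stop("empty curve")
  if (length(values) != length(grid))
    stop("grid and values differ in length")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(grid)) || any(!is.finite(values)))
    stop("non-finite curve data")
  if (!is.null(se)) {
    se <- as.numeric(se)
    stopifnot(length(se) == length(grid))
  }
  structure(list(grid = grid, values = values, kind = kind,
                 meta = meta, se = se),
            class = "scat_curve")
}

#' @export
print.scat_curve <- function(x, ...) {
  ax <- if (x$kind == "pdf") "r" else "Q"
  cat("<scat_curve>", x$kind, "on", length(x$grid), ax, "points [",
      format(min(x$grid)), ",", format(max(x$grid)), "]\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

# arithmetic helpers on shared grids
.check_same_grid <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-9)
    stop("curves are defined on different grids")
}

#' @export
`+.scat_curve` <- function(e1, e2) {
  if (is.numeric(e2)) return(curve_record(e1$grid, e1$values + e2, e1$kind, e1$meta))
  .check_same_grid(e1, e2)
  curve_record(e1$grid, e1$values + e2$values, e1$kind, e1$meta)
}

#' @export
`-.scat_curve` <- function(e1, e2) {
  if (missing(e2)) return(curve_record(e1$grid, -e1$values, e1$kind, e1$meta))
  if (is.numeric(e2)) return(curve_record(e1$grid, e1$values - e2, e1$kind, e1$meta))
  .check_same_grid(e1, e2)
  curve_record(e1$grid, e1$values - e2$values, e1$kind, e1$meta)
}

#' @export
`*.scat_curve` <- function(e1, e2) {
  if (is.numeric(e1)) { tmp <- e1; e1 <- e2; e2 <- tmp }
  stopifnot(is.numeric(e2))
  curve_record(e1$grid, e1$values * e2, e1$kind, e1$meta)
}

#' Write a curve to a two-column text file
#'
#' Whitespace-separated two-column format in the style of common .fq/.gr
#' files: a comment header (\code{# key = value} lines) holding the kind,
#' units, normalization note and any metadata, then abscissa and ordinate.
#'
#' @param curve a [curve_record()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scat_curve"))
  ax <- if (curve$kind == "pdf") c("r", "A") else c("Q", "1/A")
  hdr <- c(sprintf("# solvscat %s curve file", .pkg_version()),
           sprintf("# kind = %s", curve$kind),
           sprintf("# abscissa = %s (%s)", ax[1], ax[2]))
  for (k in names(curve$meta))
    hdr <- c(hdr, sprintf("# %s = %s", k, format(curve$meta[[k]],
                                                 digits = 15)))
  body <- sprintf("%.10g %.10g", curve$grid, curve$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a curve written by [write_curve()]
#'
#' @param path input file
#' @return a [curve_record()] with metadata recovered from the header
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("empty curve file: ", path)
  meta <- list()
  kind <- "intensity"
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      if (key == "kind") kind <- val
      else if (key != "abscissa") {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      }
    }
  }
  dat <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop("malformed data record in ", path, " (data line ", i, ")")
    v[1:2]
  }))
  curve_record(dat[, 1], dat[, 2], kind = kind, meta = meta)
}
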