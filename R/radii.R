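#' van der Waals radii tables
#'
#' Two editable plain-text radii sets ship with the package.  \code{"ff"}
#' (the default for the solvation workflow) holds force-field flavoured
#' Lennard-Jones half-minimum radii as used by Amber-family force fields;
#' under this set the fused-sphere volume of a solute matches the excluded
#' volume bookkeeping of MD-based differential scattering studies.
#' \code{"bondi"} is the classic Bondi (1964) crystallographic contact set,
#' whose systematically smaller radii give fused-sphere volumes roughly 25
#' percent smaller for organic solutes; the choice of set is the dominant
#' sensitivity of every excluded-volume quantity downstream.
#'
#' @param set \code{"ff"} or \code{"bondi"}, ignored when \code{path} given
#' @param path optional path to a custom two-column table
#'   (\code{element radius}, \code{#} comments)
#' @return named numeric vector of radii in Angstroms
#' @export
vdw_radii <- function(set = c("ff", "bondi"), path = NULL) {
  if (is.null(path)) {
    set <- match.arg(set)
    key <- paste0("radii_", set)
    if (!is.null(.solvscat_env[[key]])) return(.solvscat_env[[key]])
    path <- system.file("extdata", paste0("radii_", set, ".txt"),
                        package = "solvscat")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, col.names = c("element", "r"))
  r <- setNames(tab$r, tab$element)
  attr(r, "set") <- if (cache) set else "custom"
  if (cache) .solvscat_env[[key]] <- r
  r
}

# radius lookup with an explicit error naming missing elements
.radii_for <- function(elements, radii) {
  miss <- setdiff(unique(elements), names(radii))
  if (length(miss))
    stop("no van der Waals radius defined for element(s): ",
         paste(miss, collapse = ", "))
  unname(radii[elements])
}
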