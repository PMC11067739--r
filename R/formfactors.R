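#' Tabulated X-ray atomic form factors
#'
#' Loads the packaged four-Gaussian-plus-constant parameterization of the
#' neutral-atom X-ray form factors (International Tables analytic
#' coefficients), \deqn{f(Q) = \sum_{k=1}^{4} a_k \exp(-b_k (Q/4\pi)^2) + c,}
#' in electrons with \eqn{b_k} in square Angstroms.  The parameterization is
#' valid over the package's working range \eqn{Q \le 25} 1/A.  Form factors
#' are treated as real-valued: anomalous (resonant) terms are neglected,
#' appropriate for high-energy measurements far from absorption edges.
#'
#' @param path optional path to an alternative coefficient table with columns
#'   \code{element a1..a4 b1..b4 c} (whitespace separated, \code{#} comments)
#' @return a data frame of class \code{ff_table}, one row per element
#' @export
form_factor_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.solvscat_env$ff_table)) return(.solvscat_env$ff_table)
    path <- system.file("extdata", "formfactors_it92.txt", package = "solvscat")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("element", paste0("a", 1:4),
                                  paste0("b", 1:4), "c"))
  rownames(tab) <- tab$element
  class(tab) <- c("ff_table", "data.frame")
  if (cache) .solvscat_env$ff_table <- tab
  tab
}

#' Atomic form factor f(Q)
#'
#' Evaluates the tabulated sum-of-Gaussians form factor of one element on a
#' grid of momentum transfer values.  At \eqn{Q = 0} the form factor equals
#' the electron count of the neutral atom.
#'
#' @param element element symbol (e.g. \code{"C"}, \code{"Ru"})
#' @param q momentum transfer grid (1/A), non-negative
#' @param table coefficient table from [form_factor_table()]
#' @return numeric vector of form-factor values (electrons), one per Q
#' @export
#' @examples
#' atomic_form_factor("C", 0)     # 6 electrons
#' atomic_form_factor("O", c(0, 2, 10))
atomic_form_factor <- function(element, q, table = form_factor_table()) {
  stopifnot(length(element) == 1L)
  if (!element %in% rownames(table))
    stop("unknown element symbol: '", element, "'")
  if (any(q < 0)) stop("q must be non-negative")
  row <- table[element, ]
  s2 <- (q / (4 * pi))^2
  f <- rep(row$c, length(q))
  for (k in 1:4)
    f <- f + row[[paste0("a", k)]] * exp(-row[[paste0("b", k)]] * s2)
  f
}

# form-factor matrix (length(q) x length(elements)) for a set of symbols
.ff_matrix <- function(elements, q, table = form_factor_table()) {
  m <- vapply(elements, function(e) atomic_form_factor(e, q, table),
              numeric(length(q)))
  matrix(m, nrow = length(q), ncol = length(elements),
         dimnames = list(NULL, elements))
}

#' Per-atom scattering powers of an atom set
#'
#' Computes the average scattering power "per atom" of a multiset of atoms:
#' the mean form factor \eqn{\langle f \rangle(Q) = N^{-1}\sum_i f_i(Q)} and
#' the mean squared form factor
#' \eqn{\langle f^2 \rangle(Q) = N^{-1}\sum_i f_i(Q)^2}.  These are the
#' normalization quantities of reduced structure functions; by Jensen's
#' inequality \eqn{\langle f^2\rangle \ge \langle f\rangle^2} at every Q.
#'
#' @param elements character vector of element symbols (with repeats), the
#'   atom multiset to average over
#' @param q momentum transfer grid (1/A)
#' @param table coefficient table
#' @return object of class \code{scattering_power}: a list with
#'   \code{mean_f}, \code{mean_f2} (numeric vectors on \code{q}) and \code{n}
#' @export
scattering_powers <- function(elements, q, table = form_factor_table()) {
  if (length(elements) == 0L) stop("empty atom set")
  uniq <- unique(elements)
  fm <- .ff_matrix(uniq, q, table)
  cnt <- as.numeric(table(factor(elements, levels = uniq)))
  n <- length(elements)
  out <- list(mean_f = drop(fm %*% cnt) / n,
              mean_f2 = drop(fm^2 %*% cnt) / n,
              n = n, q = q)
  class(out) <- "scattering_power"
  out
}

#' @export
print.scattering_power <- function(x, ...) {
  cat("<scattering_power> N =", x$n, "atoms;",
      length(x$q), "Q points\n")
  cat("  <f>(Qmin)  =", format(x$mean_f[1], digits = 6), "e-\n")
  cat("  <f2>(Qmin) =", format(x$mean_f2[1], digits = 6), "e-^2\n")
  invisible(x)
}
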