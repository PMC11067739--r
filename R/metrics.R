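# Model-ladder statistics: coefficient of determination and
# crystallographic R factor between a model curve and a reference curve.

.curve_values <- function(x) if (inherits(x, "scat_curve")) x$values else as.numeric(x)

#' Coefficient of determination
#'
#' \eqn{r^2 = 1 - \sum (ref - model)^2 / \sum (ref - \bar{ref})^2}: 1 for a
#' perfect model, 0 for a model no better than the mean of the reference,
#' negative for worse.
#'
#' @param model,reference curves (or numeric vectors) on a shared grid
#' @return dimensionless r-squared
#' @export
r_squared <- function(model, reference) {
  if (inherits(model, "scat_curve") && inherits(reference, "scat_curve"))
    .check_same_grid(model, reference)
  m <- .curve_values(model); r <- .curve_values(reference)
  stopifnot(length(m) == length(r))
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot <= 0) stop("reference has zero variance")
  1 - sum((r - m)^2) / ss_tot
}

#' Crystallographic R factor
#'
#' Goodness-of-fit between a model and a reference curve as a percentage.
#' The default is the standard L1 convention
#' \eqn{R = 100 \sum |ref - model| / \sum |ref|}; an L2 (Rw-style,
#' unweighted) variant \eqn{100 \sqrt{\sum (ref-model)^2 / \sum ref^2}} is
#' also available.  R is invariant under a common rescaling of model and
#' reference.
#'
#' @param model,reference curves (or numeric vectors) on a shared grid
#' @param convention \code{"l1"} or \code{"l2"}
#' @return R factor in percent
#' @export
r_factor <- function(model, reference, convention = c("l1", "l2")) {
  convention <- match.arg(convention)
  if (inherits(model, "scat_curve") && inherits(reference, "scat_curve"))
    .check_same_grid(model, reference)
  m <- .curve_values(model); r <- .curve_values(reference)
  stopifnot(length(m) == length(r))
  if (all(r == 0)) stop("reference is identically zero")
  if (convention == "l1") 100 * sum(abs(r - m)) / sum(abs(r))
  else 100 * sqrt(sum((r - m)^2) / sum(r^2))
}

#' Model ladder over a decomposition
#'
#' Scores a series of nested models formed by the cumulative addition of
#' decomposition components against the exact total.  Components are added
#' with the sign they carry in the total (the excluded-solvent term
#' \code{x} enters negatively).  The final row, containing every term, is
#' exact by construction: r2 = 1 and R = 0 at machine precision.
#'
#' @param decomp a \code{scat_decomposition} (typically in r space, where
#'   the analysis is usually performed)
#' @param order component names in order of addition; the default ladder is
#'   \code{uu}, \code{uv}, \code{x}, \code{restructure}
#' @return data frame of class \code{model_ladder}: model name, r2, and the
#'   L1 and L2 R factors (percent) per rung
#' @export
model_ladder <- function(decomp, order = c("uu", "uv", "x", "restructure")) {
  stopifnot(inherits(decomp, "scat_decomposition"))
  unknown <- setdiff(order, names(decomp$components))
  if (length(unknown))
    stop("unknown component name(s): ", paste(unknown, collapse = ", "))
  ref <- decomp$total$values
  cum <- numeric(length(ref))
  rows <- vector("list", length(order))
  label <- character(0)
  for (i in seq_along(order)) {
    nm <- order[i]
    sgn <- if (nm == "x") -1 else 1
    cum <- cum + sgn * decomp$components[[nm]]$values
    label <- c(label, paste0(if (sgn < 0) "-" else if (i > 1) "+" else "", nm))
    rows[[i]] <- data.frame(model = paste(label, collapse = " "),
                            r2 = r_squared(cum, ref),
                            r_factor = r_factor(cum, ref, "l1"),
                            r_factor_l2 = r_factor(cum, ref, "l2"))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_ladder", "data.frame")
  out
}

#' @export
print.model_ladder <- function(x, digits = 3, ...) {
  cat("Model ladder (scored against the exact total):\n")
  df <- data.frame(model = x$model,
                   `r2` = round(x$r2, digits),
                   `R%` = round(x$r_factor, 1),
                   `Rw%` = round(x$r_factor_l2, 1),
                   check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
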