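#' Define a continuous minimization problem over a box domain
#'
#' A problem bundles a deterministic objective function with its search box.
#' All optimization in this package minimizes: lower objective values are
#' better ("better territorial superiority" in the snow-leopard metaphor).
#'
#' @param objective Function taking a numeric vector of length `dim` and
#'   returning a single finite numeric value.
#' @param dim Dimensionality of the search space (positive integer).
#' @param lower,upper Scalar box bounds applied to every dimension
#'   (`lower < upper`).
#' @return An object of class `slo_problem`.
#' @examples
#' sphere <- slo_problem(function(x) sum(x^2), dim = 2, lower = -5, upper = 5)
#' sphere$objective(c(1, 1))
#' @export
slo_problem <- function(objective, dim, lower, upper) {
  stopifnot(is.function(objective))
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("`dim` must be a positive integer")
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("bounds must be finite with lower < upper")
  structure(
    list(objective = objective, dim = dim, lower = as.numeric(lower),
         upper = as.numeric(upper), sense = "minimize"),
    class = "slo_problem"
  )
}

#' @export
print.slo_problem <- function(x, ...) {
  cat(sprintf("<slo_problem> dim = %d, bounds = [%g, %g], sense = %s\n",
              x$dim, x$lower, x$upper, x$sense))
  invisible(x)
}

# clip every component into the box
.clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)
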