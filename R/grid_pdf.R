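#' Gridded probability density
#'
#' A `grid_pdf` tabulates a one-dimensional density on a uniform grid.
#' It is the memory object of the Bayes-optimal grid algorithm (the pdf
#' of the target's position relative to the agent) and the input to
#' numerical Fisher-information computation.
#'
#' Invariants enforced on construction: values are non-negative and
#' integrate to 1 (within 1e-8), and the mass in the outermost grid cell
#' on either side is below 1e-6, so nothing is silently truncated.
#'
#' @param x0 Left grid edge.
#' @param dx Grid spacing (> 0).
#' @param values Non-negative density values, one per grid point.
#' @param normalize If `TRUE`, rescale `values` to integrate to 1 instead
#'   of insisting that they already do.
#' @return An object of class `grid_pdf` with elements `x0`, `dx`,
#'   `values`.
#' @export
grid_pdf <- function(x0, dx, values, normalize = FALSE) {
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0) {
    stop("'dx' must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(values) || length(values) < 2L || anyNA(values) ||
      any(values < 0)) {
    stop("'values' must be non-negative densities (length >= 2)",
         call. = FALSE)
  }
  total <- sum(values) * dx
  if (normalize) {
    if (total <= 0) stop("degenerate density: total mass is zero",
                         call. = FALSE)
    values <- values / total
    total <- 1
  }
  if (abs(total - 1) > 1e-8) {
    stop("density does not integrate to 1 (integral = ", format(total), ")",
         call. = FALSE)
  }
  n <- length(values)
  if ((values[1] + values[n]) * dx >= 1e-6) {
    stop("truncation: mass within one grid cell of the support edge ",
         "exceeds 1e-6", call. = FALSE)
  }
  structure(list(x0 = as.numeric(x0), dx = dx, values = as.numeric(values)),
            class = "grid_pdf")
}

#' @export
print.grid_pdf <- function(x, ...) {
  m <- grid_moments(x)
  cat("<grid_pdf> ", length(x$values), " points on [",
      format(x$x0), ", ", format(x$x0 + (length(x$values) - 1) * x$dx),
      "], dx = ", format(x$dx), "\n", sep = "")
  cat("  mean ", format(m[["mean"]]), ", variance ", format(m[["var"]]),
      "\n", sep = "")
  invisible(x)
}

grid_x <- function(g) g$x0 + (seq_along(g$values) - 1) * g$dx

#' Mean and variance of a gridded density
#'
#' @param g A [grid_pdf()] object.
#' @return Named numeric vector with elements `mean` and `var`.
#' @export
grid_moments <- function(g) {
  x <- grid_x(g)
  w <- g$values * g$dx
  m <- sum(x * w)
  c(mean = m, var = sum((x - m)^2 * w))
}

## Linear interpolation of grid values at arbitrary points, zero outside.
grid_interp <- function(g, at) {
  n <- length(g$values)
  pos <- (at - g$x0) / g$dx
  lo <- floor(pos)
  frac <- pos - lo
  i <- as.integer(lo) + 1L
  out <- numeric(length(at))
  ok <- i >= 1L & i < n
  out[ok] <- g$values[i[ok]] * (1 - frac[ok]) + g$values[i[ok] + 1L] * frac[ok]
  exact <- i == n & frac == 0
  out[exact] <- g$values[n]
  out
}

## Shift a gridded density by `delta` (values of the new density at x are the
## old density at x + delta), renormalising to compensate interpolation loss.
grid_shift <- function(g, delta) {
  v <- grid_interp(g, grid_x(g) + delta)
  grid_pdf(g$x0, g$dx, v, normalize = TRUE)
}

same_lattice <- function(a, b) {
  isTRUE(all.equal(a$dx, b$dx, tolerance = 1e-12)) &&
    length(a$values) == length(b$values) &&
    isTRUE(all.equal(a$x0, b$x0, tolerance = 1e-9))
}
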