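#' Distribution specifications for initial positions and measurement noise
#'
#' A `dist_spec` is a named, zero-mean probability density with a known
#' variance, a sampler, a pdf, and (when a closed form exists) its
#' translation-family Fisher information.  Agent initial positions are drawn
#' from such densities centred on the target value, and the passive
#' measurement noise is described by one as well.
#'
#' Supported kinds and their parameters:
#' \describe{
#'   \item{`gaussian`}{`var` (variance, > 0). Fisher information `1/var`.}
#'   \item{`laplace`}{`b` (scale, > 0). Variance `2 b^2`, Fisher
#'     information `1/b^2`.}
#'   \item{`double_gaussian`}{equal-weight mixture of two Gaussians at
#'     `-c` and `+c` with common component variance `s2`; total variance
#'     `s2 + c^2`. No closed-form Fisher information (computed
#'     numerically on a tabulation).}
#'   \item{`uniform`}{`half_width` (> 0), uniform on
#'     `[-half_width, half_width]`, variance `half_width^2/3`. Its density
#'     is discontinuous, so the translation-family Fisher information is
#'     not finite; no closed form is stored and grid estimates are
#'     resolution-dependent.}
#'   \item{`point_mass`}{degenerate mass at 0, variance 0. Used for a
#'     noiseless measurement channel and for perfectly informed agents;
#'     it cannot be tabulated.}
#' }
#'
#' @param kind Character, one of `"gaussian"`, `"laplace"`,
#'   `"double_gaussian"`, `"uniform"`, `"point_mass"`.
#' @param ... Kind-specific parameters, see Details.
#'
#' @return An object of class `dist_spec`: a list with elements `kind`,
#'   `params`, `variance`, and `closed_form_fisher` (`NA` when no closed
#'   form exists; `Inf` for a point mass).
#'
#' @examples
#' make_distribution("gaussian", var = 4)
#' make_distribution("double_gaussian", c = 1, s2 = 0.25)
#' @export
make_distribution <- function(kind, ...) {
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1]]) && is.null(names(params))) {
    params <- params[[1]]
  }
  kinds <- c("gaussian", "laplace", "double_gaussian", "uniform", "point_mass")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("unsupported distribution kind: ", deparse(substitute(kind)),
         " (expected one of ", paste(kinds, collapse = ", "), ")",
         call. = FALSE)
  }
  chk_pos <- function(p, name) {
    if (is.null(p) || !is.numeric(p) || length(p) != 1L || !is.finite(p) ||
        p <= 0) {
      stop("invalid parameter: '", name, "' must be a single finite value > 0",
           call. = FALSE)
    }
    as.numeric(p)
  }
  spec <- switch(kind,
    gaussian = {
      v <- chk_pos(params$var, "var")
      list(params = list(var = v), variance = v, fisher = 1 / v)
    },
    laplace = {
      b <- chk_pos(params$b, "b")
      list(params = list(b = b), variance = 2 * b^2, fisher = 1 / b^2)
    },
    double_gaussian = {
      cc <- chk_pos(params$c, "c")
      s2 <- chk_pos(params$s2, "s2")
      list(params = list(c = cc, s2 = s2), variance = s2 + cc^2,
           fisher = NA_real_)
    },
    uniform = {
      hw <- chk_pos(params$half_width, "half_width")
      list(params = list(half_width = hw), variance = hw^2 / 3,
           fisher = NA_real_)
    },
    point_mass = list(params = list(), variance = 0, fisher = Inf)
  )
  structure(
    list(kind = kind, params = spec$params, variance = spec$variance,
         closed_form_fisher = spec$fisher),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  pstr <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "-"
  cat("<dist_spec> ", x$kind, " (", pstr, ")\n", sep = "")
  cat("  variance: ", format(x$variance), "\n", sep = "")
  cat("  closed-form Fisher information: ",
      if (is.na(x$closed_form_fisher)) "none" else
        format(x$closed_form_fisher), "\n", sep = "")
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

stopifnot_spec <- function(spec) {
  if (!is_dist_spec(spec)) {
    stop("expected a 'dist_spec' object (see make_distribution())",
         call. = FALSE)
  }
  invisible(spec)
}

#' Evaluate the density of a distribution spec
#'
#' @param spec A [make_distribution()] object.
#' @param x Numeric vector of evaluation points.
#' @return Density values at `x`.
#' @export
dist_pdf <- function(spec, x) {
  stopifnot_spec(spec)
  p <- spec$params
  switch(spec$kind,
    gaussian = stats::dnorm(x, 0, sqrt(p$var)),
    laplace = exp(-abs(x) / p$b) / (2 * p$b),
    double_gaussian = 0.5 * stats::dnorm(x, -p$c, sqrt(p$s2)) +
      0.5 * stats::dnorm(x, p$c, sqrt(p$s2)),
    uniform = stats::dunif(x, -p$half_width, p$half_width),
    point_mass = stop("point_mass has no density", call. = FALSE)
  )
}

#' Draw i.i.d. samples from a distribution spec
#'
#' Uses the R session's random number generator state, so results are
#' reproducible under [set.seed()].
#'
#' @param spec A [make_distribution()] object.
#' @param n Number of draws (>= 0).
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n) {
  stopifnot_spec(spec)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n)) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  p <- spec$params
  switch(spec$kind,
    gaussian = stats::rnorm(n, 0, sqrt(p$var)),
    laplace = {
      u <- stats::runif(n, -0.5, 0.5)
      -p$b * sign(u) * log1p(-2 * abs(u))
    },
    double_gaussian = {
      sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
      stats::rnorm(n, sgn * p$c, sqrt(p$s2))
    },
    uniform = stats::runif(n, -p$half_width, p$half_width),
    point_mass = numeric(n)
  )
}

#' Tabulate a distribution spec on a uniform grid
#'
#' Produces the [grid_pdf()] representation used by the Bayes-optimal
#' grid algorithm and by numerical Fisher-information computation.  The
#' grid is centred on the (zero) mean of the spec with half-width
#' `half_width_sigmas` standard deviations.  The tabulated values are
#' renormalised to integrate to exactly 1; tabulation is refused when the
#' density places non-negligible mass in the outermost grid cells (silent
#' truncation).
#'
#' @param spec A [make_distribution()] object with positive variance.
#' @param half_width_sigmas Grid half-width in standard deviations
#'   (>= 6; default 8, which keeps the truncated Gaussian mass below
#'   1e-10 and bounds convolution aliasing).
#' @param n_points Number of grid points (>= 64; default 2048).
#' @return A [grid_pdf()] object.
#' @export
tabulate_pdf <- function(spec, half_width_sigmas = 8, n_points = 2048) {
  stopifnot_spec(spec)
  if (spec$kind == "point_mass" || spec$variance <= 0) {
    stop("cannot tabulate a zero-variance distribution", call. = FALSE)
  }
  if (n_points < 64) stop("'n_points' must be >= 64", call. = FALSE)
  if (half_width_sigmas < 6) {
    stop("truncation: 'half_width_sigmas' must be >= 6; ",
         "widen the support to avoid truncating density mass",
         call. = FALSE)
  }
  sd <- sqrt(spec$variance)
  hw <- half_width_sigmas * sd
  x <- seq(-hw, hw, length.out = n_points)
  dx <- x[2] - x[1]
  v <- dist_pdf(spec, x)
  edge_mass <- (v[1] + v[n_points]) * dx
  total <- sum(v) * dx
  if (edge_mass >= 1e-6 || abs(1 - total) >= 1e-4) {
    stop("truncation: density mass at the grid edges exceeds tolerance; ",
         "increase 'half_width_sigmas'", call. = FALSE)
  }
  grid_pdf(x0 = x[1], dx = dx, values = v / total)
}
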