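## Independent oracles used across the test files.  These deliberately avoid
## the package's grid/FFT code paths: densities and their derivatives are
## written out analytically and integrated with stats::integrate.

## Analytic density and derivative for the supported absolutely continuous
## kinds, as plain closures.
oracle_pdf_funs <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    gaussian = list(
      f = function(x) dnorm(x, 0, sqrt(p$var)),
      df = function(x) -x / p$var * dnorm(x, 0, sqrt(p$var))),
    laplace = list(
      f = function(x) exp(-abs(x) / p$b) / (2 * p$b),
      df = function(x) -sign(x) / p$b * exp(-abs(x) / p$b) / (2 * p$b)),
    double_gaussian = list(
      f = function(x) 0.5 * dnorm(x, -p$c, sqrt(p$s2)) +
        0.5 * dnorm(x, p$c, sqrt(p$s2)),
      df = function(x) 0.5 * (-(x + p$c) / p$s2) * dnorm(x, -p$c, sqrt(p$s2)) +
        0.5 * (-(x - p$c) / p$s2) * dnorm(x, p$c, sqrt(p$s2))),
    stop("no oracle for kind ", spec$kind)
  )
}

## Fisher information by adaptive quadrature of (f')^2 / f with analytic f'.
oracle_fisher <- function(spec, half_width = 12 * sqrt(spec$variance)) {
  fn <- oracle_pdf_funs(spec)
  integrate(function(x) fn$df(x)^2 / pmax(fn$f(x), 1e-300),
            -half_width, half_width, rel.tol = 1e-10,
            subdivisions = 2000L)$value
}

## Minimum-variance linear combination of two independent unbiased
## estimators with variances v1 and v2, found numerically.
oracle_min_var_weight <- function(v1, v2) {
  optimize(function(l) (1 - l)^2 * v1 + l^2 * v2, c(0, 1), tol = 1e-12)
}

## Direct O(n^2) evaluation of the grid-algorithm likelihood
## L(z) = sum_s f_y(s) g(d - z + s) ds  on the observer's lattice.
oracle_grid_likelihood <- function(mem_y, d, noise_fun, z) {
  s <- mem_y$x0 + (seq_along(mem_y$values) - 1) * mem_y$dx
  vapply(z, function(zz) sum(mem_y$values * noise_fun(d - zz + s)) * mem_y$dx,
         numeric(1))
}

grid_xs <- function(g) g$x0 + (seq_along(g$values) - 1) * g$dx
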