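#' Fisher information of a gridded density
#'
#' Computes the Fisher information of the translation family generated by
#' a density `f`, `J = integral (f'(x))^2 / f(x) dx`, by central
#' differences on the tabulation grid plus quadrature.  The density is
#' floored at 1e-300 inside the quotient so that regions of vanishing
#' density do not blow up the division.  For a translation family the
#' Fisher information is parameter-free and lower-bounds the variance of
#' any unbiased location estimator via the Cramer-Rao inequality
#' `Var >= 1/J`.
#'
#' @param pdf A [grid_pdf()] object (or a [make_distribution()] spec,
#'   which is tabulated with default settings first).
#' @return Non-negative scalar `J` (units position^-2).
#' @examples
#' g <- tabulate_pdf(make_distribution("gaussian", var = 2))
#' fisher_information(g)  # ~ 0.5
#' @export
fisher_information <- function(pdf) {
  if (is_dist_spec(pdf)) pdf <- tabulate_pdf(pdf)
  if (!inherits(pdf, "grid_pdf")) {
    stop("expected a 'grid_pdf' or 'dist_spec' object", call. = FALSE)
  }
  v <- pdf$values
  n <- length(v)
  if ((v[1] + v[n]) * pdf$dx >= 1e-6) {
    stop("truncation: edge mass exceeds 1e-6; widen the tabulation support",
         call. = FALSE)
  }
  i <- 2:(n - 1)
  deriv <- (v[i + 1] - v[i - 1]) / (2 * pdf$dx)
  sum(deriv^2 / pmax(v[i], 1e-300)) * pdf$dx
}

#' Fisher-deviation of a distribution
#'
#' The Fisher-deviation of a density is its variance multiplied by its
#' translation-family Fisher information.  By the Cramer-Rao bound it is
#' at least 1 for any distribution, with equality exactly for Gaussians;
#' it measures how much better than "Gaussian of the same variance" a
#' density localises a translation parameter.
#'
#' Closed forms are used when available (Gaussian: 1; Laplace: 2);
#' otherwise the spec is tabulated and the Fisher information computed
#' numerically.
#'
#' @param spec A [make_distribution()] object with finite positive
#'   variance.
#' @return Dimensionless scalar >= 1.
#' @export
fisher_deviation <- function(spec) {
  stopifnot_spec(spec)
  if (spec$variance <= 0) {
    stop("Fisher-deviation requires positive variance", call. = FALSE)
  }
  J <- if (!is.na(spec$closed_form_fisher)) spec$closed_form_fisher
       else fisher_information(tabulate_pdf(spec))
  spec$variance * J
}

#' Initial Fisher-deviation of a simulation setting
#'
#' The supremum of the Fisher-deviations over all distributions involved
#' in a run: the per-agent initial-position distributions and the
#' measurement-noise distribution.  This constant bounds the
#' competitiveness of the confidence-sharing rule against the
#' unrestricted Bayes-optimal algorithm; it equals 1 when everything is
#' Gaussian.
#'
#' @param initial_specs Non-empty list of [make_distribution()] objects
#'   (a single spec is accepted).
#' @param noise_spec The measurement-noise [make_distribution()] object;
#'   a zero-variance (point-mass) noise contributes 1 (the noiseless
#'   channel adds no deviation).
#' @return Scalar >= 1.
#' @export
initial_fisher_deviation <- function(initial_specs, noise_spec) {
  if (is_dist_spec(initial_specs)) initial_specs <- list(initial_specs)
  if (!is.list(initial_specs) || length(initial_specs) == 0L) {
    stop("'initial_specs' must be a non-empty list of dist_spec objects",
         call. = FALSE)
  }
  stopifnot_spec(noise_spec)
  devs <- vapply(initial_specs, fisher_deviation, numeric(1))
  noise_dev <- if (noise_spec$variance > 0) fisher_deviation(noise_spec) else 1
  max(c(devs, noise_dev))
}

#' Fisher channel capacity of a measurement channel
#'
#' The Fisher channel capacity `C` is the Fisher information of the
#' measurement-noise distribution.  It caps the relative Fisher
#' information an observer can gain from a single passive observation,
#' for any algorithm and any level of noise in active communication, and
#' is therefore a property of the information channel itself.
#'
#' @param noise_spec A [make_distribution()] object describing the
#'   passive measurement noise.  Zero variance (point mass) yields an
#'   infinite capacity (noiseless channel), not an error.
#' @return An object of class `capacity_bound` with elements `C` and
#'   `noiseless`.
#' @examples
#' channel_capacity(make_distribution("gaussian", var = 0.25))  # C = 4
#' @export
channel_capacity <- function(noise_spec) {
  stopifnot_spec(noise_spec)
  if (noise_spec$variance == 0) {
    C <- Inf
  } else if (!is.na(noise_spec$closed_form_fisher)) {
    C <- noise_spec$closed_form_fisher
  } else {
    C <- fisher_information(tabulate_pdf(noise_spec))
  }
  structure(list(C = C, noiseless = !is.finite(C)), class = "capacity_bound")
}

#' @export
print.capacity_bound <- function(x, ...) {
  cat("<capacity_bound> C = ",
      if (x$noiseless) "Inf (noiseless channel)" else format(x$C),
      "\n", sep = "")
  invisible(x)
}

as_capacity <- function(cap) {
  if (inherits(cap, "capacity_bound")) return(cap)
  if (is_dist_spec(cap)) return(channel_capacity(cap))
  if (is.numeric(cap) && length(cap) == 1L && cap > 0) {
    return(structure(list(C = cap, noiseless = !is.finite(cap)),
                     class = "capacity_bound"))
  }
  stop("expected a 'capacity_bound', a noise 'dist_spec', or a positive ",
       "scalar capacity", call. = FALSE)
}

#' Per-interaction information-gain bound
#'
#' The maximal admissible increase of an observer's relative Fisher
#' information from a single observation of a partner: the observer can
#' obtain neither more information than the partner holds nor a
#' measurement more precise than the channel allows, so the gain is
#' capped at `min(J_partner, C)`.
#'
#' @param J_partner Partner's relative Fisher information (>= 0).
#' @param cap A [channel_capacity()] object (or a noise spec / scalar
#'   capacity).
#' @return Scalar bound on the information gain.
#' @export
info_gain_bound <- function(J_partner, cap) {
  if (!is.numeric(J_partner) || anyNA(J_partner) || any(J_partner < 0)) {
    stop("'J_partner' must be non-negative", call. = FALSE)
  }
  cap <- as_capacity(cap)
  pmin(J_partner, cap$C)
}

#' Lower bound on collective convergence time
#'
#' For the population to converge into a window of half-width `eps`
#' around the target, the typical agent's estimator variance must be of
#' order `eps^2`, hence (Cramer-Rao) its Fisher information must exceed
#' `1/eps^2`.  Since one observation gains at most the channel capacity
#' `C`, a typical agent starting from the median initial information
#' `J_median_init` needs at least `(1/eps^2 - J_median_init)/C`
#' observations.
#'
#' With a noiseless channel (infinite capacity) the additive-capacity
#' argument is vacuous and the per-round doubling bound is returned
#' instead: [noiseless_doubling_bound()] with target information
#' `1/eps^2`.
#'
#' @param target_halfwidth Convergence window half-width `eps` (> 0).
#' @param J_median_init Median initial Fisher information over agents
#'   (> 0 for the noiseless fallback).
#' @param cap A [channel_capacity()] object (or noise spec / scalar).
#' @return Non-negative scalar: minimum number of observations per
#'   typical agent (rounds, when each agent observes once per round).
#' @export
convergence_time_lower_bound <- function(target_halfwidth, J_median_init,
                                         cap) {
  if (!is.numeric(target_halfwidth) || length(target_halfwidth) != 1L ||
      target_halfwidth <= 0) {
    stop("'target_halfwidth' must be > 0", call. = FALSE)
  }
  cap <- as_capacity(cap)
  target_J <- 1 / target_halfwidth^2
  if (cap$noiseless) {
    if (target_J <= J_median_init) return(0)
    return(noiseless_doubling_bound(target_J, J_median_init))
  }
  max(0, (target_J - J_median_init) / cap$C)
}

#' Doubling bound on rounds in the noiseless scenario
#'
#' In a noiseless round-based schedule the additivity of Fisher
#' information implies that the maximum Fisher information over all
#' agents can grow by at most a factor of 2 per round (an observer can at
#' best add its partner's full information to its own).  Reaching a
#' target information `target_J` from a maximal initial information
#' `J_max_init` therefore takes at least `log2(target_J / J_max_init)`
#' rounds.
#'
#' @param target_J Target Fisher information (>= `J_max_init`; smaller
#'   values return 0).
#' @param J_max_init Maximal initial Fisher information over agents
#'   (> 0).
#' @return Non-negative scalar lower bound on the number of rounds.
#' @export
noiseless_doubling_bound <- function(target_J, J_max_init) {
  if (!is.numeric(J_max_init) || length(J_max_init) != 1L ||
      J_max_init <= 0) {
    stop("'J_max_init' must be > 0", call. = FALSE)
  }
  if (!is.numeric(target_J) || length(target_J) != 1L || target_J < 0) {
    stop("'target_J' must be >= 0", call. = FALSE)
  }
  if (target_J <= J_max_init) return(0)
  log2(target_J / J_max_init)
}

#' Fisher report for a distribution
#'
#' Bundles the Fisher information, variance and Fisher-deviation of a
#' distribution into one record (serialisable as JSON by the CLI).
#'
#' @param spec A [make_distribution()] object with positive variance.
#' @return An object of class `fisher_report`: list with `J`, `variance`,
#'   `fisher_deviation`.
#' @export
fisher_report <- function(spec) {
  stopifnot_spec(spec)
  dev <- fisher_deviation(spec)
  structure(list(J = dev / spec$variance, variance = spec$variance,
                 fisher_deviation = dev),
            class = "fisher_report")
}

#' @export
print.fisher_report <- function(x, ...) {
  cat("<fisher_report> J = ", format(x$J),
      ", variance = ", format(x$variance),
      ", Fisher-deviation = ", format(x$fisher_deviation), "\n", sep = "")
  invisible(x)
}
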