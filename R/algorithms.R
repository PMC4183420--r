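#' Confidence-sharing interaction update
#'
#' The compact confidence-sharing rule.  Each agent stores a single
#' confidence scalar `w`, maintained as the reciprocal of its estimator
#' variance.  On observing a partner, the observer receives the noisy
#' relative-distance measurement `d = X_y - X_x + eta` (passive) and the
#' partner's confidence `w_y` (active), forms the effective observation
#' weight
#' `w_obs = w_y / (1 + noise_var * w_y)`
#' (the inverse variance of `X_x + d` as an estimator of the target),
#' and fuses by inverse-variance weighted averaging:
#' `delta = d * w_obs / (w_x + w_obs)`, `w_new = w_x + w_obs`.
#'
#' If the observer's error and the effective observation's error are
#' independent and unbiased, the updated position is again unbiased with
#' variance exactly `1 / w_new`, which is what keeps the confidence
#' calibrated round after round.  An infinitely confident partner yields
#' `w_obs = 1 / noise_var` (the channel capacity); a zero-confidence
#' partner is ignored.
#'
#' All arguments are vectorised.
#'
#' @param w_x Observer confidence (>= 0; may be `Inf`).
#' @param d Measured relative distance to the partner (sign convention
#'   `d = X_y - X_x + eta`).
#' @param noise_var Variance of the passive measurement noise (>= 0).
#' @param w_y Partner confidence from the active message (>= 0; may be
#'   `Inf`).
#' @return List with `delta` (position change of the observer) and
#'   `w_new` (updated confidence).
#' @examples
#' conf_update(w_x = 1, d = 1, noise_var = 0, w_y = 1)  # delta 0.5, w 2
#' @export
conf_update <- function(w_x, d, noise_var, w_y) {
  if (anyNA(w_x) || anyNA(w_y) || anyNA(noise_var) ||
      any(w_x < 0) || any(w_y < 0) || any(noise_var < 0)) {
    stop("confidences and noise variance must be non-negative", call. = FALSE)
  }
  if (any(is.infinite(w_x) & is.infinite(w_y) & noise_var == 0)) {
    stop("two infinitely confident agents over a noiseless channel are ",
         "degenerate", call. = FALSE)
  }
  w_obs <- conf_obs_weight(w_y, noise_var)
  wt <- w_x + w_obs
  frac <- ifelse(is.infinite(w_obs), 1,
          ifelse(is.infinite(w_x), 0,
          ifelse(wt > 0, w_obs / wt, 0)))
  list(delta = d * frac, w_new = wt)
}

## Effective observation weight: inverse variance of (partner position +
## measurement noise) as seen by the observer.
conf_obs_weight <- function(w_y, noise_var) {
  n <- max(length(w_y), length(noise_var))
  w_y <- rep_len(w_y, n)
  nv <- rep_len(noise_var, n)
  out <- ifelse(nv > 0, w_y / (1 + nv * w_y), w_y)
  inf <- is.infinite(w_y)
  out[inf] <- ifelse(nv[inf] > 0, 1 / nv[inf], Inf)
  out
}

#' Closed-form Gaussian Bayes-optimal update
#'
#' Exact Bayesian update for a Gaussian prior on the observer's error
#' (variance `var_x`) and a Gaussian observation of the target with
#' variance `var_y + noise_var`.  Algebraically identical to
#' [conf_update()] under `w = 1/var`; it serves as the closed-form oracle
#' for the grid algorithm and establishes the optimality of the
#' confidence-sharing rule in the all-Gaussian case.
#'
#' @param var_x Observer estimator variance (> 0).
#' @param d Measured relative distance (`d = X_y - X_x + eta`).
#' @param noise_var Measurement-noise variance (>= 0).
#' @param var_y Partner estimator variance (>= 0).
#' @return List with `delta` and `var_new`.
#' @export
opt_update_gaussian <- function(var_x, d, noise_var, var_y) {
  if (anyNA(var_x) || any(var_x <= 0)) {
    stop("'var_x' must be > 0", call. = FALSE)
  }
  if (anyNA(var_y) || any(var_y < 0) || anyNA(noise_var) ||
      any(noise_var < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  obs_var <- var_y + noise_var
  if (any(obs_var == 0 & var_x == 0)) {
    stop("degenerate: both prior and observation have zero variance",
         call. = FALSE)
  }
  frac <- ifelse(is.infinite(obs_var), 0, var_x / (var_x + obs_var))
  var_new <- ifelse(is.infinite(obs_var), var_x,
                    var_x * obs_var / (var_x + obs_var))
  list(delta = d * frac, var_new = var_new)
}

#' Bayes-optimal update on gridded densities
#'
#' One interaction of the unrestricted optimal algorithm.  The observer
#' maintains a gridded pdf `f_x(z)` of the target's position relative to
#' itself; the partner's pdf `f_y` and the measurement `d` define the
#' likelihood
#' `L(z) = integral f_y(s) g(d - z + s) ds`
#' (cross-correlation of the partner density with the noise density `g`,
#' shifted by `d`; `g` is a point mass when the channel is noiseless).
#' The posterior is `f'(z) proportional to f_x(z) L(z)`, the observer
#' moves by the posterior mean, and the stored pdf is re-centred by the
#' move so that its mean returns to 0.
#'
#' The cross-correlation is computed by FFT with zero padding to at
#' least twice the grid length (no circular aliasing), and `L` is
#' evaluated at `z - d` by linear interpolation.
#'
#' @param mem_x Observer memory, a [grid_pdf()].
#' @param mem_y Partner memory, a [grid_pdf()] on the same lattice.
#' @param d Measured relative distance (`d = X_y - X_x + eta`).
#' @param noise_pdf Noise density as a [grid_pdf()] with the same
#'   spacing, or `NULL` for a noiseless channel.
#' @return List with `delta` (move of the observer) and `mem_new` (the
#'   re-centred posterior [grid_pdf()]).
#' @export
opt_update_grid <- function(mem_x, mem_y, d, noise_pdf = NULL) {
  if (!inherits(mem_x, "grid_pdf") || !inherits(mem_y, "grid_pdf")) {
    stop("memories must be 'grid_pdf' objects", call. = FALSE)
  }
  if (!same_lattice(mem_x, mem_y)) {
    stop("incompatible grids: memories must share x0, dx and length",
         call. = FALSE)
  }
  z <- grid_x(mem_x)
  if (is.null(noise_pdf)) {
    lik <- grid_interp(mem_y, z - d)
  } else {
    if (!inherits(noise_pdf, "grid_pdf") ||
        !isTRUE(all.equal(noise_pdf$dx, mem_x$dx, tolerance = 1e-12))) {
      stop("incompatible grids: 'noise_pdf' must use the same spacing",
           call. = FALSE)
    }
    cc <- grid_crosscor(mem_y, noise_pdf)
    ## L(z) = cc evaluated at u = z - d
    lik <- grid_interp(cc, z - d)
  }
  post <- mem_x$values * lik
  total <- sum(post) * mem_x$dx
  if (!is.finite(total) || total <= 1e-300) {
    stop("degenerate posterior: the product of prior and likelihood has ",
         "no mass on the grid", call. = FALSE)
  }
  post <- post / total
  delta <- sum(z * post) * mem_x$dx
  mem_new <- grid_shift(grid_pdf(mem_x$x0, mem_x$dx, post, normalize = TRUE),
                        delta)
  list(delta = delta, mem_new = mem_new)
}

## Cross-correlation c(u) = integral f(s) g(s - u) ds on the common lattice,
## returned as an (unnormalised) grid object spanning all lags.
## Computed by FFT with zero padding to >= 2x length.
grid_crosscor <- function(f, g) {
  nf <- length(f$values)
  ng <- length(g$values)
  m <- stats::nextn(nf + ng, 2)
  F <- stats::fft(c(f$values, rep(0, m - nf)))
  G <- stats::fft(c(g$values, rep(0, m - ng)))
  cc <- Re(stats::fft(F * Conj(G), inverse = TRUE)) / m * f$dx
  ## lag k = j_f - j_g ranges over -(ng-1) .. (nf-1); negative lags wrap to
  ## the tail of the padded circular correlation
  lags <- c(0:(nf - 1), -(ng - 1):-1)
  vals <- cc[c(seq_len(nf), (m - ng + 2):m)]
  ord <- order(lags)
  u0 <- f$x0 - g$x0 + min(lags) * f$dx
  structure(list(x0 = u0, dx = f$dx, values = pmax(vals[ord], 0)),
            class = "grid_pdf")
}

#' Constant linear-combination (passive-only) update
#'
#' The memoryless rule `delta = alpha * d`: the observer moves a constant
#' fraction of the measured relative distance, ignoring any internal
#' state.  `alpha = 0.5` is the simple-average algorithm; `alpha = 0`
#' ignores social information.  These rules exhibit a speed-accuracy
#' tradeoff: convergence on a timescale ~ `1/alpha` to a steady-state
#' variance ~ `alpha * sigma^2` (see [linear_steady_state_variance()]).
#'
#' @param d Measured relative distance.
#' @param alpha Constant combination weight in `[0, 1]`.
#' @return Position change `alpha * d`.
#' @export
linear_update <- function(d, alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0) ||
      any(alpha > 1)) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  alpha * d
}

#' Mean-field steady-state variance of the constant linear rule
#'
#' Fixed point of the variance recursion
#' `V' = (1-alpha)^2 V + alpha^2 (V + sigma2)` for a fully mixed
#' population: `V* = alpha * sigma2 / (2 (1 - alpha))`.  With a finite
#' population of `n` agents the exact fixed point of the pair-moment
#' recursion carries an O(1/n) correction,
#' `V*_n = alpha^2 sigma2 / (2 alpha (1-alpha) (1 + 1/(n-1)) +
#' alpha^2 (n-2)/(n-1)^2)`,
#' which is returned when `n` is supplied.
#'
#' @param alpha Combination weight in `(0, 1)`.
#' @param sigma2 Measurement-noise variance.
#' @param n Optional population size for the finite-population fixed
#'   point; `Inf` (default) gives the mean-field value.
#' @return Steady-state within-population variance.
#' @export
linear_steady_state_variance <- function(alpha, sigma2, n = Inf) {
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (is.infinite(n)) return(alpha * sigma2 / (2 * (1 - alpha)))
  den <- 2 * alpha * (1 - alpha) * (1 + 1 / (n - 1)) +
    alpha^2 * (n - 2) / (n - 1)^2
  alpha^2 * sigma2 / den
}

#' Noisy transmission of a confidence value
#'
#' Active communication noise applied to a transmitted confidence:
#' multiplicative Gaussian, zero-truncated to preserve the
#' non-negativity of confidence.  The received value is
#' `w * max(0, xi)` with `xi ~ Normal(1, noise_sd^2)`.
#'
#' @param w Transmitted confidence value(s) (>= 0).
#' @param noise_sd Standard deviation of the multiplicative term
#'   (>= 0; 0 is the identity).
#' @return Received confidence value(s), >= 0.
#' @export
transmit_confidence <- function(w, noise_sd) {
  if (anyNA(w) || any(w < 0)) stop("'w' must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || anyNA(noise_sd) || any(noise_sd < 0)) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  if (all(noise_sd == 0)) return(w)
  xi <- pmax(0, stats::rnorm(length(w), 1, noise_sd))
  w * xi
}

#' Confidence update with an obsolescence bit (dynamic environments)
#'
#' Extension of the confidence-sharing rule for environments whose
#' target value can change.  Each agent carries one extra bit that is on
#' while the agent holds fresh information (it is set when the agent is
#' updated by a fresh source and expires after an obsolescence horizon).
#' When the observer's own bit is off and the partner's bit is on, the
#' observer discards its stale confidence (resets `w_x` to its initial
#' value) before fusing, then turns its own bit on.  When the observer's
#' bit is on and the partner's is off, the partner's information predates
#' the last environmental change and is ignored entirely: without this
#' rule the enormous confidence accumulated before a change would drag
#' freshly updated agents back towards the obsolete target.  When both
#' bits agree the update is exactly [conf_update()] (in particular, in a
#' stable environment all bits are off and the rule coincides with plain
#' confidence sharing).  Bit expiry against the horizon is the caller's
#' (the engine's) responsibility: pass `bit_y = FALSE` for a partner
#' whose bit has aged beyond the horizon.
#'
#' @param w_x Observer confidence.
#' @param d Measured relative distance.
#' @param noise_var Measurement-noise variance.
#' @param w_y Partner confidence.
#' @param bit_x Observer freshness bit (logical).
#' @param bit_y Partner freshness bit (logical, already expired by the
#'   caller if stale).
#' @param w_reset Confidence the observer falls back to when discarding
#'   stale information (its configured initial confidence).
#' @return List with `delta`, `w_new`, `bit_new`.
#' @export
conf_update_dynamic <- function(w_x, d, noise_var, w_y, bit_x, bit_y,
                                w_reset) {
  adopt <- bit_y & !bit_x
  ignore <- bit_x & !bit_y
  w_eff <- ifelse(adopt, w_reset, w_x)
  up <- conf_update(w_eff, d, noise_var, w_y)
  list(delta = ifelse(ignore, 0, up$delta),
       w_new = ifelse(ignore, w_x, up$w_new),
       bit_new = bit_x | bit_y)
}

#' Correlation-corrected fusion of two estimators
#'
#' Optimal linear fusion of two unbiased estimators whose errors have
#' variances `var_x`, `var_obs` and correlation `rho`: the weight on the
#' observation is
#' `lambda = (var_x - rho sqrt(var_x var_obs)) /
#'           (var_x + var_obs - 2 rho sqrt(var_x var_obs))`,
#' clipped to `[0, 1]`, and the fused variance is evaluated at the
#' applied weight (which equals
#' `var_x var_obs (1 - rho^2) / (var_x + var_obs - 2 rho sqrt(...))`
#' whenever the optimum is interior).  With `rho = 0` this reduces
#' exactly to inverse-variance weighting; with `rho` near 1 and equal
#' variances the fused variance barely improves, so confidence only
#' marginally increases between agents holding highly correlated
#' information -- the property that prevents over-confidence build-up.
#'
#' @param var_x Observer estimator variance (> 0).
#' @param var_obs Effective observation variance, partner variance plus
#'   measurement-noise variance (> 0).
#' @param rho Correlation of the two estimators' errors, in `(-1, 1)`.
#' @param d Measured relative distance.
#' @return List with `delta` (= `lambda * d`), `var_new`, and `lambda`.
#' @examples
#' correlation_corrected_fusion(1, 1, 0.5, d = 1)$var_new  # 0.75
#' @export
correlation_corrected_fusion <- function(var_x, var_obs, rho, d) {
  if (anyNA(var_x) || anyNA(var_obs) || any(var_x <= 0) ||
      any(var_obs <= 0)) {
    stop("variances must be > 0", call. = FALSE)
  }
  if (anyNA(rho) || any(abs(rho) >= 1)) {
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  }
  cv <- rho * sqrt(var_x * var_obs)
  den <- var_x + var_obs - 2 * cv
  lambda <- ifelse(den <= 1e-15, 0, (var_x - cv) / den)
  lambda <- pmin(1, pmax(0, lambda))
  var_new <- (1 - lambda)^2 * var_x + lambda^2 * var_obs +
    2 * lambda * (1 - lambda) * cv
  list(delta = lambda * d, var_new = var_new, lambda = lambda)
}

#' Biased distance perception
#'
#' In a heterogeneous population each individual perceives relative
#' distance with its own multiplicative bias: a 1.5-biased individual
#' measures a distance to be 1.5 times larger than it actually is, a
#' 1/3-biased individual perceives distances smaller by a factor of 3.
#' Bias 1 is the unbiased agent.
#'
#' @param d_true True relative distance.
#' @param bias Multiplicative perception bias (> 0).
#' @return Perceived distance `bias * d_true`.
#' @export
perceive <- function(d_true, bias) {
  if (anyNA(bias) || any(bias <= 0)) {
    stop("'bias' must be > 0", call. = FALSE)
  }
  bias * d_true
}
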