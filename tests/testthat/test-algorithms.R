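test_that("conf_update fuses by inverse variance and keeps w = 1/Var", {
  ## symmetric noiseless fusion halves the gap and doubles confidence
  up <- conf_update(1, 1, 0, 1)
  expect_equal(up$delta, 0.5)
  expect_equal(up$w_new, 2)
  ## infinitely confident partner through a noisy channel: w_obs = 1/sigma^2
  up <- conf_update(1, 2, 1, Inf)
  expect_equal(up$delta, 1)
  expect_equal(up$w_new, 2)
  ## uninformative partner is ignored
  up <- conf_update(1, 5, 1, 0)
  expect_equal(up$delta, 0)
  expect_equal(up$w_new, 1)
  ## no information at all: not an error
  up <- conf_update(0, 3, 1, 0)
  expect_equal(up$delta, 0)
  expect_equal(up$w_new, 0)
  expect_error(conf_update(-1, 0, 1, 1), "non-negative")
  expect_error(conf_update(Inf, 0, 0, Inf), "degenerate")
})

test_that("conf_update matches the brute-force minimum-variance combiner", {
  set.seed(101)
  for (i in 1:50) {
    w_x <- rexp(1)
    w_y <- rexp(1)
    s2 <- rexp(1)
    up <- conf_update(w_x, 1, s2, w_y)
    lam <- up$delta  ## d = 1, so delta is the weight on the observation
    o <- oracle_min_var_weight(1 / w_x, 1 / w_y + s2)
    expect_equal(lam, o$minimum, tolerance = 1e-6)
    expect_equal(1 / up$w_new, o$objective, tolerance = 1e-9)
  }
})

test_that("conf_update confidence is monotone in its inputs", {
  set.seed(11)
  for (i in 1:200) {
    w_x <- rexp(1); w_y <- rexp(1); s2 <- rexp(1)
    base <- conf_update(w_x, 1, s2, w_y)$w_new
    expect_gte(conf_update(w_x + 0.5, 1, s2, w_y)$w_new, base)
    expect_gte(conf_update(w_x, 1, s2, w_y + 0.5)$w_new, base)
    expect_lte(conf_update(w_x, 1, s2 + 0.5, w_y)$w_new, base)
    ## confidence never decreases across an interaction
    expect_gte(base, w_x)
  }
})

test_that("opt_update_gaussian is the conjugate-Gaussian posterior and equals conf_update", {
  up <- opt_update_gaussian(1, 0, 1, 1)
  expect_equal(up$delta, 0)
  expect_equal(up$var_new, 2 / 3)
  up <- opt_update_gaussian(1, 1, 0, 1)
  expect_equal(up$delta, 0.5)
  expect_equal(up$var_new, 0.5)
  set.seed(3)
  for (i in 1:1000) {
    vx <- rexp(1) + 1e-3; vy <- rexp(1); s2 <- rexp(1); d <- rnorm(1)
    a <- opt_update_gaussian(vx, d, s2, vy)
    b <- conf_update(1 / vx, d, s2, 1 / vy)
    expect_equal(a$delta, b$delta, tolerance = 1e-12)
    expect_equal(1 / a$var_new, b$w_new, tolerance = 1e-12)
  }
})

make_lattice <- function(hw, n = 2048) {
  x <- seq(-hw, hw, length.out = n)
  list(x = x, dx = x[2] - x[1])
}

lattice_pdf <- function(spec, lat) {
  grid_pdf(lat$x[1], lat$dx, dist_pdf(spec, lat$x), normalize = TRUE)
}

lattice_noise <- function(spec, dx, hw_sigmas = 8) {
  K <- ceiling(hw_sigmas * sqrt(spec$variance) / dx)
  xn <- seq(-K, K) * dx
  grid_pdf(xn[1], dx, dist_pdf(spec, xn), normalize = TRUE)
}

test_that("opt_update_grid agrees with the closed-form Gaussian update", {
  lat <- make_lattice(10)
  gx <- lattice_pdf(make_distribution("gaussian", var = 1), lat)
  ng <- lattice_noise(make_distribution("gaussian", var = 1), lat$dx)
  up <- opt_update_grid(gx, gx, d = 0, noise_pdf = ng)
  expect_equal(up$delta, 0, tolerance = 1e-9)
  expect_equal(grid_moments(up$mem_new)[["var"]], 2 / 3, tolerance = 1e-3)
  ## noiseless product of equal Gaussians
  up <- opt_update_grid(gx, gx, d = 0, noise_pdf = NULL)
  expect_equal(grid_moments(up$mem_new)[["var"]], 0.5, tolerance = 1e-3)
  ## re-centering contract: posterior mean returns to 0
  up <- opt_update_grid(gx, gx, d = 0.8, noise_pdf = ng)
  expect_lt(abs(grid_moments(up$mem_new)[["mean"]]), up$mem_new$dx / 2)
})

test_that("the FFT cross-correlation matches a dense direct-summation oracle", {
  ## moderate lattice so the O(n^2) oracle stays affordable
  lat <- make_lattice(12, n = 512)
  gx <- lattice_pdf(make_distribution("gaussian", var = 1), lat)
  dgy <- lattice_pdf(make_distribution("double_gaussian", c = 1, s2 = 0.25),
                     lat)
  noise <- make_distribution("gaussian", var = 0.5)
  ng <- lattice_noise(noise, lat$dx)
  ## direct O(n^2) evaluation of the same discrete cross-correlation
  nf <- length(dgy$values)
  ngn <- length(ng$values)
  lags <- -(ngn - 1):(nf - 1)
  cc_direct <- vapply(lags, function(m) {
    j <- seq_len(nf)
    i <- j - m
    ok <- i >= 1 & i <= ngn
    sum(dgy$values[j[ok]] * ng$values[i[ok]]) * dgy$dx
  }, numeric(1))
  cc_fft <- confshare:::grid_crosscor(dgy, ng)
  expect_equal(length(cc_fft$values), length(cc_direct))
  expect_lt(max(abs(cc_fft$values - cc_direct)), 1e-10)
  expect_equal(cc_fft$x0, dgy$x0 - ng$x0 + min(lags) * dgy$dx)

  for (d in c(-0.7, 0.4, 1.3)) {
    ## posterior mean/variance through the FFT path vs through the oracle's
    ## cross-correlation, interpolated identically
    cc_o <- structure(list(x0 = cc_fft$x0, dx = cc_fft$dx,
                           values = cc_direct), class = "grid_pdf")
    L_direct <- confshare:::grid_interp(cc_o, grid_xs(gx) - d)
    up <- opt_update_grid(gx, dgy, d, ng)
    post <- gx$values * L_direct
    post <- post / (sum(post) * gx$dx)
    mu <- sum(grid_xs(gx) * post) * gx$dx
    expect_equal(up$delta, mu, tolerance = 1e-6)
    ## re-centre the oracle posterior exactly as the update does before
    ## comparing second moments
    mem_oracle <- confshare:::grid_shift(
      grid_pdf(gx$x0, gx$dx, post, normalize = TRUE), mu)
    expect_equal(grid_moments(up$mem_new)[["var"]],
                 grid_moments(mem_oracle)[["var"]], tolerance = 1e-6)
    ## and the discretisation itself is faithful to the analytic integral
    L_analytic <- oracle_grid_likelihood(dgy, d,
                                         function(x) dist_pdf(noise, x),
                                         grid_xs(gx))
    expect_lt(max(abs(L_direct - L_analytic)), 1e-4)
  }
})

test_that("compressing a bimodal partner to its moments loses information", {
  ## drawing measurements from the generative model, the full bimodal pdf of
  ## the partner yields a lower expected posterior variance than its
  ## variance-matched Gaussian compression
  lat <- make_lattice(12, n = 1024)
  dg_spec <- make_distribution("double_gaussian", c = 1, s2 = 0.25)
  gx <- lattice_pdf(make_distribution("gaussian", var = 1), lat)
  dgy <- lattice_pdf(dg_spec, lat)
  gy <- lattice_pdf(make_distribution("gaussian", var = 1.25), lat)
  noise <- make_distribution("gaussian", var = 0.25)
  ng <- lattice_noise(noise, lat$dx)
  set.seed(33)
  v_full <- v_compressed <- numeric(60)
  for (i in seq_along(v_full)) {
    z <- rnorm(1)                       ## true target relative to observer
    e_y <- dist_sample(dg_spec, 1)      ## partner's error
    d <- z - e_y + dist_sample(noise, 1)
    v_full[i] <- grid_moments(opt_update_grid(gx, dgy, d, ng)$mem_new)[["var"]]
    v_compressed[i] <-
      grid_moments(opt_update_grid(gx, gy, d, ng)$mem_new)[["var"]]
  }
  expect_lt(mean(v_full), mean(v_compressed))
})

test_that("opt_update_grid rejects incompatible grids and degenerate posteriors", {
  lat <- make_lattice(10)
  lat2 <- make_lattice(11)
  gx <- lattice_pdf(make_distribution("gaussian", var = 1), lat)
  gz <- lattice_pdf(make_distribution("gaussian", var = 1), lat2)
  expect_error(opt_update_grid(gx, gz, 0), "incompatible")
  ## noiseless likelihood far outside the prior's support
  expect_error(opt_update_grid(gx, gx, d = 50, noise_pdf = NULL),
               "degenerate posterior")
})

test_that("linear_update is the constant combination rule", {
  expect_equal(linear_update(2, 0.5), 1)
  expect_equal(linear_update(7, 0), 0)
  expect_error(linear_update(1, 1.5), "\\[0, 1\\]")
  expect_error(linear_update(1, -0.1), "\\[0, 1\\]")
})

test_that("transmit_confidence is multiplicative, zero-truncated, unbiased", {
  expect_identical(transmit_confidence(3, 0), 3)
  set.seed(5)
  expect_equal(transmit_confidence(0, 0.5), 0)
  draws <- transmit_confidence(rep(1, 1e5), 0.2)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 1, tolerance = 4 * 0.2 / sqrt(1e5))
})

test_that("the obsolescence-bit rule reduces to conf_update in stable environments", {
  set.seed(8)
  for (i in 1:20) {
    w_x <- rexp(1); w_y <- rexp(1); d <- rnorm(1); s2 <- rexp(1)
    a <- conf_update_dynamic(w_x, d, s2, w_y, bit_x = FALSE, bit_y = FALSE,
                             w_reset = 1)
    b <- conf_update(w_x, d, s2, w_y)
    expect_equal(a$delta, b$delta)
    expect_equal(a$w_new, b$w_new)
    expect_false(a$bit_new)
  }
  ## fresh observer ignores a stale partner entirely
  a <- conf_update_dynamic(2, 1, 0, 1e6, bit_x = TRUE, bit_y = FALSE,
                           w_reset = 1)
  expect_equal(a$delta, 0)
  expect_equal(a$w_new, 2)
  expect_true(a$bit_new)
  ## stale observer adopts: confidence resets before fusing
  a <- conf_update_dynamic(1e6, 1, 0, 10, bit_x = FALSE, bit_y = TRUE,
                           w_reset = 1)
  expect_equal(a$w_new, 11)
  expect_equal(a$delta, 10 / 11)
  expect_true(a$bit_new)
})

test_that("correlation-corrected fusion is optimal for correlated estimators", {
  ## rho = 0 reduces exactly to inverse-variance weighting
  f <- correlation_corrected_fusion(1, 2, 0, 1)
  expect_equal(f$lambda, 1 / 3)
  expect_equal(f$var_new, 2 / 3)
  ## printed example: equal variances, rho = 0.5
  expect_equal(correlation_corrected_fusion(1, 1, 0.5, 1)$var_new, 0.75)
  ## fully redundant information: essentially no gain
  f <- correlation_corrected_fusion(1, 1, 0.999, 1)
  expect_equal(f$lambda, 0.5)
  expect_equal(f$var_new, 0.9995)
  expect_error(correlation_corrected_fusion(1, 1, 1, 0), "rho")
  ## numerical minimiser cross-check on random draws
  set.seed(21)
  for (i in 1:100) {
    v1 <- rexp(1) + 0.05; v2 <- rexp(1) + 0.05; rho <- runif(1, -0.95, 0.95)
    f <- correlation_corrected_fusion(v1, v2, rho, 1)
    obj <- function(l) (1 - l)^2 * v1 + l^2 * v2 +
      2 * l * (1 - l) * rho * sqrt(v1 * v2)
    o <- optimize(obj, c(0, 1), tol = 1e-12)
    expect_equal(f$var_new, o$objective, tolerance = 1e-6)
    expect_lte(f$var_new, v1 + 1e-12)  ## fusing never hurts
  }
})

test_that("perceive applies the multiplicative perception bias", {
  expect_equal(perceive(2, 1.5), 3)
  expect_equal(perceive(3, 1 / 3), 1)
  expect_equal(perceive(-1.2, 1), -1.2)
  expect_error(perceive(1, 0), "bias")
})
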