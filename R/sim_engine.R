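#' Draw one round of pairwise interactions
#'
#' Returns the (observer, observed) pairs of a single interaction round
#' for a population of `n` agents under the given meeting pattern.
#' Self-pairing is impossible by construction.  `well_mixed` and
#' `oracle_independent` give every observer an independent uniform
#' partner; `round_robin_pairs` draws a random perfect matching in which
#' both members of a pair observe each other (one agent sits out when
#' `n` is odd); `hypercube` pairs agent `i` with `i XOR 2^((round-1) mod
#' log2 n)` deterministically.
#'
#' @param n Number of agents (>= 2).
#' @param pattern Meeting-pattern name, as in [sim_config()].
#' @param round Round number (only used by the deterministic hypercube
#'   schedule).
#' @param observers Indices of agents that act as observers (defaults to
#'   all; environment agents are excluded by the engine).
#' @return A data.frame with columns `observer` and `observed`.
#' @export
draw_pairs <- function(n, pattern = c("well_mixed", "oracle_independent",
                                      "round_robin_pairs", "hypercube"),
                       round = 1, observers = seq_len(n)) {
  pattern <- match.arg(pattern)
  if (n < 2) stop("need at least 2 agents", call. = FALSE)
  partner <- partner_indices(n, pattern, round)
  keep <- intersect(observers, which(!is.na(partner)))
  data.frame(observer = keep, observed = partner[keep])
}

## Partner index for every agent (NA = no interaction this round).
partner_indices <- function(n, pattern, round) {
  if (pattern %in% c("well_mixed", "oracle_independent")) {
    p <- sample.int(n - 1L, n, replace = TRUE)
    p + (p >= seq_len(n))
  } else if (pattern == "round_robin_pairs") {
    perm <- sample.int(n)
    partner <- rep(NA_integer_, n)
    k <- seq_len(n %/% 2L)
    partner[perm[2 * k - 1L]] <- perm[2 * k]
    partner[perm[2 * k]] <- perm[2 * k - 1L]
    partner
  } else {
    lg <- as.integer(round(log2(n)))
    bit <- bitwShiftL(1L, (round - 1L) %% lg)
    bitwXor(seq_len(n) - 1L, bit) + 1L
  }
}

#' Run a population simulation
#'
#' Initialises every agent's position by sampling its initial
#' distribution around the target, initialises memory per the configured
#' algorithm (confidence = the reciprocal of the agent's initial
#' variance), then iterates rounds of simultaneous pairwise interactions
#' under the configured meeting pattern, recording population metrics.
#' Fully reproducible from `cfg$seed`.
#'
#' Recorded metrics (averaged over replicates, mobile agents only):
#' \describe{
#'   \item{`population_mse`}{mean squared error of positions about the
#'     current target.}
#'   \item{`population_var`}{mean within-population variance about the
#'     replicate mean (the dispersion a drifting population settles to).}
#'   \item{`mean_confidence`, `max_confidence`}{moments of the stored
#'     confidence (for the grid algorithm, of the inverse variance of
#'     the stored pdf).}
#'   \item{`cr_bound`}{the Cramer-Rao benchmark variance where it is
#'     exactly computable: under `oracle_independent` the mean of `1/w`
#'     (the tracked inverse-variance recursion); in noiseless runs with
#'     identical initial specs the information-cone bound
#'     `1/(J0 min(n, 2^t))`; otherwise `NA`.}
#'   \item{`normalized_ratio`}{`population_mse / cr_bound`; 1 means the
#'     population attains the optimal variance.}
#' }
#'
#' @param cfg A [sim_config()] object.
#' @param keep_positions If `TRUE`, store the position matrix at every
#'   recorded round (for trajectory-level analyses).
#' @return An object of class `conf_sim`: list with `config`, `metrics`
#'   (data.frame as above), `final` (positions, confidences, target),
#'   `max_w_trace` (recorded-round x replicate matrix of the maximum
#'   confidence per replicate), and, when provenance is tracked,
#'   `interactions` (per-interaction information-gain audit log) and
#'   `provenance` (exact affine-coefficient snapshots for
#'   [audit_provenance()]).
#' @export
run_simulation <- function(cfg, keep_positions = FALSE) {
  if (!inherits(cfg, "sim_config")) {
    stop("expected a 'sim_config' object", call. = FALSE)
  }
  set.seed(cfg$seed)
  if (cfg$algorithm == "opt_grid") {
    return(run_simulation_grid(cfg, keep_positions))
  }
  run_simulation_linear(cfg, keep_positions)
}

record_rounds <- function(cfg) {
  r <- unique(c(0L, seq_len(cfg$rounds)[seq_len(cfg$rounds) %%
                                          cfg$record_every == 0L],
                cfg$rounds))
  sort(r)
}

## ---------------------------------------------------------------------------
## Linear-family engine: conf, opt_gaussian, linear, conf_dynamic,
## conf_corrected.  Vectorised across replicates; optional exact provenance.
## ---------------------------------------------------------------------------
run_simulation_linear <- function(cfg, keep_positions) {
  n_mob <- cfg$n_agents
  N <- n_mob + cfg$n_environment
  R <- cfg$replicates
  s2 <- cfg$noise_spec$variance
  theta <- cfg$target_theta
  alg <- cfg$algorithm
  conf_like <- alg %in% c("conf", "opt_gaussian", "conf_dynamic",
                          "conf_corrected")
  oracle <- cfg$meeting_pattern == "oracle_independent"
  prov_on <- cfg$track_provenance

  init_var <- vapply(cfg$initial_specs, function(s) s$variance, numeric(1))
  env_var <- cfg$env_spec$variance
  is_env <- c(rep(FALSE, n_mob), rep(TRUE, cfg$n_environment))
  mob <- which(!is_env)

  ## initial draws
  err <- matrix(0, R, N)
  for (j in seq_len(n_mob)) err[, j] <- dist_sample(cfg$initial_specs[[j]], R)
  if (cfg$n_environment > 0) {
    for (j in (n_mob + 1):N) err[, j] <- dist_sample(cfg$env_spec, R)
  }
  pos <- theta + err
  w0 <- c(1 / init_var, rep(if (env_var > 0) 1 / env_var else Inf,
                            cfg$n_environment))
  w <- matrix(rep(w0, each = R), R, N)
  bias_full <- c(cfg$bias, rep(1, cfg$n_environment))
  bits <- matrix(FALSE, R, N)
  btime <- matrix(-Inf, R, N)

  ## provenance state
  prov <- NULL
  interactions <- NULL
  if (prov_on) {
    B_max <- N + cfg$rounds * N * ((s2 > 0) + oracle) + 8L
    basis0 <- c(init_var, rep(env_var, cfg$n_environment))
    prov <- lapply(seq_len(R), function(r) {
      M <- matrix(0, N, B_max)
      M[cbind(seq_len(N), seq_len(N))] <- 1
      list(M = M, bvar = c(basis0, rep(0, B_max - N)),
           draws = c(err[r, ], rep(0, B_max - N)), bcount = N)
    })
    interactions <- vector("list", cfg$rounds)
  }
  prov_var <- function(p) {
    idx <- seq_len(p$bcount)
    (p$M[, idx, drop = FALSE]^2) %*% p$bvar[idx]
  }

  recs <- record_rounds(cfg)
  metrics <- vector("list", length(recs))
  max_w_trace <- matrix(NA_real_, length(recs), R)
  pos_trace <- if (keep_positions) vector("list", length(recs)) else NULL
  snapshots <- if (prov_on) vector("list", length(recs)) else NULL
  rec_i <- 0L

  record_state <- function(t) {
    pm <- pos[, mob, drop = FALSE]
    mse <- mean((pm - theta)^2)
    pv <- mean(apply(pm, 1, stats::var))
    if (conf_like) {
      wm <- w[, mob, drop = FALSE]
      mean_c <- mean(wm[is.finite(wm)])
      max_c <- max(wm)
    } else {
      mean_c <- NA_real_
      max_c <- NA_real_
    }
    cr <- NA_real_
    if (conf_like && oracle) {
      cr <- mean(1 / w[, mob, drop = FALSE])
    } else if (conf_like && s2 == 0 && cfg$n_environment == 0 &&
               length(unique(init_var)) == 1L) {
      J0 <- fisher_deviation(cfg$initial_specs[[1]]) / init_var[1]
      cr <- 1 / (J0 * min(n_mob, 2^t))
    }
    list(round = t, population_mse = mse, population_var = pv,
         mean_confidence = mean_c, max_confidence = max_c,
         cr_bound = cr,
         normalized_ratio = if (is.na(cr)) NA_real_ else mse / cr,
         replicate_count = R)
  }
  snap <- function(t) {
    rec_i <<- rec_i + 1L
    metrics[[rec_i]] <<- record_state(t)
    if (conf_like) {
      wm <- w[, mob, drop = FALSE]
      wm[!is.finite(wm)] <- NA
      max_w_trace[rec_i, ] <<- apply(wm, 1, max, na.rm = TRUE)
    }
    if (keep_positions) pos_trace[[rec_i]] <<- pos
    if (prov_on) {
      snapshots[[rec_i]] <<- list(round = t,
                                  M = lapply(prov, function(p)
                                    p$M[, seq_len(p$bcount), drop = FALSE]),
                                  bvar = lapply(prov, function(p)
                                    p$bvar[seq_len(p$bcount)]),
                                  draws = lapply(prov, function(p)
                                    p$draws[seq_len(p$bcount)]),
                                  w = w, pos = pos, theta = theta)
    }
  }
  snap(0L)

  for (t in seq_len(cfg$rounds)) {
    ## dynamic environment: target shift
    if (!is.null(cfg$theta_schedule)) {
      hit <- cfg$theta_schedule$round == t
      if (any(hit)) {
        new_theta <- cfg$theta_schedule$theta[hit][1]
        if (cfg$n_environment > 0) {
          env_idx <- which(is_env)
          pos[, env_idx] <- pos[, env_idx, drop = FALSE] + (new_theta - theta)
          bits[, env_idx] <- TRUE
          btime[, env_idx] <- t
        }
        theta <- new_theta
      }
    }

    ## pairings (replicate-specific except for the deterministic hypercube)
    if (cfg$meeting_pattern == "hypercube") {
      P <- matrix(rep(partner_indices(N, "hypercube", t), each = R), R, N)
    } else {
      P <- t(vapply(seq_len(R), function(r)
        partner_indices(N, cfg$meeting_pattern, t), integer(N)))
    }

    ## observers: mobile agents with a partner this round
    rid <- matrix(seq_len(R), R, N)
    act <- !is.na(P) & !matrix(is_env[col(P)], R, N)
    act[, is_env] <- FALSE

    pidx <- cbind(as.vector(rid)[as.vector(act)], P[act])
    oidx <- cbind(as.vector(rid)[as.vector(act)],
                  as.vector(col(P))[as.vector(act)])

    ## partner state
    if (oracle) {
      wp <- w[pidx]
      e_syn <- stats::rnorm(nrow(pidx), 0,
                            ifelse(is.finite(wp), 1 / sqrt(wp), 0))
      pos_p <- theta + e_syn
    } else {
      wp <- if (conf_like) w[pidx] else NULL
      pos_p <- pos[pidx]
    }

    ## passive measurement and active message
    eta <- if (s2 > 0) dist_sample(cfg$noise_spec, nrow(oidx)) else 0
    d <- (pos_p - pos[oidx] + eta) * bias_full[oidx[, 2]]
    if (conf_like && cfg$confidence_noise_sd > 0) {
      wt <- transmit_confidence(wp, cfg$confidence_noise_sd)
    } else {
      wt <- wp
    }

    ## per-algorithm fusion weight phi (coefficient on the observation)
    if (alg %in% c("conf", "opt_gaussian")) {
      w_obs <- conf_obs_weight(wt, s2)
      phi <- fuse_fraction(w[oidx], w_obs)
      w_new <- w[oidx] + w_obs
      bits_new <- NULL
    } else if (alg == "conf_dynamic") {
      fresh <- function(idx) bits[idx] & (t - btime[idx]) <= cfg$obsolescence_tau
      bx <- fresh(oidx)
      by <- fresh(pidx)
      adopt <- by & !bx
      ignore <- bx & !by     # stale partner: pre-change information
      w_eff <- ifelse(adopt, w0[oidx[, 2]], w[oidx])
      w_obs <- conf_obs_weight(wt, s2)
      phi <- ifelse(ignore, 0, fuse_fraction(w_eff, w_obs))
      w_new <- ifelse(ignore, w[oidx], w_eff + w_obs)
      bits_new <- list(bit = bx | by,
                       time = ifelse(adopt, btime[pidx], btime[oidx]))
    } else if (alg == "linear") {
      phi <- rep(cfg$alpha, nrow(oidx))
      w_new <- NULL
      bits_new <- NULL
    } else { ## conf_corrected: exact provenance-based correlation
      phi <- numeric(nrow(oidx))
      w_new <- numeric(nrow(oidx))
      for (k in seq_len(nrow(oidx))) {
        p <- prov[[oidx[k, 1]]]
        idx <- seq_len(p$bcount)
        mx <- p$M[oidx[k, 2], idx]
        my <- p$M[pidx[k, 2], idx]
        vx <- sum(mx^2 * p$bvar[idx])
        vy <- sum(my^2 * p$bvar[idx])
        cv <- sum(mx * my * p$bvar[idx])
        v_obs <- vy + s2
        rho <- max(-1 + 1e-12, min(1 - 1e-12, cv / sqrt(vx * v_obs)))
        fu <- correlation_corrected_fusion(vx, v_obs, rho, d[k])
        phi[k] <- fu$lambda
        w_new[k] <- 1 / fu$var_new
      }
      bits_new <- NULL
    }

    ## provenance + audit (before state is overwritten)
    if (prov_on) {
      interactions[[t]] <- prov_step(prov, oidx, pidx, phi, eta, s2,
                                     oracle, wp,
                                     if (oracle) e_syn else NULL, t)
      for (r in seq_len(R)) prov[[r]] <- attr(interactions[[t]], "prov")[[r]]
      attr(interactions[[t]], "prov") <- NULL
    }

    ## simultaneous application
    pos[oidx] <- pos[oidx] + phi * d
    if (conf_like) {
      w[oidx] <- w_new
      if (!is.null(bits_new)) {
        bits[oidx] <- bits_new$bit
        btime[oidx] <- bits_new$time
      }
    }
    if (t %in% recs) snap(t)
  }

  out <- list(
    config = cfg,
    metrics = do.call(rbind, lapply(metrics, as.data.frame)),
    final = list(pos = pos, w = if (conf_like) w else NULL, theta = theta),
    max_w_trace = max_w_trace,
    pos_trace = pos_trace,
    record_rounds = recs
  )
  if (prov_on) {
    out$interactions <- do.call(rbind, interactions)
    out$provenance <- list(snapshots = snapshots)
  }
  class(out) <- "conf_sim"
  out
}

## Fraction of the measured displacement adopted by the observer under
## inverse-variance fusion (robust to infinite weights).
fuse_fraction <- function(w_x, w_obs) {
  ifelse(is.infinite(w_x), 0,
  ifelse(is.infinite(w_obs), 1,
  ifelse(w_x + w_obs > 0, w_obs / (w_x + w_obs), 0)))
}

## One provenance round: update coefficient matrices and build the
## per-interaction audit log.  Returns the audit data.frame with the updated
## provenance list in an attribute (to keep the update atomic per round).
prov_step <- function(prov, oidx, pidx, phi, eta, s2, oracle, wp, e_syn, t) {
  R <- length(prov)
  logs <- vector("list", R)
  eta <- rep_len(eta, nrow(oidx))
  for (r in seq_len(R)) {
    sel <- which(oidx[, 1] == r)
    p <- prov[[r]]
    if (!length(sel)) { logs[[r]] <- NULL; next }
    obs <- oidx[sel, 2]
    par <- pidx[sel, 2]
    ph <- phi[sel]
    idx <- seq_len(p$bcount)
    Mold <- p$M[, idx, drop = FALSE]
    bv <- p$bvar[idx]
    var_before <- as.vector((Mold^2) %*% bv)

    ## new basis columns: synthesized partner errors, then noise draws
    n_new <- length(sel) * (oracle + (s2 > 0))
    if (p$bcount + n_new > ncol(p$M)) {
      grow <- matrix(0, nrow(p$M), n_new + 16L)
      p$M <- cbind(p$M, grow)
      p$bvar <- c(p$bvar, numeric(ncol(grow)))
      p$draws <- c(p$draws, numeric(ncol(grow)))
    }
    new_rows <- Mold[obs, , drop = FALSE] * (1 - ph)
    if (oracle) {
      syn_cols <- p$bcount + seq_along(sel)
      p$bvar[syn_cols] <- ifelse(is.finite(wp[sel]), 1 / wp[sel], 0)
      p$draws[syn_cols] <- e_syn[sel]
      par_var <- p$bvar[syn_cols]
    } else {
      new_rows <- new_rows + Mold[par, , drop = FALSE] * ph
      par_var <- var_before_of(Mold, bv, par)
    }
    nb <- p$bcount + length(sel) * oracle
    if (s2 > 0) {
      noise_cols <- nb + seq_along(sel)
      p$bvar[noise_cols] <- s2
      p$draws[noise_cols] <- eta[sel]
      nb <- nb + length(sel)
    }
    Mnew <- matrix(0, length(sel), nb)
    Mnew[, idx] <- new_rows
    if (oracle) Mnew[cbind(seq_along(sel), p$bcount + seq_along(sel))] <- ph
    if (s2 > 0) {
      Mnew[cbind(seq_along(sel),
                 p$bcount + length(sel) * oracle + seq_along(sel))] <- ph
    }
    if (nb > p$bcount) p$M[, (p$bcount + 1):nb] <- 0
    p$M[obs, seq_len(nb)] <- Mnew
    p$bcount <- nb
    prov[[r]] <- p

    var_after <- as.vector((p$M[obs, seq_len(nb), drop = FALSE]^2) %*%
                             p$bvar[seq_len(nb)])
    gain <- 1 / var_after - 1 / var_before[obs]
    bound <- pmin(1 / par_var, if (s2 > 0) 1 / s2 else Inf)
    logs[[r]] <- data.frame(round = t, replicate = r, observer = obs,
                            observed = par, var_before = var_before[obs],
                            var_after = var_after,
                            var_partner = par_var, gain = gain,
                            bound = bound)
  }
  out <- do.call(rbind, logs)
  attr(out, "prov") <- prov
  out
}

var_before_of <- function(M, bv, rows) {
  as.vector((M[rows, , drop = FALSE]^2) %*% bv)
}

#' @export
print.conf_sim <- function(x, ...) {
  cfg <- x$config
  cat("<conf_sim> ", cfg$algorithm, " | ", cfg$meeting_pattern,
      " | n = ", cfg$n_agents, " | ", cfg$rounds, " rounds x ",
      cfg$replicates, " replicates\n", sep = "")
  last <- x$metrics[nrow(x$metrics), ]
  cat("  final population MSE ", format(last$population_mse, digits = 4),
      if (!is.na(last$normalized_ratio))
        paste0(" (", format(last$normalized_ratio, digits = 4),
               " x Cramer-Rao optimum)"),
      "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Grid engine: the unrestricted Bayes-optimal algorithm on gridded pdfs.
## ---------------------------------------------------------------------------
run_simulation_grid <- function(cfg, keep_positions) {
  if (cfg$n_environment > 0) {
    stop("environment agents are not supported by the grid engine",
         call. = FALSE)
  }
  n <- cfg$n_agents
  R <- cfg$replicates
  s2 <- cfg$noise_spec$variance
  theta <- cfg$target_theta

  ## common lattice wide enough for the widest initial spec
  sd_max <- sqrt(max(vapply(cfg$initial_specs, function(s) s$variance,
                            numeric(1))))
  hw <- cfg$grid_half_width_sigmas * sd_max
  x <- seq(-hw, hw, length.out = cfg$grid_points)
  dx <- x[2] - x[1]
  init_vals <- lapply(cfg$initial_specs, function(s) {
    v <- dist_pdf(s, x)
    grid_pdf(x[1], dx, v, normalize = TRUE)
  })
  noise_g <- NULL
  if (s2 > 0) {
    K <- ceiling(cfg$grid_half_width_sigmas * sqrt(s2) / dx)
    xn <- seq(-K, K) * dx
    noise_g <- grid_pdf(xn[1], dx, dist_pdf(cfg$noise_spec, xn),
                        normalize = TRUE)
  }

  recs <- record_rounds(cfg)
  acc_mse <- acc_var <- acc_meaninfo <- acc_maxinfo <-
    matrix(0, length(recs), R)
  pos_trace <- if (keep_positions) array(NA_real_,
                                         c(length(recs), R, n)) else NULL

  for (r in seq_len(R)) {
    err <- vapply(cfg$initial_specs, function(s) dist_sample(s, 1),
                  numeric(1))
    pos <- theta + err
    mem <- init_vals ## list of grid_pdf; pdf of (theta - X), symmetric specs
    rec_i <- 0L
    grid_var <- function(g) grid_moments(g)[["var"]]
    record <- function() {
      rec_i <<- rec_i + 1L
      acc_mse[rec_i, r] <<- mean((pos - theta)^2)
      acc_var[rec_i, r] <<- stats::var(pos)
      infos <- 1 / vapply(mem, grid_var, numeric(1))
      acc_meaninfo[rec_i, r] <<- mean(infos)
      acc_maxinfo[rec_i, r] <<- max(infos)
      if (keep_positions) pos_trace[rec_i, r, ] <<- pos
    }
    record()
    for (t in seq_len(cfg$rounds)) {
      P <- partner_indices(n, cfg$meeting_pattern, t)
      eta <- if (s2 > 0) dist_sample(cfg$noise_spec, n) else numeric(n)
      old_mem <- mem
      old_pos <- pos
      for (i in which(!is.na(P))) {
        d <- old_pos[P[i]] - old_pos[i] + eta[i]
        up <- opt_update_grid(old_mem[[i]], old_mem[[P[i]]], d, noise_g)
        pos[i] <- old_pos[i] + up$delta
        mem[[i]] <- up$mem_new
      }
      if (t %in% recs) record()
    }
  }

  metrics <- data.frame(
    round = recs,
    population_mse = rowMeans(acc_mse),
    population_var = rowMeans(acc_var),
    mean_confidence = rowMeans(acc_meaninfo),
    max_confidence = rowMeans(acc_maxinfo),
    cr_bound = NA_real_, normalized_ratio = NA_real_,
    replicate_count = R
  )
  structure(list(config = cfg, metrics = metrics,
                 final = list(pos = NULL, w = NULL, theta = theta),
                 max_w_trace = acc_maxinfo, pos_trace = pos_trace,
                 record_rounds = recs),
            class = "conf_sim")
}

## ---------------------------------------------------------------------------
## Audits
## ---------------------------------------------------------------------------

#' Exact variance and correlation audit of a tracked run
#'
#' For runs with provenance tracking (linear update rules), every
#' position is an exact affine combination of initial positions and
#' noise draws, so its variance and any pairwise correlation can be
#' computed exactly, with no Monte-Carlo error.  This also verifies that
#' the affine reconstruction reproduces the simulated positions.
#'
#' @param sim A [run_simulation()] result with `track_provenance = TRUE`.
#' @return A list with `variances` (data.frame: round, replicate, agent,
#'   exact variance, stored confidence), `correlations` (per recorded
#'   round, a list of replicate-wise agent-by-agent correlation
#'   matrices), and `reconstruction_max_abs_err`.
#' @export
audit_provenance <- function(sim) {
  if (!inherits(sim, "conf_sim") || is.null(sim$provenance)) {
    stop("unsupported: provenance audit requires a run with ",
         "track_provenance = TRUE (linear update rules only)",
         call. = FALSE)
  }
  snaps <- sim$provenance$snapshots
  n_mob <- sim$config$n_agents
  rows <- list()
  corrs <- list()
  max_err <- 0
  for (s in snaps) {
    R <- length(s$M)
    cm <- vector("list", R)
    for (r in seq_len(R)) {
      M <- s$M[[r]]
      bv <- s$bvar[[r]]
      Sig <- M %*% (t(M) * bv)
      v <- diag(Sig)
      sdv <- sqrt(pmax(v, 1e-300))
      cm[[r]] <- Sig / outer(sdv, sdv)
      rec_pos <- s$theta + as.vector(M %*% s$draws[[r]])
      max_err <- max(max_err, max(abs(rec_pos - s$pos[r, ])))
      rows[[length(rows) + 1L]] <- data.frame(
        round = s$round, replicate = r, agent = seq_len(nrow(M)),
        var_exact = v, confidence = s$w[r, ])
    }
    corrs[[as.character(s$round)]] <- cm
  }
  list(variances = do.call(rbind, rows), correlations = corrs,
       reconstruction_max_abs_err = max_err)
}

#' Per-interaction information-gain (capacity) audit
#'
#' Checks every interaction of a provenance-tracked run against the
#' information-flow bound: the gain in exact inverse variance of the
#' observer must not exceed `min(J_partner, C)`, the partner's exact
#' information capped by the Fisher channel capacity.
#'
#' @param sim A [run_simulation()] result with `track_provenance = TRUE`.
#' @param cap Optional [channel_capacity()] override (defaults to the
#'   run's configured noise spec).
#' @return List with `max_excess` (maximum of gain minus bound over all
#'   interactions; <= 0 means no violation), `n_interactions`, and the
#'   audit data.frame `log`.
#' @export
capacity_audit <- function(sim, cap = NULL) {
  if (!inherits(sim, "conf_sim") || is.null(sim$interactions)) {
    stop("unsupported: capacity audit requires a run with ",
         "track_provenance = TRUE", call. = FALSE)
  }
  log <- sim$interactions
  if (!is.null(cap)) {
    cap <- as_capacity(cap)
    log$bound <- pmin(1 / log$var_partner, cap$C)
  }
  excess <- log$gain - log$bound
  list(max_excess = max(excess), n_interactions = nrow(log), log = log)
}

#' Rumor-spread experiment
#'
#' One perfectly informed agent (a very tight initial distribution) in a
#' population of nearly uninformed agents, noiseless channel,
#' random-perfect-matching rounds under the confidence-sharing rule.
#' Because the informed agent's confidence dwarfs the others', every
#' meeting with an informed agent transfers the "rumor" (the target
#' estimate) wholesale, so the informed set roughly doubles per round
#' and the population converges in about `log2(n)` rounds (plus matching
#' slack: two informed agents paired together waste their round).
#'
#' @param n Population size (>= 2).
#' @param seed Optional seed (an integer) for reproducibility.
#' @param informed_var Initial variance of the informed agent.
#' @param uninformed_var Initial variance of everyone else.
#' @param tol Convergence window half-width; every agent must be within
#'   `tol` of the target.  Defaults to 6 standard deviations of the
#'   informed agent's initial distribution (the steady-state optimum up
#'   to negligible corrections).
#' @param max_rounds Give up after this many rounds.
#' @return Integer: first round at which every agent is within `tol` of
#'   the target, or `NA` (with a warning carrying diagnostics) if the
#'   rumor has not spread within `max_rounds`.
#' @export
rumor_spread_experiment <- function(n, seed = NULL,
                                    informed_var = 1e-9,
                                    uninformed_var = 1e6,
                                    tol = 6 * sqrt(informed_var),
                                    max_rounds = ceiling(10 * log2(max(n, 2)))) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pos <- stats::rnorm(n, 0, sqrt(uninformed_var))
  pos[1] <- stats::rnorm(1, 0, sqrt(informed_var))
  w <- rep(1 / uninformed_var, n)
  w[1] <- 1 / informed_var
  for (t in seq_len(max_rounds)) {
    P <- partner_indices(n, "round_robin_pairs", t)
    ok <- !is.na(P)
    up <- conf_update(w[ok], pos[P[ok]] - pos[ok], 0, w[P[ok]])
    pos[ok] <- pos[ok] + up$delta
    w[ok] <- up$w_new
    if (all(abs(pos) <= tol)) return(t)
  }
  warning("rumor did not spread within ", max_rounds, " rounds; ",
          sum(abs(pos) > tol), "/", n, " agents remain outside the window",
          call. = FALSE)
  NA_integer_
}
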