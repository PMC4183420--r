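gauss <- function(v) make_distribution("gaussian", var = v)
noiseless <- function() make_distribution("point_mass")

test_that("draw_pairs never self-pairs and round-robin is a perfect matching", {
  set.seed(1)
  for (pattern in c("well_mixed", "oracle_independent", "round_robin_pairs")) {
    for (i in 1:20) {
      p <- draw_pairs(12, pattern)
      expect_true(all(p$observer != p$observed))
    }
  }
  p <- draw_pairs(12, "round_robin_pairs")
  expect_setequal(p$observer, 1:12)
  ## matching is symmetric: y's partner is x
  expect_equal(p$observed[order(p$observer)][p$observed[order(p$observer)]],
               1:12)
  ## hypercube is deterministic and complementary
  p1 <- draw_pairs(8, "hypercube", round = 1)
  expect_equal(p1$observed, bitwXor(0:7, 1L) + 1L)
  ## n = 2: the single possible pair
  p <- draw_pairs(2, "well_mixed")
  expect_equal(p$observed, c(2L, 1L))
})

test_that("draw_pairs is reproducible and well-mixed partners are uniform", {
  set.seed(9)
  a <- draw_pairs(16, "round_robin_pairs")
  set.seed(9)
  b <- draw_pairs(16, "round_robin_pairs")
  expect_identical(a, b)

  set.seed(10)
  n_draws <- 8000
  tab <- table(replicate(n_draws, draw_pairs(8, "well_mixed")$observed[1]))
  expect_equal(length(tab), 7)  ## all partners but itself occur
  p_hat <- as.numeric(tab) / n_draws
  se <- sqrt((1 / 7) * (6 / 7) / n_draws)
  expect_true(all(abs(p_hat - 1 / 7) < 4 * se))
})

test_that("a zero-round simulation reports the initial variance", {
  cfg <- sim_config(8, gauss(2), gauss(1), algorithm = "conf",
                    rounds = 0, replicates = 400, seed = 2)
  s <- run_simulation(cfg)
  expect_equal(nrow(s$metrics), 1)
  se <- 2 * sqrt(2 / (400 * 8))
  expect_equal(s$metrics$population_mse, 2, tolerance = 4 * se)
})

test_that("identical seeds give identical runs", {
  cfg <- sim_config(8, gauss(1), gauss(1), algorithm = "conf",
                    meeting_pattern = "well_mixed", rounds = 5,
                    replicates = 30, seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final$pos, b$final$pos)
})

test_that("conf under the independence oracle follows the exact variance recursion", {
  cfg <- sim_config(32, gauss(1), gauss(1), algorithm = "conf",
                    meeting_pattern = "oracle_independent",
                    rounds = 10, replicates = 400, seed = 3)
  s <- run_simulation(cfg)
  ## deterministic recursion: w' = w + w/(1 + sigma^2 w)
  w <- 1
  for (t in 1:10) w <- w + w / (1 + w)
  expect_equal(s$metrics$mean_confidence[nrow(s$metrics)], w)
  se <- sqrt(2 / (400 * 32))
  expect_equal(s$metrics$population_mse[nrow(s$metrics)] * w, 1,
               tolerance = 4 * se)
  ## positions remain unbiased estimators of the target
  expect_equal(mean(s$final$pos), 0,
               tolerance = 4 * sqrt(1 / (w * 400 * 32)))
})

test_that("provenance reconstructs positions exactly and matches empirical variance", {
  cfg <- sim_config(6, gauss(2), gauss(0.5), algorithm = "conf",
                    meeting_pattern = "well_mixed", rounds = 5,
                    replicates = 200, seed = 13, track_provenance = TRUE)
  s <- run_simulation(cfg)
  a <- audit_provenance(s)
  expect_lt(a$reconstruction_max_abs_err, 1e-9)
  ## round 0: exact variances equal the initial spec variances
  v0 <- subset(a$variances, round == 0)
  expect_true(all(v0$var_exact == 2))
  ## exact variance (averaged over replicates) vs empirical MSE at final round
  vT <- subset(a$variances, round == 5)
  exact <- mean(vT$var_exact)
  emp <- s$metrics$population_mse[nrow(s$metrics)]
  se <- exact * sqrt(2 / (200 * 6))
  expect_equal(emp, exact, tolerance = 4 * se)
})

test_that("one symmetric noiseless interaction gives Var 0.5 and correlation 1", {
  cfg <- sim_config(2, gauss(1), noiseless(), algorithm = "conf",
                    meeting_pattern = "round_robin_pairs", rounds = 1,
                    replicates = 1, seed = 4, track_provenance = TRUE)
  s <- run_simulation(cfg)
  a <- audit_provenance(s)
  v1 <- subset(a$variances, round == 1)
  expect_equal(v1$var_exact, c(0.5, 0.5))
  expect_equal(a$correlations[["1"]][[1]][1, 2], 1)
  ## both agents hold the same average
  expect_equal(s$final$pos[1, 1], s$final$pos[1, 2])
})

test_that("per-interaction information gain respects the capacity bound", {
  ## noiseless symmetric pair: the gain equals the partner's information
  cfg <- sim_config(2, gauss(1), noiseless(), algorithm = "conf",
                    meeting_pattern = "round_robin_pairs", rounds = 1,
                    replicates = 1, seed = 4, track_provenance = TRUE)
  s <- run_simulation(cfg)
  expect_equal(s$interactions$gain, c(1, 1))
  expect_equal(s$interactions$bound, c(1, 1))

  ## noisy channel caps the gain at C even for a very confident partner
  specs <- list(gauss(0.1), gauss(10))
  cfg <- sim_config(2, specs, gauss(1), algorithm = "conf",
                    meeting_pattern = "oracle_independent", rounds = 1,
                    replicates = 50, seed = 5, track_provenance = TRUE)
  s <- run_simulation(cfg)
  ca <- capacity_audit(s)
  expect_lte(ca$max_excess, 1e-6)
  expect_true(all(s$interactions$gain <= 1 + 1e-9))

  ## random-config sweep across patterns
  set.seed(6)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    cfg <- sim_config(n, gauss(exp(runif(1, -1, 1))),
                      if (runif(1) < 0.3) noiseless() else
                        gauss(exp(runif(1, -1, 1))),
                      algorithm = "conf",
                      meeting_pattern = sample(c("well_mixed",
                                                 "oracle_independent",
                                                 "round_robin_pairs"), 1),
                      rounds = 3, replicates = 2, seed = i,
                      track_provenance = TRUE)
    expect_lte(capacity_audit(run_simulation(cfg))$max_excess, 1e-6)
  }
})

test_that("noiseless synchronous rounds never double the best information", {
  specs <- lapply(exp(seq(-1, 1, length.out = 16)), gauss)
  cfg <- sim_config(16, specs, noiseless(), algorithm = "conf",
                    meeting_pattern = "round_robin_pairs", rounds = 10,
                    replicates = 50, seed = 7)
  s <- run_simulation(cfg)
  tr <- s$max_w_trace
  growth <- tr[-1, ] / tr[-nrow(tr), ]
  expect_lte(max(growth), 2 + 1e-6)
})

test_that("environment agents are immobile and anchor the population", {
  cfg <- sim_config(6, gauss(1), gauss(1), algorithm = "conf",
                    meeting_pattern = "well_mixed", n_environment = 2,
                    env_spec = gauss(0.04), rounds = 8, replicates = 50,
                    seed = 8, track_provenance = TRUE)
  s <- run_simulation(cfg, keep_positions = TRUE)
  ## environment agents (last two columns) never move
  first <- s$pos_trace[[1]][, 7:8]
  last <- s$pos_trace[[length(s$pos_trace)]][, 7:8]
  expect_identical(first, last)
  ## mobile agents improve beyond their own initial information
  expect_lt(s$metrics$population_mse[nrow(s$metrics)], 0.3)
})

test_that("the linear rule settles at its finite-population fixed point", {
  cfg <- build_scenario("linear_tradeoff",
                        list(alpha = 0.25, replicates = 2000), seed = 31)
  s <- run_simulation(cfg, keep_positions = TRUE)
  v <- apply(s$pos_trace[[length(s$pos_trace)]], 1, var)
  se <- sd(v) / sqrt(length(v))
  expect_equal(mean(v), linear_steady_state_variance(0.25, 1, 128),
               tolerance = 4 * se / mean(v))
  ## and the mean-field value is the n -> infinity limit of the exact one
  expect_equal(linear_steady_state_variance(0.25, 1, 1e9),
               linear_steady_state_variance(0.25, 1), tolerance = 1e-6)
})

test_that("correlation-corrected fusion never exceeds the population's total information", {
  cfg <- sim_config(16, gauss(1), noiseless(),
                    algorithm = "conf_corrected",
                    meeting_pattern = "round_robin_pairs",
                    rounds = 60, replicates = 1, seed = 3)
  s <- run_simulation(cfg)
  a <- audit_provenance(s)
  vT <- subset(a$variances, round == 60)
  info <- 1 / vT$var_exact
  expect_true(all(info <= 16 + 1e-9))   ## no over-confidence, ever
  expect_true(all(info > 12))           ## but most information disseminated
})

test_that("a dynamic population tracks a target shift while plain conf cannot", {
  cfg <- build_scenario("dynamic_environment", list(replicates = 5), seed = 2)
  s <- run_simulation(cfg, keep_positions = TRUE)
  recs <- s$record_rounds
  mob <- seq_len(cfg$n_agents)
  med_err <- function(sim, i, theta) {
    median(abs(sim$pos_trace[[i]][, mob] - theta))
  }
  i_pre <- which(recs == 29)
  i_post <- which(recs == 40)
  expect_lt(med_err(s, i_pre, 0), 0.5)     ## converged before the shift
  expect_lt(med_err(s, i_post, 5), 0.5)    ## re-converged within ~10 rounds
  ## plain confidence sharing is frozen by its accumulated confidence
  l <- config_to_list(cfg)
  l$algorithm <- "conf"
  s2 <- run_simulation(config_from_list(l), keep_positions = TRUE)
  expect_gt(med_err(s2, i_post, 5), 4)
})

test_that("rumor spread completes in one round for n = 2 and is reproducible", {
  expect_equal(rumor_spread_experiment(2, seed = 1), 1L)
  expect_identical(rumor_spread_experiment(32, seed = 5),
                   rumor_spread_experiment(32, seed = 5))
})

test_that("heterogeneous perception biases still allow collective improvement", {
  cfg <- build_scenario("heterogeneous_perception",
                        list(replicates = 50), seed = 6)
  expect_true(all(cfg$bias >= 0.5 & cfg$bias <= 2))
  s <- run_simulation(cfg)
  expect_lt(s$metrics$population_mse[nrow(s$metrics)], 0.3)
})
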