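# TAS ordered-regression random-effects model.

test_that("score simulation matches the closed-form ordinal probabilities", {
  th <- c(-1, 0.5, 2)
  f <- c(V = 0.8); beta <- c(B = 0.3); tau <- c(B = 1.2)
  sco <- simulate_tas_scores(f, beta, tau, th, assays = "focus_formation",
                             n_rep = 1e5, seed = 21)
  obs <- tabulate(sco$score, 4) / nrow(sco)
  expected <- oracle_ordinal_probs(beta + tau * f, th)
  expect_lt(max(abs(obs - expected)), 0.01)
})

test_that("the noise-free limit and monotonicity in f behave as expected", {
  th <- c(-1, 0, 1)
  sco <- simulate_tas_scores(c(a = -5), c(B = 0), c(B = 1), th,
                             epsilon_scale = 0, n_rep = 50, seed = 1)
  expect_true(all(sco$score == 1))

  # larger f gives first-order stochastically larger scores
  lo <- simulate_tas_scores(c(a = -0.5), c(B = 0), c(B = 1), th,
                            n_rep = 1e5, seed = 3)$score
  hi <- simulate_tas_scores(c(a = 0.7), c(B = 0), c(B = 1), th,
                            n_rep = 1e5, seed = 3)$score
  for (k in 1:3) expect_gt(mean(lo <= k), mean(hi <= k))
})

test_that("degenerate data abort and thin designs are flagged", {
  sco <- tibble::tibble(variant_id = "v", assay = "focus_formation",
                        batch = "b1", score = rep(4L, 6))
  expect_error(fit_tas(sco), class = "mano_degenerate_data")

  sco2 <- tibble::tibble(variant_id = rep(c("a", "b"), each = 2),
                         assay = "focus_formation", batch = "b1",
                         score = c(1L, 1L, 4L, 4L))
  expect_warning(fit_tas(sco2, chains = 1, warmup = 100, samples = 100),
                 "fewer than 2 batches")

  sco3 <- tibble::tibble(variant_id = rep(c("a", "b"), 2),
                         assay = "focus_formation",
                         batch = rep(c("b1", "b2"), each = 2),
                         score = c(1L, 4L, 4L, 4L))
  expect_warning(fit_tas(sco3, chains = 1, warmup = 100, samples = 100),
                 "single observed score level")
})

test_that("batch-constant extreme variants order their posterior activities", {
  sco <- tidyr::expand_grid(batch = paste0("b", 1:4),
                            assay = c("focus_formation", "low_serum_proliferation")) |>
    dplyr::reframe(tibble::tibble(variant_id = c("v1_low", "v2_high"),
                                  score = c(1L, 4L)),
                   .by = c("batch", "assay"))
  fit <- fit_tas(sco, chains = 2, warmup = 300, samples = 400, seed = 2)
  d <- fit$draws
  # strictly greater in every chain
  for (ch in seq_along(fit$coda)) {
    m <- as.matrix(fit$coda[[ch]])
    expect_gt(mean(m[, "f[1]"] < m[, "f[2]"]), 0.99)
  }
  expect_lt(mean(d[, "f[1]"]), mean(d[, "f[2]"]))
})

test_that("threshold ordering holds in every posterior draw", {
  scn <- tas_recovery_scenario(n_variants = 8, n_batches = 3, seed = 4)
  fit <- fit_tas(scn$scores, chains = 2, warmup = 200, samples = 300, seed = 4)
  th <- fit$draws[, c("th[1]", "th[2]", "th[3]")]
  expect_true(all(th[, 1] < th[, 2]))
  expect_true(all(th[, 2] < th[, 3]))
})

test_that("the sampler agrees with a brute-force grid posterior on the 2-variant toy", {
  beta <- c(0.2, -0.3); tau <- c(1, 1.3); th <- c(-1, 0, 1)
  set.seed(5)
  scn <- simulate_tas_scores(c(v1 = -0.8, v2 = 0.9),
                             stats::setNames(beta, c("b1", "b2")),
                             stats::setNames(tau, c("b1", "b2")),
                             th, n_rep = 3, seed = 5)
  fit <- fit_tas(scn, chains = 2, warmup = 500, samples = 1500, seed = 5,
                 fixed = list(beta = beta, tau = tau, thresholds = th))
  p_mcmc <- c(mean(fit$draws[, "f[1]"] > 0), mean(fit$draws[, "f[2]"] > 0))
  p_grid <- oracle_grid_posterior_fpos(scn, beta, tau, th)
  expect_lt(max(abs(p_mcmc - unname(p_grid))), 0.05)
})

test_that("inference is invariant to variant relabeling", {
  scn <- tas_recovery_scenario(n_variants = 6, n_batches = 3, seed = 6)
  fit <- fit_tas(scn$scores, chains = 2, warmup = 500, samples = 1000, seed = 6)
  relabeled <- scn$scores
  # reverse the lexicographic order of variant labels
  relabeled$variant_id <- sprintf("W%02d",
                                  max(as.integer(sub("V", "", relabeled$variant_id))) + 1 -
                                    as.integer(sub("V", "", relabeled$variant_id)))
  fit2 <- fit_tas(relabeled, chains = 2, warmup = 500, samples = 1000, seed = 6)
  f1 <- colMeans(fit$draws[, paste0("f[", 1:6, "]")])
  f2 <- rev(colMeans(fit2$draws[, paste0("f[", 1:6, "]")]))
  expect_lt(max(abs(f1 - f2)), 0.12)
})

test_that("compute_tas reproduces hand-computed values on point-mass posteriors", {
  # one batch: beta = 0, tau = 1, f = 2, thresholds (-1, 1, 3)
  draws <- matrix(rep(c(2, 0, 1, -1, 1, 3), each = 600), nrow = 600,
                  dimnames = list(NULL, c("f[1]", "beta[1]", "tau[1]",
                                          "th[1]", "th[2]", "th[3]")))
  fit <- tas_fit_from_draws(draws, variants = "v", batches = "b")
  tas <- compute_tas(fit, n_draws = 500, seed = 1)
  expect_equal(tas$upsilon_mean, 2)
  expect_equal(tas$tas_class, 3L)

  # a value exactly at a threshold takes the higher class
  draws[, "f[1]"] <- 1
  tas2 <- compute_tas(tas_fit_from_draws(draws, "v", "b"), 500, seed = 1)
  expect_equal(tas2$upsilon_mean, 1)
  expect_equal(tas2$tas_class, 3L)

  # more draws than samples is an error
  expect_error(compute_tas(fit, n_draws = 601), "exceeds")
})

test_that("tidiers summarise fits sensibly", {
  scn <- tas_recovery_scenario(n_variants = 5, n_batches = 2, seed = 7)
  fit <- fit_tas(scn$scores, chains = 2, warmup = 200, samples = 200, seed = 7)
  td <- generics::tidy(fit)
  expect_true(all(c("parameter", "estimate", "conf.low", "conf.high", "rhat") %in%
                    names(td)))
  expect_equal(nrow(td), ncol(fit$draws))
  gl <- generics::glance(fit)
  expect_equal(gl$n_variants, 5L)
  expect_equal(gl$n_obs, nrow(scn$scores))
})
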