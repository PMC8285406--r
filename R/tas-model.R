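# Transformation activity score (TAS): a Bayesian ordered-regression
# random-effects model that integrates ordinal transformation-assay scores
# (focus formation, low-serum proliferation; each scored 1-4) across
# experimental batches.
#
# Latent model, per experiment:
#   Upsilon = beta[batch] + tau[batch] * f[variant] + epsilon
# with epsilon standard-logistic (scale fixed at 1, which pins down the
# scale non-identifiability between epsilon, tau and the thresholds), and
# the observed score obtained by thresholding Upsilon at T12 < T23 < T34.
# beta (batch location) and tau > 0 (batch scale) absorb batch effects;
# f is the variant's transforming activity on a unit-normal scale.

tas_assays <- c("focus_formation", "low_serum_proliferation")

validate_scores <- function(scores) {
  scores <- as_tibble(scores)
  assert_cols(scores, c("variant_id", "assay", "batch", "score"), "assay scores")
  if (!all(scores$score %in% 1:4)) abort("scores must be integers in 1..4")
  if (any(!nzchar(scores$batch))) abort("batch identifiers must be non-empty")
  scores
}

build_tas_model <- function(fixed) {
  lines <- c(
    "model {",
    "  for (i in 1:N) {",
    "    eta[i] <- beta[batch[i]] + tau[batch[i]] * f[variant[i]]",
    "    q[i,1] <- ilogit((th[1] - eta[i]) / eps)",
    "    q[i,2] <- ilogit((th[2] - eta[i]) / eps)",
    "    q[i,3] <- ilogit((th[3] - eta[i]) / eps)",
    "    p[i,1] <- q[i,1]",
    "    p[i,2] <- q[i,2] - q[i,1]",
    "    p[i,3] <- q[i,3] - q[i,2]",
    "    p[i,4] <- 1 - q[i,3]",
    "    score[i] ~ dcat(p[i,1:4])",
    "  }",
    "  for (v in 1:V) { f[v] ~ dnorm(0, 1) }")
  if (!"beta" %in% names(fixed)) {
    lines <- c(lines, "  for (b in 1:B) { beta[b] ~ dnorm(0, 0.04) }")
  }
  if (!"tau" %in% names(fixed)) {
    lines <- c(lines, "  for (b in 1:B) { tau[b] ~ dnorm(0, 1) T(0,) }")
  }
  if (!"thresholds" %in% names(fixed)) {
    lines <- c(lines,
               "  for (k in 1:3) { th0[k] ~ dnorm(0, 0.04) }",
               "  th[1:3] <- sort(th0)")
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit the TAS ordered-regression random-effects model
#'
#' Bayesian fit by MCMC (JAGS). Priors are weakly informative:
#' `f ~ N(0, 1)` (fixing the variant-effect scale), `beta ~ N(0, 5^2)`,
#' `tau` half-normal(1), thresholds an ordered vague `N(0, 5^2)` vector;
#' the latent error is standard logistic. Threshold ordering holds in every
#' draw by construction. All sampling iterations are retained.
#'
#' @param scores tibble of ordinal assay results: `variant_id`, `assay`,
#'   `batch`, `score` (integer 1-4).
#' @param chains,warmup,samples MCMC settings (defaults 4, 1500, 2000).
#' @param seed integer seed; all chain RNGs derive from it.
#' @param epsilon_scale scale of the latent logistic error (default 1).
#' @param fixed optional named list to clamp `beta` (length-B vector),
#'   `tau` (length-B), and/or `thresholds` (length-3 increasing) at known
#'   values instead of sampling them; used for calibration checks against
#'   closed-form posteriors.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `tas_fit`: joint posterior draws (all chains
#'   pooled) plus per-chain `coda` samples, variant/batch lookups and
#'   convergence diagnostics (split across chains: potential scale
#'   reduction R-hat and effective sample size).
#' @export
fit_tas <- function(scores, chains = 4, warmup = 1500, samples = 2000,
                    seed = 1, epsilon_scale = 1, fixed = list(), quiet = TRUE) {
  scores <- validate_scores(scores)
  variants <- sort(unique(scores$variant_id))
  batches <- sort(unique(scores$batch))
  if (length(unique(scores$score)) < 2) {
    abort("degenerate data: all observed scores are identical; batch and variant effects are not separable",
          class = "mano_degenerate_data")
  }
  if (length(batches) < 2 && !all(c("beta", "tau") %in% names(fixed))) {
    warn("fewer than 2 batches: batch effects are weakly identified")
  }
  if (length(variants) < 2) warn("fewer than 2 variants: f is weakly identified")
  lvl <- scores |>
    group_by(.data$batch) |>
    summarise(k = length(unique(.data$score)), .groups = "drop") |>
    filter(.data$k < 2)
  if (nrow(lvl) > 0) {
    warn(sprintf("batch(es) with a single observed score level: %s",
                 paste(lvl$batch, collapse = ", ")))
  }

  dat <- list(N = nrow(scores),
              score = as.integer(scores$score),
              batch = match(scores$batch, batches),
              variant = match(scores$variant_id, variants),
              V = length(variants), B = length(batches),
              eps = epsilon_scale)
  if ("beta" %in% names(fixed)) dat$beta <- fixed$beta
  if ("tau" %in% names(fixed)) dat$tau <- fixed$tau
  if ("thresholds" %in% names(fixed)) dat$th <- fixed$thresholds
  if (all(c("beta", "tau") %in% names(fixed))) dat$B <- NULL

  monitors <- c("f",
                if (!"beta" %in% names(fixed)) "beta",
                if (!"tau" %in% names(fixed)) "tau",
                if (!"thresholds" %in% names(fixed)) "th")

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  inits <- lapply(chain_seeds, function(s) {
    ini <- list(f = rep(0, dat$V),
                .RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
    if (!"beta" %in% names(fixed)) ini$beta <- rep(0, dat$B)
    if (!"tau" %in% names(fixed)) ini$tau <- rep(1, dat$B)
    if (!"thresholds" %in% names(fixed)) ini$th0 <- c(-2, 0, 2)
    ini
  })

  model_str <- build_tas_model(fixed)
  jm <- rjags::jags.model(textConnection(model_str), data = dat, inits = inits,
                          n.chains = chains, n.adapt = max(200, warmup %/% 3),
                          quiet = quiet)
  stats::update(jm, warmup, progress.bar = "none")
  coda_samples <- rjags::coda.samples(jm, monitors, n.iter = samples,
                                      progress.bar = "none")

  draws <- as.matrix(coda_samples)
  # clamp fixed parameters back into the draw matrix so downstream
  # summarisation sees a complete parameter set
  n_total <- nrow(draws)
  if ("beta" %in% names(fixed)) {
    add <- matrix(rep(fixed$beta, each = n_total), n_total,
                  dimnames = list(NULL, paste0("beta[", seq_along(batches), "]")))
    draws <- cbind(draws, add)
  }
  if ("tau" %in% names(fixed)) {
    add <- matrix(rep(fixed$tau, each = n_total), n_total,
                  dimnames = list(NULL, paste0("tau[", seq_along(batches), "]")))
    draws <- cbind(draws, add)
  }
  if ("thresholds" %in% names(fixed)) {
    add <- matrix(rep(fixed$thresholds, each = n_total), n_total,
                  dimnames = list(NULL, paste0("th[", 1:3, "]")))
    draws <- cbind(draws, add)
  }

  diag <- tryCatch({
    g <- coda::gelman.diag(coda_samples, multivariate = FALSE, autoburnin = FALSE)
    tibble(parameter = rownames(g$psrf),
           rhat = g$psrf[, 1],
           ess = as.numeric(coda::effectiveSize(coda_samples))[
             match(rownames(g$psrf), names(coda::effectiveSize(coda_samples)))])
  }, error = function(e) {
    tibble(parameter = colnames(as.matrix(coda_samples)), rhat = NA_real_,
           ess = as.numeric(coda::effectiveSize(coda_samples)))
  })

  structure(list(draws = draws, coda = coda_samples,
                 variants = variants, batches = batches,
                 diagnostics = diag, epsilon_scale = epsilon_scale,
                 fixed = fixed,
                 mcmc = list(chains = chains, warmup = warmup,
                             samples = samples, seed = seed),
                 data = scores),
            class = "tas_fit")
}

#' Assemble a `tas_fit` from explicit posterior draws
#'
#' Mainly for calibration work: builds the object [compute_tas()] consumes
#' from a matrix of joint draws (columns named `f[i]`, `beta[b]`, `tau[b]`,
#' `th[1..3]`). A point-mass posterior is a matrix of identical rows.
#'
#' @param draws numeric matrix of joint posterior draws.
#' @param variants,batches character vectors naming the variant/batch order
#'   used in the column indices.
#' @return a `tas_fit` object (no coda samples or diagnostics).
#' @export
tas_fit_from_draws <- function(draws, variants, batches) {
  need <- c(paste0("f[", seq_along(variants), "]"),
            paste0("beta[", seq_along(batches), "]"),
            paste0("tau[", seq_along(batches), "]"),
            paste0("th[", 1:3, "]"))
  missing <- setdiff(need, colnames(draws))
  if (length(missing) > 0) {
    abort(sprintf("draw matrix is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  structure(list(draws = draws, coda = NULL, variants = variants,
                 batches = batches, diagnostics = NULL, epsilon_scale = 1,
                 fixed = list(), mcmc = list(), data = NULL),
            class = "tas_fit")
}

#' @export
print.tas_fit <- function(x, ...) {
  cat(sprintf("<tas_fit> %d variants, %d batches, %d joint draws\n",
              length(x$variants), length(x$batches), nrow(x$draws)))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max R-hat %.3f, min ESS %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  }
  invisible(x)
}

tas_classify <- function(u, thresholds) {
  # Eq-2 thresholding; boundary ties break upward (a value exactly at a
  # threshold takes the higher class)
  vapply(u, function(ui) 1L + sum(ui >= thresholds), integer(1))
}

#' Summarise a TAS posterior into per-variant scores
#'
#' Draws `n_draws` joint parameter sets from the trace, generates
#' per-variant latent activity values as the unweighted average over
#' batches of `beta[b] + tau[b] * f[v]` (the experiment-level error term is
#' excluded: it is assay noise, not variant signal), averages them, and
#' discretises the average with the posterior-mean thresholds. Ties at a
#' threshold take the higher class.
#'
#' @param fit a `tas_fit`.
#' @param n_draws number of posterior parameter sets to draw (default 500).
#' @param seed seed for the draw selection.
#' @param ci_level central credible-interval level for `f` (default 0.90).
#' @return a tibble of class `tas_scores`: `variant_id`, `upsilon_mean`,
#'   `tas_class`, `f_mean`, `f_ci_low`, `f_ci_high`, `rhat_max`. The
#'   `n_draws` x variants matrix of latent values is attached as attribute
#'   `upsilon_draws`; the thresholds used as attribute `thresholds`.
#' @export
compute_tas <- function(fit, n_draws = 500, seed = 1, ci_level = 0.90) {
  stopifnot(inherits(fit, "tas_fit"))
  draws <- fit$draws
  if (n_draws > nrow(draws)) {
    abort(sprintf("n_draws (%d) exceeds available posterior samples (%d)",
                  n_draws, nrow(draws)))
  }
  set.seed(seed)
  take <- sample.int(nrow(draws), n_draws)
  V <- length(fit$variants); B <- length(fit$batches)
  f <- draws[take, paste0("f[", seq_len(V), "]"), drop = FALSE]
  beta <- draws[take, paste0("beta[", seq_len(B), "]"), drop = FALSE]
  tau <- draws[take, paste0("tau[", seq_len(B), "]"), drop = FALSE]

  # per draw: Upsilon_v = mean_b(beta_b + tau_b * f_v)
  beta_bar <- rowMeans(beta)
  tau_bar <- rowMeans(tau)
  ups <- matrix(beta_bar, n_draws, V) + matrix(tau_bar, n_draws, V) * f
  colnames(ups) <- fit$variants

  th_mean <- colMeans(draws[, paste0("th[", 1:3, "]"), drop = FALSE])
  alpha <- (1 - ci_level) / 2
  f_all <- fit$draws[, paste0("f[", seq_len(V), "]"), drop = FALSE]
  rhat_max <- if (!is.null(fit$diagnostics)) {
    suppressWarnings(max(fit$diagnostics$rhat, na.rm = TRUE))
  } else NA_real_

  out <- tibble(
    variant_id = fit$variants,
    upsilon_mean = unname(colMeans(ups)),
    tas_class = unname(tas_classify(colMeans(ups), th_mean)),
    f_mean = colMeans(f_all),
    f_ci_low = apply(f_all, 2, quantile, probs = alpha, names = FALSE),
    f_ci_high = apply(f_all, 2, quantile, probs = 1 - alpha, names = FALSE),
    rhat_max = rhat_max
  )
  attr(out, "upsilon_draws") <- ups
  attr(out, "thresholds") <- th_mean
  class(out) <- c("tas_scores", class(out))
  out
}

#' Simulate ordinal assay scores from the TAS generative model
#'
#' Draws experiment-level latent values from the TAS equation (batch
#' location + batch scale x variant activity + logistic error) and
#' discretises them at the thresholds, yielding scores 1-4. This is the
#' single source of truth for the generative model used in recovery and
#' calibration studies.
#'
#' @param f_variant named numeric vector of true variant activities.
#' @param beta_batch,tau_batch named numeric vectors of batch location and
#'   (positive) scale effects; names define the batches.
#' @param thresholds strictly increasing numeric length-3 vector.
#' @param assays assay labels replicated per (variant, batch); default the
#'   two transformation assays.
#' @param n_rep scores per (variant, batch, assay) cell (default 1).
#' @param epsilon_scale logistic error scale (default 1); 0 gives the
#'   noise-free limit.
#' @param seed optional seed.
#' @return tibble: `variant_id`, `assay`, `batch`, `score`.
#' @export
simulate_tas_scores <- function(f_variant, beta_batch, tau_batch, thresholds,
                                assays = tas_assays, n_rep = 1,
                                epsilon_scale = 1, seed = NULL) {
  if (is.null(names(f_variant))) names(f_variant) <- paste0("V", seq_along(f_variant))
  if (is.null(names(beta_batch))) names(beta_batch) <- paste0("B", seq_along(beta_batch))
  stopifnot(length(tau_batch) == length(beta_batch), all(tau_batch > 0),
            length(thresholds) == 3, !is.unsorted(thresholds, strictly = TRUE),
            epsilon_scale >= 0)
  names(tau_batch) <- names(beta_batch)
  if (!is.null(seed)) set.seed(seed)
  design <- expand_grid(variant_id = names(f_variant),
                        batch = names(beta_batch),
                        assay = assays,
                        rep = seq_len(n_rep))
  eta <- beta_batch[design$batch] + tau_batch[design$batch] * f_variant[design$variant_id]
  eps <- if (epsilon_scale > 0) rlogis(nrow(design), 0, epsilon_scale) else 0
  u <- eta + eps
  design |>
    mutate(score = vapply(u, function(ui) 1L + sum(ui > thresholds), integer(1))) |>
    select("variant_id", "assay", "batch", "score")
}

#' Standard TAS recovery-study scenario
#'
#' The fixed simulation conditions used by the package's recovery and
#' calibration studies: `n_variants` true activities drawn from the unit
#' normal (the model's own prior, so interval calibration is meaningful),
#' modest batch location shifts (`beta ~ N(0, 0.5)`), batch scale factors
#' around 2 (`tau ~ |N(2, 0.3)|`, which spreads simulated scores over the
#' full 1-4 rubric the way real transformation assays do), thresholds at
#' (-1.5, 0, 1.5), and one score per variant x batch x assay.
#'
#' @param n_variants,n_batches design size (defaults 50, 8).
#' @param seed seed for both the true parameters and the scores.
#' @return list: `f`, `beta`, `tau`, `thresholds`, `scores`.
#' @export
tas_recovery_scenario <- function(n_variants = 50, n_batches = 8, seed = 1) {
  set.seed(seed)
  f <- rnorm(n_variants)
  names(f) <- sprintf("V%02d", seq_len(n_variants))
  beta <- rnorm(n_batches, 0, 0.5)
  names(beta) <- sprintf("B%d", seq_len(n_batches))
  tau <- abs(rnorm(n_batches, 2, 0.3))
  names(tau) <- names(beta)
  thresholds <- c(-1.5, 0, 1.5)
  scores <- simulate_tas_scores(f, beta, tau, thresholds,
                                seed = derive_seed(seed, "tas_scores"))
  list(f = f, beta = beta, tau = tau, thresholds = thresholds, scores = scores)
}
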