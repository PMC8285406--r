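# Three-parameter log-logistic dose-response fitting.
#
# Model: viability(x) = d / (1 + exp(b * (ln x - e))), lower asymptote
# fixed at 0 (response without drug already normalised out). e is the
# natural-log IC50 location; the IC50 is the curve's inflection point,
# exp(e), where viability equals d/2. Fitting is ordinary least squares
# (Levenberg-Marquardt) with a deterministic self-starter and restart grid.

ll3 <- function(x, b, d, e) d / (1 + exp(b * (log(x) - e)))

ll3_start <- function(conc, viab) {
  d0 <- max(viab)
  if (d0 <= 0) d0 <- 1
  # dose nearest half-max
  mean_by_dose <- tapply(viab, conc, mean)
  doses <- as.numeric(names(mean_by_dose))
  e0 <- log(doses[which.min(abs(mean_by_dose - d0 / 2))])
  # linearised logit regression for the slope
  y <- pmin(pmax(viab / d0, 1e-3), 1 - 1e-3)
  lf <- stats::lm(qlogis(y) ~ log(conc))
  b0 <- -unname(coef(lf)[2])
  if (!is.finite(b0) || b0 <= 0) b0 <- 1
  list(b = b0, d = d0, e = e0)
}

fit_ll3_once <- function(conc, viab, start) {
  df <- data.frame(x = conc, y = viab)
  tryCatch(
    minpack.lm::nlsLM(y ~ d / (1 + exp(b * (log(x) - e))), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Fit a log-logistic dose-response curve to one variant x drug series
#'
#' @param conc dose vector (same unit throughout; conventionally nM).
#' @param viab relative viability vector (vs untreated/vehicle control).
#' @return one-row tibble with parameters `b`, `d`, `e`, `ic50` (unit of
#'   `conc`), standard errors, residual scale `sigma`, and flags
#'   `converged` and `censored`. A fit is censored when no half-maximal
#'   inhibition is observed within the tested range or the fitted location
#'   falls outside it; censored fits report `ic50 = NA` (never an
#'   extrapolated value) and the censoring bound is `max_dose`.
#' @export
fit_curve <- function(conc, viab) {
  stopifnot(length(conc) == length(viab))
  keep <- is.finite(conc) & is.finite(viab)
  conc <- conc[keep]; viab <- viab[keep]
  if (any(conc <= 0)) abort("concentrations must be positive")
  if (length(unique(conc)) < 4) abort("at least 4 distinct doses are required")
  if (any(viab < -0.1)) {
    warn("viabilities below -0.1 observed; retained in the fit")
  }
  max_dose <- max(conc)

  start <- ll3_start(conc, viab)
  fit <- fit_ll3_once(conc, viab, start)
  if (is.null(fit)) {
    # restart grid over slope and location
    for (b0 in c(0.5, 1, 2, 4)) {
      for (e0 in log(range(conc))) {
        fit <- fit_ll3_once(conc, viab, list(b = b0, d = start$d, e = e0))
        if (!is.null(fit)) break
      }
      if (!is.null(fit)) break
    }
  }

  # no half-maximal inhibition observed in range: the IC50 is only known to
  # exceed the highest tested dose (right-censored)
  min_dose <- min(conc)
  v_lo <- mean(viab[conc == min_dose])
  v_hi <- mean(viab[conc == max_dose])
  no_halfmax <- v_hi > 0.5 * max(v_lo, 1e-12)
  if (is.null(fit)) {
    return(tibble(b = NA_real_, d = NA_real_, e = NA_real_, ic50 = NA_real_,
                  se_b = NA_real_, se_d = NA_real_, se_e = NA_real_,
                  sigma = NA_real_, max_dose = max_dose,
                  converged = FALSE, censored = no_halfmax))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(b = NA, d = NA, e = NA))
  censored <- no_halfmax || unname(cf["e"]) > log(max_dose) ||
    unname(cf["e"]) < log(min_dose)
  tibble(b = unname(cf["b"]), d = unname(cf["d"]), e = unname(cf["e"]),
         ic50 = if (censored) NA_real_ else exp(unname(cf["e"])),
         se_b = unname(se["b"]), se_d = unname(se["d"]), se_e = unname(se["e"]),
         sigma = summary(fit)$sigma, max_dose = max_dose,
         converged = TRUE, censored = censored)
}

#' Fit dose-response curves across variants and drugs
#'
#' Maps [fit_curve()] over every variant x drug series of a tidy viability
#' table, as produced by plate-reader assays or by
#' [viability_from_counts()] for pooled-screen data.
#'
#' @param viability tibble with columns `variant_id`, `drug`,
#'   `concentration_nM`, `viability` (replicate rows enter the least
#'   squares individually).
#' @return a tibble of class `ic50_fits`, one row per variant x drug, with
#'   the [fit_curve()] columns plus `ic50_nM`; the input data are attached
#'   as attribute `data` for plotting.
#' @export
fit_dose_response <- function(viability) {
  assert_cols(viability, c("variant_id", "drug", "concentration_nM", "viability"),
              "viability table")
  out <- viability |>
    group_by(.data$variant_id, .data$drug) |>
    group_modify(function(df, key) fit_curve(df$concentration_nM, df$viability)) |>
    ungroup() |>
    rename(ic50_nM = "ic50", max_dose_nM = "max_dose")
  attr(out, "data") <- as_tibble(viability)
  class(out) <- c("ic50_fits", class(out))
  out
}

#' Compare log-IC50 between two fitted curves
#'
#' Two-sided z-test on the difference of the log-IC50 location parameters
#' using the fit standard errors. Censored or failed fits are reported as
#' not comparable.
#'
#' @param fit_a,fit_b one-row fit tibbles (rows of an `ic50_fits` table).
#' @param conf_level confidence level for the log-ratio interval.
#' @return one-row tibble: `log_ratio` (`e_a - e_b`, natural log),
#'   `se`, `z`, `p`, `ci_low`, `ci_high`, `comparable`.
#' @export
compare_ic50 <- function(fit_a, fit_b, conf_level = 0.95) {
  ok <- isTRUE(fit_a$converged) && isTRUE(fit_b$converged) &&
    !isTRUE(fit_a$censored) && !isTRUE(fit_b$censored) &&
    is.finite(fit_a$se_e) && is.finite(fit_b$se_e)
  if (!ok) {
    return(tibble(log_ratio = NA_real_, se = NA_real_, z = NA_real_,
                  p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  comparable = FALSE))
  }
  dr <- fit_a$e - fit_b$e
  se <- sqrt(fit_a$se_e^2 + fit_b$se_e^2)
  z <- if (se == 0) {
    if (dr == 0) 0 else sign(dr) * Inf
  } else dr / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(log_ratio = dr, se = se, z = z,
         p = 2 * pnorm(-abs(z)),
         ci_low = dr - q * se, ci_high = dr + q * se,
         comparable = TRUE)
}

#' All pairwise IC50 comparisons within each drug
#'
#' @param fits an `ic50_fits` table.
#' @return tibble: `drug`, `variant_a`, `variant_b`, comparison columns
#'   from [compare_ic50()], and a Benjamini-Hochberg adjusted p column
#'   (`p_adj_BH`; the primary calls use the raw p).
#' @export
compare_ic50_all <- function(fits) {
  out <- fits |>
    group_by(.data$drug) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2) return(tibble())
      pairs <- utils::combn(nrow(df), 2)
      map(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        compare_ic50(df[i, ], df[j, ]) |>
          mutate(variant_a = df$variant_id[i], variant_b = df$variant_id[j],
                 .before = 1)
      }) |> list_rbind()
    }) |>
    ungroup()
  out |> mutate(p_adj_BH = stats::p.adjust(.data$p, method = "BH"))
}

#' Adapt pooled-screen viabilities to the curve-fitting contract
#'
#' Bridge from [drug_relative_viability()] output (one viability per
#' variant x drug x dose) to the tidy table [fit_dose_response()] expects.
#' Requires at least 4 doses per variant x drug.
#'
#' The pooled drug/vehicle fraction ratio is compositional: it equals the
#' variant's survival divided by the pool-average survival at that dose,
#' which inflates apparent IC50s when much of the pool is killed. With
#' `reference = "negative_control"` (default) each variant's ratio is
#' divided by the same dose's mean ratio over the drug-insensitive
#' negative-control clones, which cancels the pool-average term exactly and
#' restores absolute survival; `reference = "none"` keeps the raw ratios
#' (then the adapter is lossless).
#'
#' @param profile output of [drug_relative_viability()] over a dose grid.
#' @param reference `"negative_control"` or `"none"`.
#' @return tibble: `variant_id`, `drug`, `concentration_nM`, `viability`.
#' @export
viability_from_counts <- function(profile,
                                  reference = c("negative_control", "none")) {
  reference <- match.arg(reference)
  assert_cols(profile, c("variant_id", "drug", "concentration_nM", "viability"),
              "viability profile")
  if (reference == "negative_control") {
    assert_cols(profile, "role", "viability profile (reference normalisation)")
    ctrl <- profile |>
      filter(.data$role == "negative_control") |>
      group_by(.data$drug, .data$concentration_nM) |>
      summarise(v_ctrl = mean(.data$viability), .groups = "drop")
    if (nrow(ctrl) == 0) {
      abort("no negative_control clones available as drug-insensitive reference")
    }
    profile <- profile |>
      left_join(ctrl, by = c("drug", "concentration_nM")) |>
      mutate(viability = .data$viability / .data$v_ctrl)
  }
  out <- profile |>
    select("variant_id", "drug", "concentration_nM", "viability")
  shallow <- out |>
    group_by(.data$variant_id, .data$drug) |>
    summarise(k = length(unique(.data$concentration_nM)), .groups = "drop") |>
    filter(.data$k < 4)
  if (nrow(shallow) > 0) {
    abort(sprintf("fewer than 4 doses for: %s",
                  paste(paste(shallow$variant_id, shallow$drug), collapse = "; ")))
  }
  out
}
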