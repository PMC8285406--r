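# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @describeIn fit_tas posterior summary per parameter: mean, sd, central
#'   90% interval, R-hat and effective sample size.
#' @param x a `tas_fit`.
#' @param ... unused.
#' @method tidy tas_fit
#' @export
tidy.tas_fit <- function(x, ...) {
  d <- x$draws
  out <- tibble(parameter = colnames(d),
                estimate = colMeans(d),
                std.error = apply(d, 2, sd),
                conf.low = apply(d, 2, quantile, 0.05, names = FALSE),
                conf.high = apply(d, 2, quantile, 0.95, names = FALSE))
  if (!is.null(x$diagnostics)) {
    out <- out |> left_join(x$diagnostics, by = "parameter")
  }
  out
}

#' @describeIn fit_tas one-row fit summary: data size, MCMC settings,
#'   worst-case convergence diagnostics.
#' @method glance tas_fit
#' @export
glance.tas_fit <- function(x, ...) {
  tibble(n_obs = if (!is.null(x$data)) nrow(x$data) else NA_integer_,
         n_variants = length(x$variants),
         n_batches = length(x$batches),
         chains = x$mcmc$chains %||% NA_integer_,
         samples = x$mcmc$samples %||% NA_integer_,
         rhat_max = if (!is.null(x$diagnostics))
           suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)) else NA_real_,
         ess_min = if (!is.null(x$diagnostics))
           suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)) else NA_real_)
}

#' @describeIn fit_dose_response parameters in long format, one row per
#'   parameter per variant x drug.
#' @param x an `ic50_fits` table.
#' @param ... unused.
#' @method tidy ic50_fits
#' @export
tidy.ic50_fits <- function(x, ...) {
  as_tibble(x) |>
    select("variant_id", "drug", "b", "d", "e", "se_b", "se_d", "se_e") |>
    pivot_longer(c("b", "d", "e"), names_to = "term", values_to = "estimate") |>
    mutate(std.error = dplyr::case_when(
      .data$term == "b" ~ .data$se_b,
      .data$term == "d" ~ .data$se_d,
      .data$term == "e" ~ .data$se_e)) |>
    select("variant_id", "drug", "term", "estimate", "std.error")
}

#' @describeIn fit_dose_response one-row summary of the fit table.
#' @method glance ic50_fits
#' @export
glance.ic50_fits <- function(x, ...) {
  tibble(n_fits = nrow(x),
         n_converged = sum(x$converged),
         n_censored = sum(x$censored),
         median_ic50_nM = median(x$ic50_nM[x$converged & !x$censored]))
}

#' @describeIn cluster_sensitivity merge table of the tree.
#' @param x a `sensitivity_clustering`.
#' @param ... unused.
#' @method tidy sensitivity_clustering
#' @export
tidy.sensitivity_clustering <- function(x, ...) x$merge_table

#' Plot TAS summaries
#'
#' Variants ordered by latent activity, with the posterior mean and 90%
#' interval of `f` and points coloured by the discrete TAS class.
#'
#' @param object a `tas_scores` tibble from [compute_tas()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tas_scores
#' @export
autoplot.tas_scores <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(variant_id = stats::reorder(.data$variant_id, .data$upsilon_mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_mean, y = .data$variant_id)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$f_ci_low,
                                         xmax = .data$f_ci_high),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$tas_class))) +
    ggplot2::labs(x = "variant activity f (posterior mean, 90% CrI)",
                  y = NULL, colour = "TAS class") +
    ggplot2::theme_minimal()
}

#' Plot fitted dose-response curves
#'
#' Observed viabilities with the fitted log-logistic curves, facetted by
#' variant; censored fits are labelled.
#'
#' @param object an `ic50_fits` table (with its `data` attribute).
#' @param drug_name optional single drug to display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ic50_fits
#' @export
autoplot.ic50_fits <- function(object, drug_name = NULL, ...) {
  data <- attr(object, "data")
  fits <- as_tibble(object) |> filter(.data$converged)
  if (!is.null(drug_name)) {
    data <- data |> filter(.data$drug == drug_name)
    fits <- fits |> filter(.data$drug == drug_name)
  }
  grid <- fits |>
    mutate(curve = map(seq_len(n()), function(i) {
      x <- exp(seq(log(min(data$concentration_nM)),
                   log(max(data$concentration_nM)), length.out = 80))
      tibble(concentration_nM = x,
             viability = ll3(x, fits$b[i], fits$d[i], fits$e[i]))
    })) |>
    select("variant_id", "drug", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$concentration_nM,
                                     y = .data$viability)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant_id, .data$drug)) +
    ggplot2::labs(x = "dose (nM)", y = "relative viability") +
    ggplot2::theme_minimal()
}

#' Plot a UPGMA dendrogram
#'
#' @param object a `sensitivity_clustering`.
#' @param ... unused.
#' @return a ggplot of the merge tree.
#' @method autoplot sensitivity_clustering
#' @export
autoplot.sensitivity_clustering <- function(object, ...) {
  hc <- object$hclust
  dend <- as.dendrogram(hc)
  # node coordinates: leaves at integer x in dendrogram order, height 0
  xpos <- stats::order.dendrogram(dend)
  leaf_x <- numeric(length(hc$labels))
  leaf_x[xpos] <- seq_along(xpos)
  node_x <- numeric(nrow(hc$merge)); node_h <- hc$height
  seg <- vector("list", nrow(hc$merge))
  coord <- function(idx) {
    if (idx < 0) c(leaf_x[-idx], 0) else c(node_x[idx], node_h[idx])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- coord(hc$merge[i, 1]); b <- coord(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    seg[[i]] <- tibble(x = c(a[1], a[1], b[1]),
                       xend = c(a[1], b[1], b[1]),
                       y = c(a[2], node_h[i], b[2]),
                       yend = c(node_h[i], node_h[i], node_h[i]))
  }
  segments <- list_rbind(seg)
  labels <- tibble(x = seq_along(xpos), label = hc$labels[xpos])
  ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = 2.8) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "UPGMA merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Growth-profile bar plot
#'
#' log2 relative proliferation versus wild type per variant, coloured by
#' role.
#'
#' @param profile output of [relative_proliferation()].
#' @return a ggplot.
#' @export
plot_growth_profile <- function(profile) {
  df <- as_tibble(profile) |>
    filter(is.finite(.data$log2_vs_wt)) |>
    mutate(variant_id = stats::reorder(.data$variant_id, .data$log2_vs_wt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_id, y = .data$log2_vs_wt,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 relative proliferation vs WT") +
    ggplot2::theme_minimal()
}

#' Drug-sensitivity heatmap
#'
#' Transformed IC50 matrix with rows and columns ordered by their UPGMA
#' trees; censor-imputed cells are outlined.
#'
#' @param z a `sensitivity_matrix`.
#' @return a ggplot.
#' @export
plot_sensitivity_heatmap <- function(z) {
  rows <- if (nrow(z) > 2) {
    cluster_sensitivity(z, "variants")$hclust$order
  } else seq_len(nrow(z))
  cols <- if (ncol(z) > 2) {
    cluster_sensitivity(z, "drugs")$hclust$order
  } else seq_len(ncol(z))
  cens <- attr(z, "censored")
  df <- as_tibble(unclass(z)[rows, cols, drop = FALSE], rownames = "variant_id") |>
    pivot_longer(-"variant_id", names_to = "drug", values_to = "value") |>
    mutate(variant_id = factor(.data$variant_id, levels = rownames(z)[rows]),
           drug = factor(.data$drug, levels = colnames(z)[cols]),
           censored = as.vector(cens[rows, cols, drop = FALSE][
             cbind(match(.data$variant_id, rownames(z)[rows]),
                   match(.data$drug, colnames(z)[cols]))]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = .data$variant_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df |> filter(.data$censored),
                       colour = "black", linewidth = 0.4, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(log10 IC50)") +
    ggplot2::theme_minimal()
}
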