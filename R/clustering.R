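# Drug-sensitivity clustering: variants (or drugs) are clustered by UPGMA
# (unweighted group-average linkage) on Euclidean distances of the
# log10-then-Z-standardised IC50 matrix.

#' Transform an IC50 matrix for clustering
#'
#' Applies log10 to every IC50 and then Z-standardises each drug column
#' (sample SD, n-1). Censored entries are imputed at their censoring bound
#' (the highest tested dose) and flagged; alternatively they can be
#' dropped. The transform provenance (log base, standardisation axis,
#' column centres/scales) is attached so the transform can be inverted.
#'
#' @param fits an `ic50_fits` table, or a tibble with columns
#'   `variant_id`, `drug`, `ic50_nM` and optionally `censored` and
#'   `max_dose_nM`.
#' @param censored_policy `"impute"` (default: censored IC50s enter at the
#'   censoring bound) or `"drop"` (variants with any censored entry are
#'   removed).
#' @param standardise_axis `"drug"` (default) standardises within each drug
#'   column; `"variant"` within each variant row.
#' @return a numeric matrix (rows variants, columns drugs) of class
#'   `sensitivity_matrix`, with attributes `log_base`, `axis`, `centre`,
#'   `scale`, `censored` (logical matrix of imputed cells).
#' @export
transform_sensitivity <- function(fits, censored_policy = c("impute", "drop"),
                                  standardise_axis = c("drug", "variant")) {
  censored_policy <- match.arg(censored_policy)
  standardise_axis <- match.arg(standardise_axis)
  assert_cols(fits, c("variant_id", "drug", "ic50_nM"), "IC50 table")
  tbl <- as_tibble(fits)
  if (!"censored" %in% names(tbl)) tbl$censored <- FALSE
  if (censored_policy == "impute") {
    if (any(tbl$censored)) {
      if (!"max_dose_nM" %in% names(tbl)) {
        abort("imputing censored IC50s requires a max_dose_nM column")
      }
      tbl <- tbl |> mutate(ic50_use = if_else(.data$censored,
                                              .data$max_dose_nM, .data$ic50_nM))
    } else {
      tbl <- tbl |> mutate(ic50_use = .data$ic50_nM)
    }
  } else {
    bad <- tbl |> filter(.data$censored) |> pull("variant_id") |> unique()
    tbl <- tbl |> filter(!.data$variant_id %in% bad) |>
      mutate(ic50_use = .data$ic50_nM)
  }
  if (any(!is.finite(tbl$ic50_use)) || any(tbl$ic50_use <= 0)) {
    abort("all IC50 values must be finite and positive after the censoring policy")
  }
  wide <- tbl |>
    select("variant_id", "drug", "ic50_use") |>
    pivot_wider(names_from = "drug", values_from = "ic50_use")
  cens <- tbl |>
    select("variant_id", "drug", "censored") |>
    pivot_wider(names_from = "drug", values_from = "censored")
  if (anyNA(wide)) abort("IC50 matrix has missing variant x drug entries")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$variant_id
  m <- log10(m)
  if (standardise_axis == "variant") m <- t(m)
  centre <- colMeans(m)
  scale <- apply(m, 2, sd)
  flat <- names(scale)[scale == 0]
  if (length(flat) > 0) {
    abort(sprintf("zero variance in %s column(s): %s — cannot Z-standardise",
                  standardise_axis, paste(flat, collapse = ", ")))
  }
  z <- sweep(sweep(m, 2, centre), 2, scale, "/")
  if (standardise_axis == "variant") z <- t(z)
  cm <- as.matrix(cens[, -1])
  rownames(cm) <- cens$variant_id
  structure(z, class = c("sensitivity_matrix", "matrix", "array"),
            log_base = 10, axis = standardise_axis,
            centre = centre, scale = scale,
            censored = cm[rownames(z), colnames(z), drop = FALSE])
}

#' Invert the clustering transform back to log10 IC50
#'
#' @param z a `sensitivity_matrix`.
#' @return matrix of log10 IC50 values (exact round trip).
#' @export
inverse_transform_sensitivity <- function(z) {
  stopifnot(inherits(z, "sensitivity_matrix"))
  axis <- attr(z, "axis")
  m <- unclass(z)
  attributes(m)[c("log_base", "axis", "centre", "scale", "censored", "class")] <- NULL
  if (axis == "variant") m <- t(m)
  m <- sweep(sweep(m, 2, attr(z, "scale"), "*"), 2, attr(z, "centre"), "+")
  if (axis == "variant") m <- t(m)
  m
}

#' UPGMA clustering of a sensitivity matrix
#'
#' Agglomerative group-average (UPGMA) clustering on Euclidean distances,
#' along the variant (row) or drug (column) axis. Merge heights are
#' non-decreasing (UPGMA is monotone); an optional cut into `k` clusters is
#' returned alongside.
#'
#' @param z a `sensitivity_matrix` (or any numeric matrix).
#' @param axis `"variants"` (rows, default) or `"drugs"` (columns).
#' @param k optional number of clusters to cut the tree into.
#' @return a list of class `sensitivity_clustering`: `hclust` (the tree),
#'   `merge_table` (tibble of merge heights), `clusters` (named integer
#'   vector, when `k` given), `axis`.
#' @export
cluster_sensitivity <- function(z, axis = c("variants", "drugs"), k = NULL) {
  axis <- match.arg(axis)
  m <- if (axis == "drugs") t(unclass(z)) else unclass(z)
  if (nrow(m) < 2) abort("need at least 2 items on the clustered axis")
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  merge_table <- tibble(step = seq_along(hc$height),
                        height = hc$height,
                        left = hc$merge[, 1], right = hc$merge[, 2])
  clusters <- if (!is.null(k)) cutree(hc, k = k) else NULL
  structure(list(hclust = hc, merge_table = merge_table,
                 clusters = clusters, axis = axis),
            class = "sensitivity_clustering")
}

#' @export
print.sensitivity_clustering <- function(x, ...) {
  cat(sprintf("<sensitivity_clustering> UPGMA over %d %s; heights %.3g .. %.3g\n",
              length(x$hclust$labels), x$axis,
              min(x$hclust$height), max(x$hclust$height)))
  if (!is.null(x$clusters)) print(table(x$clusters))
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' @param clustering a `sensitivity_clustering`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "sensitivity_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
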