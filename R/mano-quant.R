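# Normalization of clone count matrices into the screen's two readouts:
# relative proliferation (transformation assay, day-3 reference) and
# relative viability (drug assay, vehicle reference).
#
# Counts are compositional: each sample is converted to within-sample
# fractions (count / matched total) before any ratio is taken, which removes
# sequencing-depth differences between samples. A 0.5-read pseudocount is
# applied to zero counts only, so log ratios stay finite without perturbing
# samples where every clone was observed.

sample_fractions <- function(counts, pseudo_zero = 0.5) {
  counts |>
    group_by(.data$sample_id) |>
    mutate(.adj = .data$count + if_else(.data$count == 0, pseudo_zero, 0),
           frac = .data$.adj / sum(.data$.adj)) |>
    ungroup() |>
    select(-".adj")
}

#' Relative proliferation of each variant in a growth competition screen
#'
#' Implements the day-3-reference normalization of the pooled growth assay:
#' per clone, counts become within-sample fractions, fractions are averaged
#' across replicates per day, and the clone's relative proliferation is the
#' target-day fraction divided by the reference-day fraction. The variant
#' value is the mean over its (typically three) clones, and is also reported
#' on a log2 scale relative to the same gene's wild type.
#'
#' @param counts long count tibble from [build_count_matrix()].
#' @param reference_day reference day (default 3, the post-mixing baseline).
#' @param target_day endpoint day (default 18).
#' @param condition which sample condition carries the growth screen
#'   (default `"baseline"`).
#' @return a tibble with one row per variant: `variant_id`, `gene`, `role`,
#'   `n_clones`, `r` (relative proliferation), `log2_r`, `log2_vs_wt`.
#'   Replicate-level variant values (needed for paired tests) are attached
#'   as attribute `replicates`; clone-level ratios as attribute `clones`.
#'   Clones with a zero reference-day fraction are excluded with a warning;
#'   variants with no usable clone are reported as `NA`, not zero.
#' @export
relative_proliferation <- function(counts, reference_day = 3, target_day = 18,
                                   condition = "baseline") {
  assert_cols(counts, c("clone_id", "variant_id", "gene", "role", "sample_id",
                        "day", "condition", "replicate", "count"), "count matrix")
  cc <- counts |> filter(.data$condition == !!condition,
                         .data$day %in% c(reference_day, target_day))
  if (!reference_day %in% cc$day || !target_day %in% cc$day) {
    abort(sprintf("both day %d and day %d must be present in the count matrix",
                  reference_day, target_day))
  }

  fr <- sample_fractions(cc)

  # raw fractions (no pseudocount) to detect truly absent reference clones
  raw_ref <- cc |>
    filter(.data$day == reference_day) |>
    group_by(.data$clone_id) |>
    summarise(ref_reads = sum(.data$count), .groups = "drop")
  dead <- raw_ref |> filter(.data$ref_reads == 0)
  if (nrow(dead) > 0) {
    warn(sprintf("excluding %d clone(s) with zero reference-day reads: %s",
                 nrow(dead), paste(head(dead$clone_id, 5), collapse = ", ")))
    fr <- fr |> filter(!.data$clone_id %in% dead$clone_id)
  }

  # average fractions across replicates per day, then ratio, then clones
  clone_r <- fr |>
    group_by(.data$clone_id, .data$variant_id, .data$gene, .data$role, .data$day) |>
    summarise(frac = mean(.data$frac), .groups = "drop") |>
    pivot_wider(names_from = "day", values_from = "frac", names_prefix = "d") |>
    mutate(r = .data[[paste0("d", target_day)]] / .data[[paste0("d", reference_day)]])

  profile <- clone_r |>
    group_by(.data$variant_id, .data$gene, .data$role) |>
    summarise(n_clones = sum(!is.na(.data$r)), r = mean(.data$r), .groups = "drop") |>
    mutate(log2_r = log2(.data$r))

  # variants whose clones were all excluded come back as missing, not zero
  profile <- cc |>
    distinct(.data$variant_id, .data$gene, .data$role) |>
    left_join(profile, by = c("variant_id", "gene", "role")) |>
    mutate(n_clones = replace_na(.data$n_clones, 0L))

  wt <- profile |>
    filter(.data$role == "wild_type") |>
    select("gene", wt_r = "r")
  profile <- profile |>
    left_join(wt, by = "gene") |>
    mutate(log2_vs_wt = log2(.data$r / .data$wt_r)) |>
    select(-"wt_r")

  # replicate-level variant values, pairing unit for the paired t-test
  rep_r <- fr |>
    pivot_wider(id_cols = c("clone_id", "variant_id", "gene", "role", "replicate"),
                names_from = "day", values_from = "frac", names_prefix = "d") |>
    mutate(r = .data[[paste0("d", target_day)]] / .data[[paste0("d", reference_day)]]) |>
    group_by(.data$variant_id, .data$gene, .data$role, .data$replicate) |>
    summarise(r = mean(.data$r), .groups = "drop") |>
    mutate(log2_r = log2(.data$r))

  attr(profile, "replicates") <- rep_r
  attr(profile, "clones") <- clone_r
  profile
}

paired_p <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  if (length(d) < 3) return(NA_real_)
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(x[is.finite(x - y)], y[is.finite(x - y)], paired = TRUE)$p.value
}

#' Paired significance of growth differences vs a comparator
#'
#' Two-sided paired t-test on log2 relative proliferation, pairing by
#' replicate experiment (each variant's clones are averaged within a
#' replicate first). Comparators: the same gene's wild type, or the
#' negative-control (GFP) cells. A variant is flagged `activating` when its
#' mean exceeds the comparator's and p < alpha.
#'
#' @param profile output of [relative_proliferation()] (its `replicates`
#'   attribute carries the paired values).
#' @param comparator `"wild_type"` (same-gene WT) or `"negative_control"`.
#' @param alpha significance level (default 0.05).
#' @return tibble: `variant_id`, `gene`, `delta_log2` (variant minus
#'   comparator mean), `p`, `significant`, `activating`. Variants with
#'   fewer than 3 complete pairs get `p = NA` with `reason`.
#' @export
growth_significance <- function(profile, comparator = c("wild_type", "negative_control"),
                                alpha = 0.05) {
  comparator <- match.arg(comparator)
  reps <- attr(profile, "replicates")
  if (is.null(reps)) abort("profile must come from relative_proliferation()")

  test_one <- function(df, comp_df) {
    merged <- inner_join(df, comp_df, by = "replicate", suffix = c("", "_cmp"))
    n_pairs <- sum(is.finite(merged$log2_r - merged$log2_r_cmp))
    if (n_pairs < 3) {
      return(tibble(delta_log2 = NA_real_, p = NA_real_,
                    n_pairs = n_pairs, reason = "fewer than 3 complete pairs"))
    }
    tibble(delta_log2 = mean(merged$log2_r - merged$log2_r_cmp),
           p = paired_p(merged$log2_r, merged$log2_r_cmp),
           n_pairs = n_pairs, reason = NA_character_)
  }

  if (comparator == "wild_type") {
    comp <- reps |> filter(.data$role == "wild_type") |>
      select("gene", "replicate", "log2_r")
    out <- reps |>
      filter(.data$role != "wild_type") |>
      group_by(.data$variant_id, .data$gene) |>
      group_modify(function(df, key) {
        test_one(df, comp |> filter(.data$gene == key$gene) |> select(-"gene"))
      }) |>
      ungroup()
  } else {
    comp <- reps |> filter(.data$role == "negative_control") |>
      group_by(.data$replicate) |>
      summarise(log2_r = mean(.data$log2_r), .groups = "drop")
    out <- reps |>
      filter(.data$role != "negative_control") |>
      group_by(.data$variant_id, .data$gene) |>
      group_modify(function(df, key) test_one(df, comp)) |>
      ungroup()
  }
  out |>
    mutate(significant = !is.na(.data$p) & .data$p < alpha,
           activating = .data$significant & .data$delta_log2 > 0)
}

#' Relative viability of each variant under drug treatment
#'
#' Vehicle(DMSO)-reference normalization of the pooled drug assay: per
#' clone, the within-sample fraction under drug (averaged across
#' triplicates) is divided by the fraction under vehicle (averaged across
#' triplicates) of the same batch, and clone ratios are averaged per
#' variant. Because the pool is compositional, a resistant variant in a
#' dying pool shows viability above 1 (enrichment).
#'
#' @param counts long count tibble from [build_count_matrix()].
#' @param drug_name drug to evaluate; `NULL` (default) evaluates all drugs
#'   present.
#' @return tibble: `variant_id`, `gene`, `role`, `drug`,
#'   `concentration_nM`, `batch`, `viability`, `n_clones`. Replicate-level
#'   values attached as attribute `replicates`.
#' @export
drug_relative_viability <- function(counts, drug_name = NULL) {
  assert_cols(counts, c("clone_id", "variant_id", "gene", "role", "sample_id",
                        "condition", "drug", "concentration_nM", "replicate",
                        "batch", "count"), "count matrix")
  drugged <- counts |> filter(.data$condition == "drug")
  if (!is.null(drug_name)) drugged <- drugged |> filter(.data$drug %in% drug_name)
  if (nrow(drugged) == 0) abort("no drug-condition samples found")
  batches <- unique(drugged$batch)
  vehicle <- counts |> filter(.data$condition == "vehicle", .data$batch %in% batches)
  missing_b <- setdiff(batches, unique(vehicle$batch))
  if (length(missing_b) > 0) {
    abort(sprintf("no vehicle (DMSO) samples in batch(es): %s",
                  paste(missing_b, collapse = ", ")))
  }

  veh_frac <- sample_fractions(vehicle) |>
    group_by(.data$clone_id, .data$batch) |>
    summarise(veh = mean(.data$frac), .groups = "drop")
  veh_rep <- sample_fractions(vehicle) |>
    select("clone_id", "batch", "replicate", veh_rep = "frac")

  drug_frac <- sample_fractions(drugged) |>
    group_by(.data$clone_id, .data$variant_id, .data$gene, .data$role,
             .data$drug, .data$concentration_nM, .data$batch) |>
    summarise(trt = mean(.data$frac), .groups = "drop")

  out <- drug_frac |>
    left_join(veh_frac, by = c("clone_id", "batch")) |>
    mutate(v = .data$trt / .data$veh) |>
    group_by(.data$variant_id, .data$gene, .data$role, .data$drug,
             .data$concentration_nM, .data$batch) |>
    summarise(viability = mean(.data$v), n_clones = n(), .groups = "drop")

  reps <- sample_fractions(drugged) |>
    left_join(veh_rep, by = c("clone_id", "batch", "replicate")) |>
    mutate(v = .data$frac / .data$veh_rep) |>
    group_by(.data$variant_id, .data$gene, .data$role, .data$drug,
             .data$concentration_nM, .data$batch, .data$replicate) |>
    summarise(viability = mean(.data$v), .groups = "drop")

  attr(out, "replicates") <- reps
  out
}
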