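# Five-class oncogenicity annotation combining TAS and growth evidence.
#
# Rules (relative to the same gene's wild type):
#   oncogenic        higher TAS, significantly faster growth
#   likely_oncogenic higher TAS, not significantly faster
#   likely_LoF       lower TAS, not significantly slower
#   LoF              lower TAS, significantly slower
#   neutral          none of the above (equal TAS always lands here, as does
#                    e.g. significantly faster growth with lower TAS)

onco_classes <- c("oncogenic", "likely_oncogenic", "neutral",
                  "likely_LoF", "LoF", "not_evaluable")

classify_one <- function(tas_variant, tas_wt, growth_log2_vs_wt, p_vs_wt, alpha) {
  if (any(is.na(c(tas_variant, tas_wt, growth_log2_vs_wt, p_vs_wt)))) {
    return("not_evaluable")
  }
  sig_faster <- growth_log2_vs_wt > 0 && p_vs_wt < alpha
  sig_slower <- growth_log2_vs_wt < 0 && p_vs_wt < alpha
  if (tas_variant > tas_wt) {
    if (sig_faster) "oncogenic" else "likely_oncogenic"
  } else if (tas_variant < tas_wt) {
    if (sig_slower) "LoF" else "likely_LoF"
  } else {
    "neutral"
  }
}

#' Classify variant oncogenicity from TAS and growth evidence
#'
#' Applies the five-class rule set to each row of a merged evidence table.
#' "Higher/lower TAS" is a strict comparison against the same gene's wild
#' type (discrete TAS class by default; pass the continuous latent mean to
#' compare on the real scale instead); "significantly faster/slower" means
#' the growth difference has the corresponding sign and `p < alpha`. Any
#' missing input yields `not_evaluable`, never a silent `neutral`.
#'
#' @param evidence tibble with columns `variant_id`, `tas_variant`,
#'   `tas_wt`, `growth_log2_vs_wt`, `p_vs_wt` (paired t-test vs wild type).
#' @param alpha significance level, in (0, 1); default 0.05.
#' @return the input with a `call` factor column added (levels:
#'   `oncogenic`, `likely_oncogenic`, `neutral`, `likely_LoF`, `LoF`,
#'   `not_evaluable`).
#' @export
#' @examples
#' classify_variants(tibble::tibble(
#'   variant_id = "FGFR2_N549K", tas_variant = 4, tas_wt = 2,
#'   growth_log2_vs_wt = 3, p_vs_wt = 0.01))
classify_variants <- function(evidence, alpha = 0.05) {
  assert_cols(evidence, c("variant_id", "tas_variant", "tas_wt",
                          "growth_log2_vs_wt", "p_vs_wt"), "evidence table")
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("alpha must be a single number in (0, 1)")
  }
  evidence |>
    mutate(call = factor(
      pmap(list(.data$tas_variant, .data$tas_wt,
                .data$growth_log2_vs_wt, .data$p_vs_wt),
           function(tv, tw, g, p) classify_one(tv, tw, g, p, alpha)) |>
        unlist(),
      levels = onco_classes))
}

#' Assemble the classifier evidence table from pipeline results
#'
#' Joins TAS scores with same-gene wild-type TAS and the growth
#' significance results into the input [classify_variants()] expects.
#'
#' @param tas a `tas_scores` tibble from [compute_tas()].
#' @param growth output of [growth_significance()] with
#'   `comparator = "wild_type"`.
#' @param variant_info tibble `variant_id`, `gene`, `role` identifying each
#'   gene's wild type.
#' @return evidence tibble for [classify_variants()].
#' @export
oncogenicity_evidence <- function(tas, growth, variant_info) {
  assert_cols(variant_info, c("variant_id", "gene", "role"), "variant_info")
  tas_tbl <- tas |> select("variant_id", "tas_class")
  wt_tas <- variant_info |>
    filter(.data$role == "wild_type") |>
    left_join(tas_tbl, by = "variant_id") |>
    select("gene", tas_wt = "tas_class")
  variant_info |>
    filter(.data$role %in% c("variant", "positive_control")) |>
    left_join(tas_tbl, by = "variant_id") |>
    rename(tas_variant = "tas_class") |>
    left_join(wt_tas, by = "gene") |>
    left_join(growth |> select("variant_id", growth_log2_vs_wt = "delta_log2",
                               p_vs_wt = "p"),
              by = "variant_id") |>
    select("variant_id", "gene", "tas_variant", "tas_wt",
           "growth_log2_vs_wt", "p_vs_wt")
}
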