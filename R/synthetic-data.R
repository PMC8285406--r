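# Synthetic screen generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: barcoded clones
# (three per variant) growing exponentially with variant-specific fitness,
# multinomial read sampling at a stated depth, substitution sequencing
# errors, log-logistic per-variant drug kill, and the TAS generative model
# for ordinal assay scores (via simulate_tas_scores(), the single source of
# truth for that model).

#' Generate a barcode whitelist with guaranteed pairwise separation
#'
#' Random 10-nt barcodes with minimum pairwise Hamming distance
#' `min_dist` (rejection sampling), so that single-substitution rescue can
#' never mis-assign a barcode.
#'
#' @param n number of barcodes.
#' @param width barcode width (default 10).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed optional seed.
#' @return character vector of barcodes.
#' @export
generate_barcodes <- function(n, width = 10, min_dist = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- paste(sample(DNA_ALPHABET, width, replace = TRUE), collapse = "")
    ok <- length(out) == 0 || all(hamming_to(out, cand) >= min_dist)
    if (ok) out <- c(out, cand)
    tries <- tries + 1
    if (tries > 1e5) abort("could not generate enough separated barcodes")
  }
  out
}

#' Define a synthetic screen scenario
#'
#' The scenario fixes the ground truth of a desk-scale pooled screen
#' mirroring the real experimental design: three barcoded clones per
#' variant, triplicate samples, a day-3 reference and day-18 endpoint for
#' the growth assay, a 5-day drug exposure over an 8-point dose grid
#' spanning 0.1 nM to 10 uM, and read depths of 1e5 per sample. Variants
#' comprise oncogenic mutants (fitness above wild type and drug-sensitive
#' with true IC50s log-spaced from 1 nM to 1 uM), neutral mutants, slow
#' loss-of-function mutants, a resistant gatekeeper-like mutant, per-gene
#' wild types, a GFP negative control (growth-arrested in low serum,
#' drug-insensitive) and a RAS-like positive control.
#'
#' @param n_oncogenic,n_neutral,n_lof counts of each mutant class
#'   (defaults 18, 4, 2).
#' @param genes gene symbols the mutants are spread across.
#' @param clones_per_variant clones (barcodes) per variant (default 3).
#' @param depth reads per sample (default 1e5; must be >= 1e3).
#' @param replicates samples per condition (default 3).
#' @param days growth-assay sampling days, reference first (default 3, 18).
#' @param treatment_days drug exposure length in days (default 5).
#' @param doses_nM dose grid (default 8 log-spaced points, 0.1 nM-10 uM).
#' @param drug drug name for the drug screen (default "FGFRi").
#' @param hill_slope Hill slope of the true kill curves (default 1).
#' @param error_rate per-base substitution sequencing-error rate used when
#'   reads are emitted (default 0).
#' @param seed root seed; recorded in the scenario and fanned out to each
#'   simulated output.
#' @return a list of class `screen_scenario`: `variants` (truth tibble with
#'   `variant_id`, `gene`, `role`, `fitness_log2_per_day`, `ic50_nM`,
#'   `hill`), `manifest`, and the design fields above.
#' @export
screen_scenario <- function(n_oncogenic = 18, n_neutral = 4, n_lof = 2,
                            genes = c("FGFR1", "FGFR2", "FGFR3", "FGFR4"),
                            clones_per_variant = 3, depth = 1e5,
                            replicates = 3, days = c(3, 18),
                            treatment_days = 5,
                            doses_nM = 10^seq(log10(0.1), log10(1e4), length.out = 8),
                            drug = "FGFRi", hill_slope = 1,
                            error_rate = 0, seed = 1) {
  stopifnot(depth >= 1e3, length(days) >= 2, all(doses_nM > 0))
  set.seed(seed)
  n_mut <- n_oncogenic + n_neutral + n_lof
  mut_gene <- rep(genes, length.out = n_mut)
  variants <- tibble(
    variant_id = c(paste0(mut_gene, "_M", seq_len(n_mut)),
                   "FGFR4_gatekeeper",
                   paste0(genes, "_WT"), "GFP", "RASpos"),
    gene = c(mut_gene, "FGFR4", genes, "GFP", "RAS"),
    role = c(rep("variant", n_mut + 1),
             rep("wild_type", length(genes)),
             "negative_control", "positive_control"),
    fitness_log2_per_day = c(
      runif(n_oncogenic, 0.2, 0.5),        # transforming mutants
      rnorm(n_neutral, 0, 0.01),           # near-WT
      runif(n_lof, -0.2, -0.1),            # loss of function
      0.45,                                # resistant but transforming
      rep(0, length(genes)),               # wild types (reference)
      -0.2,                                # GFP: arrest in low serum
      0.5),                                # positive control
    ic50_nM = c(10^seq(0, 3, length.out = n_oncogenic),  # 1 nM .. 1 uM
                rep(NA_real_, n_neutral + n_lof),        # not transformed
                NA_real_,                                # gatekeeper: resistant
                rep(NA_real_, length(genes)),            # WT: FGFR-independent
                NA_real_, NA_real_),                     # GFP, RAS control
    hill = hill_slope)
  clones <- variants |>
    select("variant_id", "gene", "role") |>
    tidyr::uncount(clones_per_variant, .id = "k") |>
    mutate(clone_id = paste0(.data$variant_id, "_c", .data$k)) |>
    select(-"k")
  manifest <- clones |>
    mutate(barcode = generate_barcodes(nrow(clones), seed = NULL)) |>
    select("barcode", "clone_id", "variant_id", "gene", "role")
  structure(list(variants = variants, manifest = manifest,
                 clones_per_variant = clones_per_variant, depth = depth,
                 replicates = replicates, days = days,
                 treatment_days = treatment_days, doses_nM = doses_nM,
                 drug = drug, error_rate = error_rate, seed = seed),
            class = "screen_scenario")
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat(sprintf("<screen_scenario> %d variants x %d clones, depth %g, %d replicates, seed %d\n",
              nrow(x$variants), x$clones_per_variant, x$depth, x$replicates, x$seed))
  invisible(x)
}

clone_truth <- function(scenario) {
  scenario$manifest |>
    left_join(scenario$variants |>
                select("variant_id", "fitness_log2_per_day", "ic50_nM", "hill"),
              by = "variant_id")
}

draw_counts <- function(weights, depth, noise) {
  w <- weights / sum(weights)
  if (noise == "none") depth * w else as.numeric(rmultinom(1, depth, w))
}

#' Simulate a pooled growth competition screen
#'
#' Clone abundances evolve exponentially at the variant's fitness
#' (log2 doublings/day relative to wild type); reads are drawn
#' multinomially at the scenario depth per sample. `noise = "none"` emits
#' the exact expected (real-valued) counts, the limit used by exactness
#' checks.
#'
#' @param scenario a [screen_scenario()].
#' @param noise `"multinomial"` (default) or `"none"`.
#' @param seed seed (default: derived from the scenario root seed).
#' @return list: `counts` (long count tibble in the [build_count_matrix()]
#'   layout), `samples` (metadata), `truth` (tibble `variant_id`,
#'   `true_log2_vs_wt` over the reference-to-endpoint window), `manifest`.
#' @export
simulate_growth_screen <- function(scenario, noise = c("multinomial", "none"),
                                   seed = derive_seed(scenario$seed, "growth_screen")) {
  noise <- match.arg(noise)
  set.seed(seed)
  tr <- clone_truth(scenario)
  days <- scenario$days
  samples <- expand_grid(day = days, replicate = seq_len(scenario$replicates)) |>
    mutate(sample_id = sprintf("growth_d%02d_r%d", .data$day, .data$replicate),
           condition = "baseline", drug = NA_character_,
           concentration_nM = NA_real_, batch = "b1")
  counts <- samples |>
    group_by(.data$sample_id) |>
    group_modify(function(s, key) {
      w <- 2^(tr$fitness_log2_per_day * s$day)
      tibble(clone_id = tr$clone_id,
             count = draw_counts(w, scenario$depth, noise))
    }) |>
    ungroup() |>
    left_join(tr |> select("clone_id", "variant_id", "gene", "role"), by = "clone_id") |>
    left_join(samples, by = "sample_id") |>
    select("clone_id", "variant_id", "gene", "role", "sample_id", "day",
           "condition", "drug", "concentration_nM", "replicate", "batch", "count")
  window <- days[length(days)] - days[1]
  truth <- scenario$variants |>
    mutate(true_log2_vs_wt = .data$fitness_log2_per_day * window) |>
    select("variant_id", "gene", "role", "fitness_log2_per_day", "true_log2_vs_wt")
  list(counts = counts, samples = samples, truth = truth,
       manifest = scenario$manifest)
}

log_logistic_survival <- function(dose_nM, ic50_nM, hill) {
  # insensitive clones (NA ic50) survive fully; otherwise the same
  # 3-parameter log-logistic law the fitter assumes (d = 1, lower 0)
  if_else(is.na(ic50_nM), 1,
          1 / (1 + exp(hill * (log(dose_nM) - log(ic50_nM)))))
}

#' Simulate a pooled drug screen over a dose grid
#'
#' Clones first expand for the treatment window at their growth fitness
#' (identically under vehicle and drug), then drug-treated cells survive
#' according to the variant's true log-logistic kill curve while vehicle
#' (DMSO) cells are untouched; reads are sampled multinomially per sample.
#'
#' @param scenario a [screen_scenario()].
#' @param noise `"multinomial"` (default) or `"none"`.
#' @param seed seed (default derived from the scenario root seed).
#' @return list: `counts` (vehicle plus one drug condition per dose, in
#'   triplicate), `samples`, `truth` (tibble `variant_id`, `drug`,
#'   `true_ic50_nM`, `hill`; `NA` for insensitive clones), `manifest`.
#' @export
simulate_drug_screen <- function(scenario, noise = c("multinomial", "none"),
                                 seed = derive_seed(scenario$seed, "drug_screen")) {
  noise <- match.arg(noise)
  set.seed(seed)
  tr <- clone_truth(scenario)
  growth_w <- 2^(tr$fitness_log2_per_day * scenario$treatment_days)
  samples <- dplyr::bind_rows(
    expand_grid(replicate = seq_len(scenario$replicates)) |>
      mutate(condition = "vehicle", concentration_nM = NA_real_),
    expand_grid(concentration_nM = scenario$doses_nM,
                replicate = seq_len(scenario$replicates)) |>
      mutate(condition = "drug")) |>
    mutate(drug = if_else(.data$condition == "drug", scenario$drug, NA_character_),
           day = scenario$treatment_days, batch = "b1",
           sample_id = sprintf("%s_%s_r%d", .data$condition,
                               if_else(is.na(.data$concentration_nM), "0",
                                       formatC(.data$concentration_nM, format = "g")),
                               .data$replicate))
  counts <- samples |>
    group_by(.data$sample_id) |>
    group_modify(function(s, key) {
      surv <- if (s$condition == "vehicle") 1 else {
        log_logistic_survival(s$concentration_nM, tr$ic50_nM, tr$hill)
      }
      tibble(clone_id = tr$clone_id,
             count = draw_counts(growth_w * surv, scenario$depth, noise))
    }) |>
    ungroup() |>
    left_join(tr |> select("clone_id", "variant_id", "gene", "role"), by = "clone_id") |>
    left_join(samples, by = "sample_id") |>
    select("clone_id", "variant_id", "gene", "role", "sample_id", "day",
           "condition", "drug", "concentration_nM", "replicate", "batch", "count")
  truth <- scenario$variants |>
    mutate(drug = scenario$drug) |>
    select("variant_id", "gene", "role", "drug", true_ic50_nM = "ic50_nM", "hill")
  list(counts = counts, samples = samples, truth = truth,
       manifest = scenario$manifest)
}

#' Simulate amplicon reads carrying clone barcodes
#'
#' Emits reads of the form `<context>CTAGACTGCC<barcode>GGATCACTCT<context>`
#' with barcodes drawn from the given weights, and per-base substitution
#' errors applied uniformly over the read. The truth table records each
#' read's source barcode and how many substitutions hit the barcode,
#' flanks, or context, so rescue rates can be scored exactly.
#'
#' @param manifest barcode manifest (or a character vector of barcodes).
#' @param n_reads number of reads.
#' @param weights sampling weight per barcode (default uniform).
#' @param error_rate per-base substitution probability (default 0).
#' @param context flanking random-sequence length on each side (default 8).
#' @param seed optional seed.
#' @return list: `reads` (named character vector, names `read0001`...),
#'   `truth` (tibble `read_id`, `barcode`, `n_err_barcode`, `n_err_flank`).
#' @export
simulate_reads <- function(manifest, n_reads, weights = NULL, error_rate = 0,
                           context = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  barcodes <- if (is.character(manifest)) manifest else validate_manifest(manifest)$barcode
  if (is.null(weights)) weights <- rep(1, length(barcodes))
  stopifnot(length(weights) == length(barcodes), n_reads >= 1)
  pick <- sample.int(length(barcodes), n_reads, replace = TRUE,
                     prob = weights / sum(weights))
  ctx_l <- vapply(seq_len(n_reads), function(i)
    paste(sample(DNA_ALPHABET, context, replace = TRUE), collapse = ""), character(1))
  ctx_r <- vapply(seq_len(n_reads), function(i)
    paste(sample(DNA_ALPHABET, context, replace = TRUE), collapse = ""), character(1))
  reads <- paste0(ctx_l, BARCODE_FLANK_5, barcodes[pick], BARCODE_FLANK_3, ctx_r)
  L <- nchar(reads[1])
  bc_pos <- (context + 10 + 1):(context + 20)
  flank_pos <- c((context + 1):(context + 10), (context + 21):(context + 30))
  n_err_bc <- integer(n_reads)
  n_err_flank <- integer(n_reads)
  if (error_rate > 0) {
    err <- matrix(runif(n_reads * L) < error_rate, n_reads, L)
    hit <- which(rowSums(err) > 0)
    for (i in hit) {
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      pos <- which(err[i, ])
      for (p in pos) {
        chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1)
      }
      reads[i] <- paste(chars, collapse = "")
      n_err_bc[i] <- sum(pos %in% bc_pos)
      n_err_flank[i] <- sum(pos %in% flank_pos)
    }
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = tibble(read_id = ids, barcode = barcodes[pick],
                      n_err_barcode = n_err_bc, n_err_flank = n_err_flank))
}

#' Write reads to a FASTQ file
#'
#' @param reads named character vector of sequences.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
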