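# Growth and drug normalization of count matrices.

small_scenario <- function(...) {
  screen_scenario(n_oncogenic = 6, n_neutral = 2, n_lof = 1, depth = 5e4, ...)
}

test_that("relative proliferation is exact on noise-free exponential growth", {
  sc <- small_scenario(seed = 5)
  gs <- simulate_growth_screen(sc, noise = "none")
  pr <- relative_proliferation(gs$counts)
  cmp <- dplyr::left_join(pr, gs$truth, by = c("variant_id", "gene", "role"))
  expect_lt(max(abs(cmp$log2_vs_wt - cmp$true_log2_vs_wt), na.rm = TRUE), 1e-12)
})

test_that("the reference-day self-ratio is exactly 1", {
  sc <- small_scenario(seed = 6)
  gs <- simulate_growth_screen(sc)
  pr <- relative_proliferation(gs$counts, reference_day = 3, target_day = 3)
  expect_true(all(pr$r == 1))
  # genes without a same-gene wild type (GFP, RAS controls) have no WT ratio
  expect_true(all(pr$log2_vs_wt == 0, na.rm = TRUE))
  clones <- attr(pr, "clones")
  expect_true(all(clones$r == 1))
})

test_that("ratios are invariant to per-sample sequencing depth", {
  sc <- small_scenario(seed = 7)
  gs <- simulate_growth_screen(sc)
  scaled <- gs$counts
  one <- scaled$sample_id == scaled$sample_id[1]
  scaled$count[one] <- scaled$count[one] * 17
  expect_equal(relative_proliferation(scaled)$r,
               relative_proliferation(gs$counts)$r)
})

test_that("zero-reference clones are excluded and fully absent variants are NA", {
  sc <- small_scenario(seed = 8)
  gs <- simulate_growth_screen(sc)
  counts <- gs$counts
  # kill one clone of one variant at the reference day
  v <- counts$variant_id[counts$role == "variant"][1]
  kill_clone <- counts$clone_id[counts$variant_id == v][1]
  counts$count[counts$clone_id == kill_clone & counts$day == 3] <- 0
  expect_warning(pr <- relative_proliferation(counts), "zero reference")
  expect_equal(pr$n_clones[pr$variant_id == v], sc$clones_per_variant - 1L)

  # kill every clone of the variant: reported missing, not zero
  counts2 <- gs$counts
  counts2$count[counts2$variant_id == v & counts2$day == 3] <- 0
  expect_warning(pr2 <- relative_proliferation(counts2), "zero reference")
  row <- pr2[pr2$variant_id == v, ]
  expect_equal(nrow(row), 1L)
  expect_true(is.na(row$r))
  expect_equal(row$n_clones, 0L)
})

make_profile <- function(variant_log2, wt_log2) {
  reps <- dplyr::bind_rows(
    tibble::tibble(variant_id = "mut", gene = "g", role = "variant",
                   replicate = seq_along(variant_log2),
                   r = 2^variant_log2, log2_r = variant_log2),
    tibble::tibble(variant_id = "wt", gene = "g", role = "wild_type",
                   replicate = seq_along(wt_log2),
                   r = 2^wt_log2, log2_r = wt_log2))
  profile <- tibble::tibble(variant_id = c("mut", "wt"), gene = "g",
                            role = c("variant", "wild_type"), n_clones = 3L,
                            r = NA_real_, log2_r = NA_real_, log2_vs_wt = NA_real_)
  attr(profile, "replicates") <- reps
  profile
}

test_that("paired growth test matches the textbook paired t-test", {
  # paired differences (1.0, 1.1, 0.9) in log2 units
  wt <- c(0.2, -0.1, 0.3)
  prof <- make_profile(wt + c(1.0, 1.1, 0.9), wt)
  res <- growth_significance(prof, "wild_type")
  oracle <- stats::t.test(c(1.0, 1.1, 0.9))$p.value
  expect_equal(res$p, oracle)
  expect_true(res$activating)

  # identical values in every pair: p = 1, no flag
  prof0 <- make_profile(wt, wt)
  res0 <- growth_significance(prof0, "wild_type")
  expect_equal(res0$p, 1)
  expect_false(res0$activating)

  # fewer than 3 pairs: missing with a reason
  prof2 <- make_profile(wt[1:2] + 1, wt[1:2])
  res2 <- growth_significance(prof2, "wild_type")
  expect_true(is.na(res2$p))
  expect_match(res2$reason, "pairs")
})

test_that("a strong oncogene is flagged in nearly every replicate experiment", {
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    wt <- rnorm(3, 0, 0.2)
    prof <- make_profile(wt + 3 + rnorm(3, 0, 0.2), wt)
    growth_significance(prof, "wild_type")$activating
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("drug viability is 1 when drug equals vehicle, and enriches resistant clones", {
  sc <- small_scenario(seed = 9)
  ds <- simulate_drug_screen(sc, noise = "none")
  counts <- ds$counts
  # overwrite one drug dose with the vehicle expectation
  veh <- counts[counts$condition == "vehicle" & counts$replicate == 1, ]
  dose1 <- unique(counts$concentration_nM[counts$condition == "drug"])[1]
  for (r in 1:3) {
    sel <- counts$condition == "drug" & counts$concentration_nM == dose1 &
      counts$replicate == r
    counts$count[sel] <- veh$count[match(counts$clone_id[sel], veh$clone_id)]
  }
  vi <- drug_relative_viability(counts)
  expect_equal(vi$viability[vi$concentration_nM == dose1],
               rep(1, sum(vi$concentration_nM == dose1)))

  # at the top dose nearly all sensitive clones die: the resistant
  # gatekeeper-like variant is compositionally enriched above 1
  vi_all <- drug_relative_viability(ds$counts)
  top <- max(vi_all$concentration_nM)
  expect_gt(vi_all$viability[vi_all$variant_id == "FGFR4_gatekeeper" &
                               vi_all$concentration_nM == top], 1)
})

test_that("a 90% kill of one variant in a large stable pool reads out near 0.1", {
  sc <- screen_scenario(n_oncogenic = 18, n_neutral = 4, n_lof = 2,
                        depth = 2e5, seed = 10)
  tr <- sc$manifest
  veh_w <- rep(1, nrow(tr))
  target <- tr$variant_id == tr$variant_id[tr$role == "variant"][1]
  drug_w <- ifelse(target, 0.1, 1)
  set.seed(42)
  rows <- list()
  for (r in 1:3) {
    for (cond in c("vehicle", "drug")) {
      w <- if (cond == "vehicle") veh_w else drug_w
      rows[[paste(cond, r)]] <- tibble::tibble(
        clone_id = tr$clone_id, variant_id = tr$variant_id, gene = tr$gene,
        role = tr$role, sample_id = paste0(cond, r), day = 5L,
        condition = cond, drug = ifelse(cond == "drug", "X", NA_character_),
        concentration_nM = ifelse(cond == "drug", 100, NA_real_),
        replicate = r, batch = "b1",
        count = as.numeric(rmultinom(1, 2e5, w / sum(w))))
    }
  }
  vi <- drug_relative_viability(dplyr::bind_rows(rows))
  v_target <- vi$viability[vi$variant_id == tr$variant_id[target][1]]
  expect_lt(abs(v_target - 0.1), 0.02)
})

test_that("missing vehicle samples are a hard error naming the batch", {
  sc <- small_scenario(seed = 11)
  ds <- simulate_drug_screen(sc)
  no_veh <- ds$counts[ds$counts$condition != "vehicle", ]
  expect_error(drug_relative_viability(no_veh), "b1")
})
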