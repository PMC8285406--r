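# Barcode extraction and count-matrix assembly.

test_that("the literal flank pattern is applied to single reads", {
  man <- tibble::tibble(barcode = "AAACCCGGTT", clone_id = "c1",
                        variant_id = "v1", gene = "FGFR2", role = "variant")
  tl <- extract_barcodes("TTCTAGACTGCCAAACCCGGTTGGATCACTCTAA", man)
  expect_equal(tl$counts$count, 1L)
  expect_equal(tl$matched_reads, 1L)

  # no flank anywhere: unmatched, counts untouched
  tl2 <- extract_barcodes("ACGTACGTACGTACGTACGTACGTACGTACGTAC", man)
  expect_equal(tl2$counts$count, 0L)
  expect_equal(tl2$unmatched_reads, 1L)
  expect_equal(tl2$unmatched$reason, "no_flank")
})

test_that("error-free extraction equals the brute-force substring scan exactly", {
  man <- make_test_manifest()
  sim <- simulate_reads(man, 10000, weights = runif(nrow(man), 0.2, 1),
                        error_rate = 0, seed = 11)
  tl <- extract_barcodes(sim$reads, man, max_mismatch = 0)
  oracle <- oracle_barcode_scan(unname(sim$reads), man$barcode)
  expect_identical(tl$counts$count, oracle$counts)
  expect_identical(tl$matched_reads, oracle$n_matched)
  # conservation
  expect_identical(tl$matched_reads + tl$unmatched_reads, tl$total_reads)
})

test_that("single-mismatch rescue recovers singly-mutated barcodes without mis-assignment", {
  man <- make_test_manifest()
  sim <- simulate_reads(man, 8000, error_rate = 0.01, seed = 12)
  tl0 <- extract_barcodes(sim$reads, man, max_mismatch = 0)
  tl1 <- extract_barcodes(sim$reads, man, max_mismatch = 1)
  # rescue only adds counts
  expect_true(all(tl1$counts$count >= tl0$counts$count))

  # score per-read assignments on the subset with exactly one barcode error
  # and intact flanks: all must be rescued to the true barcode
  single <- sim$truth$n_err_barcode == 1 & sim$truth$n_err_flank == 0
  per_read <- vapply(which(single), function(i) {
    t1 <- extract_barcodes(sim$reads[i], man, max_mismatch = 1)
    hit <- t1$counts$barcode[t1$counts$count > 0]
    if (length(hit) == 0) NA_character_ else hit
  }, character(1))
  rescued <- !is.na(per_read)
  expect_gte(mean(rescued), 0.95)
  expect_identical(per_read[rescued], sim$truth$barcode[single][rescued])
})

test_that("orientation policy counts a read and its reverse complement alike", {
  man <- make_test_manifest(n_variants = 2, clones_per_variant = 1)
  read <- paste0("AAAA", "CTAGACTGCC", man$barcode[1], "GGATCACTCT", "TTTT")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(read, "")[[1]]), collapse = ""))
  both <- extract_barcodes(c(a = read, b = rc), man, orientation = "both")
  fwd_twice <- extract_barcodes(c(a = read, b = read), man, orientation = "forward")
  expect_identical(both$counts$count, fwd_twice$counts$count)
  # forward-only misses the reverse-complement read
  fwd <- extract_barcodes(c(a = read, b = rc), man, orientation = "forward")
  expect_identical(fwd$matched_reads, 1L)
})

test_that("counting is invariant to read order and mates are deduplicated", {
  man <- make_test_manifest()
  sim <- simulate_reads(man, 500, error_rate = 0.005, seed = 13)
  perm <- sample(length(sim$reads))
  a <- extract_barcodes(sim$reads, man, max_mismatch = 1)
  b <- extract_barcodes(sim$reads[perm], man, max_mismatch = 1)
  expect_equal(a$counts, b$counts)

  # two mates with the same id and barcode count once
  read <- paste0("AAAA", "CTAGACTGCC", man$barcode[1], "GGATCACTCT", "TTTT")
  mates <- c(r1 = read, r1 = read)
  tl <- extract_barcodes(mates, man)
  expect_equal(sum(tl$counts$count), 1L)
  expect_equal(tl$unmatched$n[tl$unmatched$reason == "duplicate_mate"], 1L)
  expect_identical(tl$matched_reads + tl$unmatched_reads, tl$total_reads)
})

test_that("surplus pattern occurrences are counted as multi-hits, leftmost wins", {
  man <- make_test_manifest(n_variants = 2, clones_per_variant = 1)
  read <- paste0("CTAGACTGCC", man$barcode[1], "GGATCACTCT",
                 "CTAGACTGCC", man$barcode[2], "GGATCACTCT")
  tl <- extract_barcodes(read, man)
  expect_equal(tl$multi_hit, 1L)
  expect_equal(tl$counts$count[tl$counts$barcode == man$barcode[1]], 1L)
  expect_equal(sum(tl$counts$count), 1L)
})

test_that("manifest validation rejects bad input", {
  expect_error(extract_barcodes("ACGT", tibble::tibble(
    barcode = character(), clone_id = character(), variant_id = character(),
    gene = character(), role = character())), class = "mano_config_error")
  bad <- tibble::tibble(barcode = "AAACCCGGNT", clone_id = "c", variant_id = "v",
                        gene = "g", role = "variant")
  expect_error(extract_barcodes("ACGT", bad), class = "mano_validation_error")
})

test_that("count matrices zero-fill, aggregate clones, and keep totals", {
  man <- tibble::tibble(barcode = c("AAAAAAAAAA", "CCCCCCCCCC"),
                        clone_id = c("cloneA", "cloneB"),
                        variant_id = c("v1", "v2"), gene = "g",
                        role = c("variant", "variant"))
  samples <- tibble::tibble(sample_id = c("s1", "s2"), day = 3L,
                            condition = "baseline", drug = NA_character_,
                            concentration_nM = NA_real_, replicate = 1:2,
                            batch = "b1")
  counts <- tibble::tibble(sample_id = "s1", barcode = "AAAAAAAAAA", count = 5L)
  m <- build_count_matrix(counts, man, samples[1, ])
  expect_equal(m$count[m$clone_id == "cloneA"], 5L)
  expect_equal(m$count[m$clone_id == "cloneB"], 0L)

  # disjoint barcodes across samples: zeros off-block
  counts2 <- tibble::tibble(sample_id = c("s1", "s2"),
                            barcode = c("AAAAAAAAAA", "CCCCCCCCCC"),
                            count = c(3L, 7L))
  m2 <- build_count_matrix(counts2, man, samples)
  wide <- tidyr::pivot_wider(m2[, c("clone_id", "sample_id", "count")],
                             names_from = "sample_id", values_from = "count")
  expect_equal(wide$s2[wide$clone_id == "cloneA"], 0L)
  expect_equal(wide$s1[wide$clone_id == "cloneB"], 0L)

  # unknown barcode is a hard error naming the offender
  expect_error(build_count_matrix(
    tibble::tibble(sample_id = "s1", barcode = "GGGGGGGGGG", count = 1L),
    man, samples), "GGGGGGGGGG")
})

test_that("simulated screen column sums equal the simulator's matched totals", {
  man <- make_test_manifest()
  tallies <- lapply(1:3, function(i) {
    sim <- simulate_reads(man, 3000, seed = 20 + i)
    extract_barcodes(sim$reads, man)
  })
  names(tallies) <- paste0("s", 1:3)
  samples <- tibble::tibble(sample_id = paste0("s", 1:3), day = 3L,
                            condition = "baseline", drug = NA_character_,
                            concentration_nM = NA_real_, replicate = 1:3,
                            batch = "b1")
  m <- build_count_matrix(tallies, man, samples)
  sums <- tapply(m$count, m$sample_id, sum)
  expect_equal(as.integer(sums[paste0("s", 1:3)]),
               vapply(tallies, function(t) t$matched_reads, integer(1),
                      USE.NAMES = FALSE))
  report <- attr(m, "run_report")
  expect_equal(report$total_reads, rep(3000L, 3))
})

test_that("FASTQ round trip preserves counts", {
  man <- make_test_manifest(n_variants = 3, clones_per_variant = 1)
  sim <- simulate_reads(man, 200, seed = 31)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(sim$reads, path)
  direct <- extract_barcodes(sim$reads, man)
  from_file <- extract_barcodes(path, man)
  expect_equal(from_file$counts, direct$counts)
})
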