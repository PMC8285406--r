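# Barcode extraction and counting for pooled competition screens.
#
# Reads carry a 10-bp clone barcode embedded between two fixed 10-bp flanks
# (5'-CTAGACTGCC <NNNNNNNNNN> GGATCACTCT-3'). Flank matching is always exact;
# an optional single-mismatch rescue applies to the barcode itself against
# the manifest whitelist.

BARCODE_FLANK_5 <- "CTAGACTGCC"
BARCODE_FLANK_3 <- "GGATCACTCT"
BARCODE_WIDTH <- 10L

#' Read a barcode manifest
#'
#' The manifest maps each 10-nt clone barcode to its clone, variant and gene,
#' and records the clone's role in the screen (`variant`, `wild_type`,
#' `negative_control`, `positive_control`).
#'
#' @param path path to a tab-separated file with header columns
#'   `barcode`, `clone_id`, `variant_id`, `gene`, `role`.
#' @return a validated tibble.
#' @export
read_barcode_manifest <- function(path) {
  manifest <- readr::read_tsv(path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  validate_manifest(manifest)
}

#' Validate a barcode manifest
#'
#' Checks barcode uniqueness, width (exactly 10 nt), DNA alphabet and the
#' role vocabulary.
#'
#' @param manifest a data frame with columns `barcode`, `clone_id`,
#'   `variant_id`, `gene`, `role`.
#' @return the manifest as a tibble, invisibly checked.
#' @export
validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  assert_cols(manifest, c("barcode", "clone_id", "variant_id", "gene", "role"),
              "barcode manifest")
  if (nrow(manifest) == 0) abort("barcode manifest is empty", class = "mano_config_error")
  if (anyDuplicated(manifest$barcode)) {
    abort(sprintf("duplicated barcode(s): %s",
                  paste(unique(manifest$barcode[duplicated(manifest$barcode)]), collapse = ", ")))
  }
  if (any(nchar(manifest$barcode) != BARCODE_WIDTH)) {
    abort("all barcodes must be exactly 10 nt")
  }
  if (any(grepl("[^ACGT]", manifest$barcode))) {
    abort("barcodes must use only A/C/G/T", class = "mano_validation_error")
  }
  bad_role <- setdiff(unique(manifest$role),
                      c("variant", "wild_type", "negative_control", "positive_control"))
  if (length(bad_role) > 0) {
    abort(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")))
  }
  manifest
}

#' Read sample metadata
#'
#' @param path tab-separated file with header columns `sample_id`, `day`,
#'   `condition`, `drug`, `concentration_nM`, `replicate`, `batch`.
#' @return a tibble; `condition` must be one of `baseline`, `vehicle`, `drug`.
#' @export
read_sample_metadata <- function(path) {
  samples <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               sample_id = "c", day = "i", condition = "c",
                               drug = "c", concentration_nM = "d",
                               replicate = "i", batch = "c"))
  validate_samples(samples)
}

validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  assert_cols(samples, c("sample_id", "day", "condition", "drug",
                         "concentration_nM", "replicate", "batch"),
              "sample metadata")
  if (anyDuplicated(samples$sample_id)) abort("sample_id values must be unique")
  bad <- setdiff(unique(samples$condition), c("baseline", "vehicle", "drug"))
  if (length(bad) > 0) abort(sprintf("unknown condition(s): %s", paste(bad, collapse = ", ")))
  samples
}

#' Load reads from a FASTQ file
#'
#' Plain or gzip-compressed FASTQ; sequences are returned as a named
#' character vector (names are read ids up to the first whitespace), ready
#' for [extract_barcodes()].
#'
#' @param path path to a `.fastq`/`.fq`(`.gz`) file.
#' @return named character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTQ requires the Biostrings package")
  }
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- as.character(dss)
  names(reads) <- sub("\\s.*$", "", names(dss))
  reads
}

#' Extract clone barcodes from reads
#'
#' Scans each read for the fixed flank pattern
#' `CTAGACTGCC<10 nt>GGATCACTCT` (flanks exact, always), pulls the embedded
#' 10-mer, and assigns it to the manifest whitelist. With `max_mismatch = 1`
#' an extracted 10-mer absent from the whitelist is rescued iff exactly one
#' whitelist barcode lies within Hamming distance 1; ambiguous or
#' unrescuable 10-mers are tallied as unmatched with a reason code. Each
#' read contributes at most one barcode: the leftmost pattern occurrence on
#' the forward strand is used, then (under the `both` orientation policy)
#' the reverse complement is searched; surplus occurrences increment a
#' multi-hit diagnostic. Mates sharing a read id that yield the same barcode
#' are deduplicated so the barcode counts once.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids; unnamed reads are treated as distinct), or a path to a FASTQ file.
#' @param manifest barcode manifest (see [read_barcode_manifest()]).
#' @param max_mismatch 0 or 1; mismatch tolerance on the barcode only.
#' @param orientation `"both"` (default) searches the read and its reverse
#'   complement; `"forward"` searches the given sequence only.
#' @return an object of class `barcode_tally`: a list with `counts`
#'   (tibble `barcode`, `clone_id`, `count`, zero-filled over the manifest),
#'   `unmatched` (tibble `reason`, `n`), `total_reads`, `matched_reads`,
#'   `unmatched_reads` and `multi_hit`.
#' @export
#' @examples
#' man <- tibble::tibble(barcode = "AAACCCGGTT", clone_id = "c1",
#'                       variant_id = "FGFR2_N549K", gene = "FGFR2",
#'                       role = "variant")
#' extract_barcodes("TTCTAGACTGCCAAACCCGGTTGGATCACTCTAA", man)$counts
extract_barcodes <- function(reads, manifest, max_mismatch = 0,
                             orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  if (!max_mismatch %in% c(0L, 1L)) abort("max_mismatch must be 0 or 1")
  manifest <- validate_manifest(manifest)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq_reads(reads)
  }
  if (length(reads) == 0) abort("reads must be non-empty")
  ids <- names(reads) %||% as.character(seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  reads <- toupper(unname(reads))

  pattern <- paste0(BARCODE_FLANK_5, "(.{", BARCODE_WIDTH, "})", BARCODE_FLANK_3)

  # leftmost forward-strand occurrence, then reverse complement
  hit_fwd <- regexpr(pattern, reads, perl = TRUE)
  n_fwd <- vapply(gregexpr(pattern, reads, perl = TRUE),
                  function(m) sum(m > 0L), integer(1))
  extracted <- rep(NA_character_, length(reads))
  has_fwd <- hit_fwd > 0L
  extracted[has_fwd] <- substr(reads[has_fwd],
                               hit_fwd[has_fwd] + nchar(BARCODE_FLANK_5),
                               hit_fwd[has_fwd] + nchar(BARCODE_FLANK_5) + BARCODE_WIDTH - 1L)
  n_occ <- n_fwd
  if (orientation == "both") {
    todo <- !has_fwd
    rc <- revcomp(reads)
    hit_rc <- regexpr(pattern, rc, perl = TRUE)
    n_rc <- vapply(gregexpr(pattern, rc, perl = TRUE),
                   function(m) sum(m > 0L), integer(1))
    use_rc <- todo & hit_rc > 0L
    extracted[use_rc] <- substr(rc[use_rc],
                                hit_rc[use_rc] + nchar(BARCODE_FLANK_5),
                                hit_rc[use_rc] + nchar(BARCODE_FLANK_5) + BARCODE_WIDTH - 1L)
    # forward occurrences and reverse-complement occurrences of the same
    # pattern are distinct hits for the multi-hit diagnostic
    n_occ <- n_fwd + n_rc
  }
  multi_hit <- sum(pmax(n_occ - 1L, 0L))

  whitelist <- manifest$barcode
  assigned <- whitelist[match(extracted, whitelist)]
  reason <- rep(NA_character_, length(reads))
  reason[is.na(extracted)] <- "no_flank"

  if (max_mismatch == 1L) {
    unknown <- !is.na(extracted) & is.na(assigned)
    if (any(unknown)) {
      uniq <- unique(extracted[unknown])
      clean <- !grepl("[^ACGT]", uniq)
      rescue <- rep(NA_character_, length(uniq))
      status <- rep("unrescuable_barcode", length(uniq))
      for (i in which(clean)) {
        d <- hamming_to(whitelist, uniq[i])
        near <- which(d <= 1L)
        if (length(near) == 1L) {
          rescue[i] <- whitelist[near]
          status[i] <- "rescued"
        } else if (length(near) > 1L) {
          status[i] <- "ambiguous_rescue"
        }
      }
      idx <- match(extracted[unknown], uniq)
      assigned[unknown] <- rescue[idx]
      reason[unknown] <- ifelse(status[idx] == "rescued", NA_character_, status[idx])
    }
  } else {
    reason[!is.na(extracted) & is.na(assigned)] <- "unrescuable_barcode"
  }

  # deduplicate mates: the same (read id, barcode) pair counts once
  matched <- !is.na(assigned)
  key <- paste(ids, assigned, sep = "\r")
  dup <- matched & duplicated(key)
  assigned[dup] <- NA_character_
  reason[dup] <- "duplicate_mate"
  matched <- !is.na(assigned)

  counts <- manifest |>
    select("barcode", "clone_id") |>
    left_join(tibble(barcode = assigned[matched]) |> count(.data$barcode, name = "count"),
              by = "barcode") |>
    mutate(count = as.integer(replace_na(.data$count, 0L)))

  unmatched <- tibble(reason = reason[!matched]) |>
    count(.data$reason, name = "n") |>
    arrange(.data$reason)

  structure(list(
    counts = counts,
    unmatched = unmatched,
    total_reads = length(reads),
    matched_reads = sum(matched),
    unmatched_reads = sum(!matched),
    multi_hit = multi_hit
  ), class = "barcode_tally")
}

#' @export
print.barcode_tally <- function(x, ...) {
  cat(sprintf("<barcode_tally> %d reads: %d matched, %d unmatched, %d surplus hits\n",
              x$total_reads, x$matched_reads, x$unmatched_reads, x$multi_hit))
  print(x$counts, n = 5)
  invisible(x)
}

#' Build a clone-by-sample count matrix
#'
#' Aggregates per-sample barcode tallies to clone level (one barcode is one
#' clone), zero-fills clones with no reads, and joins clone annotation and
#' sample metadata into one long tibble ready for normalization.
#'
#' @param tallies a named list of `barcode_tally` objects (names are sample
#'   ids), or a tibble with columns `sample_id`, `barcode`, `count`.
#' @param manifest barcode manifest.
#' @param samples sample metadata (see [read_sample_metadata()]); every
#'   tally name must appear in `sample_id`.
#' @return a tibble with one row per clone x sample: `clone_id`,
#'   `variant_id`, `gene`, `role`, `sample_id`, `day`, `condition`, `drug`,
#'   `concentration_nM`, `replicate`, `batch`, `count`. A per-sample run
#'   report (total/matched/unmatched/multi-hit, when available) is attached
#'   as attribute `run_report`.
#' @export
build_count_matrix <- function(tallies, manifest, samples) {
  manifest <- validate_manifest(manifest)
  samples <- validate_samples(samples)
  report <- NULL
  if (is.data.frame(tallies)) {
    assert_cols(tallies, c("sample_id", "barcode", "count"), "barcode counts")
    long <- as_tibble(tallies)
  } else {
    stopifnot(is.list(tallies), !is.null(names(tallies)))
    long <- imap(tallies, function(t, sid) {
      stopifnot(inherits(t, "barcode_tally"))
      t$counts |> select("barcode", "count") |> mutate(sample_id = sid)
    }) |> list_rbind()
    report <- imap(tallies, function(t, sid) {
      tibble(sample_id = sid, total_reads = t$total_reads,
             matched_reads = t$matched_reads,
             unmatched_reads = t$unmatched_reads, multi_hit = t$multi_hit)
    }) |> list_rbind()
  }
  stray <- setdiff(unique(long$barcode), manifest$barcode)
  if (length(stray) > 0) {
    abort(sprintf("barcode(s) absent from manifest: %s", paste(stray, collapse = ", ")))
  }
  missing_s <- setdiff(unique(long$sample_id), samples$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("sample(s) missing metadata: %s", paste(missing_s, collapse = ", ")))
  }
  counts <- long |>
    left_join(manifest |> select("barcode", "clone_id"), by = "barcode") |>
    group_by(.data$clone_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  grid <- expand_grid(clone_id = manifest$clone_id,
                      sample_id = unique(long$sample_id))
  out <- grid |>
    left_join(counts, by = c("clone_id", "sample_id")) |>
    mutate(count = as.integer(replace_na(.data$count, 0L))) |>
    left_join(manifest |> select("clone_id", "variant_id", "gene", "role") |> distinct(),
              by = "clone_id") |>
    left_join(samples, by = "sample_id") |>
    select("clone_id", "variant_id", "gene", "role", "sample_id", "day",
           "condition", "drug", "concentration_nM", "replicate", "batch", "count")
  attr(out, "run_report") <- report
  out
}

#' Write a count matrix and its run report
#'
#' Writes the clone x sample counts as a wide TSV (rows clones, columns
#' samples) and, when present, the per-sample run report as JSON.
#'
#' @param counts long count tibble from [build_count_matrix()].
#' @param path output TSV path; the JSON report is written next to it as
#'   `<path>.report.json`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  wide <- counts |>
    select("clone_id", "sample_id", "count") |>
    pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path)
  report <- attr(counts, "run_report")
  if (!is.null(report)) {
    jsonlite::write_json(report, paste0(path, ".report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
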