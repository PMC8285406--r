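# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Brute-force barcode scan: per-offset substring comparison (no regular
# expressions), forward strand first, then reverse complement; leftmost
# hit wins; exact whitelist match only.
oracle_barcode_scan <- function(reads, whitelist) {
  flank5 <- "CTAGACTGCC"; flank3 <- "GGATCACTCT"
  rc <- function(x) chartr("ACGT", "TGCA",
                           vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                                  character(1)))
  scan_one_strand <- function(seqs) {
    found <- rep(NA_character_, length(seqs))
    width <- nchar(seqs)
    for (off in seq_len(max(width) - 29)) {
      open <- is.na(found) & width >= off + 29
      if (!any(open)) break
      hit <- open &
        substr(seqs, off, off + 9) == flank5 &
        substr(seqs, off + 20, off + 29) == flank3
      found[hit] <- substr(seqs[hit], off + 10, off + 19)
    }
    found
  }
  fwd <- scan_one_strand(reads)
  rev <- scan_one_strand(rc(reads))
  extracted <- ifelse(is.na(fwd), rev, fwd)
  assigned <- extracted[extracted %in% whitelist]
  counts <- table(factor(assigned, levels = whitelist))
  list(counts = as.integer(counts),
       barcodes = whitelist,
       n_matched = length(assigned),
       n_unmatched = length(reads) - length(assigned))
}

# Naive O(n^3) UPGMA on a distance matrix: explicit cluster member lists,
# inter-cluster distance recomputed as the mean over all member pairs.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Closed-form ordinal class probabilities for the latent-logistic model.
oracle_ordinal_probs <- function(eta, thresholds, scale = 1) {
  q <- plogis((thresholds - eta) / scale)
  c(q[1], q[2] - q[1], q[3] - q[2], 1 - q[3])
}

# Brute-force grid posterior for the two-variant toy with batch effects and
# thresholds clamped: integrates the ordinal-logistic likelihood times the
# N(0,1) prior over a fine (f1, f2) grid.
oracle_grid_posterior_fpos <- function(scores, beta, tau, thresholds,
                                       grid = seq(-4, 4, by = 0.05)) {
  variants <- sort(unique(scores$variant_id))
  batches <- sort(unique(scores$batch))
  stopifnot(length(variants) == 2)
  loglik_f <- function(f, vid) {
    sub <- scores[scores$variant_id == vid, ]
    b <- match(sub$batch, batches)
    eta <- beta[b] + tau[b] * f
    sum(log(vapply(seq_along(eta), function(i) {
      oracle_ordinal_probs(eta[i], thresholds)[sub$score[i]]
    }, numeric(1))))
  }
  # f1 and f2 are a posteriori independent here (likelihood factorises)
  vapply(variants, function(vid) {
    lp <- vapply(grid, function(f) loglik_f(f, vid) + dnorm(f, log = TRUE),
                 numeric(1))
    w <- exp(lp - max(lp))
    sum(w[grid > 0]) / sum(w)
  }, numeric(1))
}

# Small helper manifest used across barcode tests.
make_test_manifest <- function(n_variants = 10, clones_per_variant = 3,
                               seed = 101) {
  n <- n_variants * clones_per_variant
  tibble::tibble(
    barcode = generate_barcodes(n, min_dist = 3, seed = seed),
    clone_id = sprintf("v%02d_c%d", rep(seq_len(n_variants), each = clones_per_variant),
                       rep(seq_len(clones_per_variant), n_variants)),
    variant_id = sprintf("v%02d", rep(seq_len(n_variants), each = clones_per_variant)),
    gene = "FGFR2",
    role = rep(c("wild_type", rep("variant", n_variants - 2), "negative_control"),
               each = clones_per_variant))
}
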