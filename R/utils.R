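# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Hamming distance between equal-length DNA strings
#'
#' Vectorised over `x`; `y` is a single string of the same width.
#'
#' @param x character vector of sequences.
#' @param y single sequence of the same nchar as the elements of `x`.
#' @return integer vector of mismatch counts.
#' @keywords internal
#' @noRd
hamming_to <- function(x, y) {
  stopifnot(length(y) == 1L)
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = nchar(y), byrow = TRUE)
  ym <- strsplit(y, "", fixed = TRUE)[[1]]
  rowSums(xm != matrix(ym, nrow(xm), length(ym), byrow = TRUE))
}

#' Reverse complement of DNA strings
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Derive a stage-specific seed from a root seed
#'
#' One root seed is fanned out to per-stage seeds by hashing the stage name
#' (FNV-1a, folded into the positive 31-bit integer range) and combining it
#' with the root seed. Deterministic and platform-independent, so any single
#' stage is reproducible in isolation.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return a single integer usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "barcode_quant")
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stage))
  h <- 2166136261
  for (code in utf8ToInt(stage)) {
    # xor only touches the low byte (code < 256); keeps h exact as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), code)
    # 32-bit FNV-1a multiply, kept exact with double arithmetic
    h <- (h %% 65536) * 16777619 %% 4294967296 +
      ((h %/% 65536) * 16777619 %% 65536) * 65536
    h <- h %% 4294967296
  }
  as.integer((as.numeric(root_seed) + h) %% 2147483647)
}

#' FNV-1a hash of a character scalar (hex), used for config provenance
#' @keywords internal
#' @noRd
fnv1a_hex <- function(x) {
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), code)
    h <- (h %% 65536) * 16777619 %% 4294967296 +
      ((h %/% 65536) * 16777619 %% 65536) * 65536
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
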