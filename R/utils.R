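# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Running windowed extreme over a truncated (edge-clipped) window of
# half-width `half_window`. `op` is pmin (erosion) or pmax (dilation).
# Vectorised as a reduction over shifted copies; out-of-range positions are
# padded with the operation's neutral element so edges see the clipped window.
.running_extreme <- function(x, half_window, op = pmin) {
  n <- length(x)
  pad <- if (identical(op, pmin)) Inf else -Inf
  out <- x
  for (k in seq_len(half_window)) {
    right <- c(x[-seq_len(k)], rep.int(pad, k))        # x[i + k]
    left <- c(rep.int(pad, k), x[seq_len(n - k)])      # x[i - k]
    out <- op(out, right, left)
  }
  out
}

# Stratified fold assignment: within each class, samples are shuffled and
# folds dealt out cyclically, so fold sizes differ by at most one per class.
# Consumes the current RNG stream.
.stratified_folds <- function(y, k) {
  n <- length(y)
  if (n < k) {
    stop("fewer samples (", n, ") than folds (", k, ")", call. = FALSE)
  }
  folds <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# 0/0-safe ratio: undefined diagnostic ratios are reported as NA, never 0.
.safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

# Deterministic md5-based hash of an arbitrary configuration object,
# embedded in artifacts for provenance.
.hash_config <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                           force = TRUE)), tf)
  unname(tools::md5sum(tf))
}
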