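# Internal helpers shared across modules.

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise read sequences to the DNA alphabet: uppercase, U -> T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Half-up rounding to `digits` decimal places (R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Stop unless `x` is a data frame containing all of `cols`.
check_cols <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Per-position signal from interval placements via a difference array.
# starts/ends are 0-based half-open offsets within [0, L); w is the weight
# added over each interval. Returns a numeric vector of length L.
interval_coverage <- function(starts, ends, w, L) {
  cov <- numeric(L + 1)
  if (length(starts) > 0) {
    s <- pmax(starts, 0L) + 1L
    e <- pmin(ends, L) + 1L
    keep <- s <= L & e >= s
    s <- s[keep]; e <- e[keep]; wk <- w[keep]
    if (length(s) > 0) {
      idx <- c(s, e)
      val <- c(wk, -wk)
      agg <- rowsum(val, idx)
      cov[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  cumsum(cov)[seq_len(L)]
}

# Region keys used to join placements, profiles and peaks.
region_keys <- c("gene_id", "anchor", "region_strand")
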