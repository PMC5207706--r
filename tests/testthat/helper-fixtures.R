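# Fixture builders and independent brute-force oracles used across tests.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, random_dna(n)))
  }
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal boundary-region row compatible with the mapping / scanning API.
fixture_region <- function(sequence, gene_id = "g1", anchor = "TSS",
                           region_strand = "sense", chrom = "Chr1",
                           g_start = 1000L, gene_strand = "+") {
  L <- nchar(sequence)
  tibble::tibble(
    gene_id = gene_id, anchor = anchor, region_strand = region_strand,
    chrom = chrom, g_start = as.integer(g_start),
    g_end = as.integer(g_start + L), L = L,
    anchor_offset = 0L, truncated = FALSE, gene_strand = gene_strand,
    seq_rev = xor(gene_strand == "-", region_strand == "antisense"),
    compartment = "nuclear", sequence = sequence
  )
}

# Placement rows keyed to a fixture region.
fixture_placements <- function(starts, ends, rpm,
                               gene_id = "g1", anchor = "TSS",
                               region_strand = "sense",
                               library_id = "libA", role = "wt",
                               organ_or_genotype = "leaf") {
  tibble::tibble(
    gene_id = gene_id, anchor = anchor, region_strand = region_strand,
    start = as.integer(starts), end = as.integer(ends), rpm = rpm,
    sequence = strrep("A", ends - starts),
    raw_count = 1L, library_id = library_id, role = role,
    organ_or_genotype = organ_or_genotype
  )
}

# Random placements with integer rpm over a region of length L.
random_placements <- function(n, L, seed, max_rpm = 50, ...) {
  withr::with_seed(seed, {
    len <- sample(19:28, n, replace = TRUE)
    start <- sample(0:(L - max(len)), n, replace = TRUE)
    fixture_placements(start, start + len,
                       rpm = as.numeric(sample(1:max_rpm, n, TRUE)), ...)
  })
}

# Brute-force oracles ------------------------------------------------------

# Per-position signal by explicit position-by-position recount.
oracle_coverage <- function(placements, L) {
  vapply(seq_len(L) - 1L, function(p) {
    sum(placements$rpm[placements$start <= p & placements$end > p])
  }, numeric(1))
}

# Window sums by explicit enumeration of all offsets (overlap assignment).
oracle_window_S2 <- function(placements, L, w = 50) {
  offsets <- 0:(L - w)
  vapply(offsets, function(o) {
    sum(placements$rpm[placements$start < o + w & placements$end > o])
  }, numeric(1))
}

# All exact occurrences of a pattern by scanning every offset.
oracle_match_offsets <- function(pattern, subject) {
  n <- nchar(pattern)
  hits <- integer(0)
  for (o in 0:(nchar(subject) - n)) {
    if (substring(subject, o + 1, o + n) == pattern) hits <- c(hits, o)
  }
  hits
}

write_tmp_fasta <- function(headers, seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
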