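test_that("longest model wins and anchors follow the gene strand", {
  tx <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_id = c("gA.1", "gA.2", "gB.1", "gC.1"),
    chrom = "Chr1",
    strand = c("+", "+", "+", "-"),
    start = c(5001L, 5101L, 800L, 1000L),
    end = c(6200L, 6000L, 1200L, 2000L)
  )
  models <- select_longest_models(tx)

  gA <- models[models$gene_id == "gA", ]
  expect_equal(gA$body_length, 1200L)
  expect_equal(gA$tss, 5001L)
  expect_equal(gA$terminus, 6200L)

  # single isoform returned unchanged
  gB <- models[models$gene_id == "gB", ]
  expect_equal(c(gB$tss, gB$terminus, gB$body_length), c(800L, 1200L, 401L))

  # minus strand: TSS is the 3'-most genomic coordinate
  gC <- models[models$gene_id == "gC", ]
  expect_equal(gC$tss, 2000L)
  expect_equal(gC$terminus, 1000L)
})

test_that("conflicting strand or chromosome raises a named error", {
  tx <- tibble::tibble(
    gene_id = "gX", transcript_id = c("t1", "t2"), chrom = "Chr1",
    strand = c("+", "-"), start = c(1L, 1L), end = c(100L, 90L)
  )
  expect_error(select_longest_models(tx), "gX")
})

test_that("organellar compartments are inferred from chromosome names", {
  tx <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), transcript_id = c("a", "b", "c"),
    chrom = c("Chr2", "ChrC", "ChrM"), strand = "+",
    start = 1L, end = 100L
  )
  models <- select_longest_models(tx)
  expect_equal(models$compartment,
               c("nuclear", "chloroplast", "mitochondrial"))
})

test_that("boundary regions follow the flank + min(flank, body) rule", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = random_dna(20000, seed = 11)))
  models <- tibble::tibble(
    gene_id = c("long", "short"),
    chrom = "Chr1", strand = "+",
    tss = c(10001L, 1001L),
    terminus = c(12000L, 1300L),
    body_length = c(2000L, 300L),
    compartment = "nuclear"
  )
  regions <- extract_boundary_regions(models, genome)

  tl <- regions[regions$gene_id == "long" & regions$anchor == "TSS" &
                  regions$region_strand == "sense", ]
  # 1-based [9501, 10500]
  expect_equal(c(tl$g_start, tl$g_end, tl$L), c(9500L, 10500L, 1000L))
  expect_equal(tl$anchor_offset, 500L)

  term <- regions[regions$gene_id == "long" & regions$anchor == "terminus" &
                    regions$region_strand == "sense", ]
  expect_equal(c(term$g_start, term$g_end, term$L), c(11500L, 12500L, 1000L))

  ts <- regions[regions$gene_id == "short" & regions$anchor == "TSS" &
                  regions$region_strand == "sense", ]
  # short-gene rule: 500 + min(500, 300); 1-based [501, 1300]
  expect_equal(c(ts$g_start, ts$g_end, ts$L), c(500L, 1300L, 800L))

  # all four regions exist per gene; L = 1000 for the long-bodied gene
  expect_equal(nrow(regions), 8L)
  expect_true(all(regions$L[regions$gene_id == "long"] == 1000L))
})

test_that("antisense sequence is the reverse complement over the same interval", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = random_dna(5000, seed = 3)))
  models <- tibble::tibble(
    gene_id = "g", chrom = "Chr1", strand = "+", tss = 2001L,
    terminus = 3500L, body_length = 1500L, compartment = "nuclear"
  )
  regions <- extract_boundary_regions(models, genome)
  sense <- regions[regions$anchor == "TSS" &
                     regions$region_strand == "sense", ]
  antis <- regions[regions$anchor == "TSS" &
                     regions$region_strand == "antisense", ]
  expect_equal(c(antis$g_start, antis$g_end), c(sense$g_start, sense$g_end))
  expect_equal(
    antis$sequence,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sense$sequence)
    ))
  )
  expect_equal(antis$anchor_offset, sense$L - 1L - sense$anchor_offset)
})

test_that("the anchor base sits at anchor_offset on both strands", {
  # all-A chromosome with a single C planted at the TSS
  chr <- paste0(strrep("A", 1999), "C", strrep("A", 3000))
  genome <- Biostrings::DNAStringSet(c(Chr1 = chr))
  for (strand in c("+", "-")) {
    models <- tibble::tibble(
      gene_id = "g", chrom = "Chr1", strand = strand,
      tss = 2000L,
      terminus = if (strand == "+") 3200L else 900L,
      body_length = if (strand == "+") 1201L else 1101L,
      compartment = "nuclear"
    )
    regions <- extract_boundary_regions(models, genome)
    sense <- regions[regions$anchor == "TSS" &
                       regions$region_strand == "sense", ]
    base <- substring(sense$sequence, sense$anchor_offset + 1,
                      sense$anchor_offset + 1)
    expect_equal(base, if (strand == "+") "C" else "G")
  }
})

test_that("regions truncated at chromosome ends are flagged with reduced L", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = random_dna(3000, seed = 5)))
  models <- tibble::tibble(
    gene_id = "edge", chrom = "Chr1", strand = "+", tss = 200L,
    terminus = 1400L, body_length = 1201L, compartment = "nuclear"
  )
  regions <- extract_boundary_regions(models, genome)
  ts <- regions[regions$anchor == "TSS" & regions$region_strand == "sense", ]
  expect_true(ts$truncated)
  expect_equal(ts$g_start, 0L)
  expect_equal(ts$L, 199L + 500L)
  expect_equal(ts$anchor_offset, 199L)
})

test_that("region sequences round-trip to their genomic coordinates", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = random_dna(30000, seed = 8)))
  models <- tibble::tibble(
    gene_id = c("p", "m"), chrom = "Chr1", strand = c("+", "-"),
    tss = c(5001L, 24000L), terminus = c(7000L, 22001L),
    body_length = 2000L, compartment = "nuclear"
  )
  regions <- extract_boundary_regions(models, genome)
  fwd <- substring(as.character(genome[["Chr1"]]),
                   regions$g_start + 1, regions$g_end)
  expected <- ifelse(
    regions$seq_rev,
    vapply(fwd, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1)),
    fwd
  )
  expect_equal(regions$sequence, unname(expected))
})

test_that("invalid gene models are rejected", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = random_dna(1000, seed = 2)))
  base <- tibble::tibble(
    gene_id = "g", chrom = "Chr1", strand = "+", tss = 100L,
    terminus = 200L, body_length = 101L, compartment = "nuclear"
  )
  expect_error(
    extract_boundary_regions(dplyr::mutate(base, tss = 5000L), genome),
    "bounds"
  )
  expect_error(
    extract_boundary_regions(dplyr::mutate(base, body_length = 0L), genome),
    "Zero-length"
  )
  expect_error(
    extract_boundary_regions(dplyr::mutate(base, chrom = "Chr9"), genome),
    "Chr9"
  )
})
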