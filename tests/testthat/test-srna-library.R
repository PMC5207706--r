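test_that("collapsed FASTA loads with summed totals and collapsing", {
  s1 <- "ACGTACGTACGTACGTACGTA"
  s2 <- "TGCATGCATGCATGCATGCAT"
  path <- write_tmp_fasta(c("r1_5", "r2_3"), c(s1, s2))
  reads <- load_srna_library(path, "libA")
  expect_equal(unique(reads$total_raw_count), 8L)
  expect_equal(sort(reads$raw_count), c(3L, 5L))

  # duplicate sequences collapse with summed counts
  path2 <- write_tmp_fasta(c("a_5", "b_3"), c(s1, s1))
  reads2 <- load_srna_library(path2, "libB")
  expect_equal(nrow(reads2), 1L)
  expect_equal(reads2$raw_count, 8L)
  # U and T spellings of the same read collapse together
  path3 <- write_tmp_fasta(c("a_2", "b_3"),
                           c("ACGUACGUACGUACGUACGUA", s1))
  reads3 <- load_srna_library(path3, "libC")
  expect_equal(nrow(reads3), 1L)
  expect_equal(reads3$raw_count, 5L)
})

test_that("malformed count fields are rejected with the record index", {
  path <- write_tmp_fasta(c("r1_5", "r2_x"), c("ACGT", "AAAA"))
  expect_error(load_srna_library(path, "bad"), "record 2")
})

test_that("FASTQ records each count once", {
  seqs <- withr::with_seed(9, {
    pool <- replicate(8, random_dna(21))
    sample(pool, 12, replace = TRUE)
  })
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(
    paste0("@r", seq_along(seqs)), seqs, "+",
    strrep("I", nchar(seqs))
  )), path)
  reads <- load_srna_library(path, "fq")
  expect_equal(unique(reads$total_raw_count), 12L)
  expect_equal(nrow(reads), length(unique(seqs)))
  expect_equal(sum(reads$raw_count), 12L)
})

test_that("reads with N or >= 40 nt stay in the total but not the read set", {
  path <- write_tmp_fasta(
    c("ok_4", "hasn_2", "long_3"),
    c("ACGTACGTACGTACGTACGTA", "ACGTNCGTACGTACGTACGTA", strrep("A", 45))
  )
  expect_warning(reads <- load_srna_library(path, "filt"), "excluded")
  expect_equal(nrow(reads), 1L)
  expect_equal(unique(reads$total_raw_count), 9L)
  expect_equal(reads$rpm, 4 / 9 * 1e6)
})

test_that("RPM normalisation follows the printed formula", {
  expect_equal(normalize_rpm(5, 2e6), 2.5)
  expect_equal(normalize_rpm(0, 1e6), 0)
  expect_error(normalize_rpm(1, 0), "positive")

  # conservation: rpm over a whole library sums to one million
  counts <- withr::with_seed(4, sample(1:500, 200, replace = TRUE))
  rpm <- normalize_rpm(counts, sum(counts))
  expect_equal(sum(rpm), 1e6, tolerance = 1e-9)
})

test_that("perfect-match mapping finds exactly the exact occurrences", {
  read <- "ACGTACGT"
  left <- random_dna(17, seed = 21)
  seq <- paste0(left, read, random_dna(75, seed = 22))
  region <- fixture_region(seq)
  reads <- tibble::tibble(sequence = read, raw_count = 1L, rpm = 1,
                          library_id = "l", role = "wt",
                          organ_or_genotype = "leaf")
  hits <- map_perfect(reads, region)
  oracle <- oracle_match_offsets(read, seq)
  expect_equal(hits$start, oracle)
  expect_true(all(hits$end - hits$start == nchar(read)))

  # one mismatch: no placements
  mm <- tibble::tibble(sequence = "ACGTACGA", raw_count = 1L, rpm = 1,
                       library_id = "l", role = "wt",
                       organ_or_genotype = "leaf")
  mm_hits <- map_perfect(mm, region)
  oracle_mm <- oracle_match_offsets("ACGTACGA", seq)
  expect_equal(nrow(mm_hits), length(oracle_mm))
})

test_that("multiple occurrences match a naive all-offsets scan", {
  motif <- "TTAGGCATTAGGCATTAGGCA"  # 21 nt
  seq <- paste0(random_dna(40, seed = 31), motif, random_dna(30, seed = 32),
                motif, random_dna(50, seed = 33))
  region <- fixture_region(seq)
  reads <- tibble::tibble(sequence = motif, raw_count = 2L, rpm = 4,
                          library_id = "l", role = "wt",
                          organ_or_genotype = "leaf")
  hits <- map_perfect(reads, region)
  expect_equal(sort(hits$start), oracle_match_offsets(motif, seq))
  expect_true(nrow(hits) >= 2)
})

test_that("U and T spellings of a read map identically", {
  seq <- random_dna(200, seed = 41)
  region <- fixture_region(seq)
  sub <- substring(seq, 51, 72)
  as_u <- chartr("T", "U", sub)
  hits_t <- map_perfect(tibble::tibble(sequence = sub), region)
  hits_u <- map_perfect(tibble::tibble(sequence = as_u), region)
  expect_equal(hits_t$start, hits_u$start)
  expect_gt(nrow(hits_t), 0)
})

test_that("a sense hit implies the reverse-complement antisense hit", {
  seq <- random_dna(300, seed = 51)
  sense <- fixture_region(seq, region_strand = "sense")
  antis <- fixture_region(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    region_strand = "antisense"
  )
  regions <- dplyr::bind_rows(sense, antis)
  read <- substring(seq, 101, 124)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)
  ))
  hits <- map_perfect(tibble::tibble(sequence = c(read, rc)), regions)
  fwd <- hits[hits$sequence == read & hits$region_strand == "sense", ]
  rev <- hits[hits$sequence == rc & hits$region_strand == "antisense", ]
  expect_equal(fwd$start, 100L)
  expect_equal(rev$start, 300L - 100L - 24L)
})

test_that("fractional multi-mapping splits rpm across placements", {
  seq1 <- paste0(random_dna(50, seed = 61), "ACGTACGTACGTACGTACGTA",
                 random_dna(50, seed = 62))
  seq2 <- paste0(random_dna(30, seed = 63), "ACGTACGTACGTACGTACGTA",
                 random_dna(70, seed = 64))
  regions <- dplyr::bind_rows(
    fixture_region(seq1, gene_id = "g1"),
    fixture_region(seq2, gene_id = "g2")
  )
  reads <- tibble::tibble(sequence = "ACGTACGTACGTACGTACGTA",
                          raw_count = 1L, rpm = 10)
  full <- map_perfect(reads, regions, multimap = "full")
  frac <- map_perfect(reads, regions, multimap = "fractional")
  expect_equal(nrow(full), 2L)
  expect_equal(full$rpm, c(10, 10))
  expect_equal(frac$rpm, c(5, 5))
})
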