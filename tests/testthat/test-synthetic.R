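# Small simulated datasets exercise the generator contracts; the
# full-scale recovery run lives in the acceptance tests.

small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_genes = 24,
             n_organellar = c(chloroplast = 2, mitochondrial = 2),
             library_size = 100000, ...)
}

test_that("a dataset with no planted peaks yields no screened peaks", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(seed = 12, frac_planted = 0), dir)
  expect_equal(nrow(sim$truth), 0L)
  res <- run_pipeline(dir)
  expect_equal(nrow(res$catalog), 0L)
  expect_equal(res$summary$counts$n_genes, rep(0L, 6))
})

test_that("library totals match the configured size and RPM sums to 1e6", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 13)
  simulate_dataset(cfg, dir)
  manifest <- readr::read_tsv(file.path(dir, "libraries.tsv"),
                              show_col_types = FALSE)
  srna <- manifest[manifest$role != "dsrna", ]
  for (i in sample(nrow(srna), 3)) {
    reads <- load_srna_library(file.path(dir, srna$file[i]),
                               srna$library_id[i], srna$role[i],
                               srna$organ_or_genotype[i])
    expect_equal(unique(reads$total_raw_count), cfg$library_size)
    expect_equal(sum(reads$rpm), 1e6, tolerance = 1e-9)
  }
})

test_that("truth records correspond to reads actually emitted", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 14)
  sim <- simulate_dataset(cfg, dir)
  expect_gt(nrow(sim$truth), 0)
  genome <- read_genome(file.path(dir, "genome.fa"))
  regions <- extract_boundary_regions(
    select_longest_models(read_gene_annotation(
      file.path(dir, "annotation.gff3")
    )),
    genome
  )
  reads <- load_library_set(file.path(dir, "libraries.tsv"), dir = dir)
  pl <- map_perfect(dplyr::filter(reads, role == "wt"), regions)
  # every planted locus has wild-type placements inside its span
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    n_in <- pl |>
      dplyr::filter(gene_id == tr$gene_id, anchor == tr$anchor,
                    region_strand == tr$region_strand) |>
      dplyr::inner_join(
        dplyr::select(regions, dplyr::all_of(srnapeaks:::region_keys),
                      rg_start = g_start, rg_end = g_end, seq_rev),
        by = srnapeaks:::region_keys
      ) |>
      dplyr::mutate(
        pg_start = ifelse(seq_rev, rg_end - end, rg_start + start),
        pg_end = ifelse(seq_rev, rg_end - start, rg_start + end)
      ) |>
      dplyr::filter(pg_start < tr$g_end, pg_end > tr$g_start) |>
      nrow()
    expect_gt(n_in, 0)
  }
})

test_that("planted regions show the configured enrichment scale", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 15)
  sim <- simulate_dataset(cfg, dir)
  res <- run_pipeline(dir)
  called <- dplyr::semi_join(
    res$scan$peaks[res$scan$peaks$screened, ],
    sim$truth, by = srnapeaks:::region_keys
  )
  expect_gt(nrow(called), 0)
  # in-peak vs out-of-peak density approximates the planted 20x contrast
  expect_gt(stats::median(called$noise_ratio), cfg$enrichment / 2)
})

test_that("truth evaluation scores matches, misses and shifted calls", {
  truth <- tibble::tibble(
    gene_id = c("g1", "g2"), anchor = "TSS", region_strand = "sense",
    chrom = "Chr1", g_start = c(1000L, 5000L), g_end = c(1080L, 5080L),
    span = 80L, organ = "none", ago = c("AGO4", "none"),
    suppressed_genotypes = c("dcl3,rdr2", ""),
    dsrna_covered = FALSE, methylated = FALSE
  )
  perfect <- tibble::tibble(
    gene_id = c("g1", "g2"), anchor = "TSS", region_strand = "sense",
    g_start = c(1000L, 5000L), g_end = c(1080L, 5080L),
    ago_preference = c("AGO4", "none"), organ_specific = "none",
    dsrna_covered = FALSE, methylation_overlap = FALSE,
    dep_dcl3 = c("repressed", "not_repressed"),
    dep_rdr2 = c("repressed", "not_repressed"),
    dep_dcl2 = c("not_repressed", "not_repressed")
  )
  ev <- truth_evaluation(perfect, truth)
  expect_equal(ev$value[ev$metric == "sensitivity"], 1)
  expect_equal(ev$value[ev$metric == "precision"], 1)
  expect_equal(ev$value[ev$metric == "ago_agreement"], 1)
  expect_equal(ev$value[ev$metric == "mutant_agreement"], 1)

  # zero calls: sensitivity 0, precision undefined
  ev0 <- truth_evaluation(perfect[0, ], truth)
  expect_equal(ev0$value[ev0$metric == "sensitivity"], 0)
  expect_true(is.na(ev0$value[ev0$metric == "precision"]))

  # a 40%-overlap shifted call misses under the 50% rule
  shifted <- dplyr::mutate(perfect[1, ], g_start = 1048L, g_end = 1128L)
  ev_shift <- truth_evaluation(shifted, truth[1, ])
  expect_equal(ev_shift$value[ev_shift$metric == "sensitivity"], 0)
  # a 60%-overlap shifted call matches
  shifted2 <- dplyr::mutate(perfect[1, ], g_start = 1032L, g_end = 1112L)
  ev_shift2 <- truth_evaluation(shifted2, truth[1, ])
  expect_equal(ev_shift2$value[ev_shift2$metric == "sensitivity"], 1)
})
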