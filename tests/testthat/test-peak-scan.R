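test_that("profile statistics follow A1 = S1 / L", {
  region <- fixture_region(random_dna(1000, seed = 71))
  pl <- fixture_placements(100, 124, rpm = 100)
  prof <- build_profiles(pl, region)
  expect_equal(prof$S1, 100)
  expect_equal(prof$A1, 0.1)
  expect_equal(sum(prof$coverage[[1]] > 0), 24)
  expect_equal(prof$coverage[[1]][101], 100)

  # empty placements: valid all-zero profile
  empty <- build_profiles(pl[0, ], region)
  expect_equal(empty$S1, 0)
  expect_equal(empty$A1, 0)
  expect_true(all(empty$coverage[[1]] == 0))
})

test_that("window statistics match hand computation on a single read", {
  region <- fixture_region(random_dna(1000, seed = 72))
  pl <- fixture_placements(100, 124, rpm = 100)
  prof <- build_profiles(pl, region)
  win <- scroll_windows(prof, scan_config())
  w100 <- win[win$start == 100, ]
  expect_equal(w100$S2, 100)
  expect_equal(w100$A2, 2)
  expect_equal(w100$A1, 0.1)
  expect_true(w100$passes)  # 2 >= 10 * 0.1 and 2 >= 1
  # offsets out of reach of the read carry no signal
  expect_equal(win$S2[win$start == 300], 0)
  expect_equal(nrow(win), 1000 - 50 + 1)
})

test_that("window sums agree with a brute-force recount", {
  L <- 400L
  region <- fixture_region(random_dna(L, seed = 73))
  pl <- random_placements(50, L, seed = 74)
  prof <- build_profiles(pl, region)
  win <- scroll_windows(prof, scan_config())
  expect_equal(win$S2, oracle_window_S2(pl, L))
  expect_equal(prof$coverage[[1]], oracle_coverage(pl, L))
})

test_that("coverage and five_prime assignments differ as documented", {
  L <- 300L
  region <- fixture_region(random_dna(L, seed = 75))
  pl <- random_placements(30, L, seed = 76)
  prof <- build_profiles(pl, region)
  cov <- scroll_windows(prof, scan_config(assignment = "coverage"))
  cs <- cumsum(c(0, oracle_coverage(pl, L)))
  expect_equal(cov$S2, cs[cov$start + 51] - cs[cov$start + 1])
  fp <- scroll_windows(prof, scan_config(assignment = "five_prime"))
  oracle_fp <- vapply(0:(L - 50), function(o) {
    sum(pl$rpm[pl$start >= o & pl$start < o + 50])
  }, numeric(1))
  expect_equal(fp$S2, oracle_fp)
})

test_that("a flat nonzero profile yields no passing windows and no peaks", {
  L <- 500L
  region <- fixture_region(random_dna(L, seed = 77))
  # one read starting at every offset: constant start density
  pl <- fixture_placements(0:(L - 21), 21:L, rpm = 5)
  prof <- build_profiles(pl, region)
  win <- scroll_windows(prof, scan_config())
  expect_true(prof$A1 > 0)
  expect_false(any(win$passes))
  peaks <- call_peaks(win, prof, region, scan_config())
  expect_equal(nrow(peaks), 0L)
})

test_that("overlapping passing windows merge into one peak interval", {
  region <- fixture_region(random_dna(1000, seed = 78))
  pl <- fixture_placements(100, 146, rpm = 300)
  prof <- build_profiles(pl, region)
  win <- scroll_windows(prof, scan_config())
  # the read overlaps windows starting in [51, 145]
  peaks <- call_peaks(win, prof, region, scan_config())
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$start, 51L)
  expect_equal(peaks$end, 145L + 50L)
  expect_equal(peaks$n_windows, 95L)
  expect_equal(peaks$g_start, region$g_start + peaks$start)

  # two well-separated clusters give two peaks
  pl2 <- dplyr::bind_rows(
    fixture_placements(100, 124, rpm = 300),
    fixture_placements(700, 724, rpm = 300)
  )
  prof2 <- build_profiles(pl2, region)
  peaks2 <- call_peaks(scroll_windows(prof2, scan_config()), prof2,
                       region, scan_config())
  expect_equal(nrow(peaks2), 2L)
  expect_true(all(diff(peaks2$start) > 50))
})

test_that("the noise screen separates sharp peaks from submerged ones", {
  region <- fixture_region(random_dna(1000, seed = 79))
  sharp <- fixture_placements(100, 150, rpm = 500)
  prof <- build_profiles(sharp, region)
  pk <- call_peaks(scroll_windows(prof, scan_config()), prof, region,
                   scan_config())
  expect_true(all(pk$screened))
  expect_equal(pk$mean_density_out, 0)
  expect_equal(pk$noise_ratio, Inf)

  # strong peak over a heavy uniform floor: windows pass the absolute
  # criterion but the peak drowns in noise under a high noise threshold
  floor_reads <- fixture_placements(0:(1000 - 21), 21:1000, rpm = 2)
  mix <- dplyr::bind_rows(fixture_placements(100, 150, rpm = 800),
                          floor_reads)
  prof2 <- build_profiles(mix, region)
  cfg_lenient <- scan_config(ratio_threshold = 2, noise_ratio_min = 3)
  pk2 <- call_peaks(scroll_windows(prof2, cfg_lenient), prof2, region,
                    cfg_lenient)
  cfg_strict <- scan_config(ratio_threshold = 2, noise_ratio_min = 50)
  pk3 <- call_peaks(scroll_windows(prof2, cfg_strict), prof2, region,
                    cfg_strict)
  expect_true(any(pk2$screened))
  expect_false(any(pk3$screened))
})

test_that("genomic projection respects region orientation", {
  seq <- random_dna(1000, seed = 80)
  region <- fixture_region(seq, gene_strand = "-", g_start = 5000)
  expect_true(region$seq_rev)
  pl <- fixture_placements(100, 150, rpm = 500)
  prof <- build_profiles(pl, region)
  pk <- call_peaks(scroll_windows(prof, scan_config()), prof, region,
                   scan_config())
  expect_equal(pk$strand, "-")
  # offsets [51, 195) on the reversed sequence = genomic [g_end-195, g_end-51)
  expect_equal(pk$g_end, region$g_end - pk$start)
  expect_equal(pk$g_start, region$g_end - pk$end)
})

test_that("sense/antisense peaks pair only when genomic intervals overlap", {
  base <- tibble::tibble(
    gene_id = "g1", anchor = "TSS", chrom = "Chr1", screened = TRUE
  )
  peaks <- dplyr::bind_rows(
    dplyr::mutate(base, region_strand = "sense", g_start = 5100,
                  g_end = 5180),
    dplyr::mutate(base, region_strand = "antisense", g_start = 5120,
                  g_end = 5200)
  )
  pairs <- pair_peaks(peaks)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_nt, 60)
  expect_equal(nrow(pair_peaks(peaks, min_pair_overlap = 61)), 0L)

  disjoint <- dplyr::bind_rows(
    dplyr::mutate(base, region_strand = "sense", g_start = 5100,
                  g_end = 5150),
    dplyr::mutate(base, region_strand = "antisense", g_start = 5200,
                  g_end = 5260)
  )
  expect_equal(nrow(pair_peaks(disjoint)), 0L)
})

test_that("statistics scale with rpm and ratio-based calls are invariant", {
  L <- 600L
  region <- fixture_region(random_dna(L, seed = 81))
  pl <- random_placements(40, L, seed = 82)
  cfg <- scan_config(abs_threshold = 0)   # isolate the ratio criterion
  prof1 <- build_profiles(pl, region)
  win1 <- scroll_windows(prof1, cfg)
  for (c_scale in c(3, 0.25)) {
    pl2 <- dplyr::mutate(pl, rpm = rpm * c_scale)
    prof2 <- build_profiles(pl2, region)
    win2 <- scroll_windows(prof2, cfg)
    expect_equal(prof2$S1, prof1$S1 * c_scale)
    expect_equal(prof2$A1, prof1$A1 * c_scale)
    expect_equal(win2$S2, win1$S2 * c_scale)
    expect_equal(win2$passes, win1$passes)
  }
})

test_that("raising any screening threshold never adds screened peaks", {
  L <- 1000L
  region <- fixture_region(random_dna(L, seed = 83))
  pl <- dplyr::bind_rows(
    random_placements(60, L, seed = 84, max_rpm = 5),
    fixture_placements(c(200, 210, 220, 230), c(250, 255, 260, 270),
                       rpm = 120)
  )
  base_cfg <- scan_config(ratio_threshold = 4, abs_threshold = 0.5,
                          noise_ratio_min = 1.5)
  n_screened <- function(cfg) {
    prof <- build_profiles(pl, region)
    sum(call_peaks(scroll_windows(prof, cfg), prof, region, cfg)$screened)
  }
  n0 <- n_screened(base_cfg)
  expect_gt(n0, 0)
  grid <- list(
    scan_config(ratio_threshold = 8, abs_threshold = 0.5,
                noise_ratio_min = 1.5),
    scan_config(ratio_threshold = 4, abs_threshold = 5,
                noise_ratio_min = 1.5),
    scan_config(ratio_threshold = 4, abs_threshold = 0.5,
                noise_ratio_min = 40)
  )
  for (cfg in grid) expect_lte(n_screened(cfg), n0)
})
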