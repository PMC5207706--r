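#' Scan configuration for 50-nt window peak calling
#'
#' Bundles the parameters of the scrolling-window screen. The defaults are
#' the published criteria: a 50-nt window scrolled in 1-nt steps, with a
#' window accepted when its average density `A2 = S2 / window` is at least
#' `ratio_threshold` times the region average `A1 = S1 / L` *and* at least
#' `abs_threshold` RPM/nt. Candidate windows are merged into peaks and a
#' noise screen (`noise_ratio_min`) stands in for the published manual
#' inspection that peaks must not be submerged in surrounding signal.
#'
#' @param window Window width in nt (default 50).
#' @param step Scroll step in nt; only 1 is supported.
#' @param ratio_threshold Required ratio `A2 / A1` (default 10).
#' @param abs_threshold Absolute floor on `A2`, in RPM per nt (default 1).
#' @param scan_start,scan_end Offsets (0-based half-open) delimiting the
#'   scanned part of each region; `NULL` means the full region.
#' @param noise_ratio_min Minimum ratio of mean in-peak density to mean
#'   out-of-peak density over the scan interval for a peak to be screened
#'   in (default 3; a zero out-of-peak density passes).
#' @param min_pair_overlap Minimum genomic overlap, in nt, for sense and
#'   antisense peaks to be reported as a pair (default 1).
#' @param assignment How a read contributes to a window's `S2`:
#'   `"overlap"` (counts if its interval overlaps the window; default),
#'   `"five_prime"` (counts if its first position lies in the window) or
#'   `"coverage"` (per-position coverage summed over the window).
#' @param min_peak_rpm_fraction Optional extra screen: minimum fraction of
#'   the region's signal mass inside the peak (0 disables it; default).
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 50, step = 1, ratio_threshold = 10,
                        abs_threshold = 1, scan_start = NULL,
                        scan_end = NULL, noise_ratio_min = 3,
                        min_pair_overlap = 1,
                        assignment = c("overlap", "five_prime", "coverage"),
                        min_peak_rpm_fraction = 0) {
  assignment <- match.arg(assignment)
  if (step != 1) abort("Only `step = 1` scrolling is supported.")
  if (window < 1) abort("`window` must be >= 1.")
  stopifnot(ratio_threshold >= 0, abs_threshold >= 0, noise_ratio_min >= 0,
            min_pair_overlap >= 1, min_peak_rpm_fraction >= 0)
  structure(
    list(
      window = as.integer(window), step = 1L,
      ratio_threshold = ratio_threshold, abs_threshold = abs_threshold,
      scan_start = scan_start, scan_end = scan_end,
      noise_ratio_min = noise_ratio_min,
      min_pair_overlap = as.integer(min_pair_overlap),
      assignment = assignment,
      min_peak_rpm_fraction = min_peak_rpm_fraction
    ),
    class = "scan_config"
  )
}

scan_bounds <- function(L, config) {
  s0 <- config$scan_start %||% 0L
  s1 <- config$scan_end %||% L
  s0 <- max(0L, as.integer(s0))
  s1 <- min(as.integer(s1), L)
  if (s1 - s0 < config$window) {
    abort(sprintf(
      "Scan interval [%d, %d) shorter than the %d-nt window.",
      s0, s1, config$window
    ))
  }
  c(s0, s1)
}

#' Build per-region abundance profiles
#'
#' Sums placement RPM into the region-level statistics `S1` (total signal)
#' and `A1 = S1 / L`, and a per-position RPM coverage vector used for
#' noise screening and plotting. Libraries listed in `library_pool` are
#' pooled by summing RPM; `NULL` pools every library present.
#'
#' @param placements Placements from [map_perfect()] (needs `rpm`).
#' @param regions Boundary regions from [extract_boundary_regions()].
#' @param library_pool Character vector of `library_id`s to pool, or
#'   `NULL` for all.
#' @return A tibble with one row per region: region keys, `L`, `S1`, `A1`,
#'   `n_placements` and a `coverage` list-column (numeric vector of length
#'   `L`).
#' @export
build_profiles <- function(placements, regions, library_pool = NULL) {
  check_cols(regions, c(region_keys, "L"))
  check_cols(placements, c(region_keys, "start", "end", "rpm"))
  if (any(regions$L <= 0)) abort("Empty region (L <= 0) in `regions`.")
  if (!is.null(library_pool)) {
    placements <- filter(placements, .data$library_id %in% library_pool)
  }

  grouped <- placements |>
    summarise(
      placed = list(pick("start", "end", "rpm")),
      .by = all_of(region_keys)
    )
  prof <- regions |>
    select(all_of(region_keys), "L") |>
    left_join(grouped, by = region_keys)

  prof |>
    mutate(
      placed = purrr::map(.data$placed, \(p) {
        p %||% tibble(start = integer(), end = integer(), rpm = numeric())
      }),
      S1 = purrr::map_dbl(.data$placed, \(p) sum(p$rpm)),
      A1 = .data$S1 / .data$L,
      n_placements = purrr::map_int(.data$placed, nrow),
      coverage = purrr::map2(.data$placed, .data$L, \(p, l) {
        interval_coverage(p$start, p$end, p$rpm, l)
      })
    ) |>
    select(all_of(region_keys), "L", "S1", "A1", "n_placements",
           "placed", "coverage") |>
    as_tibble()
}

# Window sums for one region: S2 for every window start in [s0, s1 - w].
# Under "overlap" assignment a placement [s, e) contributes its rpm to all
# window starts in [s - w + 1, e - 1]; computed with a difference array.
window_sums <- function(placed, L, config) {
  b <- scan_bounds(L, config)
  w <- config$window
  starts <- seq.int(b[1], b[2] - w)
  n <- length(starts)
  if (nrow(placed) == 0) return(tibble(start = starts, S2 = numeric(n)))

  if (config$assignment == "coverage") {
    cov <- interval_coverage(placed$start, placed$end, placed$rpm, L)
    cs <- cumsum(c(0, cov))
    S2 <- cs[starts + w + 1] - cs[starts + 1]
  } else {
    # A placement contributes to the windows starting in [lo, hi) on the
    # window-start axis; accumulate with a difference array clipped to the
    # scanned starts.
    if (config$assignment == "five_prime") {
      # window [x, x + w) contains the read start s iff x in [s - w + 1, s]
      lo <- placed$start - w + 1L
      hi <- placed$start + 1L
    } else {
      # overlap: [s, e) meets [x, x + w) iff x in [s - w + 1, e - 1]
      lo <- placed$start - w + 1L
      hi <- placed$end
    }
    S2 <- interval_coverage(lo - b[1], hi - b[1], placed$rpm, n)
  }
  tibble(start = starts, S2 = as.numeric(S2))
}

#' Scroll the 50-nt window across each region
#'
#' Computes, for every 1-nt step of the window inside the scan interval,
#' the window sum `S2`, the window average `A2 = S2 / window`, and whether
#' the window passes the dual criterion
#' `A2 >= ratio_threshold * A1` and `A2 >= abs_threshold`.
#'
#' @param profiles Profiles from [build_profiles()].
#' @param config A [scan_config()].
#' @return A tibble of window statistics: region keys, `start`, `width`,
#'   `S2`, `A2`, `A1`, `passes`.
#' @export
scroll_windows <- function(profiles, config = scan_config()) {
  check_cols(profiles, c(region_keys, "L", "A1", "placed"))
  w <- config$window
  res <- profiles |>
    mutate(win = purrr::map2(.data$placed, .data$L, window_sums,
                             config = config)) |>
    select(all_of(region_keys), "A1", "win") |>
    tidyr::unnest("win")
  res |>
    mutate(
      width = w,
      A2 = .data$S2 / w,
      passes = .data$A2 >= config$ratio_threshold * .data$A1 &
        .data$A2 >= config$abs_threshold
    ) |>
    select(all_of(region_keys), "start", "width", "S2", "A2", "A1",
           "passes") |>
    as_tibble()
}

# Merge maximal runs of overlapping passing windows (windows overlap iff
# their starts differ by less than the window width).
merge_passing <- function(starts, A2, w) {
  if (length(starts) == 0) {
    return(tibble(start = integer(), end = integer(), a2_max = numeric(),
                  n_windows = integer()))
  }
  o <- order(starts)
  starts <- starts[o]; A2 <- A2[o]
  grp <- cumsum(c(1L, as.integer(diff(starts) >= w)))
  tibble(win_start = starts, win_A2 = A2, grp = grp) |>
    summarise(
      start = min(.data$win_start),
      end = max(.data$win_start) + w,
      a2_max = max(.data$win_A2),
      n_windows = n(),
      .by = "grp"
    ) |>
    select(-"grp")
}

#' Call peaks from passing windows
#'
#' Maximal runs of overlapping passing windows are merged into one peak
#' each (the peak interval is the union of the windows). Each peak gets a
#' noise ratio — mean per-position RPM inside the peak over the mean
#' outside it (within the scan interval) — and is `screened` when that
#' ratio reaches `noise_ratio_min` (a zero out-of-peak density passes).
#' Peaks are reported both in region offsets and genomic coordinates.
#'
#' @param windows Window statistics from [scroll_windows()].
#' @param profiles Profiles from [build_profiles()].
#' @param regions Boundary regions (for genomic coordinates).
#' @param config A [scan_config()].
#' @return A tibble with one row per peak: region keys, `start`, `end`,
#'   `width`, `a2_max`, `n_windows`, `A1`, `S1`, `mean_density_in`,
#'   `mean_density_out`, `noise_ratio`, `peak_rpm_fraction`, `screened`,
#'   `chrom`, `g_start`, `g_end`, `strand`.
#' @export
call_peaks <- function(windows, profiles, regions, config = scan_config()) {
  check_cols(windows, c(region_keys, "start", "A2", "passes"))
  check_cols(profiles, c(region_keys, "L", "S1", "A1", "coverage"))
  check_cols(regions, c(region_keys, "chrom", "g_start", "g_end", "seq_rev"))
  w <- config$window

  merged <- windows |>
    filter(.data$passes) |>
    summarise(
      peak = list(merge_passing(.data$start, .data$A2, w)),
      .by = all_of(region_keys)
    ) |>
    tidyr::unnest("peak")

  if (nrow(merged) == 0) {
    return(empty_peaks())
  }

  merged <- merged |>
    left_join(
      select(profiles, all_of(region_keys), "L", "S1", "A1", "coverage"),
      by = region_keys
    ) |>
    left_join(
      select(regions, all_of(region_keys), "chrom", "g_start", "g_end",
             "seq_rev"),
      by = region_keys
    )

  peaks <- merged |>
    mutate(
      width = .data$end - .data$start,
      bounds = purrr::map(.data$L, \(l) scan_bounds(l, config)),
      mean_density_in = purrr::pmap_dbl(
        list(.data$coverage, .data$start, .data$end),
        \(cv, s, e) mean(cv[(s + 1):e])
      ),
      mean_density_out = purrr::pmap_dbl(
        list(.data$coverage, .data$start, .data$end, .data$bounds),
        \(cv, s, e, b) {
          idx <- setdiff(seq.int(b[1] + 1, b[2]), seq.int(s + 1, e))
          if (length(idx) == 0) 0 else mean(cv[idx])
        }
      ),
      noise_ratio = if_else(.data$mean_density_out == 0, Inf,
                            .data$mean_density_in / .data$mean_density_out),
      peak_rpm_fraction = purrr::pmap_dbl(
        list(.data$coverage, .data$start, .data$end),
        \(cv, s, e) {
          tot <- sum(cv)
          if (tot == 0) 0 else sum(cv[(s + 1):e]) / tot
        }
      ),
      screened = .data$noise_ratio >= config$noise_ratio_min &
        .data$peak_rpm_fraction >= config$min_peak_rpm_fraction,
      pk_g_start = if_else(.data$seq_rev, .data$g_end - .data$end,
                           .data$g_start + .data$start),
      pk_g_end = if_else(.data$seq_rev, .data$g_end - .data$start,
                         .data$g_start + .data$end),
      strand = if_else(.data$seq_rev, "-", "+")
    )

  peaks |>
    select(all_of(region_keys), "start", "end", "width", "a2_max",
           "n_windows", "A1", "S1", "mean_density_in", "mean_density_out",
           "noise_ratio", "peak_rpm_fraction", "screened", "chrom",
           g_start = "pk_g_start", g_end = "pk_g_end", "strand") |>
    arrange(.data$gene_id, .data$anchor, .data$region_strand,
            .data$start) |>
    as_tibble()
}

empty_peaks <- function() {
  tibble(
    gene_id = character(), anchor = character(),
    region_strand = character(), start = integer(), end = integer(),
    width = integer(), a2_max = numeric(), n_windows = integer(),
    A1 = numeric(), S1 = numeric(), mean_density_in = numeric(),
    mean_density_out = numeric(), noise_ratio = numeric(),
    peak_rpm_fraction = numeric(), screened = logical(),
    chrom = character(), g_start = integer(), g_end = integer(),
    strand = character()
  )
}

#' Pair sense and antisense peaks at the same anchor
#'
#' A screened sense peak and a screened antisense peak of the same gene and
#' anchor are reported as a pair when their genomic intervals overlap by at
#' least `min_pair_overlap` nt.
#'
#' @param peaks Peaks from [call_peaks()].
#' @param min_pair_overlap Minimum genomic overlap in nt (default 1).
#' @return A tibble with one row per pair: `gene_id`, `anchor`, sense and
#'   antisense peak genomic intervals, and `overlap_nt`.
#' @export
pair_peaks <- function(peaks, min_pair_overlap = 1) {
  check_cols(peaks, c(region_keys, "g_start", "g_end", "screened"))
  scr <- filter(peaks, .data$screened)
  sense <- filter(scr, .data$region_strand == "sense") |>
    select("gene_id", "anchor", sense_start = "g_start",
           sense_end = "g_end")
  antis <- filter(scr, .data$region_strand == "antisense") |>
    select("gene_id", "anchor", antisense_start = "g_start",
           antisense_end = "g_end")
  inner_join(sense, antis, by = c("gene_id", "anchor"),
             relationship = "many-to-many") |>
    mutate(
      overlap_nt = pmin(.data$sense_end, .data$antisense_end) -
        pmax(.data$sense_start, .data$antisense_start)
    ) |>
    filter(.data$overlap_nt >= min_pair_overlap) |>
    as_tibble()
}

#' Run the full boundary-peak scan
#'
#' Convenience wrapper chaining [build_profiles()], [scroll_windows()],
#' [call_peaks()] and [pair_peaks()] over one placement table.
#'
#' @param placements Placements from [map_perfect()].
#' @param regions Boundary regions.
#' @param config A [scan_config()].
#' @param library_pool Libraries pooled for detection (`NULL` = all).
#' @return An object of class `srna_scan` with elements `profiles`,
#'   `windows`, `peaks`, `pairs` and `config`. Use [tidy()] for the peak
#'   table, [glance()] for a one-row summary and [autoplot()] to plot a
#'   region profile.
#' @export
scan_boundary_peaks <- function(placements, regions,
                                config = scan_config(),
                                library_pool = NULL) {
  profiles <- build_profiles(placements, regions, library_pool)
  windows <- scroll_windows(profiles, config)
  peaks <- call_peaks(windows, profiles, regions, config)
  pairs <- pair_peaks(peaks, config$min_pair_overlap)
  structure(
    list(profiles = profiles, windows = windows, peaks = peaks,
         pairs = pairs, config = config),
    class = "srna_scan"
  )
}

#' @export
print.srna_scan <- function(x, ...) {
  cat(sprintf(
    "<srna_scan> %d regions scanned; %d peaks (%d screened), %d sense/antisense pairs\n",
    nrow(x$profiles), nrow(x$peaks), sum(x$peaks$screened), nrow(x$pairs)
  ))
  invisible(x)
}

#' @rdname scan_boundary_peaks
#' @param x An `srna_scan` object.
#' @param ... Unused.
#' @export
tidy.srna_scan <- function(x, ...) {
  x$peaks
}

#' @rdname scan_boundary_peaks
#' @export
glance.srna_scan <- function(x, ...) {
  scr <- filter(x$peaks, .data$screened)
  tibble(
    n_regions = nrow(x$profiles),
    n_windows_pass = sum(x$windows$passes),
    n_peaks = nrow(x$peaks),
    n_screened = nrow(scr),
    n_genes_with_peak = n_distinct(scr$gene_id),
    n_pairs = nrow(x$pairs)
  )
}

#' @rdname scan_boundary_peaks
#' @param object An `srna_scan` object.
#' @param gene_id,anchor,region_strand Region to plot.
#' @export
autoplot.srna_scan <- function(object, gene_id, anchor = "TSS",
                               region_strand = "sense", ...) {
  prof <- object$profiles |>
    filter(.data$gene_id == !!gene_id, .data$anchor == !!anchor,
           .data$region_strand == !!region_strand)
  if (nrow(prof) != 1) abort("Region not found in scan profiles.")
  cov <- prof$coverage[[1]]
  df <- tibble(position = seq_along(cov) - 1L, rpm = cov)
  pk <- object$peaks |>
    filter(.data$gene_id == !!gene_id, .data$anchor == !!anchor,
           .data$region_strand == !!region_strand, .data$screened)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$rpm)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::geom_hline(yintercept = prof$A1[1], linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("offset in %s %s region (nt)", gene_id, anchor),
      y = "RPM per nt",
      title = sprintf("%s | %s | %s", gene_id, anchor, region_strand)
    ) +
    ggplot2::theme_minimal()
  if (nrow(pk) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = pk$start, xmax = pk$end, ymin = -Inf, ymax = Inf,
      alpha = 0.2, fill = "firebrick"
    )
  }
  p
}
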