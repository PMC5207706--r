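#' Continuous dsRNA-seq coverage runs within boundary regions
#'
#' Projects dsRNA-read placements to genomic coordinates and finds, for
#' each gene and anchor, the maximal runs of consecutive positions with
#' read depth of at least `min_depth`. By default dsRNA reads are treated
#' as strand-agnostic duplex evidence: placements from both region
#' strands are pooled and each run applies to peaks on either strand.
#'
#' @param placements dsRNA-read placements from [map_perfect()] (any
#'   `role`; typically the `dsrna` library).
#' @param regions Boundary regions (for genomic projection).
#' @param min_depth Minimum read depth for a position to count as covered
#'   (default 1).
#' @param strand_agnostic Pool the two region strands (default `TRUE`);
#'   if `FALSE`, runs are computed per region strand.
#' @return A tibble of runs: `gene_id`, `anchor` (and `region_strand`
#'   when `strand_agnostic = FALSE`), `chrom`, `g_start`, `g_end`
#'   (0-based half-open genomic), `length`.
#' @export
coverage_runs <- function(placements, regions, min_depth = 1,
                          strand_agnostic = TRUE) {
  check_cols(placements, c(region_keys, "start", "end"))
  check_cols(regions, c(region_keys, "chrom", "g_start", "g_end",
                        "seq_rev"))
  if (min_depth < 1) abort("`min_depth` must be >= 1.")

  proj <- placements |>
    inner_join(
      select(regions, all_of(region_keys), "chrom",
             rg_start = "g_start", rg_end = "g_end", "seq_rev"),
      by = region_keys
    ) |>
    mutate(
      pg_start = if_else(.data$seq_rev, .data$rg_end - .data$end,
                         .data$rg_start + .data$start),
      pg_end = if_else(.data$seq_rev, .data$rg_end - .data$start,
                       .data$rg_start + .data$end)
    )

  group_cols <- if (strand_agnostic) c("gene_id", "anchor") else region_keys
  span <- regions |>
    summarise(chrom = .data$chrom[1], span_start = min(.data$g_start),
              span_end = max(.data$g_end), .by = all_of(group_cols))

  runs <- proj |>
    rename(s = "pg_start", e = "pg_end") |>
    summarise(
      placed = list(pick("s", "e")),
      .by = all_of(group_cols)
    ) |>
    inner_join(span, by = group_cols) |>
    mutate(run = purrr::pmap(
      list(.data$placed, .data$span_start, .data$span_end),
      function(p, s0, s1) {
        depth <- interval_coverage(p$s - s0, p$e - s0, rep(1, nrow(p)),
                                   s1 - s0)
        covered <- depth >= min_depth
        r <- rle(covered)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values
        tibble(g_start = s0 + starts[keep], g_end = s0 + ends[keep])
      }
    )) |>
    select(all_of(group_cols), "chrom", "run") |>
    tidyr::unnest("run")

  if (nrow(runs) == 0) {
    out <- tibble(gene_id = character(), anchor = character(),
                  chrom = character(), g_start = integer(),
                  g_end = integer(), length = integer())
    if (!strand_agnostic) out$region_strand <- character()
    return(out)
  }
  runs |>
    mutate(g_start = as.integer(.data$g_start),
           g_end = as.integer(.data$g_end),
           length = .data$g_end - .data$g_start) |>
    arrange(.data$gene_id, .data$anchor, .data$g_start) |>
    as_tibble()
}

#' Flag peaks residing in long dsRNA coverage runs
#'
#' A peak is dsRNA-covered when its genomic interval is fully contained in
#' a coverage run of at least `min_run` nt (default 100). A
#' partial-overlap mode is available: with `mode = "fraction"` the peak
#' counts when at least `min_fraction` of it lies within a qualifying run.
#'
#' @param peaks Peaks from [call_peaks()].
#' @param runs Coverage runs from [coverage_runs()].
#' @param min_run Minimum run length in nt (default 100).
#' @param mode `"contain"` (default) or `"fraction"`.
#' @param min_fraction Minimum overlap fraction for `mode = "fraction"`.
#' @return `peaks` with logical column `dsrna_covered` added.
#' @export
peak_in_run <- function(peaks, runs, min_run = 100,
                        mode = c("contain", "fraction"),
                        min_fraction = 0.5) {
  mode <- match.arg(mode)
  check_cols(peaks, c("gene_id", "anchor", "g_start", "g_end"))
  long_runs <- filter(runs, .data$length >= min_run)

  if (nrow(long_runs) == 0 || nrow(peaks) == 0) {
    return(mutate(peaks, dsrna_covered = logical(nrow(peaks))))
  }
  hits <- peaks |>
    mutate(.peak_row = dplyr::row_number()) |>
    inner_join(
      select(long_runs, "gene_id", "anchor", run_start = "g_start",
             run_end = "g_end"),
      by = c("gene_id", "anchor"), relationship = "many-to-many"
    )
  hits <- if (mode == "contain") {
    filter(hits, .data$g_start >= .data$run_start,
           .data$g_end <= .data$run_end)
  } else {
    filter(hits,
           (pmin(.data$g_end, .data$run_end) -
              pmax(.data$g_start, .data$run_start)) /
             (.data$g_end - .data$g_start) >= min_fraction)
  }
  peaks |>
    mutate(dsrna_covered = dplyr::row_number() %in% hits$.peak_row) |>
    as_tibble()
}
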