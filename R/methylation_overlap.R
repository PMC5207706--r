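#' Load a DNA-methylation track
#'
#' Reads a methylation track from bedGraph (per-cytosine level in
#' `[0, 1]`) or plain BED (methylated intervals, merged and assigned level
#' 1). Multi-nt bedGraph intervals are expanded to one site per position.
#' The returned track is sorted by chromosome and position.
#'
#' @param path Path to the track file.
#' @param format `"auto"` (by extension; `.bedgraph`/`.bdg` vs `.bed`),
#'   `"bedgraph"` or `"bed"`.
#' @return A tibble of methylated sites: `chrom`, `pos` (0-based),
#'   `level`.
#' @export
load_methylation_track <- function(path,
                                   format = c("auto", "bedgraph", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Cannot read track file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg)$", path, ignore.case = TRUE)) {
      "bedgraph"
    } else {
      "bed"
    }
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) &
                   nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_min <- if (format == "bedgraph") 4L else 3L
  bad <- which(lengths(fields) < n_min)
  if (length(bad) > 0) {
    abort(sprintf("Malformed track line %d in %s (expected >= %d fields)",
                  bad[1], path, n_min))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end) || any(end <= start)) {
    bad <- which(is.na(start) | is.na(end) | end <= start)[1]
    abort(sprintf("Malformed interval on track line %d in %s", bad, path))
  }

  if (format == "bedgraph") {
    level <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 4))
    )
    if (anyNA(level) || any(level < 0 | level > 1)) {
      bad <- which(is.na(level) | level < 0 | level > 1)[1]
      abort(sprintf(
        "Methylation level outside [0, 1] on track line %d in %s",
        bad, path
      ))
    }
  } else {
    # plain BED: merge overlapping intervals, level 1
    merged <- tibble(chrom = chrom, start = start, end = end) |>
      summarise(
        rng = list(IRanges::reduce(IRanges::IRanges(.data$start + 1L,
                                                    .data$end))),
        .by = "chrom"
      )
    chrom <- rep(merged$chrom, vapply(merged$rng, length, integer(1)))
    start <- unlist(lapply(merged$rng, IRanges::start)) - 1L
    end <- unlist(lapply(merged$rng, IRanges::end))
    level <- rep(1, length(start))
  }

  n_pos <- end - start
  tibble(
    chrom = rep(chrom, n_pos),
    pos = unlist(purrr::map2(start, end, \(s, e) seq.int(s, e - 1L))),
    level = rep(level, n_pos)
  ) |>
    arrange(.data$chrom, .data$pos) |>
    as_tibble()
}

#' Methylation overlap of each peak
#'
#' A peak overlaps site-specific methylation when at least `min_sites`
#' methylated positions with level of at least `level_min` fall within the
#' peak's genomic interval extended by `slop` nt on each side (boundary
#' positions inclusive). Peaks on chromosomes absent from the track are
#' flagged `FALSE` with a notice.
#'
#' @param peaks Peaks from [call_peaks()] (genomic coordinates required).
#' @param track Methylation sites from [load_methylation_track()].
#' @param level_min Minimum methylation level (default 0.1).
#' @param slop Extension of the peak interval on each side, nt
#'   (default 50).
#' @param min_sites Minimum number of qualifying sites (default 3).
#' @param context Optional cytosine context filter (e.g. `"CG"`): applied
#'   when the track carries a `context` column, ignored otherwise.
#' @return `peaks` with columns `methylation_overlap` (logical) and
#'   `meth_sites` (qualifying-site count) added.
#' @export
peak_methylation_overlap <- function(peaks, track, level_min = 0.1,
                                     slop = 50, min_sites = 3,
                                     context = NULL) {
  check_cols(peaks, c("chrom", "g_start", "g_end"))
  check_cols(track, c("chrom", "pos", "level"))
  absent <- setdiff(unique(peaks$chrom), unique(track$chrom))
  if (length(absent) > 0 && nrow(peaks) > 0) {
    inform(sprintf(
      "Chromosome(s) absent from the methylation track (peaks flagged FALSE): %s",
      paste(absent, collapse = ", ")
    ))
  }
  sites <- filter(track, .data$level >= level_min)
  if (!is.null(context) && "context" %in% names(sites)) {
    sites <- filter(sites, .data$context %in% !!context)
  }

  counts <- peaks |>
    mutate(.peak_row = dplyr::row_number()) |>
    inner_join(select(sites, "chrom", "pos"), by = "chrom",
               relationship = "many-to-many") |>
    filter(.data$pos >= .data$g_start - slop,
           .data$pos < .data$g_end + slop) |>
    count(.data$.peak_row, name = "meth_sites")

  n <- integer(nrow(peaks))
  n[counts$.peak_row] <- counts$meth_sites
  peaks |>
    mutate(meth_sites = n,
           methylation_overlap = .data$meth_sites >= min_sites) |>
    as_tibble()
}
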