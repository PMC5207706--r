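#' Collect boundary-associated sRNAs per category
#'
#' Gathers the distinct collapsed reads with at least one placement
#' overlapping the scan interval of a peak-bearing region, grouped into
#' four categories by anchor and region strand: `PASR_plus` (TSS, sense),
#' `PASR_RC` (TSS, antisense), `TASR_plus` (terminus, sense) and `TASR_RC`
#' (terminus, antisense). A read straddling the scan-interval edge counts
#' (partial residence is enough); a read sequence may appear in several
#' categories but only once per category.
#'
#' @param placements Placements from [map_perfect()].
#' @param peaks Peaks from [call_peaks()]; only regions with at least one
#'   screened peak contribute reads.
#' @param regions Boundary regions (for region lengths).
#' @param config A [scan_config()] defining the scan interval.
#' @return A tibble with columns `category`, `sequence`, `length`.
#' @export
collect_boundary_srnas <- function(placements, peaks, regions,
                                   config = scan_config()) {
  check_cols(placements, c(region_keys, "start", "end", "sequence"))
  check_cols(peaks, c(region_keys, "screened"))
  check_cols(regions, c(region_keys, "L"))

  peaked <- peaks |>
    filter(.data$screened) |>
    distinct(across(all_of(region_keys)))
  if (nrow(peaked) == 0) {
    return(tibble(category = character(), sequence = character(),
                  length = integer()))
  }
  bounds <- regions |>
    semi_join(peaked, by = region_keys) |>
    mutate(b = purrr::map(.data$L, \(l) scan_bounds(l, config)),
           scan_s = purrr::map_int(.data$b, \(b) as.integer(b[1])),
           scan_e = purrr::map_int(.data$b, \(b) as.integer(b[2]))) |>
    select(all_of(region_keys), "scan_s", "scan_e")

  placements |>
    inner_join(bounds, by = region_keys) |>
    filter(.data$start < .data$scan_e, .data$end > .data$scan_s) |>
    mutate(category = srna_category(.data$anchor, .data$region_strand)) |>
    distinct(.data$category, .data$sequence) |>
    mutate(length = nchar(.data$sequence)) |>
    arrange(.data$category, .data$sequence) |>
    as_tibble()
}

srna_category <- function(anchor, region_strand) {
  paste0(
    if_else(anchor == "TSS", "PASR", "TASR"),
    if_else(region_strand == "sense", "_plus", "_RC")
  )
}

#' Read-length distribution
#'
#' Tabulates read lengths into per-nt bins (19-28 nt by default) plus an
#' `other` bin, as counts and fractions. If a `category` column is present
#' the histogram is computed per category.
#'
#' @param reads A tibble with a `length` column (and optionally
#'   `category`), e.g. from [collect_boundary_srnas()].
#' @param bins Integer lengths given their own bin.
#' @return A tibble with `category` (if grouped), `length_bin`, `n`,
#'   `fraction`. For an empty read set the histogram rows are returned
#'   with zero counts and `NA` fractions.
#' @export
length_distribution <- function(reads, bins = 19:28) {
  check_cols(reads, "length")
  levels <- c(as.character(bins), "other")
  grouping <- intersect("category", names(reads))

  binned <- reads |>
    mutate(length_bin = factor(
      if_else(.data$length %in% bins, as.character(.data$length), "other"),
      levels = levels
    ))
  out <- binned |>
    count(across(all_of(grouping)), .data$length_bin, .drop = FALSE) |>
    mutate(
      fraction = if (sum(.data$n) == 0) NA_real_ else .data$n / sum(.data$n),
      .by = all_of(grouping)
    )
  if (length(grouping) == 0 && nrow(reads) == 0) {
    out <- tibble(length_bin = factor(levels, levels = levels),
                  n = 0L, fraction = NA_real_)
  }
  as_tibble(out)
}

#' 5'-terminal nucleotide composition
#'
#' Tallies the first nucleotide of each read in the RNA alphabet (`T` is
#' reported as `U`). Reads starting with any other character (e.g. `N`)
#' are counted in a separate `other` row and excluded from the fractions.
#' If a `category` column is present the composition is computed per
#' category.
#'
#' @param reads A tibble with a `sequence` column (and optionally
#'   `category`).
#' @return A tibble with `category` (if grouped), `first_nt` (`A`, `C`,
#'   `G`, `U`, `other`), `n`, `fraction` (`NA` for the `other` row).
#' @export
five_prime_composition <- function(reads) {
  check_cols(reads, "sequence")
  grouping <- intersect("category", names(reads))
  levels <- c("A", "C", "G", "U", "other")

  tallied <- reads |>
    mutate(first_nt = factor(
      dplyr::case_match(
        substr(normalize_seq(.data$sequence), 1, 1),
        "A" ~ "A", "C" ~ "C", "G" ~ "G", "T" ~ "U",
        .default = "other"
      ),
      levels = levels
    )) |>
    count(across(all_of(grouping)), .data$first_nt, .drop = FALSE)

  tallied |>
    mutate(
      fraction = {
        denom <- sum(.data$n[.data$first_nt != "other"])
        if_else(.data$first_nt == "other", NA_real_,
                if (denom == 0) NA_real_ else .data$n / denom)
      },
      .by = all_of(grouping)
    ) |>
    as_tibble()
}

#' Summarise sequence features of boundary-associated sRNAs
#'
#' Runs [collect_boundary_srnas()], [length_distribution()] and
#' [five_prime_composition()] in one call.
#'
#' @inheritParams collect_boundary_srnas
#' @return A list with `reads`, `n_reads` (per category),
#'   `length_distribution` and `five_prime`.
#' @export
summarize_features <- function(placements, peaks, regions,
                               config = scan_config()) {
  reads <- collect_boundary_srnas(placements, peaks, regions, config)
  list(
    reads = reads,
    n_reads = count(reads, .data$category, name = "n_reads"),
    length_distribution = length_distribution(reads),
    five_prime = five_prime_composition(reads)
  )
}

#' Plot a read-length histogram
#'
#' @param lengths Output of [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(lengths) {
  check_cols(lengths, c("length_bin", "fraction"))
  p <- ggplot2::ggplot(lengths,
                       ggplot2::aes(x = .data$length_bin,
                                    y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads") +
    ggplot2::theme_minimal()
  if ("category" %in% names(lengths)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Plot 5'-terminal nucleotide composition
#'
#' @param comp Output of [five_prime_composition()].
#' @return A ggplot object.
#' @export
plot_five_prime <- function(comp) {
  check_cols(comp, c("first_nt", "fraction"))
  dat <- filter(comp, .data$first_nt != "other")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$first_nt,
                                         y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkolivegreen") +
    ggplot2::labs(x = "5' nucleotide", y = "fraction of reads") +
    ggplot2::theme_minimal()
  if ("category" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}
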