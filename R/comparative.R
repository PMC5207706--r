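#' Mean signal density of library groups over peak intervals
#'
#' For each screened peak and each library group, computes the mean RPM
#' per nt of the group's placements over the peak interval (per-position
#' coverage averaged across the peak width). Placements are matched to
#' peaks on the same region (gene, anchor, region strand).
#'
#' @param placements Placements from [map_perfect()] (needs `rpm` and the
#'   grouping columns named in `group_vars`).
#' @param peaks Peaks from [call_peaks()].
#' @param group_vars Columns of `placements` defining a library group
#'   (default `c("role", "organ_or_genotype")`).
#' @param screened_only Restrict to screened peaks (default `TRUE`).
#' @return A tibble with one row per peak x group: region keys, `start`,
#'   `end`, the grouping columns, and `density` (RPM/nt; groups without
#'   any overlapping placement are absent — treat missing as 0).
#' @export
peak_group_density <- function(placements, peaks,
                               group_vars = c("role", "organ_or_genotype"),
                               screened_only = TRUE) {
  check_cols(placements, c(region_keys, "start", "end", "rpm", group_vars))
  check_cols(peaks, c(region_keys, "start", "end", "screened"))
  pk <- peaks
  if (screened_only) pk <- filter(pk, .data$screened)
  pk <- select(pk, all_of(region_keys), pk_start = "start", pk_end = "end")

  inner_join(placements, pk, by = region_keys,
             relationship = "many-to-many") |>
    mutate(overlap = pmin(.data$end, .data$pk_end) -
             pmax(.data$start, .data$pk_start)) |>
    filter(.data$overlap > 0) |>
    summarise(
      density = sum(.data$rpm * .data$overlap) /
        (.data$pk_end[1] - .data$pk_start[1]),
      .by = all_of(c(region_keys, "pk_start", "pk_end", group_vars))
    ) |>
    rename(start = "pk_start", end = "pk_end") |>
    as_tibble()
}

#' AGO loading preference of each peak
#'
#' Compares AGO1-IP against AGO4-IP signal densities over each screened
#' peak, organ by organ. An organ votes `AGO4` when the AGO4 density is at
#' least `fold` times the AGO1 density and reaches `floor`; `AGO1`
#' symmetrically; `none` otherwise. Organs present in only one of the two
#' IP groups are skipped with a notice. A per-peak consensus is also
#' reported: the single label supported by at least one organ with no
#' organ voting for the other AGO (`mixed` if both occur, `none`
#' otherwise).
#'
#' @param placements Placements including `ago1` and `ago4` role libraries
#'   (with `organ_or_genotype` giving the organ).
#' @param peaks Peaks from [call_peaks()].
#' @param fold Required fold difference between the two densities
#'   (default 2).
#' @param floor Minimum density of the preferred group, RPM/nt (default 1).
#' @return A list of two tibbles: `per_organ` (peak keys, `organ`,
#'   `density_ago1`, `density_ago4`, `label`) and `consensus` (peak keys,
#'   `ago_preference`).
#' @export
ago_preference <- function(placements, peaks, fold = 2, floor = 1) {
  ip <- filter(placements, .data$role %in% c("ago1", "ago4"))
  organs1 <- unique(ip$organ_or_genotype[ip$role == "ago1"])
  organs4 <- unique(ip$organ_or_genotype[ip$role == "ago4"])
  skipped <- c(setdiff(organs1, organs4), setdiff(organs4, organs1))
  if (length(skipped) > 0) {
    inform(sprintf(
      "Organ(s) present in only one AGO-IP group skipped: %s",
      paste(skipped, collapse = ", ")
    ))
  }
  organs <- intersect(organs1, organs4)

  dens <- peak_group_density(ip, peaks) |>
    filter(.data$organ_or_genotype %in% organs)
  pk <- peaks |>
    filter(.data$screened) |>
    select(all_of(region_keys), "start", "end")
  grid <- tidyr::crossing(pk, organ = organs)

  wide <- dens |>
    tidyr::pivot_wider(names_from = "role", values_from = "density",
                       names_prefix = "density_")
  for (col in c("density_ago1", "density_ago4")) {
    if (!col %in% names(wide)) wide[[col]] <- numeric(nrow(wide))
  }
  per_organ <- grid |>
    left_join(
      wide,
      by = c(region_keys, "start", "end",
             organ = "organ_or_genotype")
    ) |>
    mutate(
      density_ago1 = dplyr::coalesce(.data$density_ago1, 0),
      density_ago4 = dplyr::coalesce(.data$density_ago4, 0),
      label = dplyr::case_when(
        .data$density_ago4 >= fold * .data$density_ago1 &
          .data$density_ago4 >= floor ~ "AGO4",
        .data$density_ago1 >= fold * .data$density_ago4 &
          .data$density_ago1 >= floor ~ "AGO1",
        .default = "none"
      )
    )

  # Consensus: the same decision rule applied to densities pooled across
  # the matched organs (robust to sampling noise in low-signal organs).
  consensus <- per_organ |>
    summarise(
      d1 = sum(.data$density_ago1),
      d4 = sum(.data$density_ago4),
      .by = all_of(c(region_keys, "start", "end"))
    ) |>
    mutate(
      ago_preference = dplyr::case_when(
        .data$d4 >= fold * .data$d1 & .data$d4 >= floor ~ "AGO4",
        .data$d1 >= fold * .data$d4 & .data$d1 >= floor ~ "AGO1",
        .default = "none"
      )
    ) |>
    select(-"d1", -"d4")
  list(per_organ = as_tibble(per_organ), consensus = as_tibble(consensus))
}

#' Organ-specific accumulation of each peak
#'
#' Labels a screened peak with an organ when that organ's wild-type
#' library contributes at least `dominance` of the summed wild-type
#' density over the peak; `none` otherwise (including all-zero signal).
#'
#' @param placements Placements including `wt` role libraries.
#' @param peaks Peaks from [call_peaks()].
#' @param dominance Required fraction of the summed WT density
#'   (default 0.8).
#' @return A tibble: peak keys, `organ_specific` (organ label or
#'   `"none"`), `dominant_fraction`.
#' @export
organ_specificity <- function(placements, peaks, dominance = 0.8) {
  wt <- filter(placements, .data$role == "wt")
  if (n_distinct(wt$organ_or_genotype) < 2) {
    abort("Organ-specificity needs wild-type libraries from >= 2 organs.")
  }
  dens <- peak_group_density(wt, peaks)
  pk <- peaks |>
    filter(.data$screened) |>
    select(all_of(region_keys), "start", "end")

  best <- dens |>
    mutate(total = sum(.data$density),
           .by = all_of(c(region_keys, "start", "end"))) |>
    slice_max(.data$density, n = 1, with_ties = FALSE,
              by = all_of(c(region_keys, "start", "end"))) |>
    mutate(dominant_fraction = if_else(.data$total > 0,
                                       .data$density / .data$total, 0),
           organ_specific = if_else(
             .data$total > 0 & .data$dominant_fraction >= dominance,
             .data$organ_or_genotype, "none"
           )) |>
    select(all_of(region_keys), "start", "end", "organ_specific",
           "dominant_fraction")

  pk |>
    left_join(best, by = c(region_keys, "start", "end")) |>
    mutate(
      organ_specific = dplyr::coalesce(.data$organ_specific, "none"),
      dominant_fraction = dplyr::coalesce(.data$dominant_fraction, 0)
    ) |>
    as_tibble()
}

#' DCL/RDR/Pol IV dependence of each peak
#'
#' Compares pooled wild-type signal density against each biogenesis-mutant
#' library over the exact wild-type-defined peak interval (no re-calling
#' in the mutant). A peak is `repressed` in a genotype when the WT density
#' reaches `wt_floor` and exceeds the mutant density by at least
#' `repression_fold` (a zero mutant density counts as repressed);
#' `not_repressed` when WT signal is sufficient but the fold is not
#' reached; `insufficient_signal` when the WT density is below `wt_floor`.
#'
#' @param placements Placements including `wt` and `mutant` role
#'   libraries (`organ_or_genotype` giving the genotype for mutants).
#' @param peaks Peaks from [call_peaks()].
#' @param genotypes Optional character vector: the configured mutant
#'   panel. Mutant libraries with a genotype outside the panel raise an
#'   error.
#' @param repression_fold Required WT/mutant density fold (default 5).
#' @param wt_floor Minimum WT density, RPM/nt (default 1).
#' @return A tibble: peak keys, `genotype`, `wt_density`,
#'   `mutant_density`, `dependence`.
#' @export
mutant_dependence <- function(placements, peaks, genotypes = NULL,
                              repression_fold = 5, wt_floor = 1) {
  mut <- filter(placements, .data$role == "mutant")
  present <- unique(mut$organ_or_genotype)
  if (!is.null(genotypes)) {
    unknown <- setdiff(present, genotypes)
    if (length(unknown) > 0) {
      abort(sprintf("Mutant genotype(s) not in the configured panel: %s",
                    paste(unknown, collapse = ", ")))
    }
  } else {
    genotypes <- present
  }

  wt <- filter(placements, .data$role == "wt") |>
    mutate(pool = "wt")
  wt_dens <- peak_group_density(wt, peaks, group_vars = "pool") |>
    select(all_of(region_keys), "start", "end", wt_density = "density")
  mut_dens <- peak_group_density(mut, peaks) |>
    select(all_of(region_keys), "start", "end",
           genotype = "organ_or_genotype", mutant_density = "density")

  pk <- peaks |>
    filter(.data$screened) |>
    select(all_of(region_keys), "start", "end")
  grid <- tidyr::crossing(pk, genotype = genotypes)

  grid |>
    left_join(wt_dens, by = c(region_keys, "start", "end")) |>
    left_join(mut_dens, by = c(region_keys, "start", "end", "genotype")) |>
    mutate(
      wt_density = dplyr::coalesce(.data$wt_density, 0),
      mutant_density = dplyr::coalesce(.data$mutant_density, 0),
      dependence = dplyr::case_when(
        .data$wt_density < wt_floor ~ "insufficient_signal",
        .data$mutant_density == 0 ~ "repressed",
        .data$wt_density / .data$mutant_density >= repression_fold ~
          "repressed",
        .default = "not_repressed"
      )
    ) |>
    as_tibble()
}
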