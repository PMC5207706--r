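#' Format a percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places
#' and formatted with a trailing `%` — matching the convention of printed
#' retention percentages such as `62.23%`.
#'
#' @param numerator,denominator Non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`.
#' @param decimals Decimal places (default 2).
#' @return A character vector like `"62.23%"`. Use [pct_value()] for the
#'   numeric value.
#' @export
percentage <- function(numerator, denominator, decimals = 2) {
  sprintf(paste0("%.", decimals, "f%%"),
          pct_value(numerator, denominator, decimals))
}

#' @rdname percentage
#' @export
pct_value <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  if (any(numerator > denominator) || any(numerator < 0)) {
    abort("`numerator` must lie in [0, denominator].")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Assemble the annotated peak catalog
#'
#' Joins the classifier outputs onto the screened peaks to produce one
#' row per peak with its genomic interval, paired status, AGO loading
#' preference (consensus and per organ), organ specificity,
#' mutant-dependence columns (`dep_<genotype>`), dsRNA coverage and
#' methylation overlap.
#'
#' @param scan An `srna_scan` from [scan_boundary_peaks()].
#' @param ago Output of [ago_preference()] (or `NULL`).
#' @param organ Output of [organ_specificity()] (or `NULL`).
#' @param mutants Output of [mutant_dependence()] (or `NULL`).
#' @param dsrna Peaks flagged by [peak_in_run()] (or `NULL`).
#' @param methylation Peaks flagged by [peak_methylation_overlap()] (or
#'   `NULL`).
#' @return A tibble: the catalog, one row per screened peak.
#' @export
build_catalog <- function(scan, ago = NULL, organ = NULL, mutants = NULL,
                          dsrna = NULL, methylation = NULL) {
  peaks <- filter(scan$peaks, .data$screened)
  keys <- c(region_keys, "start", "end")
  catalog <- peaks |>
    select(all_of(keys), "width", "a2_max", "A1", "noise_ratio", "chrom",
           "g_start", "g_end", "strand") |>
    mutate(category = srna_category(.data$anchor, .data$region_strand))

  paired_keys <- bind_rows(
    scan$pairs |>
      transmute(.data$gene_id, .data$anchor, region_strand = "sense",
                g_start = .data$sense_start),
    scan$pairs |>
      transmute(.data$gene_id, .data$anchor, region_strand = "antisense",
                g_start = .data$antisense_start)
  ) |> distinct()
  catalog <- catalog |>
    left_join(mutate(paired_keys, paired = TRUE),
              by = c(region_keys, "g_start")) |>
    mutate(paired = dplyr::coalesce(.data$paired, FALSE))

  if (!is.null(ago)) {
    per_organ <- ago$per_organ |>
      summarise(
        ago_by_organ = paste(.data$organ, .data$label, sep = ":",
                             collapse = ";"),
        .by = all_of(keys)
      )
    catalog <- catalog |>
      left_join(ago$consensus, by = keys) |>
      left_join(per_organ, by = keys) |>
      mutate(ago_preference = dplyr::coalesce(.data$ago_preference,
                                              "none"))
  }
  if (!is.null(organ)) {
    catalog <- catalog |>
      left_join(select(organ, all_of(keys), "organ_specific",
                       "dominant_fraction"), by = keys) |>
      mutate(organ_specific = dplyr::coalesce(.data$organ_specific,
                                              "none"))
  }
  if (!is.null(mutants)) {
    wide <- mutants |>
      select(all_of(keys), "genotype", "dependence") |>
      tidyr::pivot_wider(names_from = "genotype",
                         values_from = "dependence",
                         names_prefix = "dep_")
    catalog <- left_join(catalog, wide, by = keys)
  }
  if (!is.null(dsrna)) {
    catalog <- left_join(
      catalog, select(dsrna, all_of(keys), "dsrna_covered"), by = keys
    ) |>
      mutate(dsrna_covered = dplyr::coalesce(.data$dsrna_covered, FALSE))
  }
  if (!is.null(methylation)) {
    catalog <- left_join(
      catalog,
      select(methylation, all_of(keys), "methylation_overlap",
             "meth_sites"),
      by = keys
    ) |>
      mutate(
        methylation_overlap = dplyr::coalesce(.data$methylation_overlap,
                                              FALSE),
        meth_sites = dplyr::coalesce(.data$meth_sites, 0L)
      )
  }
  arrange(catalog, .data$gene_id, .data$anchor,
          desc(.data$region_strand), .data$start)
}

#' Summarise the peak catalog
#'
#' Counts genes per category (PASR/TASR, sense/antisense strand, paired)
#' and computes retention percentages across the downstream annotation
#' stages (AGO-labelled, dsRNA-covered, methylation-overlapping peaks).
#'
#' @param catalog Catalog from [build_catalog()].
#' @param decimals Decimal places of the formatted percentages.
#' @return A list of two tibbles: `counts` (`category`, `n_genes`,
#'   `n_peaks`) and `retention` (`stage`, `category`, `numerator`,
#'   `denominator`, `percent`).
#' @export
summarize_catalog <- function(catalog, decimals = 2) {
  categories <- c("PASR_plus", "PASR_RC", "TASR_plus", "TASR_RC")
  if (nrow(catalog) == 0) {
    return(list(
      counts = tibble(category = c(categories,
                                   c("PASR_paired", "TASR_paired")),
                      n_genes = 0L, n_peaks = 0L),
      retention = tibble(stage = character(), category = character(),
                         numerator = integer(), denominator = integer(),
                         percent = character())
    ))
  }
  counts <- catalog |>
    summarise(n_genes = n_distinct(.data$gene_id), n_peaks = dplyr::n(),
              .by = "category")
  counts <- tibble(category = categories) |>
    left_join(counts, by = "category") |>
    mutate(across(c("n_genes", "n_peaks"),
                  \(x) dplyr::coalesce(x, 0L)))
  paired <- catalog |>
    filter(.data$paired) |>
    summarise(n_genes = n_distinct(.data$gene_id),
              n_peaks = dplyr::n(),
              .by = "anchor") |>
    mutate(category = if_else(.data$anchor == "TSS", "PASR_paired",
                              "TASR_paired")) |>
    select("category", "n_genes", "n_peaks")
  for (cat in c("PASR_paired", "TASR_paired")) {
    if (!cat %in% paired$category) {
      paired <- bind_rows(paired, tibble(category = cat, n_genes = 0L,
                                         n_peaks = 0L))
    }
  }
  counts <- bind_rows(counts, arrange(paired, .data$category))

  stage_flags <- list(
    ago_labelled = if ("ago_preference" %in% names(catalog)) {
      catalog$ago_preference %in% c("AGO1", "AGO4")
    },
    dsrna_covered = if ("dsrna_covered" %in% names(catalog)) {
      catalog$dsrna_covered
    },
    methylation_overlap = if ("methylation_overlap" %in% names(catalog)) {
      catalog$methylation_overlap
    }
  )
  stage_flags <- stage_flags[!vapply(stage_flags, is.null, logical(1))]
  retention <- purrr::imap(stage_flags, \(flag, stage) {
    catalog |>
      mutate(flag = flag) |>
      summarise(
        numerator = n_distinct(.data$gene_id[.data$flag]),
        denominator = n_distinct(.data$gene_id),
        .by = "category"
      ) |>
      mutate(stage = stage)
  }) |>
    bind_rows() |>
    mutate(percent = percentage(.data$numerator, .data$denominator,
                                decimals)) |>
    select("stage", "category", "numerator", "denominator", "percent")

  list(counts = counts, retention = retention)
}

#' Run the full discovery pipeline on a dataset directory
#'
#' Expects the layout written by [simulate_dataset()] (or assembled by
#' hand): `genome.fa`, `annotation.gff3`, `libraries.tsv` (columns
#' `file`, `library_id`, `role`, `organ_or_genotype`) and optionally
#' `methylation.bedgraph`. Runs region extraction, mapping, the window
#' scan on the pooled wild-type libraries, all annotation stages, the
#' sequence-feature summaries and the catalog summary. With `out_dir`
#' set, the peak table, catalog and summary tables are written as TSV
#' (plus the regions as BED).
#'
#' @param dir Dataset directory.
#' @param config A [scan_config()].
#' @param flank Boundary-region flank, nt.
#' @param out_dir Optional output directory for result tables.
#' @return An object of class `srna_pipeline`: a list with `regions`,
#'   `scan`, `features`, `catalog`, `summary`, `runs` (dsRNA coverage
#'   runs) and input paths. `tidy()` returns the catalog and `glance()`
#'   the one-row overview.
#' @export
run_pipeline <- function(dir, config = scan_config(), flank = 500,
                         out_dir = NULL) {
  genome <- read_genome(file.path(dir, "genome.fa"))
  tx <- read_gene_annotation(file.path(dir, "annotation.gff3"))
  models <- select_longest_models(tx)
  regions <- extract_boundary_regions(models, genome, flank = flank)

  reads <- load_library_set(file.path(dir, "libraries.tsv"), dir = dir)
  srna <- filter(reads, .data$role != "dsrna")
  dsrna <- filter(reads, .data$role == "dsrna")

  placements <- map_perfect(srna, regions)
  wt_ids <- unique(srna$library_id[srna$role == "wt"])
  scan <- scan_boundary_peaks(placements, regions, config,
                              library_pool = wt_ids)

  wt_placements <- filter(placements, .data$role == "wt")
  features <- summarize_features(wt_placements, scan$peaks, regions,
                                 config)

  ago <- ago_preference(placements, scan$peaks)
  organ <- organ_specificity(placements, scan$peaks)
  mutants <- mutant_dependence(placements, scan$peaks)

  runs <- NULL
  dsrna_flags <- NULL
  if (nrow(dsrna) > 0) {
    ds_placements <- map_perfect(dsrna, regions)
    runs <- coverage_runs(ds_placements, regions)
    dsrna_flags <- peak_in_run(filter(scan$peaks, .data$screened), runs)
  }

  meth_flags <- NULL
  meth_path <- file.path(dir, "methylation.bedgraph")
  if (file.exists(meth_path)) {
    track <- load_methylation_track(meth_path)
    meth_flags <- peak_methylation_overlap(
      filter(scan$peaks, .data$screened), track
    )
  }

  catalog <- build_catalog(scan, ago = ago, organ = organ,
                           mutants = mutants, dsrna = dsrna_flags,
                           methylation = meth_flags)
  summary <- summarize_catalog(catalog)

  res <- structure(
    list(
      dir = dir, regions = regions, placements = placements,
      scan = scan, features = features, catalog = catalog,
      summary = summary, runs = runs, config = config
    ),
    class = "srna_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir)
  res
}

write_pipeline_tables <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  }
  w(res$scan$peaks |> select(-any_of("bounds")), "peaks.tsv")
  w(res$scan$pairs, "paired_peaks.tsv")
  w(res$catalog, "catalog.tsv")
  w(res$summary$counts, "summary_counts.tsv")
  w(res$summary$retention, "summary_retention.tsv")
  w(res$features$length_distribution, "feature_lengths.tsv")
  w(res$features$five_prime, "feature_five_prime.tsv")
  if (!is.null(res$runs)) w(res$runs, "dsrna_runs.tsv")
  write_region_bed(res$regions, file.path(out_dir, "regions.bed"))
  invisible(out_dir)
}

#' @export
print.srna_pipeline <- function(x, ...) {
  cat(sprintf(
    "<srna_pipeline> %s\n  %d regions | %d screened peaks on %d genes | %d paired\n",
    x$dir, nrow(x$regions), nrow(x$catalog),
    n_distinct(x$catalog$gene_id), sum(x$catalog$paired)
  ))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object An `srna_pipeline` object.
#' @param ... Unused.
#' @export
tidy.srna_pipeline <- function(x, ...) {
  x$catalog
}

#' @rdname run_pipeline
#' @export
glance.srna_pipeline <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    n_screened_peaks = nrow(x$catalog),
    n_genes_with_peak = n_distinct(x$catalog$gene_id),
    n_paired_peaks = sum(x$catalog$paired),
    n_dsrna_covered = if ("dsrna_covered" %in% names(x$catalog)) {
      sum(x$catalog$dsrna_covered)
    } else {
      NA_integer_
    },
    n_methylated = if ("methylation_overlap" %in% names(x$catalog)) {
      sum(x$catalog$methylation_overlap)
    } else {
      NA_integer_
    }
  )
}
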