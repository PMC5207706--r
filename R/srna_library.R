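#' Load and collapse a small-RNA library
#'
#' Reads a collapsed FASTA (read count encoded in the header, e.g.
#' `>r1_27`) or a FASTQ file (each record counts 1). Identical sequences
#' are collapsed with summed counts; `U` is normalised to `T`. The library
#' total (`total_raw_count`) is computed over *all* records before any
#' filtering; reads containing `N` or reaching `max_len` nt are then
#' excluded from the returned (mappable) read set but still count towards
#' the total used for RPM normalisation.
#'
#' @param path Path to the reads file.
#' @param library_id Library identifier carried through all downstream
#'   tables.
#' @param role One of `wt`, `ago1`, `ago4`, `mutant`, `dsrna`.
#' @param organ_or_genotype Organ (for `wt`/`ago*` libraries) or genotype
#'   (for `mutant` libraries); free text.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param count_sep Character separating the read name from its count in
#'   collapsed-FASTA headers (`"_"` by default; `"-"` is the other common
#'   dialect).
#' @param max_len Reads of this length or longer are excluded from mapping
#'   (default 40 nt, the upper bound of small-RNA sequencing read lengths).
#' @return A tibble of collapsed reads with columns `library_id`, `role`,
#'   `organ_or_genotype`, `sequence`, `length`, `raw_count`, `rpm`,
#'   `total_raw_count`.
#' @export
load_srna_library <- function(path, library_id, role = "wt",
                              organ_or_genotype = NA_character_,
                              format = c("auto", "fasta", "fastq"),
                              count_sep = "_", max_len = 40) {
  format <- match.arg(format)
  role <- match.arg(role, c("wt", "ago1", "ago4", "mutant", "dsrna"))
  if (!file.exists(path)) abort(sprintf("Cannot read library file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  parsed <- if (format == "fasta") {
    parse_collapsed_fasta(path, count_sep)
  } else {
    parse_fastq(path)
  }

  seqs <- normalize_seq(parsed$sequence)
  collapsed <- tibble(sequence = seqs, raw_count = parsed$count) |>
    summarise(raw_count = sum(.data$raw_count), .by = "sequence")
  total <- sum(collapsed$raw_count)
  if (total <= 0) abort(sprintf("Library %s has zero total reads.", library_id))

  bad_len <- nchar(collapsed$sequence) >= max_len
  bad_n <- grepl("[^ACGT]", collapsed$sequence)
  if (any(bad_len)) {
    warn(sprintf(
      "%s: %d read(s) of length >= %d nt excluded from mapping (kept in the library total).",
      library_id, sum(bad_len), max_len
    ))
  }
  collapsed <- collapsed[!(bad_len | bad_n), , drop = FALSE]

  tibble(
    library_id = library_id,
    role = role,
    organ_or_genotype = organ_or_genotype,
    sequence = collapsed$sequence,
    length = nchar(collapsed$sequence),
    raw_count = collapsed$raw_count,
    rpm = normalize_rpm(collapsed$raw_count, total),
    total_raw_count = total
  )
}

parse_collapsed_fasta <- function(path, count_sep = "_") {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(sprintf("Empty FASTA file: %s", path))
  headers <- names(recs)
  count_str <- sub(
    paste0("^.*", ifelse(count_sep == "_", "_", "\\-"), "(\\d+)\\s*$"),
    "\\1", headers
  )
  counts <- suppressWarnings(as.integer(count_str))
  if (anyNA(counts)) {
    first_bad <- which(is.na(counts))[1]
    abort(sprintf(
      "Malformed count field in FASTA header (record %d): '%s'",
      first_bad, headers[first_bad]
    ))
  }
  list(sequence = as.character(recs), count = counts)
}

parse_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0 || length(lines) %% 4 != 0) {
    abort(sprintf(
      "Malformed FASTQ (%d lines, not a multiple of 4): %s",
      length(lines), path
    ))
  }
  seq_lines <- lines[seq(2, length(lines), by = 4)]
  list(sequence = seq_lines, count = rep(1L, length(seq_lines)))
}

#' Load a set of libraries from a manifest
#'
#' @param manifest A data frame with columns `file`, `library_id`, `role`,
#'   `organ_or_genotype` (and optionally `format`, `count_sep`), or a path
#'   to a TSV file with those columns.
#' @param dir Directory against which relative `file` paths are resolved.
#' @param ... Passed on to [load_srna_library()].
#' @return A tibble of collapsed reads across all libraries (the row-bound
#'   output of [load_srna_library()]).
#' @export
load_library_set <- function(manifest, dir = ".", ...) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  check_cols(manifest, c("file", "library_id", "role", "organ_or_genotype"))
  purrr::pmap(
    manifest[c("file", "library_id", "role", "organ_or_genotype")],
    function(file, library_id, role, organ_or_genotype) {
      path <- if (file.exists(file)) file else file.path(dir, file)
      load_srna_library(path, library_id, role, organ_or_genotype, ...)
    }
  ) |>
    bind_rows()
}

#' Reads-per-million normalisation
#'
#' `rpm = raw_count / total_raw_count * 1e6`.
#'
#' @param raw_count Raw read count(s).
#' @param total_raw_count Total raw read count of the library (before any
#'   filtering).
#' @return Numeric vector of RPM values.
#' @export
normalize_rpm <- function(raw_count, total_raw_count) {
  if (any(total_raw_count <= 0)) {
    abort("`total_raw_count` must be positive.")
  }
  raw_count / total_raw_count * 1e6
}

#' Map reads into boundary regions by perfect matching
#'
#' Every exact, ungapped occurrence of a read in a region sequence yields
#' one placement; sense and antisense region sequences are searched
#' independently, and a read may map to several regions and positions.
#' `U`/`T` spellings are equivalent (reads are normalised at load). Reads
#' containing characters outside `A/C/G/T` cannot match perfectly and
#' produce no placements.
#'
#' @param reads A tibble of collapsed reads from [load_srna_library()] /
#'   [load_library_set()] (requires at least `sequence`; library columns
#'   are carried through if present).
#' @param regions Boundary regions from [extract_boundary_regions()].
#' @param multimap Multi-mapper weighting policy: `"full"` (each placement
#'   carries the read's full rpm; default) or `"fractional"` (rpm divided
#'   by the read's total number of placements).
#' @return A tibble of placements: region keys, `start`, `end` (0-based
#'   half-open offsets within the region sequence), `sequence`, plus all
#'   per-read columns present in `reads`.
#' @export
map_perfect <- function(reads, regions, multimap = c("full", "fractional")) {
  multimap <- match.arg(multimap)
  check_cols(reads, "sequence")
  check_cols(regions, c(region_keys, "sequence"))

  uniq <- unique(normalize_seq(reads$sequence))
  uniq <- uniq[!grepl("[^ACGT]", uniq) & nchar(uniq) > 0]
  hits <- find_exact_hits(uniq, regions)

  reads2 <- reads
  reads2$sequence <- normalize_seq(reads2$sequence)
  placements <- inner_join(hits, reads2, by = "sequence",
                           relationship = "many-to-many")
  if (multimap == "fractional" && nrow(placements) > 0 &&
      "rpm" %in% names(placements)) {
    n_place <- hits |> count(.data$sequence, name = "n_placements")
    placements <- placements |>
      left_join(n_place, by = "sequence") |>
      mutate(rpm = .data$rpm / .data$n_placements) |>
      select(-"n_placements")
  }
  placements |>
    arrange(.data$gene_id, .data$anchor, .data$region_strand, .data$start) |>
    as_tibble()
}

# Exact substring search of many short patterns against all region
# sequences at once: regions are concatenated with 50-N spacers (no read
# shorter than 50 nt can straddle a junction) and searched per read length
# with an Aho-Corasick dictionary (Biostrings PDict).
find_exact_hits <- function(uniq, regions) {
  empty <- tibble(
    gene_id = character(), anchor = character(),
    region_strand = character(), start = integer(), end = integer(),
    sequence = character()
  )
  if (length(uniq) == 0 || nrow(regions) == 0) return(empty)

  spacer_len <- 50L
  widths <- nchar(regions$sequence)
  offsets <- cumsum(c(0L, head(widths + spacer_len, -1)))
  subject <- Biostrings::DNAString(
    paste(regions$sequence, collapse = strrep("N", spacer_len))
  )

  out <- vector("list", 0)
  for (len in sort(unique(nchar(uniq)))) {
    pats <- uniq[nchar(uniq) == len]
    if (len > max(widths)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    m <- Biostrings::matchPDict(pd, subject)
    starts1 <- Biostrings::startIndex(m)
    n_hit <- lengths(starts1)
    if (sum(n_hit) == 0) next
    pat_idx <- rep.int(seq_along(pats), n_hit)
    hit_start1 <- unlist(starts1, use.names = FALSE)
    region_idx <- findInterval(hit_start1 - 1L, offsets)
    start <- hit_start1 - 1L - offsets[region_idx]
    out[[length(out) + 1]] <- tibble(
      gene_id = regions$gene_id[region_idx],
      anchor = regions$anchor[region_idx],
      region_strand = regions$region_strand[region_idx],
      start = as.integer(start),
      end = as.integer(start + len),
      sequence = pats[pat_idx]
    )
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Write read placements as a tab-separated table
#'
#' @param placements Placements from [map_perfect()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  cols <- c("gene_id", "anchor", "region_strand", "start", "end",
            "sequence", "raw_count", "rpm", "library_id")
  check_cols(placements, cols)
  readr::write_tsv(placements[cols], path, progress = FALSE)
  invisible(path)
}
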