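#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the chromosome name.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read transcript records from a GFF3 annotation
#'
#' Extracts one row per transcript with its parent gene, chromosome, strand
#' and genomic span. Coordinates are returned as in GFF3 (1-based,
#' inclusive).
#'
#' @param path Path to a GFF3 file.
#' @param transcript_features GFF3 feature types treated as transcript
#'   models (default `"mRNA"`; add e.g. `"transcript"` for other dialects).
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @export
read_gene_annotation <- function(path, transcript_features = "mRNA") {
  gff <- rtracklayer::import(path, format = "gff3")
  tx <- gff[as.character(gff$type) %in% transcript_features]
  if (length(tx) == 0) {
    abort(sprintf(
      "No transcript records of type %s found in %s",
      paste(transcript_features, collapse = "/"), path
    ))
  }
  p <- S4Vectors::mcols(tx)$Parent
  parent <- vapply(as.list(p), function(z) {
    if (length(z) == 0) NA_character_ else as.character(z)[1]
  }, character(1))
  parent <- sub("^gene:", "", parent)
  if (anyNA(parent)) {
    abort("Transcript record(s) without a Parent gene attribute.")
  }
  tx_id <- S4Vectors::mcols(tx)$ID
  if (is.null(tx_id)) tx_id <- paste0("tx", seq_along(tx))
  tibble(
    gene_id = parent,
    transcript_id = as.character(tx_id),
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    start = GenomicRanges::start(tx),
    end = GenomicRanges::end(tx)
  )
}

#' Select the longest transcript model per gene
#'
#' For genes with multiple transcript models, only the model with maximal
#' genomic span is kept; its 5'-most transcribed position on the gene
#' strand becomes the TSS and its 3'-most the transcription terminus.
#'
#' @param transcripts A data frame of transcript records as returned by
#'   [read_gene_annotation()]: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (1-based inclusive).
#' @param compartment_patterns Named character vector of regular expressions
#'   (matched case-insensitively against chromosome names) used to label
#'   organellar genes. Names must be `chloroplast` and `mitochondrial`;
#'   everything else is `nuclear`.
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `tss`,
#'   `terminus` (both 1-based), `body_length`, `compartment`.
#' @export
select_longest_models <- function(
    transcripts,
    compartment_patterns = c(
      chloroplast = "^(chrc|chloroplast|pltd|pt)$",
      mitochondrial = "^(chrm|mt|mitochondri)"
    )) {
  check_cols(transcripts, c("gene_id", "chrom", "strand", "start", "end"))

  bad <- transcripts |>
    summarise(
      n_strand = n_distinct(.data$strand),
      n_chrom = n_distinct(.data$chrom),
      .by = "gene_id"
    ) |>
    filter(.data$n_strand > 1 | .data$n_chrom > 1)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Inconsistent annotation (conflicting strand or chromosome) for gene(s): %s",
      paste(bad$gene_id, collapse = ", ")
    ))
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    abort("Transcript strand must be '+' or '-'.")
  }

  models <- transcripts |>
    mutate(span = .data$end - .data$start + 1L) |>
    slice_max(.data$span, n = 1, with_ties = FALSE, by = "gene_id") |>
    mutate(
      tss = if_else(.data$strand == "+", .data$start, .data$end),
      terminus = if_else(.data$strand == "+", .data$end, .data$start),
      body_length = .data$span,
      compartment = classify_compartment(.data$chrom, compartment_patterns)
    ) |>
    select("gene_id", "chrom", "strand", "tss", "terminus",
           "body_length", "compartment") |>
    arrange(.data$gene_id)
  as_tibble(models)
}

classify_compartment <- function(chrom, patterns) {
  out <- rep("nuclear", length(chrom))
  if (!is.null(patterns["chloroplast"]) && !is.na(patterns["chloroplast"])) {
    out[grepl(patterns[["chloroplast"]], chrom, ignore.case = TRUE)] <- "chloroplast"
  }
  if (!is.null(patterns["mitochondrial"]) && !is.na(patterns["mitochondrial"])) {
    out[grepl(patterns[["mitochondrial"]], chrom, ignore.case = TRUE)] <- "mitochondrial"
  }
  out
}

#' Extract the four boundary regions of each gene
#'
#' For every gene model, four anchored regions are extracted: around the TSS
#' and around the transcription terminus, each on the sense strand (gene
#' strand) and as the reverse complement over the same genomic interval
#' (antisense). A region consists of `flank` nt outside the gene body plus
#' `min(flank, body_length)` nt of gene body adjoining the anchor, so a gene
#' with body length of at least `flank` yields regions of `2 * flank` nt.
#' Regions running past a chromosome end are truncated and flagged.
#'
#' @param models Gene models from [select_longest_models()].
#' @param genome A [Biostrings::DNAStringSet] as from [read_genome()].
#' @param flank Flanking length outside the gene body, in nt (default 500).
#' @return A tibble with one row per region: `gene_id`, `anchor`
#'   (`TSS`/`terminus`), `region_strand` (`sense`/`antisense`), `chrom`,
#'   `g_start`, `g_end` (0-based half-open genomic), `L`, `anchor_offset`
#'   (0-based offset of the anchor base in the region sequence),
#'   `truncated`, `gene_strand`, `seq_rev` (whether the region sequence
#'   runs antiparallel to the forward genomic strand), `compartment`,
#'   `sequence`.
#' @export
extract_boundary_regions <- function(models, genome, flank = 500) {
  check_cols(models, c("gene_id", "chrom", "strand", "tss", "terminus",
                       "body_length"))
  if (flank < 1) abort("`flank` must be >= 1.")
  if (any(models$body_length <= 0)) {
    abort(sprintf(
      "Zero-length gene body for gene(s): %s",
      paste(models$gene_id[models$body_length <= 0], collapse = ", ")
    ))
  }
  missing_chrom <- setdiff(unique(models$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Chromosome(s) not in genome: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  len <- chrom_len[models$chrom]
  if (any(models$tss < 1 | models$tss > len |
          models$terminus < 1 | models$terminus > len)) {
    bad <- models$gene_id[models$tss < 1 | models$tss > len |
                            models$terminus < 1 | models$terminus > len]
    abort(sprintf("TSS or terminus outside chromosome bounds for gene(s): %s",
                  paste(bad, collapse = ", ")))
  }

  d <- pmin(flank, models$body_length)
  tss0 <- models$tss - 1L
  ter0 <- models$terminus - 1L
  plus <- models$strand == "+"

  # Raw genomic intervals (0-based half-open), before truncation.
  tss_start <- ifelse(plus, tss0 - flank, tss0 - d + 1L)
  tss_end <- ifelse(plus, tss0 + d, tss0 + flank + 1L)
  ter_start <- ifelse(plus, ter0 - d + 1L, ter0 - flank)
  ter_end <- ifelse(plus, ter0 + flank + 1L, ter0 + d)

  anchored <- bind_rows(
    tibble(
      gene_id = models$gene_id, anchor = "TSS", chrom = models$chrom,
      raw_start = tss_start, raw_end = tss_end, anchor0 = tss0,
      gene_strand = models$strand, compartment = models$compartment
    ),
    tibble(
      gene_id = models$gene_id, anchor = "terminus", chrom = models$chrom,
      raw_start = ter_start, raw_end = ter_end, anchor0 = ter0,
      gene_strand = models$strand, compartment = models$compartment
    )
  )
  anchored <- anchored |>
    mutate(
      chrom_len = unname(chrom_len[.data$chrom]),
      g_start = pmax(.data$raw_start, 0L),
      g_end = pmin(.data$raw_end, .data$chrom_len),
      truncated = .data$g_start != .data$raw_start |
        .data$g_end != .data$raw_end,
      L = .data$g_end - .data$g_start
    )

  # Sense orientation: the gene strand. Its sequence is reversed relative
  # to the forward genomic strand for minus-strand genes.
  sense <- anchored |>
    mutate(
      region_strand = "sense",
      seq_rev = .data$gene_strand == "-",
      anchor_offset = if_else(.data$seq_rev,
                              .data$g_end - 1L - .data$anchor0,
                              .data$anchor0 - .data$g_start)
    )
  antis <- anchored |>
    mutate(
      region_strand = "antisense",
      seq_rev = .data$gene_strand == "+",
      anchor_offset = if_else(.data$gene_strand == "-",
                              .data$anchor0 - .data$g_start,
                              .data$g_end - 1L - .data$anchor0)
    )

  regions <- bind_rows(sense, antis) |>
    select("gene_id", "anchor", "region_strand", "chrom", "g_start",
           "g_end", "L", "anchor_offset", "truncated", "gene_strand",
           "seq_rev", "compartment")

  fwd <- as.character(Biostrings::subseq(
    genome[regions$chrom],
    start = regions$g_start + 1L,
    end = regions$g_end
  ))
  seqs <- fwd
  rev_idx <- which(regions$seq_rev)
  if (length(rev_idx) > 0) seqs[rev_idx] <- revcomp(fwd[rev_idx])
  regions$sequence <- unname(seqs)
  regions |>
    arrange(.data$gene_id, .data$anchor, desc(.data$region_strand)) |>
    as_tibble()
}

#' Write boundary regions as BED6
#'
#' One BED record per region; `name` is `gene_id|anchor|region_strand`, the
#' BED strand is the genomic orientation of the region sequence. BED
#' coordinates are 0-based half-open.
#'
#' @param regions Regions from [extract_boundary_regions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  check_cols(regions, c(region_keys, "chrom", "g_start", "g_end", "seq_rev"))
  bed <- regions |>
    transmute(
      .data$chrom, .data$g_start, .data$g_end,
      name = paste(.data$gene_id, .data$anchor, .data$region_strand,
                   sep = "|"),
      score = 0L,
      strand = if_else(.data$seq_rev, "-", "+")
    )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write boundary-region sequences as FASTA
#'
#' @inheritParams write_region_bed
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, path) {
  check_cols(regions, c(region_keys, "sequence"))
  seqs <- Biostrings::DNAStringSet(regions$sequence)
  names(seqs) <- paste(regions$gene_id, regions$anchor,
                       regions$region_strand, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
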