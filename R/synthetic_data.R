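#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a small
#' multi-chromosome genome (two nuclear chromosomes plus organellar
#' chromosomes), protein-coding genes with occasional second transcript
#' models, wild-type small-RNA libraries from four organs, AGO1-IP and
#' AGO4-IP libraries, a panel of biogenesis-mutant libraries, a dsRNA-seq
#' library and a DNA-methylation track — with peaks, AGO preferences,
#' organ specificity, mutant suppression, dsRNA coverage and methylation
#' planted at known loci.
#'
#' Read lengths follow a 19-28 nt distribution with a 23-24 nt mode
#' (54% of reads), and 5' nucleotides are biased (A 36%, U 29%) to match
#' heterochromatic-siRNA-like populations. Planted peaks concentrate
#' reads in 60-80 nt spans at 20x the background read density.
#'
#' @param seed Integer seed; the same seed and configuration reproduce
#'   byte-identical output files.
#' @param n_genes Number of genes (default 200).
#' @param n_organellar Named vector: genes placed on the chloroplast
#'   (`ChrC`) and mitochondrial (`ChrM`) chromosomes.
#' @param gene_length_range,short_gene_range,frac_short_genes Gene-body
#'   length distribution: a `frac_short_genes` fraction is drawn from
#'   `short_gene_range` (exercising the short-gene region rule), the rest
#'   from `gene_length_range`.
#' @param frac_isoforms Fraction of genes given a second, shorter
#'   transcript model.
#' @param flank Boundary-region flank in nt (default 500).
#' @param frac_planted Fraction of genes with a planted peak
#'   (default 0.2).
#' @param frac_paired,frac_antisense_only Of planted loci: fraction
#'   planted on both strands, and on the antisense strand only (the rest
#'   are sense-only).
#' @param peak_span_range Planted peak span in nt (default 60-80).
#' @param peak_margin Minimum distance of a planted span from the region
#'   edges, nt.
#' @param enrichment Planted in-peak read density as a multiple of the
#'   background density (default 20).
#' @param bg_reads_wt,bg_reads_other Background reads per region per
#'   library, for wild-type and for IP/mutant libraries.
#' @param library_size Total raw read count of every small-RNA library
#'   (structured reads are topped up with a single non-mapping filler
#'   sequence).
#' @param dsrna_library_size Total raw read count of the dsRNA library.
#' @param read_len_probs Named numeric: probabilities of lengths 19-28 nt.
#' @param five_prime_probs Named numeric: 5' nucleotide probabilities
#'   (RNA alphabet).
#' @param organs Wild-type organs (also the IP-library organs).
#' @param frac_ago4,frac_ago1 Of planted loci: fraction with planted AGO4
#'   or AGO1 loading preference (the rest have none).
#' @param ago_peak_reads Pooled IP reads at a planted peak for the
#'   preferred AGO; the other AGO receives `1 / ago_fold` of them.
#' @param ago_fold Planted fold between preferred and non-preferred IP.
#' @param frac_organ_specific Of planted loci: fraction accumulating
#'   dominantly in one organ.
#' @param organ_dominant_weight Read share of the dominant organ at
#'   organ-specific loci (default 0.92).
#' @param mutant_panel Genotype names of the mutant libraries.
#' @param pathways Named list: each pathway maps to the genotypes in
#'   which its peaks are suppressed.
#' @param frac_suppressed Of planted loci: fraction assigned a pathway
#'   (and hence suppressed in that pathway's genotypes).
#' @param suppression_factor Multiplier on planted-peak reads in a
#'   suppressing genotype's library (default 0.05).
#' @param frac_dsrna Of planted loci: fraction covered by a dsRNA-seq
#'   run.
#' @param dsrna_read_len,dsrna_tile_step,dsrna_run_margin dsRNA-read
#'   tiling parameters (read length, tile step, run extension beyond the
#'   peak).
#' @param min_dsrna_run Minimum planted run length, nt (default 110, so
#'   planted runs clear the 100-nt reporting threshold).
#' @param frac_methylated Of planted loci: fraction with methylation
#'   planted inside the peak.
#' @param meth_sites_per_peak,meth_level_range Planted methylation sites
#'   per methylated peak and their level range.
#' @param n_bg_meth_sites Scattered background methylation sites (placed
#'   at least `meth_clearance` nt away from any planted peak).
#' @param meth_clearance Exclusion distance of background sites from
#'   planted peaks, nt.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 1,
    n_genes = 200,
    n_organellar = c(chloroplast = 8, mitochondrial = 4),
    gene_length_range = c(500, 3000),
    short_gene_range = c(250, 499),
    frac_short_genes = 0.10,
    frac_isoforms = 0.20,
    flank = 500,
    frac_planted = 0.20,
    frac_paired = 0.30,
    frac_antisense_only = 0.20,
    peak_span_range = c(60, 80),
    peak_margin = 30,
    enrichment = 20,
    bg_reads_wt = 60,
    bg_reads_other = 30,
    library_size = 500000,
    dsrna_library_size = 100000,
    read_len_probs = c(
      `19` = 0.02, `20` = 0.03, `21` = 0.13, `22` = 0.10, `23` = 0.20,
      `24` = 0.34, `25` = 0.08, `26` = 0.04, `27` = 0.03, `28` = 0.03
    ),
    five_prime_probs = c(A = 0.36, C = 0.17, G = 0.18, U = 0.29),
    organs = c("flower", "leaf", "root", "seedling"),
    frac_ago4 = 0.40,
    frac_ago1 = 0.20,
    ago_peak_reads = 320,
    ago_fold = 8,
    frac_organ_specific = 0.30,
    organ_dominant_weight = 0.92,
    mutant_panel = c("dcl2", "dcl3", "dcl4", "dcl234", "rdr2", "rdr6",
                     "nrpd1a", "nrpd1b"),
    pathways = list(
      hetsirna = c("dcl3", "dcl234", "rdr2", "nrpd1a", "nrpd1b"),
      tasirna = c("dcl4", "dcl234", "rdr6"),
      dcl2_type = c("dcl2", "dcl234", "rdr2")
    ),
    frac_suppressed = 0.50,
    suppression_factor = 0.05,
    frac_dsrna = 0.40,
    dsrna_read_len = 34,
    dsrna_tile_step = 15,
    dsrna_run_margin = 30,
    min_dsrna_run = 110,
    frac_methylated = 0.40,
    meth_sites_per_peak = 8,
    meth_level_range = c(0.6, 0.9),
    n_bg_meth_sites = 60,
    meth_clearance = 300) {
  cfg <- as.list(environment())
  probs <- c(cfg$read_len_probs, cfg$five_prime_probs,
             cfg$frac_planted, cfg$frac_paired, cfg$frac_antisense_only,
             cfg$frac_ago4, cfg$frac_ago1, cfg$frac_organ_specific,
             cfg$frac_suppressed, cfg$frac_dsrna, cfg$frac_methylated,
             cfg$suppression_factor, cfg$organ_dominant_weight)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities and fractions must lie in [0, 1].")
  }
  if (abs(sum(cfg$read_len_probs) - 1) > 1e-9 ||
      abs(sum(cfg$five_prime_probs) - 1) > 1e-9) {
    abort("`read_len_probs` and `five_prime_probs` must each sum to 1.")
  }
  if (cfg$frac_ago4 + cfg$frac_ago1 > 1 ||
      cfg$frac_paired + cfg$frac_antisense_only > 1) {
    abort("Label fractions of the same family must sum to at most 1.")
  }
  min_L <- cfg$flank + min(cfg$short_gene_range[1], cfg$flank)
  if (max(cfg$peak_span_range) + 2 * cfg$peak_margin > min_L) {
    abort("Peak span plus margins exceeds the smallest possible region.")
  }
  structure(cfg, class = "sim_config")
}

lib_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 1000 + i)
}

# Sample n reads from a region sequence restricted to offsets [a, b),
# with length and 5'-nucleotide distributions. pos_by_base lists the
# 0-based offsets of each base in the region sequence.
sample_read_batch <- function(seq_str, pos_by_base, a, b, n, cfg) {
  if (n <= 0) {
    return(tibble(start = integer(), len = integer(),
                  sequence = character()))
  }
  lens <- as.integer(sample(names(cfg$read_len_probs), n, replace = TRUE,
                            prob = cfg$read_len_probs))
  fp <- names(cfg$five_prime_probs)
  bases <- sample(chartr("U", "T", fp), n, replace = TRUE,
                  prob = cfg$five_prime_probs)
  starts <- integer(n)
  for (l in unique(lens)) {
    hi <- b - l
    sel <- lens == l
    if (hi < a) {
      starts[sel] <- a
      lens[sel] <- b - a
      next
    }
    for (f in unique(bases[sel])) {
      ids <- which(sel & bases == f)
      cand <- pos_by_base[[f]]
      cand <- cand[cand >= a & cand <= hi]
      if (length(cand) == 0) cand <- a:hi
      starts[ids] <- if (length(cand) == 1) {
        rep(cand, length(ids))
      } else {
        sample(cand, length(ids), replace = TRUE)
      }
    }
  }
  tibble(
    start = starts,
    len = lens,
    sequence = substring(seq_str, starts + 1L, starts + lens)
  )
}

random_chrom <- function(len, gc = 0.38) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Writes a genome FASTA, a GFF3 annotation, collapsed-FASTA small-RNA
#' libraries (wild-type organs, AGO1/AGO4 IP, mutant panel), a dsRNA-seq
#' library, a methylation bedGraph, a library manifest (`libraries.tsv`)
#' and a truth table (`truth.tsv`) into `dir`. All randomness derives
#' from `config$seed`, with per-library sub-seeds so that libraries are
#' generated independently of each other.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `truth` (tibble of planted
#'   peaks), `paths` and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "libs"), showWarnings = FALSE)

  layout <- withr::with_seed(lib_seed(cfg$seed, 1L), sim_layout(cfg))
  genome <- layout$genome
  regions <- layout$regions
  truth <- layout$truth
  alloc <- withr::with_seed(lib_seed(cfg$seed, 2L),
                            sim_allocations(truth, cfg))

  # Per-region base-position indices, reused for every library.
  pos_index <- lapply(regions$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    lapply(c(A = "A", C = "C", G = "G", T = "T"),
           \(b) which(ch == b) - 1L)
  })

  libs <- sim_library_table(cfg)
  reads_by_lib <- vector("list", nrow(libs))
  for (i in seq_len(nrow(libs))) {
    reads_by_lib[[i]] <- withr::with_seed(
      lib_seed(cfg$seed, 100L + i),
      sim_library_reads(libs[i, ], regions, truth, alloc, pos_index, cfg)
    )
  }
  names(reads_by_lib) <- libs$library_id

  # Guard: background alone must not satisfy the window criteria in any
  # region of the pooled wild-type libraries.
  wt_idx <- which(libs$role == "wt")
  for (attempt in 1:5) {
    offenders <- background_offenders(reads_by_lib[wt_idx], regions, cfg)
    if (length(offenders) == 0) break
    inform(sprintf(
      "Resampling background in %d region(s) with accidental high-density windows.",
      length(offenders)
    ))
    for (i in wt_idx) {
      reads_by_lib[[i]] <- withr::with_seed(
        lib_seed(cfg$seed, 10000L + 100L * attempt + i),
        resample_background(reads_by_lib[[i]], offenders, libs[i, ],
                            regions, pos_index, cfg)
      )
    }
  }

  # dsRNA tiling reads (deterministic given the layout).
  dsrna_reads <- sim_dsrna_reads(regions, truth, cfg)

  meth <- withr::with_seed(lib_seed(cfg$seed, 3L),
                           sim_methylation(layout, truth, cfg))

  paths <- write_sim_files(dir, layout, libs, reads_by_lib, dsrna_reads,
                           meth, truth, cfg)
  invisible(list(dir = dir, truth = truth, paths = paths, config = cfg))
}

region_tag <- function(regions) {
  paste(regions$gene_id, regions$anchor, regions$region_strand, sep = "|")
}

# ---- layout: genome, genes, planted truth --------------------------------

sim_layout <- function(cfg) {
  n_cp <- cfg$n_organellar[["chloroplast"]]
  n_mt <- cfg$n_organellar[["mitochondrial"]]
  n_nuc <- cfg$n_genes - n_cp - n_mt
  if (n_nuc < 2) abort("Too few nuclear genes in `sim_config`.")
  chrom_of <- c(
    rep(c("Chr1", "Chr2"), length.out = n_nuc),
    rep("ChrC", n_cp), rep("ChrM", n_mt)
  )

  n <- cfg$n_genes
  short <- runif(n) < cfg$frac_short_genes
  body <- ifelse(
    short,
    sample(seq(cfg$short_gene_range[1], cfg$short_gene_range[2]), n,
           replace = TRUE),
    sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), n,
           replace = TRUE)
  )
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = chrom_of,
    strand = strand,
    body_length = as.integer(body)
  )

  # Sequential placement per chromosome; footprints (region extents) are
  # separated so boundary regions of neighbours never overlap.
  genes <- genes |>
    mutate(.by = "chrom",
           fp = .data$body_length + 2L * cfg$flank,
           fp_start = cumsum(dplyr::lag(.data$fp + 100L, default = 200L)),
           start = .data$fp_start + cfg$flank,
           end = .data$start + .data$body_length - 1L) |>
    select(-"fp", -"fp_start")
  chrom_len <- genes |>
    summarise(len = max(.data$end) + cfg$flank + 200L, .by = "chrom")

  genome <- Biostrings::DNAStringSet(vapply(
    chrom_len$len, random_chrom, character(1)
  ))
  names(genome) <- chrom_len$chrom

  models <- genes |>
    mutate(
      tss = if_else(.data$strand == "+", .data$start, .data$end),
      terminus = if_else(.data$strand == "+", .data$end, .data$start),
      compartment = dplyr::case_match(.data$chrom, "ChrC" ~ "chloroplast",
                                      "ChrM" ~ "mitochondrial",
                                      .default = "nuclear")
    ) |>
    select("gene_id", "chrom", "strand", "tss", "terminus", "body_length",
           "compartment")
  regions <- extract_boundary_regions(models, genome, flank = cfg$flank)

  truth <- sim_truth(genes, regions, cfg)
  iso <- runif(nrow(genes)) < cfg$frac_isoforms
  list(genome = genome, genes = mutate(genes, second_isoform = iso),
       models = models, regions = regions, truth = truth)
}

# Planted loci and their labels. One row per planted peak per strand;
# paired loci contribute two rows sharing a genomic interval.
sim_truth <- function(genes, regions, cfg) {
  n_loci <- round(cfg$frac_planted * nrow(genes))
  if (n_loci == 0) {
    return(tibble(
      gene_id = character(), anchor = character(),
      region_strand = character(), chrom = character(),
      g_start = integer(), g_end = integer(), span = integer(),
      offset = integer(),
      paired = logical(), organ = character(), ago = character(),
      pathway = character(), suppressed_genotypes = character(),
      dsrna_covered = logical(), methylated = logical()
    ))
  }
  # Loci are planted on genes whose TSS and terminus regions are
  # genomically disjoint (body >= 2 * flank), so cross-anchor
  # multi-mapping cannot blur the planted density contrast.
  eligible <- genes$gene_id[genes$body_length >= 2 * cfg$flank]
  if (length(eligible) < n_loci) {
    abort("Too few genes with disjoint boundary regions to plant peaks.")
  }
  picked <- sample(eligible, n_loci)
  anchor <- sample(c("TSS", "terminus"), n_loci, replace = TRUE)
  strand_mode <- sample(
    c("paired", "antisense", "sense"), n_loci, replace = TRUE,
    prob = c(cfg$frac_paired, cfg$frac_antisense_only,
             1 - cfg$frac_paired - cfg$frac_antisense_only)
  )
  span <- sample(seq(cfg$peak_span_range[1], cfg$peak_span_range[2]),
                 n_loci, replace = TRUE)
  ago <- sample(c("AGO4", "AGO1", "none"), n_loci, replace = TRUE,
                prob = c(cfg$frac_ago4, cfg$frac_ago1,
                         1 - cfg$frac_ago4 - cfg$frac_ago1))
  organ <- ifelse(runif(n_loci) < cfg$frac_organ_specific,
                  sample(cfg$organs, n_loci, replace = TRUE), "none")
  pathway <- ifelse(runif(n_loci) < cfg$frac_suppressed,
                    sample(names(cfg$pathways), n_loci, replace = TRUE),
                    "none")
  dsrna <- runif(n_loci) < cfg$frac_dsrna
  methylated <- runif(n_loci) < cfg$frac_methylated

  sense_regions <- regions |>
    filter(.data$region_strand == "sense") |>
    select("gene_id", "anchor", "chrom", "g_start", "g_end", "L",
           "seq_rev")
  loci <- tibble(
    gene_id = picked, anchor = anchor, strand_mode = strand_mode,
    span = as.integer(span), ago = ago, organ = organ, pathway = pathway,
    dsrna_covered = dsrna, methylated = methylated
  ) |>
    inner_join(sense_regions, by = c("gene_id", "anchor"))

  # Peak offset in sense-region coordinates, then projected genomically.
  loci <- loci |>
    mutate(
      offset = purrr::map2_int(.data$L, .data$span, \(l, s) {
        as.integer(sample(seq(cfg$peak_margin, l - s - cfg$peak_margin),
                          1))
      }),
      pk_g_start = if_else(.data$seq_rev,
                           .data$g_end - (.data$offset + .data$span),
                           .data$g_start + .data$offset),
      pk_g_end = .data$pk_g_start + .data$span,
      suppressed_genotypes = purrr::map_chr(.data$pathway, \(p) {
        if (p == "none") "" else paste(cfg$pathways[[p]], collapse = ",")
      })
    )

  expand <- loci |>
    mutate(strands = purrr::map(.data$strand_mode, \(m) {
      switch(m, paired = c("sense", "antisense"), antisense = "antisense",
             sense = "sense")
    })) |>
    tidyr::unnest_longer("strands") |>
    rename(region_strand = "strands") |>
    mutate(paired = .data$strand_mode == "paired")

  expand |>
    select("gene_id", "anchor", "region_strand", "chrom",
           g_start = "pk_g_start", g_end = "pk_g_end", "span", "offset",
           "paired", "organ", "ago", "pathway", "suppressed_genotypes",
           "dsrna_covered", "methylated") |>
    arrange(.data$gene_id, .data$anchor, desc(.data$region_strand)) |>
    as_tibble()
}

# ---- read-count allocations ---------------------------------------------

# Pooled planted-peak read budgets and their per-organ splits, drawn once
# so every library sees the same allocation.
sim_allocations <- function(truth, cfg) {
  if (nrow(truth) == 0) {
    return(list(wt = tibble(), ago = tibble(), K = numeric(0)))
  }
  bg_density <- length(cfg$organs) * cfg$bg_reads_wt  # pooled, per region
  K <- pmax(1L, as.integer(round(
    (cfg$enrichment - 1) * bg_density / 1000 * truth$span
  )))

  organ_weights <- function(organ) {
    w <- rep((1 - cfg$organ_dominant_weight) / (length(cfg$organs) - 1),
             length(cfg$organs))
    names(w) <- cfg$organs
    if (organ == "none") {
      w[] <- 1 / length(cfg$organs)
    } else {
      w[organ] <- cfg$organ_dominant_weight
    }
    w
  }

  split_counts <- function(total, organ) {
    w <- organ_weights(organ)
    as.integer(rmultinom(1, total, w))
  }

  n_t <- nrow(truth)
  wt <- purrr::map2(K, truth$organ, split_counts)
  ago_pref <- purrr::map2(rep(cfg$ago_peak_reads, n_t),
                          truth$organ, split_counts)
  ago_other <- purrr::map2(
    rep(pmax(1L, round(cfg$ago_peak_reads / cfg$ago_fold)), n_t),
    truth$organ, split_counts
  )
  ago_even <- purrr::map2(rep(round(cfg$ago_peak_reads / 2), n_t),
                          truth$organ, split_counts)

  list(
    K = K,
    wt = wt,            # list: per truth row, counts per organ
    ago_pref = ago_pref,
    ago_other = ago_other,
    ago_even = ago_even
  )
}

sim_library_table <- function(cfg) {
  bind_rows(
    tibble(library_id = paste0("wt_", cfg$organs), role = "wt",
           organ_or_genotype = cfg$organs),
    tibble(library_id = paste0("ago1_", cfg$organs), role = "ago1",
           organ_or_genotype = cfg$organs),
    tibble(library_id = paste0("ago4_", cfg$organs), role = "ago4",
           organ_or_genotype = cfg$organs),
    tibble(library_id = paste0("mut_", cfg$mutant_panel), role = "mutant",
           organ_or_genotype = cfg$mutant_panel)
  ) |>
    mutate(file = file.path("libs", paste0(.data$library_id, ".fa")))
}

# Number of planted-peak reads this library contributes at truth row i.
peak_reads_for <- function(lib, truth_row, i, alloc, cfg) {
  role <- lib$role
  who <- lib$organ_or_genotype
  if (role == "wt") {
    return(alloc$wt[[i]][match(who, cfg$organs)])
  }
  if (role %in% c("ago1", "ago4")) {
    side <- toupper(role)
    counts <- if (truth_row$ago == "none") {
      alloc$ago_even[[i]]
    } else if (truth_row$ago == side) {
      alloc$ago_pref[[i]]
    } else {
      alloc$ago_other[[i]]
    }
    return(counts[match(who, cfg$organs)])
  }
  # mutant: matches the pooled wild-type budget unless suppressed
  suppressed <- strsplit(truth_row$suppressed_genotypes, ",")[[1]]
  k <- alloc$K[i]
  if (who %in% suppressed) {
    return(as.integer(round(cfg$suppression_factor * k)))
  }
  as.integer(k)
}

# All reads of one library, with their sampled positions retained:
# tibble(region_row, part, start, len, sequence).
sim_library_reads <- function(lib, regions, truth, alloc, pos_index, cfg) {
  bg_n <- if (lib$role == "wt") cfg$bg_reads_wt else cfg$bg_reads_other
  out <- vector("list", nrow(regions) + nrow(truth))
  for (r in seq_len(nrow(regions))) {
    out[[r]] <- sample_read_batch(
      regions$sequence[r], pos_index[[r]], 0L, regions$L[r], bg_n, cfg
    ) |>
      mutate(region_row = r, part = "bg")
  }
  if (nrow(truth) > 0) {
    tags <- region_tag(regions)
    truth_tags <- paste(truth$gene_id, truth$anchor, truth$region_strand,
                        sep = "|")
    reg_row <- match(truth_tags, tags)
    for (i in seq_len(nrow(truth))) {
      n <- peak_reads_for(lib, truth[i, ], i, alloc, cfg)
      r <- reg_row[i]
      L <- regions$L[r]
      # planted interval in this region's own coordinates
      a <- if (truth$region_strand[i] == "sense") {
        truth$offset[i]
      } else {
        L - (truth$offset[i] + truth$span[i])
      }
      out[[nrow(regions) + i]] <- sample_read_batch(
        regions$sequence[r], pos_index[[r]], a, a + truth$span[i], n, cfg
      ) |>
        mutate(region_row = r, part = "peak")
    }
  }
  bind_rows(out)
}

# Regions where pooled wild-type *background* alone would satisfy the
# published dual window criterion (A2 >= 10 * A1 and A2 >= 1 RPM/nt),
# judged at the planned RPM scale against the background-only A1.
background_offenders <- function(wt_reads, regions, cfg) {
  rpm <- 1e6 / cfg$library_size
  bg <- bind_rows(wt_reads) |> filter(.data$part == "bg")
  offenders <- integer(0)
  for (r in unique(bg$region_row)) {
    p <- bg[bg$region_row == r, ]
    L <- regions$L[r]
    w <- cumsum_window_max(p$start, p$start + p$len, rep(rpm, nrow(p)), L)
    A1 <- nrow(p) * rpm / L
    if (w / 50 >= max(10 * A1, 1)) offenders <- c(offenders, r)
  }
  offenders
}

# Maximum 50-nt window sum (overlap assignment) over a region.
cumsum_window_max <- function(starts, ends, w, L) {
  if (L < 50) return(0)
  n <- L - 50 + 1
  max(interval_coverage(starts - 49L, ends, w, n))
}

resample_background <- function(lib_reads, offender_rows, lib, regions,
                                pos_index, cfg) {
  bg_n <- if (lib$role == "wt") cfg$bg_reads_wt else cfg$bg_reads_other
  keep <- !(lib_reads$part == "bg" &
              lib_reads$region_row %in% offender_rows)
  fresh <- purrr::map(offender_rows, \(r) {
    sample_read_batch(regions$sequence[r], pos_index[[r]], 0L,
                      regions$L[r], bg_n, cfg) |>
      mutate(region_row = r, part = "bg")
  }) |> bind_rows()
  bind_rows(lib_reads[keep, ], fresh)
}

# ---- dsRNA, methylation -------------------------------------------------

sim_dsrna_reads <- function(regions, truth, cfg) {
  if (nrow(truth) == 0 || !any(truth$dsrna_covered)) {
    return(tibble(sequence = character(), count = integer()))
  }
  covered <- truth |>
    filter(.data$dsrna_covered) |>
    distinct(.data$gene_id, .data$anchor, .data$offset, .data$span)
  sense <- regions |> filter(.data$region_strand == "sense")
  tags <- paste(sense$gene_id, sense$anchor, sep = "|")
  reads <- purrr::pmap(covered, function(gene_id, anchor, offset, span) {
    r <- match(paste(gene_id, anchor, sep = "|"), tags)
    L <- sense$L[r]
    run_a <- max(0L, offset - cfg$dsrna_run_margin)
    run_b <- min(L, offset + span + cfg$dsrna_run_margin)
    while (run_b - run_a < cfg$min_dsrna_run) {
      if (run_b < L) run_b <- run_b + 1L else run_a <- run_a - 1L
    }
    starts <- unique(c(seq(run_a, run_b - cfg$dsrna_read_len,
                           by = cfg$dsrna_tile_step),
                       run_b - cfg$dsrna_read_len))
    tibble(sequence = substring(sense$sequence[r], starts + 1,
                                starts + cfg$dsrna_read_len))
  }) |> bind_rows()
  reads |> summarise(count = dplyr::n(), .by = "sequence")
}

sim_methylation <- function(layout, truth, cfg) {
  meth_peaks <- truth |>
    filter(.data$methylated) |>
    distinct(.data$chrom, .data$g_start, .data$g_end)
  planted <- purrr::pmap(meth_peaks, function(chrom, g_start, g_end) {
    pos <- sort(sample(seq(g_start, g_end - 1L),
                       min(cfg$meth_sites_per_peak, g_end - g_start)))
    tibble(chrom = chrom, pos = pos,
           level = round(runif(length(pos), cfg$meth_level_range[1],
                               cfg$meth_level_range[2]), 3))
  }) |> bind_rows()

  # background sites kept clear of every planted peak
  chrom_len <- Biostrings::width(layout$genome)
  names(chrom_len) <- names(layout$genome)
  bg <- tibble(
    chrom = sample(names(chrom_len), cfg$n_bg_meth_sites, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
  ) |>
    mutate(pos = purrr::map_int(.data$chrom, \(cn) {
      as.integer(sample(chrom_len[[cn]], 1)) - 1L
    }),
    level = round(runif(dplyr::n(), 0.2, 0.8), 3))
  if (nrow(truth) > 0 && nrow(bg) > 0) {
    near <- purrr::map_lgl(seq_len(nrow(bg)), \(i) {
      any(truth$chrom == bg$chrom[i] &
            bg$pos[i] >= truth$g_start - cfg$meth_clearance &
            bg$pos[i] < truth$g_end + cfg$meth_clearance)
    })
    bg <- bg[!near, , drop = FALSE]
  }
  bind_rows(planted, bg) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
}

# ---- file output ---------------------------------------------------------

write_collapsed_fasta <- function(reads, path, target_total, regions_cat) {
  total <- sum(reads$count)
  if (!is.null(target_total)) {
    if (total > target_total) {
      abort("Configured library size smaller than the structured reads.")
    }
    filler <- random_filler(regions_cat)
    reads <- bind_rows(reads,
                       tibble(sequence = filler,
                              count = as.integer(target_total - total)))
  }
  reads <- arrange(reads, .data$sequence)
  lines <- character(2 * nrow(reads))
  lines[c(TRUE, FALSE)] <- sprintf(">r%06d_%d", seq_len(nrow(reads)),
                                   reads$count)
  lines[c(FALSE, TRUE)] <- reads$sequence
  readr::write_lines(lines, path)
  invisible(path)
}

# A 35-nt sequence that does not occur in any boundary region (so filler
# reads count towards the library total but never map).
random_filler <- function(regions_cat) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE),
               collapse = "")
    if (!grepl(s, regions_cat, fixed = TRUE)) return(s)
  }
}

write_sim_files <- function(dir, layout, libs, reads_by_lib, dsrna_reads,
                            meth, truth, cfg) {
  paths <- list()

  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(layout$genome, paths$genome)

  paths$annotation <- file.path(dir, "annotation.gff3")
  write_sim_gff3(layout$genes, paths$annotation)

  regions_cat <- paste(layout$regions$sequence, collapse = "#")
  withr::with_seed(lib_seed(cfg$seed, 4L), {
    for (i in seq_along(reads_by_lib)) {
      collapsed <- reads_by_lib[[i]] |>
        summarise(count = dplyr::n(), .by = "sequence")
      write_collapsed_fasta(
        collapsed,
        file.path(dir, libs$file[i]),
        cfg$library_size, regions_cat
      )
    }
    write_collapsed_fasta(
      dsrna_reads, file.path(dir, "libs", "dsrna.fa"),
      cfg$dsrna_library_size, regions_cat
    )
  })

  manifest <- libs |>
    select("file", "library_id", "role", "organ_or_genotype") |>
    bind_rows(tibble(file = file.path("libs", "dsrna.fa"),
                     library_id = "dsrna", role = "dsrna",
                     organ_or_genotype = NA_character_))
  paths$manifest <- file.path(dir, "libraries.tsv")
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)

  paths$methylation <- file.path(dir, "methylation.bedgraph")
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%.3f", meth$chrom, meth$pos, meth$pos + 1L,
            meth$level),
    paths$methylation
  )

  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(select(truth, -"offset"), paths$truth, progress = FALSE)

  paths
}

write_sim_gff3 <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, chrom, strand, body_length,
                                      start, end, second_isoform, ...) {
    g <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 chrom, start, end, strand, gene_id)
    m1 <- sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                  chrom, start, end, strand, gene_id, gene_id)
    out <- c(g, m1)
    if (second_isoform && end - start > 60) {
      out <- c(out, sprintf(
        "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.2;Parent=%s",
        chrom, start + 20L, end - 20L, strand, gene_id, gene_id
      ))
    }
    out
  })
  readr::write_lines(c("##gff-version 3", unlist(rows)), path)
}

#' Evaluate pipeline calls against planted truth
#'
#' Matches screened peak calls to planted peaks (same gene, anchor and
#' region strand, with genomic overlap of at least `min_overlap_fraction`
#' of the planted span) and computes detection sensitivity and precision
#' plus per-label agreement for the AGO, organ, mutant-dependence and
#' methylation annotations.
#'
#' @param catalog Annotated peak catalog from [build_catalog()] (one row
#'   per screened peak; mutant-dependence columns named `dep_<genotype>`).
#' @param truth Truth table from [simulate_dataset()] (or read from its
#'   `truth.tsv`).
#' @param min_overlap_fraction Minimum overlap with the planted span for
#'   a call to match (default 0.5).
#' @return A tibble of metrics: `metric`, `value`, `n` (denominator).
#'   `precision` is `NA` when there are no screened calls.
#' @export
truth_evaluation <- function(catalog, truth, min_overlap_fraction = 0.5) {
  check_cols(catalog, c(region_keys, "g_start", "g_end"))
  check_cols(truth, c(region_keys, "g_start", "g_end", "span", "organ",
                      "ago", "suppressed_genotypes", "dsrna_covered",
                      "methylated"))

  truth <- mutate(truth, .truth_row = dplyr::row_number())
  calls <- mutate(catalog, .call_row = dplyr::row_number())

  matches <- inner_join(
    calls, truth, by = region_keys, suffix = c("_call", "_truth"),
    relationship = "many-to-many"
  ) |>
    mutate(overlap = pmin(.data$g_end_call, .data$g_end_truth) -
             pmax(.data$g_start_call, .data$g_start_truth)) |>
    filter(.data$overlap >= min_overlap_fraction * .data$span)

  sens <- n_distinct(matches$.truth_row) / max(nrow(truth), 1)
  prec <- if (nrow(calls) == 0) {
    NA_real_
  } else {
    n_distinct(matches$.call_row) / nrow(calls)
  }
  metrics <- tibble(
    metric = c("sensitivity", "precision"),
    value = c(sens, prec),
    n = c(nrow(truth), nrow(calls))
  )

  # one call per truth row (best overlap) for label agreement
  best <- matches |>
    slice_max(.data$overlap, n = 1, with_ties = FALSE, by = ".truth_row")
  if (nrow(best) > 0) {
    agree <- list()
    if ("ago_preference" %in% names(best)) {
      agree$ago_agreement <- mean(best$ago_preference == best$ago)
    }
    if ("organ_specific" %in% names(best)) {
      agree$organ_agreement <- mean(best$organ_specific == best$organ)
    }
    if ("methylation_overlap" %in% names(best)) {
      agree$methylation_agreement <-
        mean(best$methylation_overlap == best$methylated)
    }
    if ("dsrna_covered_call" %in% names(best)) {
      agree$dsrna_agreement <-
        mean(best$dsrna_covered_call == best$dsrna_covered_truth)
    }
    dep_cols <- grep("^dep_", names(best), value = TRUE)
    if (length(dep_cols) > 0) {
      genos <- sub("^dep_", "", dep_cols)
      expected <- purrr::map(best$suppressed_genotypes, \(s) {
        genos %in% strsplit(s %||% "", ",")[[1]]
      })
      observed <- purrr::map(seq_len(nrow(best)), \(i) {
        unlist(best[i, dep_cols]) == "repressed"
      })
      agree$mutant_agreement <- mean(unlist(purrr::map2(
        expected, observed, `==`
      )))
    }
    if (length(agree) > 0) {
      metrics <- bind_rows(metrics, tibble(
        metric = names(agree),
        value = unname(unlist(agree)),
        n = nrow(best)
      ))
    }
  }
  metrics
}
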