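# Synthetic-data generator: toy annotated genomes with a GC-rich, mostly
# coding composition, planted STR loci, and simulated MA lines evolved under
# known per-category mutation rates. Every other module is testable against
# the planted truth without external data.

#' Simulation configuration
#'
#' Defaults emulate the composition and design of a GC-rich, ~90%-coding
#' bacterial MA experiment: 46 lines at 1,855 generations each, a per-site
#' SNV rate of 5.52e-10, a non-STR indel rate of 1.5e-11 per site, an STR
#' slippage rate of 1.23e-8 per repeat unit, and 11 ancestral variants
#' shared by every line. The default genome length (200 kb) is a scaled-down
#' stand-in for a multi-megabase chromosome; all rates are per site or per
#' unit, so truth recovery does not depend on the length.
#'
#' @param genome_length genome size in bp
#' @param gc_fraction target G+C fraction
#' @param coding_fraction fraction of the genome covered by protein-coding
#'   genes
#' @param gene_length CDS length in bp (multiple of 3)
#' @param n_rna,n_pseudo numbers of RNA genes and pseudogenes
#' @param rna_length,pseudo_length their lengths in bp
#' @param n_str_loci number of planted STR loci
#' @param str_motifs character vector of motifs sampled for planted loci
#' @param n_lines number of MA lines
#' @param generations_per_line generations elapsed per line
#' @param snv_rate per-site per-generation SNV rate
#' @param indel_rate per-site per-generation non-STR indel rate
#' @param str_rate_per_unit per-unit per-generation STR slippage rate
#' @param spectrum_weights optional named weights over the six collapsed
#'   substitution classes; `NULL` means the composition null (every change
#'   at a site equally likely)
#' @param shared_ancestral_count ancestral variants planted into every line
#' @param seed integer seed making all outputs deterministic
#' @return a list of class `sim_config`
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_fraction = 0.69,
                       coding_fraction = 0.90,
                       gene_length = 900L,
                       n_rna = 2L, n_pseudo = 2L,
                       rna_length = 300L, pseudo_length = 300L,
                       n_str_loci = 30L,
                       str_motifs = c("A", "T", "G", "C", "ATG", "GCCGG",
                                      "CAGAGCCTCGAAATCA"),
                       n_lines = 46L,
                       generations_per_line = 1855,
                       snv_rate = 5.52e-10,
                       indel_rate = 1.5e-11,
                       str_rate_per_unit = 1.23e-8,
                       spectrum_weights = NULL,
                       shared_ancestral_count = 11L,
                       seed = 1L) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            coding_fraction >= 0,
            gene_length %% 3L == 0L,
            snv_rate >= 0, indel_rate >= 0, str_rate_per_unit >= 0)
  if (coding_fraction > 1) stop("coding_fraction > 1 is infeasible")
  if (!is.null(spectrum_weights)) {
    if (!all(.SPECTRUM_CLASSES %in% names(spectrum_weights)))
      stop("spectrum_weights must name all six classes")
    if (any(spectrum_weights < 0)) stop("negative spectrum weight")
  }
  structure(as.list(environment()), class = "sim_config")
}

# i.i.d. bases at a target GC fraction
random_bases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# a run of n/3 random codons free of stop codons, as a character vector
random_cds_chars <- function(n, gc) {
  stopifnot(n %% 3L == 0L)
  chars <- random_bases(n, gc)
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    starts <- seq.int(1L, n - 2L, by = 3L)
    cods <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- which(cods %in% stops)
    if (!length(bad)) break
    for (b in bad) {
      chars[(3L * b - 2L):(3L * b)] <- random_bases(3L, gc)
    }
  }
  chars
}

#' Generate a synthetic annotated genome with planted STR loci
#'
#' Lays out non-overlapping CDS (in frame, free of internal stops, strands
#' alternating), RNA genes and pseudogenes separated by intergenic gaps over
#' an i.i.d. background at the requested GC fraction, then overwrites
#' intergenic stretches with perfect tandem repeats at recorded coordinates
#' (flanking bases are adjusted so planted loci are maximal as planted).
#'
#' @param config a [sim_config()]
#' @param set_seed seed the RNG from `config$seed` (default `TRUE`)
#' @return list with `genome` (an [annotated_genome()]) and `str_loci`
#'   (planted-locus table in the [scan_str()] column layout)
#' @export
generate_genome <- function(config, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed && !is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  n_genes <- floor(L * config$coding_fraction / config$gene_length)
  feat_lens <- c(rep(config$gene_length, n_genes),
                 rep(config$rna_length, config$n_rna),
                 rep(config$pseudo_length, config$n_pseudo))
  feat_kind <- c(rep("CDS", n_genes),
                 rep("RNA", config$n_rna),
                 rep("pseudogene", config$n_pseudo))
  if (sum(feat_lens) > L)
    stop("features do not fit in the genome; reduce coding_fraction or counts")
  # interleave features with near-equal intergenic gaps
  ord <- sample(length(feat_lens))
  feat_lens <- feat_lens[ord]
  feat_kind <- feat_kind[ord]
  n_gaps <- length(feat_lens) + 1L
  gap_total <- L - sum(feat_lens)
  gap_lens <- rep(gap_total %/% n_gaps, n_gaps)
  gap_lens[n_gaps] <- gap_lens[n_gaps] + gap_total %% n_gaps
  chars <- character(L)
  features <- list()
  pos <- 1L
  for (i in seq_len(n_gaps)) {
    if (gap_lens[i] > 0L) {
      chars[pos:(pos + gap_lens[i] - 1L)] <-
        random_bases(gap_lens[i], config$gc_fraction)
      pos <- pos + gap_lens[i]
    }
    if (i > length(feat_lens)) break
    len <- feat_lens[i]
    kind <- feat_kind[i]
    strand <- if (i %% 2L) "+" else "-"
    seg <- if (kind == "CDS") {
      cc <- random_cds_chars(len, config$gc_fraction)
      if (strand == "-") rev(unname(.COMP[cc])) else cc
    } else random_bases(len, config$gc_fraction)
    chars[pos:(pos + len - 1L)] <- seg
    features[[length(features) + 1L]] <- data.frame(
      kind = kind, start = pos, end = pos + len - 1L, strand = strand,
      gene_id = sprintf("%s_%03d", tolower(kind), i),
      stringsAsFactors = FALSE)
    pos <- pos + len
  }
  features <- do.call(rbind, features)

  # plant STR loci inside intergenic gaps
  planted <- list()
  if (config$n_str_loci > 0L) {
    occupied <- features[, c("start", "end")]
    gaps <- gap_intervals(occupied, L)
    minu <- default_min_units()
    for (s in seq_len(config$n_str_loci)) {
      motif <- sample(config$str_motifs, 1L)
      k <- nchar(motif)
      min_u <- if (as.character(k) %in% names(minu))
        minu[[as.character(k)]] else 2L
      units <- min_u + sample.int(4L, 1L)
      total <- k * units
      fits <- which(gaps$end - gaps$start - 2L >= total)
      if (!length(fits)) next        # no intergenic room for this locus
      gi <- if (length(fits) == 1L) fits else sample(fits, 1L)
      g <- gaps[gi, ]
      start <- g$start + 1L +
        sample.int(g$end - g$start - total - 1L, 1L)
      # consume the used stretch so later loci cannot overwrite this one
      gaps <- rbind(gaps[-gi, , drop = FALSE],
                    data.frame(start = g$start, end = start - 2L),
                    data.frame(start = start + total + 1L, end = g$end))
      gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
      mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
      chars[start:(start + total - 1L)] <- rep_len(mchars, total)
      # flanks chosen so the locus cannot extend left or right
      chars[start - 1L] <- sample(setdiff(.BASES, mchars[k]), 1L)
      chars[start + total] <- sample(setdiff(.BASES, mchars[1L]), 1L)
      planted[[length(planted) + 1L]] <- data.frame(
        start = start, motif = canonical_rotation(motif),
        motif_length = k, unit_count = units, total_bp = total,
        stringsAsFactors = FALSE)
    }
  }
  str_loci <- if (length(planted)) do.call(rbind, planted) else
    data.frame(start = integer(), motif = character(),
               motif_length = integer(), unit_count = integer(),
               total_bp = integer())
  str_loci <- str_loci[order(str_loci$start), , drop = FALSE]
  rownames(str_loci) <- NULL
  class(str_loci) <- c("str_loci", "data.frame")
  genome <- annotated_genome(paste(chars, collapse = ""), features,
                             id = "synthetic_genome")
  list(genome = genome, str_loci = str_loci, config = config)
}

# complement of closed intervals within [1, L]
gap_intervals <- function(occupied, L) {
  occupied <- occupied[order(occupied$start), , drop = FALSE]
  starts <- c(1L, occupied$end + 1L)
  ends <- c(occupied$start - 1L, L)
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep])
}

# alt base for a reference base under a collapsed spectrum class
.ALT_OF <- local({
  m <- matrix(NA_character_, 4, 6, dimnames = list(.BASES,
    c("AT>TA", "AT>CG", "AT>GC", "GC>TA", "GC>AT", "GC>CG")))
  m["A", c("AT>TA", "AT>CG", "AT>GC")] <- c("T", "C", "G")
  m["T", c("AT>TA", "AT>CG", "AT>GC")] <- c("A", "G", "C")
  m["G", c("GC>TA", "GC>AT", "GC>CG")] <- c("T", "A", "C")
  m["C", c("GC>TA", "GC>AT", "GC>CG")] <- c("A", "T", "G")
  m
})

#' Simulate mutation accumulation across lines
#'
#' Per line, SNV and indel counts are Poisson with mean rate x target x
#' generations; SNVs land uniformly on the genome with the alternate base
#' drawn from the configured spectrum weights conditional on the reference
#' base; STR indels are single-unit gains or losses at the planted loci
#' (sampled proportional to unit count); non-STR indels are 1-3 bp events at
#' uniform positions. The configured number of shared ancestral variants is
#' injected into every line. Mutations are planted without selection (each
#' fixes), matching the MA design's neutral-accumulation assumption.
#'
#' @param sim result of [generate_genome()] (or a list with `genome`,
#'   `str_loci`, `config`)
#' @param set_seed seed the RNG from `config$seed + 1` (default `TRUE`)
#' @return list with `catalog` (a [mutation_catalog()], ancestral variants
#'   included) and `truth` (data frame of every planted event with its true
#'   class)
#' @export
simulate_ma_lines <- function(sim, set_seed = TRUE) {
  config <- sim$config
  genome <- sim$genome
  str_loci <- sim$str_loci
  if (set_seed && !is.null(config$seed)) set.seed(config$seed + 1L)
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  w <- config$spectrum_weights
  if (is.null(w)) {
    w <- stats::setNames(rep(1, 6), colnames(.ALT_OF))
  }
  line_ids <- sprintf("MA%02d", seq_len(config$n_lines))
  lines <- data.frame(line_id = line_ids,
                      generations = config$generations_per_line,
                      stringsAsFactors = FALSE)
  total_units <- sum(str_loci$unit_count)

  draw_snv <- function(n) {
    if (n == 0L) return(NULL)
    pos <- sample.int(L, n)
    ref <- chars[pos]
    cls <- vapply(ref, function(b) {
      ok <- !is.na(.ALT_OF[b, ])
      sample(colnames(.ALT_OF)[ok], 1L, prob = w[colnames(.ALT_OF)[ok]])
    }, character(1))
    alt <- .ALT_OF[cbind(ref, cls)]
    data.frame(position = pos, ref = ref, alt = alt, true_class = "SNV",
               true_spectrum = cls, stringsAsFactors = FALSE)
  }
  draw_nonstr_indel <- function(n) {
    if (n == 0L) return(NULL)
    out <- lapply(seq_len(n), function(i) {
      len <- sample.int(3L, 1L)
      ins <- stats::runif(1) < 0.5
      p <- sample.int(L - len - 1L, 1L)
      if (ins) {
        data.frame(position = p, ref = chars[p],
                   alt = paste0(chars[p],
                                paste(random_bases(len, config$gc_fraction),
                                      collapse = "")),
                   true_class = "indel_non_STR", true_spectrum = NA,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(position = p,
                   ref = paste(chars[p:(p + len)], collapse = ""),
                   alt = chars[p], true_class = "indel_non_STR",
                   true_spectrum = NA, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, out)
  }
  draw_str_indel <- function(n) {
    if (n == 0L || nrow(str_loci) == 0L) return(NULL)
    idx <- sample.int(nrow(str_loci), n, replace = TRUE,
                      prob = str_loci$unit_count)
    out <- lapply(idx, function(h) {
      k <- str_loci$motif_length[h]
      s <- str_loci$start[h]
      unit <- paste(chars[s:(s + k - 1L)], collapse = "")
      p <- s - 1L
      ins <- stats::runif(1) < 0.5 || str_loci$unit_count[h] < 2L
      if (ins) {
        data.frame(position = p, ref = chars[p],
                   alt = paste0(chars[p], unit), true_class = "indel_STR",
                   true_spectrum = NA, stringsAsFactors = FALSE)
      } else {
        data.frame(position = p,
                   ref = paste0(chars[p], unit), alt = chars[p],
                   true_class = "indel_STR", true_spectrum = NA,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, out)
  }

  # ancestral variants shared by every line
  anc <- draw_snv(config$shared_ancestral_count)
  if (!is.null(anc)) anc$true_class <- "ancestral"

  recs <- list()
  truth <- list()
  for (lid in line_ids) {
    Tg <- config$generations_per_line
    parts <- list(
      draw_snv(stats::rpois(1L, config$snv_rate * L * Tg)),
      draw_nonstr_indel(stats::rpois(1L, config$indel_rate * L * Tg)),
      draw_str_indel(stats::rpois(1L, config$str_rate_per_unit *
                                    total_units * Tg)),
      anc)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) next
    df <- do.call(rbind, parts)
    df$line_id <- lid
    truth[[lid]] <- df
    recs[[lid]] <- df[c("line_id", "position", "ref", "alt")]
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(line_id = character(), position = integer(),
               ref = character(), alt = character(),
               true_class = character(), true_spectrum = character())
  rownames(truth) <- NULL
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(line_id = character(), position = integer(),
               ref = character(), alt = character())
  catalog <- suppressWarnings(mutation_catalog(records, lines))
  list(catalog = catalog, truth = truth, config = config)
}

#' Write a simulated MA bundle to disk
#'
#' Emits FASTA + GFF3 for the genome, a BED-like table of planted STR loci,
#' a catalog TSV, a line-metadata TSV and a truth TSV into `dir`.
#'
#' @param sim result of [generate_genome()]
#' @param ma result of [simulate_ma_lines()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_ma_bundle <- function(sim, ma, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "genome.gff3"),
             str = file.path(dir, "str_loci.bed"),
             catalog = file.path(dir, "catalog.tsv"),
             lines = file.path(dir, "lines.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genome(sim$genome, fasta = paths[["fasta"]], gff3 = paths[["gff3"]])
  write_str_bed(sim$str_loci, paths[["str"]], chrom = sim$genome$id)
  utils::write.table(ma$catalog$records[c("line_id", "position", "ref", "alt")],
                     paths[["catalog"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ma$catalog$lines, paths[["lines"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ma$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
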