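# Annotated genome representation, region classification and mutational
# target-size accounting (synonymous/nonsynonymous site counting by codon
# degeneracy under the bacterial genetic code, table 11).

.mutacc <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N
#' @return reverse-complemented character scalar
#' @keywords internal
revcomp <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(.COMP[chars])), collapse = "")
}

# Per-codon degeneracy tables, computed once from the bacterial genetic code.
# For every codon and codon position, `syn_mask` holds a 3-bit mask over the
# three possible single-base changes (alt bases in A<C<G<T order, skipping the
# reference base): bit set iff the change is synonymous. Start codons are
# treated as ordinary codons.
codon_tables <- function() {
  if (!is.null(.mutacc$codon)) return(.mutacc$codon)
  gc11 <- Biostrings::getGeneticCode("11")
  codons <- names(gc11)
  syn_mask <- matrix(0L, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (ci in seq_along(codons)) {
    cod <- codons[ci]
    aa <- gc11[[cod]]
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      alts <- setdiff(.BASES, ref)
      bit <- 1L
      m <- 0L
      for (alt in alts) {
        mut <- cod
        substr(mut, p, p) <- alt
        if (gc11[[mut]] == aa) m <- m + bit
        bit <- bit * 2L
      }
      syn_mask[ci, p] <- m
    }
  }
  # popcount for 3-bit masks; bit-order reversal used to map a mask computed
  # in minus-strand codon space onto plus-strand alt ordering (complementation
  # reverses A<C<G<T).
  popcount3 <- vapply(0:7, function(m) {
    sum(bitwAnd(m, c(1L, 2L, 4L)) > 0L)
  }, integer(1))
  revbits3 <- vapply(0:7, function(m) {
    bitwAnd(m, 2L) +
      4L * (bitwAnd(m, 1L) > 0L) +
      1L * (bitwAnd(m, 4L) > 0L)
  }, integer(1))
  # four-fold degenerate codon prefixes: first two bases for which all four
  # third-position bases encode the same amino acid
  prefixes <- as.vector(outer(.BASES, .BASES, paste0))
  fourfold <- vapply(prefixes, function(pre) {
    aas <- gc11[paste0(pre, .BASES)]
    length(unique(aas)) == 1L
  }, logical(1))
  .mutacc$codon <- list(
    code = gc11, codons = codons, syn_mask = syn_mask,
    popcount3 = popcount3, revbits3 = revbits3,
    fourfold_prefix = names(fourfold)[fourfold]
  )
  .mutacc$codon
}

#' Construct an annotated genome
#'
#' Bundles a DNA sequence with typed features (CDS, RNA genes, pseudogenes).
#' Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param sequence character scalar over A/C/G/T/N (lower case is upcased)
#' @param features data frame with columns `kind` (one of `"CDS"`, `"RNA"`,
#'   `"pseudogene"`), `start`, `end` (1-based inclusive), `strand`
#'   (`"+"`/`"-"`), `gene_id`
#' @param id genome identifier
#' @return an object of class `annotated_genome`
#' @examples
#' g <- annotated_genome("ATGAAATTTTAA",
#'   features = data.frame(kind = "CDS", start = 1, end = 12,
#'                         strand = "+", gene_id = "g1"))
#' g$length
#' @export
annotated_genome <- function(sequence, features = NULL, id = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  L <- nchar(sequence)
  if (is.null(features)) {
    features <- data.frame(kind = character(), start = integer(),
                           end = integer(), strand = character(),
                           gene_id = character(), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("kind", "start", "end", "strand", "gene_id")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols))
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(features)) {
    if (!all(features$kind %in% c("CDS", "RNA", "pseudogene")))
      stop("feature kind must be CDS, RNA or pseudogene")
    if (any(features$start > features$end))
      stop("feature with start > end")
    if (any(features$start < 1L | features$end > L))
      stop("feature outside sequence bounds [1, ", L, "]")
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
  }
  structure(list(id = id, sequence = sequence, features = features,
                 length = L),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d features (%d CDS)\n",
              x$id, format(x$length, big.mark = ","), nrow(x$features),
              sum(x$features$kind == "CDS")))
  invisible(x)
}

#' Read a genome from FASTA (first record) plus a GFF3 annotation
#'
#' GFF3 feature types are mapped onto the three feature kinds used here:
#' `CDS` stays CDS; `rRNA`, `tRNA`, `ncRNA`, `tmRNA` and `RNase_P_RNA`
#' become RNA; `pseudogene` stays pseudogene. Other types are ignored.
#'
#' @param fasta path to a FASTA file (first record used)
#' @param gff3 optional path to a GFF3 file
#' @return an [annotated_genome()]
#' @export
read_genome <- function(fasta, gff3 = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta)
  id <- sub("\\s.*$", "", names(seqs)[1])
  features <- if (is.null(gff3)) NULL else read_gff3_features(gff3)
  annotated_genome(as.character(seqs[[1]]), features, id = id)
}

rna_types <- c("rRNA", "tRNA", "ncRNA", "tmRNA", "RNase_P_RNA", "SRP_RNA")

#' Read CDS/RNA/pseudogene features from a GFF3 file
#' @param path GFF3 file path
#' @return feature data frame suitable for [annotated_genome()]
#' @export
read_gff3_features <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 9L)
  if (length(bad))
    stop("malformed GFF3 row at line ", bad[1], " of ", path)
  m <- do.call(rbind, parts)
  type <- m[, 3]
  kind <- ifelse(type == "CDS", "CDS",
          ifelse(type %in% rna_types, "RNA",
          ifelse(type == "pseudogene", "pseudogene", NA)))
  keep <- !is.na(kind)
  attr_id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", m[, 9])
  no_id <- !grepl("ID=", m[, 9])
  attr_id[no_id] <- paste0("feature_", seq_len(nrow(m))[no_id])
  data.frame(kind = kind[keep],
             start = as.integer(m[keep, 4]),
             end = as.integer(m[keep, 5]),
             strand = m[keep, 7],
             gene_id = attr_id[keep],
             stringsAsFactors = FALSE)
}

#' Write an annotated genome to FASTA and GFF3
#' @param genome an [annotated_genome()]
#' @param fasta,gff3 output paths (either may be `NULL` to skip)
#' @return invisibly, the genome
#' @export
write_genome <- function(genome, fasta = NULL, gff3 = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(genome$sequence)
    names(ss) <- genome$id
    Biostrings::writeXStringSet(ss, fasta, width = 70)
  }
  if (!is.null(gff3)) {
    f <- genome$features
    type <- c(CDS = "CDS", RNA = "ncRNA", pseudogene = "pseudogene")[f$kind]
    rows <- sprintf("%s\tmutacc\t%s\t%d\t%d\t.\t%s\t%s\tID=%s",
                    genome$id, type, f$start, f$end, f$strand,
                    ifelse(f$kind == "CDS", "0", "."), f$gene_id)
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", genome$id, genome$length),
                 rows), gff3)
  }
  invisible(genome)
}

.REGION_LEVELS <- c("protein_coding", "rna_coding", "pseudogenic", "intergenic")

#' Classify every genomic site into a region category
#'
#' Each site gets exactly one label among protein-coding, RNA-coding,
#' pseudogenic and intergenic, using the precedence
#' protein_coding > rna_coding > pseudogenic > intergenic so that labels form
#' a partition even where features overlap (overlapping ORFs are common in
#' bacteria; a site in two CDS is protein-coding once).
#'
#' @param genome an [annotated_genome()]
#' @return object of class `region_classification`: integer-coded label vector
#'   (`labels`, a factor of length `genome$length`) plus per-label `counts`
#' @export
classify_sites <- function(genome) {
  L <- genome$length
  lab <- rep.int(4L, L)  # intergenic
  f <- genome$features
  assign_kind <- function(lab, kind, code) {
    rows <- which(f$kind == kind)
    for (i in rows) {
      idx <- f$start[i]:f$end[i]
      lab[idx] <- pmin(lab[idx], code)
    }
    lab
  }
  # ascending precedence: paint low-precedence first, then overwrite
  lab <- assign_kind(lab, "pseudogene", 3L)
  lab <- assign_kind(lab, "RNA", 2L)
  lab <- assign_kind(lab, "CDS", 1L)
  labels <- factor(.REGION_LEVELS[lab], levels = .REGION_LEVELS)
  counts <- table(labels)
  stopifnot(sum(counts) == L)
  structure(list(labels = labels, counts = as.integer(counts),
                 levels = .REGION_LEVELS),
            class = "region_classification")
}

#' @export
print.region_classification <- function(x, ...) {
  cat("<region_classification>\n")
  print(stats::setNames(x$counts, x$levels))
  invisible(x)
}

#' Compute mutational target sizes
#'
#' For every protein-coding site the three possible single-base changes are
#' classified as synonymous or nonsynonymous (nonsense counts as
#' nonsynonymous) by translating in the gene's frame under genetic code 11;
#' the site contributes the synonymous fraction of its three changes to the
#' synonymous target and the rest to the nonsynonymous target, so the two
#' targets sum to the protein-coding site count. Sites inside overlapping CDS
#' are counted once with the most constrained assignment: a change is
#' synonymous only if it is synonymous in every overlapping reading frame.
#' Sites containing `N` are excluded from all targets (they mirror positions
#' without read coverage). CDS of length not divisible by three, or
#' containing an internal stop, are skipped with a warning.
#'
#' @param genome an [annotated_genome()]
#' @param classification result of [classify_sites()]; computed if missing
#' @param str_loci optional STR locus table from [scan_str()]; fills the STR
#'   unit/bp targets
#' @return object of class `target_sizes` with fields `total_sites`,
#'   `nonsynonymous_sites`, `synonymous_sites`, `intergenic_sites`,
#'   `pseudogenic_sites`, `rna_sites`, `str_units`, `str_bp`, plus the
#'   per-site synonymous-change bitmask (`syn_mask`) reused by
#'   [annotate_mutations()]
#' @export
compute_targets <- function(genome, classification = NULL, str_loci = NULL) {
  if (is.null(classification)) classification <- classify_sites(genome)
  ct <- codon_tables()
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  is_n <- chars == "N"
  syn_mask <- rep.int(NA_integer_, L)

  cds <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    s <- cds$start[i]; e <- cds$end[i]
    len <- e - s + 1L
    if (len %% 3L != 0L) {
      warning("CDS ", cds$gene_id[i], " length not divisible by 3; skipped")
      next
    }
    cds_seq <- substr(genome$sequence, s, e)
    if (cds$strand[i] == "-") cds_seq <- revcomp(cds_seq)
    n_cod <- len %/% 3L
    cods <- substring(cds_seq, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    cod_idx <- match(cods, ct$codons)        # NA for codons containing N
    aa <- ct$code[cods]
    if (any(aa[-n_cod] == "*", na.rm = TRUE)) {
      warning("CDS ", cds$gene_id[i], " has an internal stop codon; skipped")
      next
    }
    # per-CDS-position mask (codon-space), then map to genome orientation
    m <- ct$syn_mask[cbind(rep(cod_idx, each = 3L), rep_len(1:3, len))]
    if (cds$strand[i] == "+") {
      gpos <- s:e
    } else {
      gpos <- e:s
      m <- ifelse(is.na(m), NA_integer_, ct$revbits3[m + 1L])
    }
    old <- syn_mask[gpos]
    syn_mask[gpos] <- ifelse(is.na(old), m,
                      ifelse(is.na(m), old, bitwAnd(old, m)))
  }

  lab <- as.integer(classification$labels)
  ok <- !is_n
  coding_ok <- ok & lab == 1L & !is.na(syn_mask)
  syn_sites <- sum(ct$popcount3[syn_mask[coding_ok] + 1L]) / 3
  ns_sites <- sum(coding_ok) - syn_sites

  res <- structure(list(
    total_sites = sum(ok),
    nonsynonymous_sites = ns_sites,
    synonymous_sites = syn_sites,
    intergenic_sites = sum(ok & lab == 4L),
    pseudogenic_sites = sum(ok & lab == 3L),
    rna_sites = sum(ok & lab == 2L),
    str_units = NA_integer_,
    str_bp = NA_integer_,
    syn_mask = syn_mask,
    n_excluded = sum(is_n)
  ), class = "target_sizes")
  if (!is.null(str_loci)) {
    st <- str_target(str_loci)
    res$str_units <- st[["str_units"]]
    res$str_bp <- st[["str_bp"]]
  }
  res
}

#' @export
print.target_sizes <- function(x, ...) {
  cat("<target_sizes>\n")
  flds <- c("total_sites", "nonsynonymous_sites", "synonymous_sites",
            "intergenic_sites", "pseudogenic_sites", "rna_sites",
            "str_units", "str_bp")
  for (f in flds) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Export target sizes as a one-row data frame (TSV-friendly)
#' @param x a `target_sizes` object
#' @return data frame of the scalar target fields
#' @export
targets_as_data_frame <- function(x) {
  stopifnot(inherits(x, "target_sizes"))
  data.frame(total_sites = x$total_sites,
             nonsynonymous_sites = x$nonsynonymous_sites,
             synonymous_sites = x$synonymous_sites,
             intergenic_sites = x$intergenic_sites,
             pseudogenic_sites = x$pseudogenic_sites,
             rna_sites = x$rna_sites,
             str_units = x$str_units,
             str_bp = x$str_bp)
}

#' Extract four-fold degenerate alignment columns
#'
#' Scans a codon alignment (length divisible by 3, frame starting at column
#' 1) and returns the third-codon-position columns at which, given the first
#' two bases of the reference row's codon, all four third-position bases
#' encode the same amino acid. Codons with a gap or ambiguous base in the
#' reference row are excluded.
#'
#' @param alignment character vector of aligned sequences (equal lengths),
#'   or a `DNAStringSet`
#' @param ref index of the reference row used for codon context (default 1)
#' @return integer vector of four-fold degenerate column positions
#' @export
extract_fourfold_sites <- function(alignment, ref = 1L) {
  aln <- as_alignment_chars(alignment)
  L <- ncol(aln)
  if (L %% 3L != 0L)
    stop("alignment length ", L, " is not divisible by 3 (frame mismatch)")
  ct <- codon_tables()
  n_cod <- L %/% 3L
  p1 <- aln[ref, 3L * seq_len(n_cod) - 2L]
  p2 <- aln[ref, 3L * seq_len(n_cod) - 1L]
  p3 <- aln[ref, 3L * seq_len(n_cod)]
  valid <- p1 %in% .BASES & p2 %in% .BASES & p3 %in% .BASES
  pre <- paste0(p1, p2)
  sel <- valid & pre %in% ct$fourfold_prefix
  (3L * seq_len(n_cod))[sel]
}

# normalize alignment input to a character matrix (rows = sequences)
as_alignment_chars <- function(alignment) {
  if (inherits(alignment, "DNAStringSet"))
    alignment <- as.character(alignment)
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal lengths")
  do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
}
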