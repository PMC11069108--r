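# Exhaustive perfect short-tandem-repeat (microsatellite) scanner.
# STR mutational targets are counted in repeat units rather than base pairs,
# because slippage events add or remove whole motif units.

#' Default minimum unit counts per motif length
#'
#' Mononucleotide runs need at least 6 units, trinucleotide 4, pentanucleotide
#' 2 and 16-mer motifs 1 additional copy beyond the first (i.e. at least two
#' tandem copies; a single occurrence of a 16-mer is not a repeat).
#' @return named integer vector, names are motif lengths
#' @export
default_min_units <- function() c(`1` = 6L, `3` = 4L, `5` = 2L, `16` = 2L)

# is the motif primitive, i.e. not itself a tandem repeat of a shorter motif?
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  divs <- which(k %% seq_len(k - 1L) == 0L)
  for (d in divs) {
    if (paste(rep(substr(motif, 1L, d), k / d), collapse = "") == motif)
      return(FALSE)
  }
  TRUE
}

# lexicographically least rotation of a motif (canonical forward-strand form)
canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rots <- vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L))
  }, character(1))
  min(rots)
}

#' Scan a genome for perfect short tandem repeats
#'
#' Finds all maximal runs of a perfectly repeated primitive motif on the
#' forward strand, for each motif length in `names(min_units)`, keeping loci
#' with at least the configured number of whole units. Loci of different
#' motif lengths may overlap and are all reported; maximal runs of the same
#' motif length are disjoint by construction, and loci are reported in
#' leftmost-start order. An optional motif whitelist restricts the scan to
#' observed motif classes (canonical rotations are compared), matching
#' target-size accounting that is conditioned on the motifs seen to mutate.
#'
#' @param genome an [annotated_genome()] or a plain DNA string
#' @param min_units named integer vector mapping motif length to the minimum
#'   unit count (default [default_min_units()])
#' @param motif_whitelist optional character vector of motifs; only loci
#'   whose canonical motif rotation matches a whitelisted motif's canonical
#'   rotation are kept
#' @return data frame of class `str_loci` with columns `start` (1-based),
#'   `motif` (canonical rotation), `motif_length`, `unit_count`,
#'   `total_bp` (= motif_length * unit_count)
#' @examples
#' scan_str("GGAAAAAACC")            # one 6-unit A run
#' scan_str("ATGATGATGATG")          # one 4-unit ATG repeat
#' @export
scan_str <- function(genome, min_units = default_min_units(),
                     motif_whitelist = NULL) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence
         else toupper(genome)
  L <- nchar(seq)
  out <- list()
  chars <- if (L) strsplit(seq, "", fixed = TRUE)[[1]] else character()
  wl <- if (is.null(motif_whitelist)) NULL
        else unique(vapply(toupper(motif_whitelist), canonical_rotation,
                           character(1)))
  for (k in as.integer(names(min_units))) {
    minu <- min_units[[as.character(k)]]
    if (L < 2L * k) next
    eq <- chars[seq_len(L - k)] == chars[(k + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      i <- starts[j]                     # region: [i, ends[j] + k]
      region_len <- r$lengths[j] + k
      units <- region_len %/% k
      if (units < minu) next
      motif <- substr(seq, i, i + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next
      canon <- canonical_rotation(motif)
      if (!is.null(wl) && !(canon %in% wl)) next
      out[[length(out) + 1L]] <- data.frame(
        start = i, motif = canon, motif_length = k,
        unit_count = units, total_bp = k * units,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), motif = character(),
               motif_length = integer(), unit_count = integer(),
               total_bp = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$motif_length), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("str_loci", "data.frame")
  res
}

#' STR mutational target in repeat units and base pairs
#'
#' Sums unit counts across loci: each unit is one opportunity for a
#' single-unit slippage gain or loss, so the unit total is the STR target
#' size used in rate estimation.
#'
#' @param loci result of [scan_str()]
#' @return named numeric vector with `str_units` and `str_bp`
#' @export
str_target <- function(loci) {
  c(str_units = sum(loci$unit_count), str_bp = sum(loci$total_bp))
}

#' Write STR loci as BED-like TSV (0-based half-open coordinates)
#' @param loci result of [scan_str()]
#' @param path output file
#' @param chrom chromosome name for the first column
#' @return invisibly, the path
#' @export
write_str_bed <- function(loci, path, chrom = "genome") {
  df <- data.frame(chrom = chrom, start0 = loci$start - 1L,
                   end0 = loci$start - 1L + loci$total_bp,
                   motif = loci$motif, unit_count = loci$unit_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
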