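# Mutation catalog: per-line called mutations, shared-ancestral subtraction,
# and effect/spectrum annotation against an annotated genome.

.SPECTRUM_CLASSES <- c("AT>TA", "AT>CG", "AT>GC", "GC>TA", "GC>AT", "GC>CG")

#' Construct a mutation catalog
#'
#' @param records data frame with columns `line_id`, `position` (1-based),
#'   `ref`, `alt` (allele strings, VCF-style anchored for indels)
#' @param lines data frame with columns `line_id`, `generations`; defaults to
#'   the line ids present in `records` with `NA` generations
#' @return object of class `mutation_catalog`
#' @export
mutation_catalog <- function(records, lines = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("line_id", "position", "ref", "alt")
  if (length(setdiff(req, names(records))))
    stop("records needs columns: ", paste(req, collapse = ", "))
  records$ref <- toupper(records$ref)
  records$alt <- toupper(records$alt)
  if (nrow(records) && any(!nzchar(records$ref) | !nzchar(records$alt)))
    stop("empty ref or alt allele")
  records$mtype <- with(records, ifelse(
    nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNV",
    ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")))
  records$indel_len <- abs(nchar(records$alt) - nchar(records$ref))
  if (is.null(lines)) {
    ids <- unique(records$line_id)
    lines <- data.frame(line_id = ids,
                        generations = rep(NA_real_, length(ids)),
                        stringsAsFactors = FALSE)
  }
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  if (!all(records$line_id %in% lines$line_id))
    stop("records reference line ids missing from the line table")
  # collapse duplicate calls (same line, position, alleles)
  key <- with(records, paste(line_id, position, ref, alt))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate call(s) collapsed")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  records <- records[order(records$line_id, records$position), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, lines = lines),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog> %d mutations across %d lines (%d SNV, %d indel)\n",
              nrow(x$records), nrow(x$lines),
              sum(x$records$mtype == "SNV"),
              sum(x$records$mtype != "SNV")))
  invisible(x)
}

#' Total generations across all lines
#' @param catalog a [mutation_catalog()]
#' @return numeric scalar, the sum of per-line generation counts
#' @export
total_generations <- function(catalog) sum(catalog$lines$generations)

#' Read mutation calls from per-line TSV and/or minimal VCF files
#'
#' TSV files need columns `line_id`, `position`, `ref`, `alt` (a single TSV
#' may carry many lines). VCF files (one per MA line, uncompressed, minimal
#' 4.2 subset: CHROM/POS/ID/REF/ALT columns) take the line id from the file
#' name (basename without extension) unless given in `vcf_line_ids`.
#'
#' @param files character vector of file paths; format guessed from the
#'   extension (`.vcf` vs anything else = TSV)
#' @param lines optional line metadata data frame (`line_id`, `generations`)
#' @param vcf_line_ids optional named character vector mapping file path to
#'   line id
#' @return a [mutation_catalog()]
#' @export
read_mutations <- function(files, lines = NULL, vcf_line_ids = NULL) {
  recs <- list()
  for (f in files) {
    if (grepl("\\.vcf$", f, ignore.case = TRUE)) {
      lid <- if (!is.null(vcf_line_ids) && f %in% names(vcf_line_ids))
        vcf_line_ids[[f]] else sub("\\.vcf$", "", basename(f),
                                   ignore.case = TRUE)
      recs[[f]] <- read_vcf_minimal(f, lid)
    } else {
      df <- utils::read.delim(f, stringsAsFactors = FALSE)
      need <- c("line_id", "position", "ref", "alt")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("TSV ", f, " is missing columns: ", paste(miss, collapse = ", "))
      if (any(is.na(df$position)))
        stop("TSV ", f, ": non-numeric position at row ",
             which(is.na(df$position))[1])
      recs[[f]] <- df[need]
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(line_id = character(), position = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  mutation_catalog(records, lines)
}

# minimal VCF 4.2 reader: fixed columns only, one sample file per MA line
read_vcf_minimal <- function(path, line_id) {
  txt <- readLines(path)
  body <- txt[!startsWith(txt, "#") & nzchar(txt)]
  if (!length(body))
    return(data.frame(line_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 5L)
  if (length(bad))
    stop("malformed VCF row in ", path, " at data line ", bad[1])
  m <- do.call(rbind, parts)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (any(is.na(pos)))
    stop("non-integer POS in ", path, " at data line ", which(is.na(pos))[1])
  # multi-allelic rows are split on the ALT comma
  alts <- strsplit(m[, 5], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  data.frame(line_id = line_id,
             position = rep(pos, n_alt),
             ref = rep(m[, 4], n_alt),
             alt = unlist(alts),
             stringsAsFactors = FALSE)
}

#' Write a mutation catalog as TSV
#' @param catalog a [mutation_catalog()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_catalog_tsv <- function(catalog, path) {
  cols <- intersect(c("line_id", "position", "ref", "alt", "mtype", "region",
                      "effect", "spectrum_class", "ts_tv", "toward",
                      "indel_class", "indel_len"), names(catalog$records))
  utils::write.table(catalog$records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove mutations shared across (nearly) all lines
#'
#' Variants present at the same position with the same alleles in at least
#' `min_lines` lines are taken to be ancestral — carried by the experiment's
#' founder rather than arising de novo — and are removed from every line.
#'
#' @param catalog a [mutation_catalog()]
#' @param min_lines minimum number of carrier lines for removal; defaults to
#'   all registered lines (universally shared)
#' @return list with `catalog` (cleaned) and `removed` (data frame of the
#'   distinct removed variants with their carrier counts)
#' @export
subtract_shared <- function(catalog, min_lines = nrow(catalog$lines)) {
  stopifnot(nrow(catalog$lines) >= 2L)
  r <- catalog$records
  key <- paste(r$position, r$ref, r$alt)
  carriers <- tapply(r$line_id, key, function(x) length(unique(x)))
  shared_keys <- names(carriers)[carriers >= min_lines]
  drop <- key %in% shared_keys
  removed <- unique(r[drop, c("position", "ref", "alt"), drop = FALSE])
  if (nrow(removed)) {
    removed$n_lines <- as.integer(carriers[paste(removed$position,
                                                 removed$ref, removed$alt)])
    removed <- removed[order(removed$position), , drop = FALSE]
    rownames(removed) <- NULL
  } else {
    removed$n_lines <- integer()
  }
  out <- catalog
  out$records <- r[!drop, , drop = FALSE]
  rownames(out$records) <- NULL
  list(catalog = out, removed = removed)
}

# collapse a single-base substitution onto the six strand-symmetric classes
spectrum_class_of <- function(ref, alt) {
  canon_ref <- ifelse(ref %in% c("T", "C"), unname(.COMP[ref]), ref)
  canon_alt <- ifelse(ref %in% c("T", "C"), unname(.COMP[alt]), alt)
  from <- ifelse(canon_ref == "A", "AT", "GC")
  to <- c(A = "AT", C = "CG", G = "GC", T = "TA")[canon_alt]
  paste0(from, ">", unname(to))
}

#' Annotate a mutation catalog against an annotated genome
#'
#' Fills, per record: the region label; for SNVs the coding effect
#' (synonymous vs nonsynonymous, where a change nonsynonymous in any
#' overlapping reading frame is nonsynonymous and nonsense is folded into
#' nonsynonymous), the collapsed six-class spectrum label, transition vs
#' transversion, and the A/T-vs-G/C direction; for indels whether the event
#' is a single-unit STR slippage (the indel length equals one motif unit of
#' a covering STR locus and the inserted/deleted sequence is a rotation of
#' that motif).
#'
#' @param catalog a [mutation_catalog()]
#' @param genome an [annotated_genome()]
#' @param classification result of [classify_sites()]; computed if missing
#' @param targets result of [compute_targets()] (supplies the per-site
#'   synonymous-change mask); computed if missing
#' @param str_loci result of [scan_str()]; scanned with defaults if missing
#' @return the catalog with annotation columns filled
#' @export
annotate_mutations <- function(catalog, genome, classification = NULL,
                               targets = NULL, str_loci = NULL) {
  if (is.null(classification)) classification <- classify_sites(genome)
  if (is.null(targets)) targets <- compute_targets(genome, classification)
  if (is.null(str_loci)) str_loci <- scan_str(genome)
  ct <- codon_tables()
  r <- catalog$records
  if (nrow(r) == 0L) {
    for (col in c("region", "effect", "spectrum_class", "ts_tv", "toward",
                  "indel_class"))
      r[[col]] <- character()
    out <- catalog; out$records <- r
    return(out)
  }
  if (any(r$position < 1L | r$position > genome$length))
    stop("mutation position outside genome")
  # reference allele must match the genome sequence
  gref <- substring(genome$sequence, r$position,
                    r$position + nchar(r$ref) - 1L)
  bad <- which(gref != r$ref)
  if (length(bad))
    stop("ref allele disagrees with genome at position(s): ",
         paste(utils::head(r$position[bad], 5L), collapse = ", "))

  r$region <- as.character(classification$labels[r$position])
  is_snv <- r$mtype == "SNV"

  # SNV effect
  r$effect <- NA_character_
  r$effect[is_snv] <- c(protein_coding = NA, rna_coding = "rna_coding",
                        pseudogenic = "pseudogenic",
                        intergenic = "intergenic")[r$region[is_snv]]
  pc <- which(is_snv & r$region == "protein_coding")
  if (length(pc)) {
    mask <- targets$syn_mask[r$position[pc]]
    # bit index of the alt base among A<C<G<T minus ref
    bit <- mapply(function(ref, alt) {
      alts <- setdiff(.BASES, ref)
      2L^(match(alt, alts) - 1L)
    }, r$ref[pc], r$alt[pc])
    syn <- !is.na(mask) & bitwAnd(mask, bit) > 0L
    r$effect[pc] <- ifelse(syn, "synonymous", "nonsynonymous")
  }

  # spectrum class, ts/tv, direction
  r$spectrum_class <- NA_character_
  r$spectrum_class[is_snv] <- spectrum_class_of(r$ref[is_snv], r$alt[is_snv])
  r$ts_tv <- NA_character_
  pur <- c("A", "G")
  r$ts_tv[is_snv] <- ifelse((r$ref[is_snv] %in% pur) ==
                              (r$alt[is_snv] %in% pur),
                            "transition", "transversion")
  r$toward <- NA_character_
  r$toward[is_snv] <- ifelse(r$alt[is_snv] %in% c("A", "T"), "AT", "GC")

  # indel STR classification: the event must leave the covering locus a
  # perfect repeat of one unit more or fewer (whole-unit, phase-respecting
  # slippage), not merely insert some rotation of the motif
  r$indel_class <- NA_character_
  ind <- which(!is_snv)
  if (length(ind) && nrow(str_loci)) {
    locus_end <- str_loci$start + str_loci$total_bp - 1L
    is_periodic <- function(x, k) {
      n <- nchar(x)
      if (n <= k) return(n == k)
      ch <- strsplit(x, "", fixed = TRUE)[[1]]
      all(ch[seq_len(n - k)] == ch[(k + 1L):n])
    }
    r$indel_class[ind] <- vapply(ind, function(i) {
      len <- r$indel_len[i]
      insertion <- nchar(r$alt[i]) > nchar(r$ref[i])
      changed <- if (insertion)
        substr(r$alt[i], nchar(r$ref[i]) + 1L, nchar(r$alt[i]))
      else substr(r$ref[i], nchar(r$alt[i]) + 1L, nchar(r$ref[i]))
      pos <- r$position[i]   # anchor: edit applies after this base
      hit <- which(str_loci$motif_length == len &
                     str_loci$start <= pos + 1L & locus_end >= pos)
      for (h in hit) {
        st <- str_loci$start[h]
        en <- locus_end[h]
        k <- str_loci$motif_length[h]
        w <- substr(genome$sequence, st, en)
        w2 <- if (insertion) {
          if (pos < st - 1L || pos > en) next
          off <- pos - st + 1L
          paste0(substr(w, 1L, off), changed, substr(w, off + 1L, nchar(w)))
        } else {
          if (pos + 1L < st || pos + len > en) next
          off <- pos - st + 1L
          paste0(substr(w, 1L, off), substr(w, off + len + 1L, nchar(w)))
        }
        if (nchar(w2) %% k == 0L && is_periodic(w2, k))
          return("STR")
      }
      "non_STR"
    }, character(1))
  } else if (length(ind)) {
    r$indel_class[ind] <- "non_STR"
  }

  out <- catalog
  out$records <- r
  out
}

#' Tabulate a catalog along one annotation axis
#' @param catalog an annotated [mutation_catalog()]
#' @param by column of the record table to tabulate (e.g. `"spectrum_class"`)
#' @param snv_only restrict to SNVs first (default `TRUE` for SNV-specific axes)
#' @return named integer vector of counts
#' @export
catalog_counts <- function(catalog, by, snv_only = by %in%
                             c("spectrum_class", "ts_tv", "toward", "effect")) {
  r <- catalog$records
  if (snv_only) r <- r[r$mtype == "SNV", , drop = FALSE]
  tab <- table(r[[by]])
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-line mutation totals (zeros included for mutation-free lines)
#' @param catalog a [mutation_catalog()]
#' @return named integer vector over all registered lines
#' @export
per_line_totals <- function(catalog) {
  tab <- table(factor(catalog$records$line_id,
                      levels = catalog$lines$line_id))
  stats::setNames(as.integer(tab), names(tab))
}
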