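# Independent brute-force oracles and small fixture builders. These
# re-derive expected values by direct enumeration, never through the
# package's own code paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random in-frame CDS with no stop codons, as a string
random_cds <- function(n_codons, gc = 0.5) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- random_dna(3, gc)
      if (!(cod %in% stops)) break
    }
    cods[i] <- cod
  }
  paste(cods, collapse = "")
}

# exhaustive synonymous/nonsynonymous site counting for one in-frame CDS:
# enumerate all 9 single-base changes per codon under genetic code 11
oracle_cds_targets <- function(cds) {
  code <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  s <- 0
  ns <- 0
  for (i in seq(1, nchar(cds), by = 3)) {
    cod <- substr(cds, i, i + 2)
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      for (alt in setdiff(bases, ref)) {
        mut <- cod
        substr(mut, p, p) <- alt
        if (code[[mut]] == code[[cod]]) s <- s + 1 / 3 else ns <- ns + 1 / 3
      }
    }
  }
  c(S = s, NS = ns)
}

# exhaustive per-codon four-fold degeneracy decision
oracle_fourfold_cols <- function(ref_seq) {
  code <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  out <- integer()
  for (i in seq(1, nchar(ref_seq), by = 3)) {
    pre <- substr(ref_seq, i, i + 1)
    if (grepl("[^ACGT]", substr(ref_seq, i, i + 2))) next
    aas <- vapply(bases, function(b) code[[paste0(pre, b)]], character(1))
    if (length(unique(aas)) == 1L) out <- c(out, i + 2L)
  }
  out
}

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k / d) == motif) return(FALSE)
  }
  TRUE
}

oracle_canonical <- function(motif) {
  k <- nchar(motif)
  min(vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L))
  }, character(1)))
}

# brute-force STR finder: tests every (start, motif_length) pair for a
# left-maximal perfect period-k region, keeps primitive motifs meeting the
# unit threshold
oracle_scan_str <- function(seq, min_units = default_min_units()) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in as.integer(names(min_units))) {
    minu <- min_units[[as.character(k)]]
    for (i in seq_len(max(0L, L - k))) {
      if (i > 1L && ch[i - 1L] == ch[i - 1L + k]) next   # extendable left
      if (ch[i] != ch[i + k]) next                        # no repetition
      j <- i + k
      while (j < L && ch[j + 1L] == ch[j + 1L - k]) j <- j + 1L
      region_len <- j - i + 1L
      units <- region_len %/% k
      motif <- substr(seq, i, i + k - 1L)
      if (units < minu) next
      if (grepl("N", motif, fixed = TRUE)) next
      if (!oracle_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, motif = oracle_canonical(motif), motif_length = k,
        unit_count = units, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), motif = character(),
                      motif_length = integer(), unit_count = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive O(n^2 L) pairwise-difference loop
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% c("A", "C", "G", "T") &
        m[j, ] %in% c("A", "C", "G", "T")
      if (!any(ok)) next
      vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  }
  mean(vals)
}

# small annotated genome with explicit CDS strings placed at known spots
build_genome_with_cds <- function(cds_list, strands = NULL, gap = 20,
                                  gc = 0.5) {
  if (is.null(strands)) strands <- rep("+", length(cds_list))
  chars <- random_dna(gap, gc)
  feats <- list()
  for (i in seq_along(cds_list)) {
    cds <- cds_list[[i]]
    placed <- if (strands[i] == "-") mutacc:::revcomp(cds) else cds
    start <- nchar(chars) + 1L
    chars <- paste0(chars, placed, random_dna(gap, gc))
    feats[[i]] <- data.frame(kind = "CDS", start = start,
                             end = start + nchar(cds) - 1L,
                             strand = strands[i],
                             gene_id = paste0("g", i),
                             stringsAsFactors = FALSE)
  }
  annotated_genome(chars, do.call(rbind, feats))
}
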