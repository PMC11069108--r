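make_line_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("reading TSV and minimal VCF yields one record per call", {
  tsv <- make_line_tsv(data.frame(line_id = c("L1", "L1", "L2"),
                                  position = c(10, 20, 10),
                                  ref = c("A", "C", "A"),
                                  alt = c("G", "T", "G")))
  cat1 <- read_mutations(tsv)
  expect_equal(nrow(cat1$records), 3L)
  expect_equal(cat1$records$mtype, rep("SNV", 3))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr\t5\t.\tA\tT\t.\t.\t.",
               "chr\t9\t.\tC\tCATG\t.\t.\t."), vcf)
  cat2 <- read_mutations(vcf)
  expect_equal(nrow(cat2$records), 2L)
  expect_equal(cat2$records$mtype, c("SNV", "insertion"))
  expect_equal(cat2$records$line_id[1], sub("\\.vcf$", "", basename(vcf)))

  expect_equal(nrow(read_mutations(character())$records), 0L)

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("#CHROM\tPOS", "chr\tx\t.\tA\tT"), bad)
  expect_error(read_mutations(bad), "POS|malformed")
})

test_that("duplicate calls collapse with a warning and round trips preserve the catalog", {
  recs <- data.frame(line_id = c("L1", "L1"), position = c(7, 7),
                     ref = "A", alt = "G")
  expect_warning(cat <- mutation_catalog(recs), "duplicate")
  expect_equal(nrow(cat$records), 1L)

  set.seed(31)
  recs2 <- data.frame(line_id = sample(c("L1", "L2", "L3"), 20, TRUE),
                      position = sample.int(1000, 20),
                      ref = sample(c("A", "C", "G", "T"), 20, TRUE),
                      alt = "AT")
  cat2 <- mutation_catalog(recs2)
  path <- tempfile(fileext = ".tsv")
  write_catalog_tsv(cat2, path)
  back <- read_mutations(path, lines = cat2$lines)
  expect_equal(back$records[c("line_id", "position", "ref", "alt", "mtype")],
               cat2$records[c("line_id", "position", "ref", "alt", "mtype")])
})

test_that("shared-ancestral subtraction removes exactly the planted variants", {
  # planted truth: 3 ancestral variants in all lines, de novo singletons kept
  set.seed(32)
  lines <- sprintf("L%02d", 1:8)
  anc <- data.frame(position = c(100, 200, 300), ref = "G",
                    alt = c("A", "T", "C"))
  recs <- do.call(rbind, lapply(lines, function(l)
    cbind(line_id = l, anc)))
  denovo <- data.frame(line_id = sample(lines, 10, TRUE),
                       position = sample(1000:2000, 10),
                       ref = "C", alt = "T")
  cat <- mutation_catalog(rbind(recs, denovo))
  res <- subtract_shared(cat)
  expect_equal(nrow(res$removed), 3L)
  expect_setequal(res$removed$position, anc$position)
  expect_equal(nrow(res$catalog$records), nrow(denovo))

  # a variant in 7 of 8 lines is retained at min_lines = 8, removed at 7
  recs7 <- do.call(rbind, lapply(lines[1:7], function(l)
    data.frame(line_id = l, position = 500, ref = "A", alt = "G")))
  cat7 <- mutation_catalog(rbind(recs7, denovo))
  expect_equal(nrow(subtract_shared(cat7, 8)$removed), 0L)
  expect_equal(nrow(subtract_shared(cat7, 7)$removed), 1L)
})

test_that("annotation fills region, effect, spectrum, ts/tv and direction", {
  # genome with one plus-strand CDS of four-fold codons: third positions are
  # fully synonymous, first/second positions nonsynonymous
  set.seed(33)
  g <- build_genome_with_cds(list(strrep("GGA", 10)))
  s <- g$features$start[1]
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  recs <- data.frame(
    line_id = "L1",
    position = c(s + 2, s + 0, 3),
    ref = chars[c(s + 2, s + 0, 3)],
    alt = c("T", "T", setdiff(c("A", "G"), chars[3])[1]))
  cat <- mutation_catalog(recs, data.frame(line_id = "L1",
                                           generations = 100))
  ann <- annotate_mutations(cat, g)
  r <- ann$records[order(ann$records$position), ]
  expect_equal(r$effect[r$position == s + 2], "synonymous")
  expect_equal(r$effect[r$position == s + 0], "nonsynonymous")
  expect_equal(r$region[r$position == 3], "intergenic")

  # strand-complement collapse: G>A and C>T are both GC>AT transitions
  # toward AT
  g2 <- annotated_genome("GGGCCC")
  cat2 <- mutation_catalog(data.frame(line_id = "L1",
                                      position = c(1, 4),
                                      ref = c("G", "C"),
                                      alt = c("A", "T")))
  r2 <- annotate_mutations(cat2, g2)$records
  expect_equal(r2$spectrum_class, c("GC>AT", "GC>AT"))
  expect_equal(r2$ts_tv, c("transition", "transition"))
  expect_equal(r2$toward, c("AT", "AT"))

  # mismatching reference allele is an error
  bad <- mutation_catalog(data.frame(line_id = "L1", position = 1,
                                     ref = "T", alt = "A"))
  expect_error(annotate_mutations(bad, g2), "disagrees")
})

test_that("indels are classed STR only for whole-unit events at a covering locus", {
  # ATG x4 locus embedded at a known position
  pre <- "CCTTCC"
  locus <- strrep("ATG", 4)
  g <- annotated_genome(paste0(pre, locus, "CCTTAAGG"))
  loci <- scan_str(g)
  expect_equal(loci$unit_count, 4L)
  p <- nchar(pre)  # anchor base just before the locus
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  recs <- data.frame(
    line_id = "L1",
    position = c(p, p, p, 16),
    ref = c(chars[p], paste0(chars[p], "ATG"), chars[p], chars[16]),
    alt = c(paste0(chars[p], "ATG"),        # +1 unit: STR
            chars[p],                       # -1 unit: STR
            paste0(chars[p], "AT"),         # partial unit: non-STR
            paste0(chars[16], "ATG")))      # whole unit but phase-breaking
  cat <- mutation_catalog(recs)
  r <- suppressWarnings(annotate_mutations(cat, g, str_loci = loci))$records
  ins_full <- r$indel_class[r$alt == paste0(chars[p], "ATG") &
                              r$position == p]
  expect_equal(ins_full, "STR")
  expect_equal(r$indel_class[r$ref == paste0(chars[p], "ATG")], "STR")
  expect_equal(r$indel_class[r$alt == paste0(chars[p], "AT")], "non_STR")
  expect_equal(r$indel_class[r$position == 16], "non_STR")
})

test_that("spectrum identities hold on simulated catalogs", {
  sim <- generate_genome(sim_config(genome_length = 30000L, seed = 34,
                                    snv_rate = 2e-8))
  ma <- simulate_ma_lines(sim)
  ann <- annotate_mutations(subtract_shared(ma$catalog)$catalog, sim$genome,
                            str_loci = sim$str_loci)
  spec <- catalog_counts(ann, "spectrum_class")
  n_snv <- sum(ann$records$mtype == "SNV")
  expect_gt(n_snv, 50)
  expect_equal(sum(spec), n_snv)
  ts <- catalog_counts(ann, "ts_tv")
  expect_equal(unname(ts["transition"]),
               sum(spec[c("AT>GC", "GC>AT")]))
  toward <- catalog_counts(ann, "toward")
  expect_equal(unname(toward["AT"]),
               sum(spec[c("GC>AT", "GC>TA", "AT>TA")]))
  expect_equal(sum(per_line_totals(ann)), nrow(ann$records))
})
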