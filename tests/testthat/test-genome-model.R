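test_that("site classification partitions the genome with the documented precedence", {
  # no features: everything intergenic
  g0 <- annotated_genome(strrep("ACGT", 25))
  cl0 <- classify_sites(g0)
  expect_equal(sum(cl0$labels == "intergenic"), 100)

  # one CDS at 1-30 on a 100 bp genome
  g1 <- annotated_genome(strrep("ACGTA", 20),
    features = data.frame(kind = "CDS", start = 1, end = 30, strand = "+",
                          gene_id = "g1"))
  cl1 <- classify_sites(g1)
  expect_equal(as.vector(table(cl1$labels)[c("protein_coding", "intergenic")]),
               c(30, 70))

  # overlapping CDS: overlap sites labeled protein_coding exactly once
  set.seed(11)
  g2 <- annotated_genome(random_dna(100),
    features = data.frame(kind = c("CDS", "CDS"), start = c(10, 30),
                          end = c(39, 59), strand = c("+", "+"),
                          gene_id = c("a", "b")))
  cl2 <- classify_sites(g2)
  expect_equal(sum(cl2$labels == "protein_coding"), 50)
  expect_equal(sum(cl2$counts), g2$length)

  # precedence over RNA and pseudogene
  g3 <- annotated_genome(random_dna(60),
    features = data.frame(kind = c("CDS", "RNA", "pseudogene"),
                          start = c(1, 10, 15), end = c(30, 40, 50),
                          strand = "+", gene_id = c("c", "r", "p")))
  cl3 <- classify_sites(g3)
  expect_equal(as.character(cl3$labels[c(5, 35, 45, 55)]),
               c("protein_coding", "rna_coding", "pseudogenic", "intergenic"))

  expect_error(annotated_genome("ACGT",
    features = data.frame(kind = "CDS", start = 2, end = 10, strand = "+",
                          gene_id = "x")), "bounds")
})

test_that("single-codon degeneracy matches hand-computed fractions", {
  # TTT (Phe): third position has one synonymous change (T->C), positions
  # one and two none
  g <- build_genome_with_cds(list("TTT"))
  t <- compute_targets(g)
  expect_equal(t$synonymous_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(t$nonsynonymous_sites, 3 - 1 / 3, tolerance = 1e-12)

  # a run of four-fold codons: every third position fully synonymous
  g4 <- build_genome_with_cds(list(strrep("GGA", 10)))
  t4 <- compute_targets(g4)
  expect_equal(t4$synonymous_sites, 10, tolerance = 1e-12)
  expect_equal(t4$nonsynonymous_sites, 20, tolerance = 1e-12)
})

test_that("NS/S targets match the exhaustive codon-change oracle and conserve CDS bp", {
  set.seed(42)
  for (rep in 1:5) {
    n_genes <- 8
    cds <- replicate(n_genes, random_cds(sample(10:40, 1), gc = 0.6))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    g <- build_genome_with_cds(as.list(cds), strands)
    t <- compute_targets(g)
    expected <- rowSums(vapply(cds, oracle_cds_targets, numeric(2)))
    expect_equal(t$synonymous_sites, expected[["S"]], tolerance = 1e-9)
    expect_equal(t$nonsynonymous_sites, expected[["NS"]], tolerance = 1e-9)
    # conservation: NS + S = protein-coding bp
    expect_equal(t$synonymous_sites + t$nonsynonymous_sites,
                 sum(nchar(cds)), tolerance = 1e-6)
  }
})

test_that("overlapping reading frames use the most constrained assignment", {
  # same CDS twice: overlap must not double-count and masks AND to themselves
  cds <- random_cds(12)
  set.seed(3)
  g1 <- build_genome_with_cds(list(cds))
  feats <- rbind(g1$features, g1$features)
  feats$gene_id <- c("a", "b")
  g2 <- annotated_genome(g1$sequence, feats)
  t1 <- compute_targets(g1)
  t2 <- compute_targets(g2)
  expect_equal(t2$synonymous_sites, t1$synonymous_sites, tolerance = 1e-9)

  # frame-shifted second ORF (start offset not divisible by 3): a change can
  # only stay synonymous if it is synonymous in both frames, so per-site
  # synonymous-change counts in the overlap can only shrink
  set.seed(4)
  seq <- paste0("AT", random_cds(20), random_cds(20), "AT")  # 124 bp
  f_a <- data.frame(kind = "CDS", start = 3, end = 62, strand = "+",
                    gene_id = "a")
  f_b <- data.frame(kind = "CDS", start = 34, end = 123, strand = "+",
                    gene_id = "b")
  ga <- annotated_genome(seq, f_a)
  gb <- annotated_genome(seq, rbind(f_a, f_b))
  ta <- suppressWarnings(compute_targets(ga))
  tb <- suppressWarnings(compute_targets(gb))
  ct <- mutacc:::codon_tables()
  pop <- function(m) ifelse(is.na(m), NA, ct$popcount3[m + 1])
  ov <- 34:62
  both <- !is.na(tb$syn_mask[ov]) & !is.na(ta$syn_mask[ov])
  expect_true(all(pop(tb$syn_mask[ov])[both] <= pop(ta$syn_mask[ov])[both]))
})

test_that("N-containing sites are excluded from all targets", {
  cds <- random_cds(10)
  set.seed(5)
  g <- build_genome_with_cds(list(cds))
  seq_n <- g$sequence
  substr(seq_n, 1, 1) <- "N"                      # intergenic N
  pos_cds <- g$features$start[1] + 4L
  substr(seq_n, pos_cds, pos_cds) <- "N"          # CDS N
  gn <- annotated_genome(seq_n, g$features)
  t0 <- compute_targets(g)
  tn <- compute_targets(gn)
  expect_equal(tn$total_sites, t0$total_sites - 2)
  expect_equal(tn$intergenic_sites, t0$intergenic_sites - 1)
  # the whole codon containing the N is untranslatable: its other two sites
  # leave the NS/S pool too
  expect_equal(tn$synonymous_sites + tn$nonsynonymous_sites,
               t0$synonymous_sites + t0$nonsynonymous_sites - 3,
               tolerance = 1e-9)
})

test_that("degenerate CDS are skipped with a warning", {
  set.seed(6)
  g_stop <- build_genome_with_cds(list(paste0(random_cds(3), "TAA",
                                              random_cds(3))))
  expect_warning(t <- compute_targets(g_stop), "internal stop")
  expect_equal(t$synonymous_sites + t$nonsynonymous_sites, 0)
  g_frame <- annotated_genome(random_dna(50),
    features = data.frame(kind = "CDS", start = 1, end = 10, strand = "+",
                          gene_id = "bad"))
  expect_warning(compute_targets(g_frame), "divisible by 3")
})

test_that("four-fold degenerate site extraction matches the codon-table oracle", {
  # alanine codons are four-fold; tryptophan has no degeneracy
  expect_equal(extract_fourfold_sites(c("GCTGCA", "GCAGCT")), c(3, 6))
  expect_equal(length(extract_fourfold_sites("TGGTGG")), 0)
  expect_error(extract_fourfold_sites("ACGTA"), "divisible by 3")

  set.seed(7)
  for (rep in 1:3) {
    ref <- random_cds(300, gc = 0.6)
    aln <- c(ref, random_cds(300), random_cds(300))
    expect_equal(extract_fourfold_sites(aln), oracle_fourfold_cols(ref))
  }
  # gaps in the reference row exclude the codon
  gapped <- paste0("GC-", "GCA")
  expect_equal(extract_fourfold_sites(c(gapped, "GCTGCC")), 6)
})

test_that("FASTA/GFF3 round trip preserves genome and features", {
  set.seed(8)
  sim <- generate_genome(sim_config(genome_length = 20000L, seed = 8))
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_genome(sim$genome, fasta = fa, gff3 = gff)
  g2 <- read_genome(fa, gff)
  expect_equal(g2$sequence, sim$genome$sequence)
  expect_equal(nrow(g2$features), nrow(sim$genome$features))
  f1 <- sim$genome$features[order(sim$genome$features$start), ]
  f2 <- g2$features[order(g2$features$start), ]
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_equal(f2$kind, f1$kind)
  expect_equal(f2$strand, f1$strand)
})
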