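# Pipeline orchestration: end-to-end analysis of a genome + mutation-call
# bundle, and the packaged worked example (published MA summary counts for a
# GC-rich myxobacterial genome) that exercises the estimators on known
# inputs.

#' Packaged worked-example counts
#'
#' Summary counts from a published bacterial MA experiment: per-category
#' mutation counts and target sizes (in sites, or repeat units for the STR
#' class), total generations, genomic GC fraction and the auxiliary counts
#' used by the bias tests and the effective-population-size arithmetic. These
#' serve as a known-answer input for the estimators; no sequence data are
#' involved.
#'
#' @return list with `table` (category, target_size, mutations),
#'   `T` (total generations), `n_lines`, `gc`, `pi`, `transitions`,
#'   `toward_at`, region count/site splits, and the per-transfer generation
#'   count `g_per_transfer`
#' @export
ma_worked_example <- function() {
  path <- system.file("extdata", "ma_worked_example.tsv", package = "mutacc",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(
    table = tab,
    T = 85323,
    n_lines = 46L,
    gc = 0.69,
    pi = 0.011,
    transitions = 206L,
    toward_at = 295L,
    snv_region = c(coding = 361L, noncoding = 67L),
    indel_region = c(coding = 25L, noncoding = 14L),
    nonstr_region = c(coding = 12L, noncoding = 0L),
    coding_sites = 6053873 + 2143616 + 6917,
    noncoding_sites = 828655 + 47343,
    g_per_transfer = 25
  )
}

#' Recompute the worked example's statistics from its counts
#'
#' Runs the full estimator stack on the packaged worked-example counts:
#' per-category Poisson rates with exact 95% intervals, the derived
#' coding-region rate and the intergenic/coding rate ratio, the four
#' Yates-corrected placement/ratio chi-square tests, the transition and
#' toward-A/T exact binomials, the natural effective population size from
#' pi = 2*Ne*mu, the experimental effective size, and the mean mutation
#' count per line.
#'
#' @param alpha two-sided error level for the rate intervals
#' @return list with `rates` (a `rate_estimate` table), `coding_rate`,
#'   `biases` (list of `bias_test_result`), `ne`, `ne_experimental`,
#'   `mean_mutations_per_line`, `intergenic_coding_ratio`
#' @export
reproduce_worked_example <- function(alpha = 0.05) {
  wx <- ma_worked_example()
  tab <- wx$table
  rates <- rate_table(stats::setNames(tab$mutations, tab$category),
                      stats::setNames(tab$target_size, tab$category),
                      T = wx$T, alpha = alpha)
  coding_rate <- poisson_rate(wx$snv_region[["coding"]], wx$coding_sites,
                              wx$T, alpha, category = "coding")
  mu_total <- rates$mu[rates$category == "snv_total"]
  biases <- list(
    snv_region = region_chi2(wx$snv_region,
                             c(wx$coding_sites, wx$noncoding_sites),
                             labels = c("coding", "noncoding")),
    indel_region = region_chi2(wx$indel_region,
                               c(wx$coding_sites, wx$noncoding_sites),
                               labels = c("coding", "noncoding")),
    ns_s = ns_s_test(
      c(tab$mutations[tab$category == "nonsynonymous"],
        tab$mutations[tab$category == "synonymous"]),
      c(tab$target_size[tab$category == "nonsynonymous"],
        tab$target_size[tab$category == "synonymous"])),
    nonstr_region = region_chi2(wx$nonstr_region,
                                c(wx$coding_sites, wx$noncoding_sites),
                                labels = c("coding", "noncoding")),
    transition = exact_binomial(wx$transitions,
                                tab$mutations[tab$category == "snv_total"],
                                1 / 3),
    toward_at = exact_binomial(wx$toward_at,
                               tab$mutations[tab$category == "snv_total"],
                               toward_at_null(wx$gc))
  )
  list(
    rates = rates,
    coding_rate = coding_rate,
    intergenic_coding_ratio =
      rates$mu[rates$category == "intergenic"] / coding_rate$mu,
    biases = biases,
    ne = ne_from_pi(wx$pi, mu_total),
    ne_experimental = experimental_ne(wx$g_per_transfer, 1),
    mean_mutations_per_line =
      (tab$mutations[tab$category == "snv_total"] +
         tab$mutations[tab$category == "indel_total"]) / wx$n_lines
  )
}

#' Run the full MA analysis pipeline on files
#'
#' Orchestrates: genome + annotation loading, site classification, target
#' sizes, STR scan, catalog reading, shared-ancestral subtraction,
#' annotation, per-category rates, bias tests, and (optionally) diversity/Ne
#' from an alignment. Writes a rate TSV, an annotated catalog TSV and a JSON
#' report into `out_dir` when given.
#'
#' @param fasta genome FASTA path
#' @param gff3 annotation GFF3 path
#' @param mutation_files mutation-call files (TSV and/or minimal VCF)
#' @param lines optional line-metadata data frame or TSV path (`line_id`,
#'   `generations`)
#' @param T total generations; default from line metadata
#' @param min_shared_lines carrier threshold for ancestral subtraction;
#'   default all lines
#' @param gc_fraction GC override for the toward-A/T null; computed from the
#'   genome sequence if `NULL`
#' @param alignment optional FASTA alignment path for diversity/Ne
#' @param alpha two-sided error level
#' @param out_dir optional output directory
#' @return list with `targets`, `str_loci`, `catalog`, `removed_shared`,
#'   `rates`, `biases`, `per_line`, `dispersion`, `ks`, and (if an alignment
#'   was given) `diversity` and `ne`
#' @export
run_pipeline <- function(fasta, gff3, mutation_files, lines = NULL,
                         T = NULL, min_shared_lines = NULL,
                         gc_fraction = NULL, alignment = NULL,
                         alpha = 0.05, out_dir = NULL) {
  for (f in c(fasta, gff3, mutation_files, alignment))
    if (!file.exists(f)) stop("input file not found: ", f)
  genome <- read_genome(fasta, gff3)
  classification <- classify_sites(genome)
  str_loci <- scan_str(genome)
  targets <- compute_targets(genome, classification, str_loci)
  if (is.character(lines)) lines <- utils::read.delim(lines)
  catalog <- read_mutations(mutation_files, lines = lines)
  if (is.null(min_shared_lines)) min_shared_lines <- nrow(catalog$lines)
  sub <- if (nrow(catalog$lines) >= 2L)
    subtract_shared(catalog, min_shared_lines)
  else list(catalog = catalog, removed = NULL)
  catalog <- annotate_mutations(sub$catalog, genome, classification,
                                targets, str_loci)
  if (is.null(T)) T <- total_generations(catalog)
  if (is.null(gc_fraction)) {
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    gc_fraction <- mean(chars %in% c("G", "C"))
  }
  rates <- category_rates(catalog, targets, T, alpha)
  biases <- bias_test_battery(catalog, targets, gc_fraction)
  per_line <- per_line_totals(catalog)
  out <- list(
    genome_id = genome$id,
    targets = targets, str_loci = str_loci,
    catalog = catalog, removed_shared = sub$removed,
    rates = rates, biases = biases,
    per_line = per_line,
    dispersion = if (mean(per_line) > 0) dispersion_test(per_line) else NULL,
    ks = if (length(per_line) >= 2L) ks_poisson_test(per_line) else NULL,
    gc_fraction = gc_fraction, T = T)
  if (!is.null(alignment)) {
    aln <- Biostrings::readDNAStringSet(alignment)
    ff <- extract_fourfold_sites(aln)
    out$diversity <- nucleotide_diversity(aln, site_filter = ff)
    mu_total <- rates$mu[rates$category == "snv_total"]
    out$ne <- ne_from_pi(out$diversity$pi, mu_total)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(out$rates),
                       file.path(out_dir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_catalog_tsv(catalog, file.path(out_dir, "catalog_annotated.tsv"))
    report <- list(
      rates = as.data.frame(out$rates),
      biases = lapply(out$biases, function(b)
        b[c("test", "statistic", "df", "p")]),
      per_line = as.list(out$per_line),
      gc_fraction = gc_fraction, total_generations = T)
    if (!is.null(out$ne)) report$ne <- out$ne$ne
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
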