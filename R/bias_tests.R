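# Selection and mutational-bias tests with nulls derived from genome
# composition and mutational target sizes.

#' Chi-square test of mutation placement against region fractions
#'
#' Builds the 2x2 table of mutated vs unmutated sites by region (e.g. coding
#' vs non-coding) and applies the chi-square test with Yates continuity
#' correction (correction magnitude `min(0.5, |O - E|)`), df = 1. Under a
#' uniform per-site rate, mutations should fall across regions in proportion
#' to the regions' site totals.
#'
#' @param observed length-2 vector of mutation counts per region
#' @param sites length-2 vector of site totals per region (same order)
#' @param labels optional region names
#' @return object of class `bias_test_result`: list with observed and
#'   expected counts, `statistic`, `df`, `p`, and the direction of the
#'   deviation in the first region
#' @examples
#' region_chi2(c(361, 67), c(8204406, 875998),
#'             labels = c("coding", "noncoding"))   # chi2 ~ 17.0
#' @export
region_chi2 <- function(observed, sites, labels = c("region1", "region2")) {
  stopifnot(length(observed) == 2L, length(sites) == 2L,
            all(observed >= 0), all(sites > 0))
  total <- sum(observed)
  f <- sites / sum(sites)
  expected <- total * f
  if (any(expected == 0)) stop("zero expected count")
  tab <- rbind(mutated = observed, unmutated = sites - observed)
  colnames(tab) <- labels
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  structure(list(
    test = "region placement chi-square (Yates)",
    observed = stats::setNames(observed, labels),
    expected = stats::setNames(expected, labels),
    statistic = unname(ht$statistic), df = 1L, p = ht$p.value,
    direction = if (observed[1] > expected[1]) paste0("excess in ", labels[1])
                else paste0("deficit in ", labels[1])
  ), class = "bias_test_result")
}

#' Nonsynonymous/synonymous ratio test against target sizes
#'
#' Compares the observed NS:S mutation ratio with the ratio of the
#' nonsynonymous and synonymous site targets, using the same Yates-corrected
#' 2x2 construction as [region_chi2()]. A significant NS deficit would
#' indicate purifying selection acting within the MA experiment.
#'
#' @param observed length-2 vector `c(NS, S)` of mutation counts
#' @param targets length-2 vector `c(n_NS, n_S)` of site targets
#' @return a `bias_test_result` with `observed_ratio` and `expected_ratio`
#' @examples
#' ns_s_test(c(249, 109), c(6053873, 2143616))   # chi2 ~ 3.2, p ~ 0.073
#' @export
ns_s_test <- function(observed, targets) {
  stopifnot(length(observed) == 2L, length(targets) == 2L, all(targets > 0))
  if (observed[2] == 0)
    stop("zero synonymous count: observed ratio undefined")
  res <- region_chi2(observed, targets,
                     labels = c("nonsynonymous", "synonymous"))
  res$test <- "NS/S ratio vs target-size expectation (Yates chi-square)"
  res$observed_ratio <- observed[1] / observed[2]
  res$expected_ratio <- targets[1] / targets[2]
  res
}

#' Two-sided exact binomial test (minimum-likelihood rule)
#'
#' The two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one under Binomial(n, p0) — the convention of
#' `binom.test`.
#'
#' @param k observed successes
#' @param n trials
#' @param p0 null success proportion (0 < p0 < 1)
#' @return a `bias_test_result` with the observed proportion and exact p
#' @examples
#' exact_binomial(206, 428, 1/3)   # transition excess, p ~ 2.9e-10
#' @export
exact_binomial <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  ht <- stats::binom.test(k, n, p = p0)
  structure(list(
    test = "exact binomial (two-sided, minimum-likelihood)",
    observed = c(successes = k, trials = n),
    expected = c(null_proportion = p0),
    statistic = k / n, df = NA_integer_, p = ht$p.value,
    direction = if (k / n > p0) "above null" else "below null",
    observed_proportion = k / n
  ), class = "bias_test_result")
}

#' Null proportion of substitutions toward A/T under a uniform rate
#'
#' Of the three possible changes at a G/C site, two move toward A/T; at an
#' A/T site, one of three does. With genomic GC fraction `gc`, a uniformly
#' random substitution therefore moves toward A/T with probability
#' `gc * 2/3 + (1 - gc) * 1/3`.
#'
#' @param gc_fraction genomic G+C fraction in \[0, 1\]
#' @return the null toward-A/T proportion
#' @examples
#' toward_at_null(0.69)   # 0.5633
#' @export
toward_at_null <- function(gc_fraction) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  gc_fraction * 2 / 3 + (1 - gc_fraction) / 3
}

#' Expected spectrum-class counts under a uniform per-site rate
#'
#' Each of the three classes originating at G/C sites expects
#' `total * gc / 3` mutations; each AT-origin class expects
#' `total * (1 - gc) / 3`. The six expectations sum to `total`.
#'
#' @param total_snvs total SNV count to distribute
#' @param gc_fraction genomic G+C fraction
#' @return named numeric vector over the six collapsed classes
#' @export
expected_spectrum <- function(total_snvs, gc_fraction) {
  stopifnot(total_snvs >= 0, gc_fraction >= 0, gc_fraction <= 1)
  e <- ifelse(startsWith(.SPECTRUM_CLASSES, "GC"),
              total_snvs * gc_fraction / 3,
              total_snvs * (1 - gc_fraction) / 3)
  stats::setNames(e, .SPECTRUM_CLASSES)
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat("<bias_test_result>", x$test, "\n")
  cat("  observed:", paste(names(x$observed), x$observed, collapse = ", "),
      "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.3g (%s)\n",
              x$statistic, format(x$df), x$p, x$direction))
  invisible(x)
}

#' Run the standard bias-test battery on an annotated catalog
#'
#' Applies, with no multiple-testing correction (the tests answer distinct
#' questions and are reported individually): coding vs non-coding placement
#' for SNVs and for indels, the NS/S ratio test, the transition-fraction
#' exact binomial against 1/3, and the toward-A/T exact binomial against the
#' composition null from [toward_at_null()].
#'
#' @param catalog an annotated [mutation_catalog()]
#' @param targets a `target_sizes` object
#' @param gc_fraction genomic G+C fraction used for the toward-A/T null
#' @return named list of `bias_test_result` objects
#' @export
bias_test_battery <- function(catalog, targets, gc_fraction) {
  r <- catalog$records
  snv <- r[r$mtype == "SNV", , drop = FALSE]
  ind <- r[r$mtype != "SNV", , drop = FALSE]
  coding_sites <- targets$nonsynonymous_sites + targets$synonymous_sites +
    targets$rna_sites
  noncoding_sites <- targets$intergenic_sites + targets$pseudogenic_sites
  snv_coding <- sum(snv$region %in% c("protein_coding", "rna_coding"))
  ind_coding <- sum(ind$region %in% c("protein_coding", "rna_coding"))
  out <- list(
    snv_region = region_chi2(c(snv_coding, nrow(snv) - snv_coding),
                             c(coding_sites, noncoding_sites),
                             labels = c("coding", "noncoding")),
    indel_region = if (nrow(ind)) region_chi2(
      c(ind_coding, nrow(ind) - ind_coding),
      c(coding_sites, noncoding_sites),
      labels = c("coding", "noncoding")) else NULL,
    ns_s = ns_s_test(c(sum(snv$effect == "nonsynonymous"),
                       sum(snv$effect == "synonymous")),
                     c(targets$nonsynonymous_sites,
                       targets$synonymous_sites)),
    transition = exact_binomial(sum(snv$ts_tv == "transition"),
                                nrow(snv), 1 / 3),
    toward_at = exact_binomial(sum(snv$toward == "AT"), nrow(snv),
                               toward_at_null(gc_fraction))
  )
  out[!vapply(out, is.null, logical(1))]
}
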