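# Poisson maximum-likelihood mutation-rate estimation with exact (gamma-
# quantile) confidence intervals, per-category rate tables, and
# Poisson-adequacy checks (variance/mean dispersion test, one-sample KS).

#' Poisson rate estimate with exact confidence interval
#'
#' The rate is the ML estimate `m / (n * T)` for `m` mutations observed over
#' a target of `n` sites (or STR units) across `T` generations. The
#' two-sided equal-tailed exact interval comes from gamma quantiles:
#' lower `qgamma(alpha/2, m) / (nT)` (zero when `m = 0`), upper
#' `qgamma(1 - alpha/2, m + 1) / (nT)` — identical to the classical exact
#' Poisson interval.
#'
#' @param m observed mutation count (non-negative integer)
#' @param n target size in sites or repeat units (> 0)
#' @param T total generations summed across lines (> 0)
#' @param alpha two-sided error level (default 0.05 for a 95% interval)
#' @param category optional label carried through to rate tables
#' @return object of class `rate_estimate`: a one-row data frame with
#'   `category`, `m`, `n`, `T`, `mu`, `ci_low`, `ci_high`, and the
#'   per-genomic-target rate `per_target_rate` with its interval
#' @examples
#' poisson_rate(428, 9080403, 85323)   # ~5.52e-10 (5.01-6.07)
#' @export
poisson_rate <- function(m, n, T, alpha = 0.05, category = "") {
  if (n <= 0) stop("target size n must be positive")
  if (T <= 0) stop("total generations T must be positive")
  if (m < 0 || m != round(m)) stop("m must be a non-negative integer")
  lo <- if (m == 0) 0 else stats::qgamma(alpha / 2, shape = m)
  hi <- stats::qgamma(1 - alpha / 2, shape = m + 1)
  out <- data.frame(
    category = category, m = m, n = n, T = T,
    mu = m / (n * T),
    ci_low = lo / (n * T),
    ci_high = hi / (n * T),
    per_target_rate = m / T,
    per_target_low = lo / T,
    per_target_high = hi / T,
    stringsAsFactors = FALSE)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Rate table from explicit per-category counts and targets
#'
#' Lower-level companion of [category_rates()]: builds one exact Poisson
#' estimate per row of (category, count, target).
#'
#' @param counts named numeric vector of mutation counts
#' @param targets named numeric vector of target sizes (same names)
#' @param T total generations
#' @param alpha two-sided error level
#' @return a `rate_estimate` data frame, one row per category
#' @export
rate_table <- function(counts, targets, T, alpha = 0.05) {
  miss <- setdiff(names(counts), names(targets))
  if (length(miss))
    stop("no target size for category: ", paste(miss, collapse = ", "))
  rows <- lapply(names(counts), function(cat) {
    poisson_rate(counts[[cat]], targets[[cat]], T, alpha, category = cat)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Per-category mutation rates from an annotated catalog
#'
#' Produces the standard MA-experiment rate table: total SNV,
#' nonsynonymous, synonymous, intergenic, pseudogenic, RNA-coding,
#' coding-combined (protein + RNA genes over their joint site target),
#' total indel, non-STR indel (over all sites) and STR indel (over the
#' repeat-unit target).
#'
#' @param catalog an annotated [mutation_catalog()]
#' @param targets a `target_sizes` object with `str_units` filled
#' @param T total generations; defaults to the catalog's line metadata sum
#' @param alpha two-sided error level
#' @return a `rate_estimate` data frame, one row per category
#' @export
category_rates <- function(catalog, targets, T = total_generations(catalog),
                           alpha = 0.05) {
  r <- catalog$records
  if (!"effect" %in% names(r))
    stop("catalog must be annotated first (see annotate_mutations)")
  snv <- r[r$mtype == "SNV", , drop = FALSE]
  ind <- r[r$mtype != "SNV", , drop = FALSE]
  cnt <- function(x) as.numeric(x)
  counts <- c(
    snv_total = nrow(snv),
    nonsynonymous = sum(snv$effect == "nonsynonymous"),
    synonymous = sum(snv$effect == "synonymous"),
    intergenic = sum(snv$effect == "intergenic"),
    pseudogenic = sum(snv$effect == "pseudogenic"),
    rna_coding = sum(snv$effect == "rna_coding"),
    coding = sum(snv$effect %in% c("nonsynonymous", "synonymous",
                                   "rna_coding")),
    indel_total = nrow(ind),
    indel_non_str = sum(ind$indel_class == "non_STR"),
    indel_str = sum(ind$indel_class == "STR"))
  tg <- c(
    snv_total = targets$total_sites,
    nonsynonymous = targets$nonsynonymous_sites,
    synonymous = targets$synonymous_sites,
    intergenic = targets$intergenic_sites,
    pseudogenic = targets$pseudogenic_sites,
    rna_coding = targets$rna_sites,
    coding = targets$nonsynonymous_sites + targets$synonymous_sites +
      targets$rna_sites,
    indel_total = targets$total_sites,
    indel_non_str = targets$total_sites,
    indel_str = targets$str_units)
  if (is.na(tg[["indel_str"]])) {
    counts <- counts[names(counts) != "indel_str"]
    tg <- tg[names(tg) != "indel_str"]
  }
  keep <- tg > 0
  rate_table(counts[keep], tg[keep], T, alpha)
}

#' Conditional spectrum rates per collapsed substitution class
#'
#' For each of the six strand-collapsed classes, the rate is the class count
#' divided by the number of sites at risk of producing it — A/T sites for
#' AT-origin classes, G/C sites for GC-origin classes — times total
#' generations, with an exact Poisson interval.
#'
#' @param class_counts named numeric vector over the six classes
#'   (`"AT>TA"`, `"AT>CG"`, `"AT>GC"`, `"GC>TA"`, `"GC>AT"`, `"GC>CG"`);
#'   absent classes count zero
#' @param n_at,n_gc numbers of A/T and G/C sites at risk
#' @param T total generations
#' @param alpha two-sided error level
#' @return a `rate_estimate` data frame with six rows
#' @export
conditional_spectrum_rates <- function(class_counts, n_at, n_gc, T,
                                       alpha = 0.05) {
  counts <- stats::setNames(rep(0, 6), .SPECTRUM_CLASSES)
  counts[names(class_counts)] <- class_counts
  tg <- stats::setNames(ifelse(startsWith(.SPECTRUM_CLASSES, "AT"),
                               n_at, n_gc), .SPECTRUM_CLASSES)
  rate_table(counts, tg, T, alpha)
}

#' Variance/mean dispersion test for Poisson adequacy
#'
#' Under a Poisson model, `(n - 1) * s^2 / mean` for a sample of `n` counts
#' follows a chi-square distribution with `n - 1` degrees of freedom. The
#' two-sided p-value doubles the smaller tail (capped at 1), so both over-
#' and under-dispersion can reject.
#'
#' @param counts numeric vector of at least two counts with positive mean
#' @return list with `statistic`, `df`, `p`, and the dispersion index
#'   `var_mean_ratio`
#' @export
dispersion_test <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("need at least two counts")
  mu <- mean(counts)
  if (mu == 0) stop("mean of counts is zero; dispersion undefined")
  stat <- (n - 1) * stats::var(counts) / mu
  lower <- stats::pchisq(stat, df = n - 1)
  p <- min(1, 2 * min(lower, 1 - lower))
  list(statistic = stat, df = n - 1L, p = p,
       var_mean_ratio = stats::var(counts) / mu)
}

#' One-sample Kolmogorov-Smirnov test against a fitted Poisson
#'
#' Compares the empirical distribution of per-line mutation totals to a
#' Poisson with rate equal to the sample mean:
#' `D = sup_x |ECDF(x) - Poisson CDF(x)|`, evaluated over the discrete
#' support (both distribution functions are right-continuous step functions,
#' so the supremum is attained at integer support points). The p-value uses
#' the asymptotic Kolmogorov distribution, which is conservative for a
#' discrete null with an estimated rate; that direction of approximation is
#' documented rather than corrected, as is conventional for this adequacy
#' check on MA per-line counts.
#'
#' @param per_line_totals numeric vector of per-line counts (>= 2 lines)
#' @return list with `D`, `p` and the fitted mean `lambda`
#' @export
ks_poisson_test <- function(per_line_totals) {
  x <- per_line_totals
  stopifnot(length(x) >= 2L, all(x >= 0))
  n <- length(x)
  lambda <- mean(x)
  support <- 0:max(max(x), stats::qpois(1 - 1e-12, lambda))
  ecdf_x <- stats::ecdf(x)(support)
  D <- max(abs(ecdf_x - stats::ppois(support, lambda)))
  t <- sqrt(n) * D
  # Kolmogorov tail: Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
  k <- 1:100
  p <- if (t < 1e-8) 1 else
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  list(D = D, p = p, lambda = lambda)
}
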