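# Nucleotide diversity at (typically four-fold degenerate) sites, effective
# population size from pi = 2*Ne*mu under haploidy, the within-experiment
# effective size of a bottlenecked MA line, and a small neutral coalescent
# simulator used to validate the pi -> Ne pathway.

#' Nucleotide diversity (mean pairwise difference per site)
#'
#' For every unordered pair of sequences, the proportion of differing sites
#' among the sites where both carry an unambiguous base (pairwise deletion of
#' gaps and N); pi is the average of these proportions. No multiple-hit
#' correction is applied: pi is the raw mean pairwise difference.
#'
#' @param alignment character vector of aligned sequences (equal lengths), a
#'   character matrix, or a `DNAStringSet`
#' @param site_filter optional integer vector of column positions to restrict
#'   to (e.g. from [extract_fourfold_sites()])
#' @return list of class `diversity_estimate` with `pi`, `n_sequences`,
#'   `n_sites`
#' @export
nucleotide_diversity <- function(alignment, site_filter = NULL) {
  aln <- as_alignment_chars(alignment)
  if (nrow(aln) < 2L) stop("need at least two sequences")
  if (!is.null(site_filter)) aln <- aln[, site_filter, drop = FALSE]
  n <- nrow(aln)
  valid <- matrix(aln %in% .BASES, nrow = n)
  pair_pi <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      if (nc == 0L) next
      pair_pi <- c(pair_pi, sum(aln[i, comp] != aln[j, comp]) / nc)
    }
  }
  if (!length(pair_pi))
    stop("no comparable sites in any sequence pair")
  structure(list(pi = mean(pair_pi), n_sequences = n, n_sites = ncol(aln)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> pi = %.4g over %d sequences, %d sites\n",
              x$pi, x$n_sequences, x$n_sites))
  invisible(x)
}

#' Effective population size from neutral diversity
#'
#' Under haploidy, expected neutral diversity is `pi = 2 * Ne * mu`, so
#' `Ne = pi / (2 * mu)`.
#'
#' @param pi nucleotide diversity at neutral (four-fold degenerate) sites
#' @param mu per-site per-generation mutation rate (> 0)
#' @return list of class `ne_estimate` with `ne`, `pi`, `mu`
#' @examples
#' ne_from_pi(0.011, 5.52e-10)   # ~1e7
#' @export
ne_from_pi <- function(pi, mu) {
  if (mu <= 0) stop("mu must be positive")
  stopifnot(pi >= 0)
  structure(list(ne = pi / (2 * mu), pi = pi, mu = mu),
            class = "ne_estimate")
}

#' Experimental effective population size of a bottlenecked MA line
#'
#' A line repeatedly reduced to `n_b` founder cells and regrown for `g`
#' generations per cycle has effective size `g * n_b` — equal to the
#' harmonic mean of the within-cycle census trajectory `n_b * 2^t`,
#' `t = 0..g-1`.
#'
#' @param g generations per bottleneck cycle (> 0)
#' @param n_b bottleneck size in cells (>= 1), default a single colony-
#'   founding cell
#' @return list of class `ne_estimate` with `ne`, `g`, `n_b`
#' @examples
#' experimental_ne(25)   # 25
#' @export
experimental_ne <- function(g, n_b = 1) {
  stopifnot(g > 0, n_b >= 1)
  structure(list(ne = g * n_b, g = g, n_b = n_b), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne = %.4g\n", x$ne))
  invisible(x)
}

#' Neutral coalescent alignment simulator (infinite sites)
#'
#' Simulates a Kingman coalescent genealogy for `n_samples` lineages
#' (exponential coalescence times, time in units of Ne generations), drops
#' mutations on branches as a Poisson process at `theta_per_site / 2` per
#' site per coalescent time unit, and places each mutation at a distinct
#' uniformly chosen alignment column (infinite-sites approximation on `L`
#' sites). Expected pairwise diversity equals `theta_per_site`.
#'
#' @param n_samples number of sampled sequences (>= 2)
#' @param theta_per_site population-scaled mutation rate 2*Ne*mu per site
#' @param L alignment length in sites
#' @param seed optional integer seed; a fixed seed gives a bit-identical
#'   alignment
#' @return character vector of `n_samples` sequences of length `L`
#' @export
coalescent_simulate <- function(n_samples, theta_per_site, L, seed = NULL) {
  stopifnot(n_samples >= 2L, theta_per_site >= 0, L >= 1L)
  if (!is.null(seed)) set.seed(seed)
  # lineage membership sets; per-interval mutation counts per lineage
  members <- lapply(seq_len(n_samples), identity)
  mut_members <- list()
  k <- n_samples
  while (k > 1L) {
    t <- stats::rexp(1L, rate = k * (k - 1L) / 2)
    n_mut <- stats::rpois(k, theta_per_site / 2 * L * t)
    for (i in which(n_mut > 0L)) {
      mut_members <- c(mut_members,
                       rep(list(members[[i]]), n_mut[i]))
    }
    pair <- sample.int(k, 2L)
    members[[min(pair)]] <- c(members[[min(pair)]], members[[max(pair)]])
    members[[max(pair)]] <- NULL
    k <- k - 1L
  }
  M <- length(mut_members)
  if (M > L)
    stop("more mutations (", M, ") than sites (", L,
         "); infinite-sites placement impossible at this theta and L")
  anc <- sample(.BASES, L, replace = TRUE)
  seqm <- matrix(rep(anc, each = n_samples), nrow = n_samples)
  if (M > 0L) {
    pos <- sample.int(L, M)
    for (m in seq_len(M)) {
      derived <- sample(setdiff(.BASES, anc[pos[m]]), 1L)
      seqm[mut_members[[m]], pos[m]] <- derived
    }
  }
  apply(seqm, 1L, paste, collapse = "")
}
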