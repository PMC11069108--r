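test_that("exact Poisson intervals have the stated properties", {
  # zero-count case: lower bound 0, upper from the gamma quantile
  z <- poisson_rate(0, 1e6, 1e3)
  expect_equal(z$mu, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, qgamma(0.975, 1) / 1e9)

  # CI nesting: the 99% interval contains the 95% interval
  a05 <- poisson_rate(37, 1e6, 1e3, alpha = 0.05)
  a01 <- poisson_rate(37, 1e6, 1e3, alpha = 0.01)
  expect_lt(a01$ci_low, a05$ci_low)
  expect_gt(a01$ci_high, a05$ci_high)
  expect_true(a05$ci_low <= a05$mu && a05$mu <= a05$ci_high)

  # scale equivariance in n and T
  base <- poisson_rate(12, 1000, 50)
  kn <- poisson_rate(12, 3000, 50)
  kt <- poisson_rate(12, 1000, 150)
  for (f in c("mu", "ci_low", "ci_high")) {
    expect_equal(kn[[f]], base[[f]] / 3, tolerance = 1e-12)
    expect_equal(kt[[f]], base[[f]] / 3, tolerance = 1e-12)
  }
  # matches the exact interval of poisson.test
  pt <- poisson.test(37)$conf.int
  expect_equal(a05$ci_low * 1e9, pt[1], tolerance = 1e-10)
  expect_equal(a05$ci_high * 1e9, pt[2], tolerance = 1e-10)

  expect_error(poisson_rate(3, 0, 10), "positive")
  expect_error(poisson_rate(3, 10, 0), "positive")
  expect_error(poisson_rate(2.5, 10, 10), "integer")
})

test_that("category rates partition the catalog and use the right targets", {
  sim <- generate_genome(sim_config(genome_length = 30000L, seed = 41,
                                    snv_rate = 2e-8, indel_rate = 2e-9,
                                    str_rate_per_unit = 5e-7))
  ma <- simulate_ma_lines(sim)
  ann <- annotate_mutations(subtract_shared(ma$catalog)$catalog, sim$genome,
                            str_loci = sim$str_loci)
  tg <- compute_targets(sim$genome, str_loci = sim$str_loci)
  rt <- category_rates(ann, tg)
  g <- function(cat, col = "m") rt[[col]][rt$category == cat]
  expect_equal(g("snv_total"),
               g("nonsynonymous") + g("synonymous") + g("intergenic") +
                 g("pseudogenic") + g("rna_coding"))
  expect_equal(g("indel_total"), g("indel_non_str") + g("indel_str"))
  expect_equal(g("coding"),
               g("nonsynonymous") + g("synonymous") + g("rna_coding"))
  expect_equal(g("indel_str", "n"), tg$str_units)
  expect_equal(g("snv_total", "n"), tg$total_sites)
  expect_error(category_rates(ma$catalog, tg), "annotated")
})

test_that("simulated true rates fall inside their 95% intervals at nominal frequency", {
  # count-level MA replicates: per-line Poisson counts at a known rate
  set.seed(42)
  mu <- 5.52e-10
  n <- 9.08e6
  Ti <- rep(1855, 46)
  reps <- 400
  cover <- logical(reps)
  for (i in seq_len(reps)) {
    m <- sum(rpois(46, mu * n * Ti))
    est <- poisson_rate(m, n, sum(Ti))
    cover[i] <- est$ci_low <= mu && mu <= est$ci_high
  }
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("conditional spectrum rates reduce to the overall rate under uniformity", {
  # planted counts exactly proportional to sites at risk: every class rate
  # equals the overall per-site rate
  n_at <- 3e5; n_gc <- 7e5; T <- 1e4; mu <- 2e-9
  counts <- c("AT>TA" = mu * n_at * T / 3, "AT>CG" = mu * n_at * T / 3,
              "AT>GC" = mu * n_at * T / 3, "GC>TA" = mu * n_gc * T / 3,
              "GC>AT" = mu * n_gc * T / 3, "GC>CG" = mu * n_gc * T / 3)
  counts <- round(counts)
  rt <- conditional_spectrum_rates(counts, n_at, n_gc, T)
  expect_equal(rt$mu[rt$category == "AT>TA"] * 3, mu, tolerance = 0.01)
  expect_equal(rt$mu[rt$category == "GC>AT"] * 3, mu, tolerance = 0.01)
  # doubling one class doubles its conditional rate
  counts2 <- counts
  counts2["GC>AT"] <- 2 * counts2["GC>AT"]
  rt2 <- conditional_spectrum_rates(counts2, n_at, n_gc, T)
  expect_equal(rt2$mu[rt2$category == "GC>AT"],
               2 * rt$mu[rt$category == "GC>AT"], tolerance = 0.01)
})

test_that("dispersion test is calibrated and degenerate inputs behave", {
  expect_equal(dispersion_test(c(5, 5, 5, 5))$statistic, 0)
  expect_error(dispersion_test(c(0, 0)), "zero")
  expect_error(dispersion_test(5), "two")

  set.seed(43)
  pvals <- replicate(2000, dispersion_test(rpois(46, 10.2))$p)
  # null p-values approximately uniform
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
  # gross overdispersion rejects
  expect_lt(dispersion_test(rnbinom(100, size = 1, mu = 10))$p, 1e-6)
})

test_that("KS Poisson adequacy test accepts Poisson data and rejects gross misfit", {
  set.seed(44)
  res <- replicate(200, ks_poisson_test(rpois(46, 10.2))$p > 0.05)
  expect_gt(mean(res), 0.90)
  # strongly bimodal counts are rejected
  bad <- c(rep(0, 23), rep(30, 23))
  expect_lt(ks_poisson_test(bad)$p, 0.01)
  d <- ks_poisson_test(rpois(46, 10.2))
  expect_true(d$D >= 0 && d$D <= 1)
})
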