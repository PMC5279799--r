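test_that("pairwise_r2 matches the frequency-count oracle", {
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)

  # 8-line constructed pair: r2 = D^2 / (pA pa pB pb) on haplotype counts
  x <- c(0, 0, 0, 2, 2, 2, 2, 0) / 2
  y <- c(0, 2, 0, 2, 2, 0, 2, 0) / 2
  pA <- mean(x); pB <- mean(y)
  D <- mean(x * y) - pA * pB
  oracle <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(pairwise_r2(2 * x, 2 * y), oracle, tolerance = 1e-12)

  expect_error(pairwise_r2(c(0, 0), c(0, 2, 2)), "length")
  expect_error(pairwise_r2(rep(0, 4), c(0, 2, 0, 2)), "monomorphic")
  expect_error(pairwise_r2(c(0, NA, 2), c(0, 2, 2)), "missing")
})

test_that("pairwise_r2 is invariant to allele flips and line order", {
  set.seed(4)
  x <- sample(c(0, 2), 30, replace = TRUE)
  y <- ifelse(runif(30) < 0.3, sample(c(0, 2), 30, replace = TRUE), x)
  base <- pairwise_r2(x, y)
  expect_equal(pairwise_r2(2 - x, y), base)
  expect_equal(pairwise_r2(x, 2 - y), base)
  o <- sample(30)
  expect_equal(pairwise_r2(x[o], y[o]), base)
  expect_equal(pairwise_r2(y, x), base)
})

test_that("ld_table enumerates the expected pairs", {
  set.seed(9)
  d <- matrix(sample(c(0, 2), 20 * 4, replace = TRUE), nrow = 20)
  g <- toy_genotypes(d)
  map3 <- toy_map(sprintf("M%02d", 1:4), c("1A", "1A", "1A", "1B"),
                  c(0, 2, 5, 1))
  tab <- ld_table(g, map3, scope = "1A")
  expect_equal(nrow(tab), 3L)                     # C(3,2)
  expect_equal(sort(tab$dist), c(2, 3, 5))

  map22 <- toy_map(sprintf("M%02d", 1:4), c("1A", "1A", "1B", "1B"),
                   c(0, 1, 0, 1))
  inter <- ld_table(g, map22, scope = "interchromosomal")
  expect_equal(nrow(inter), 4L)
  expect_true(all(is.na(inter$dist)))

  p <- quick_panel(seed = 17, n_lines = 40, markers = 20)
  t1 <- ld_table(p$genotypes, p$map, "interchromosomal",
                 subsample = 100, seed = 42)
  t2 <- ld_table(p$genotypes, p$map, "interchromosomal",
                 subsample = 100, seed = 42)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100L)
})

test_that("critical_r2 matches its closed form and the null scale", {
  const <- data.frame(r2 = rep(0.17, 100))
  expect_equal(critical_r2(const, method = "empirical"), 0.17)

  set.seed(31)
  s <- rnorm(1e5, 0.3, 0.1)
  tab <- data.frame(r2 = s^2)
  expect_lt(abs(critical_r2(tab) - (0.3 + qnorm(0.95) * 0.1)^2), 0.005)

  # independent markers at n = 169: background threshold stays small
  p <- simulate_panel(sim_config(
    n_lines = 169, chromosomes = c(A = 5000, B = 5000),
    markers_per_chrom = 60, ld_rho = 2, missing_rate = 0,
    h2_polygenic = 0, seed = 33))
  un <- ld_table(p$genotypes, p$map, "interchromosomal",
                 subsample = 2000, seed = 1)
  expect_lt(critical_r2(un), 0.1)

  expect_error(critical_r2(data.frame(r2 = 0.1)), "at least 2")
  expect_warning(critical_r2(data.frame(r2 = runif(10))), "unstable")
})

test_that("the decay expectation has the stated analytic limits", {
  # d -> 0 with huge n: 10/22
  expect_equal(hill_weir_r2(0, 0.5, 1e9), 10 / 22, tolerance = 1e-7)
  # C -> infinity: sampling floor 1/n
  expect_equal(hill_weir_r2(1e7, 1, 169), 1 / 169, tolerance = 1e-4)
  # strictly decreasing in d for rho > 0
  grid <- hill_weir_r2(seq(0, 50, by = 0.25), 0.4, 169)
  expect_true(all(diff(grid) < 0))
})

test_that("fit_decay recovers rho and the decay distance", {
  d <- seq(0.1, 40, length.out = 500)
  exact <- data.frame(dist = d, r2 = hill_weir_r2(d, 0.5, 169))
  fit <- fit_decay(exact, n = 169, critical = 0.2)
  expect_lt(abs(fit$rho - 0.5) / 0.5, 0.01)

  noiseless <- fit_decay(
    data.frame(dist = d, r2 = hill_weir_r2(d, 0.3, 169)),
    n = 169, critical = 0.2)
  set.seed(77)
  dn <- runif(1e4, 0.1, 40)
  noisy <- fit_decay(
    data.frame(dist = dn,
               r2 = pmin(pmax(hill_weir_r2(dn, 0.3, 169) +
                                rnorm(1e4, 0, 0.05), 0), 1)),
    n = 169, critical = 0.2)
  expect_lt(abs(noisy$decay_distance - noiseless$decay_distance) /
              noiseless$decay_distance, 0.10)

  # threshold below the 1/n asymptote: curve never crosses
  nofit <- fit_decay(exact, n = 169, critical = 1 / 200)
  expect_false(nofit$crosses)
  expect_true(is.na(nofit$decay_distance))
})

test_that("per-chromosome decay distances bracket the genome-wide fit", {
  p <- simulate_panel(sim_config(
    n_lines = 150, chromosomes = setNames(rep(80, 4), c("1A", "1B", "2A", "2B")),
    markers_per_chrom = 70, ld_rho = 0.4, missing_rate = 0,
    h2_polygenic = 0, seed = 55))
  un <- ld_table(p$genotypes, p$map, "interchromosomal",
                 subsample = 3000, seed = 2)
  crit <- critical_r2(un)
  genome <- fit_decay(ld_table(p$genotypes, p$map, "genome"),
                      critical = crit)
  per <- decay_by_chromosome(p$genotypes, p$map, crit)
  per <- per[is.finite(per)]
  expect_gte(genome$decay_distance, min(per))
  expect_lte(genome$decay_distance, max(per))
})
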