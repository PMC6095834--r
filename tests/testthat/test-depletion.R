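test_that("size factors match the hand-evaluated median-of-ratios", {
  # 4 x 3 fixture; reference = per-hairpin geometric mean across samples
  k <- matrix(c(100, 200, 400,
                 50, 100, 200,
                 80, 160, 320,
                 10,  20,  40), 4, 3, byrow = TRUE,
              dimnames = list(paste0("h", 1:4), paste0("s", 1:3)))
  geo <- apply(k, 1, function(r) prod(r)^(1/3))
  expected <- apply(k / geo, 2, median)
  expect_equal(unname(size_factors(k)), unname(expected))
  # this fixture doubles column to column, so factors must too
  sf <- size_factors(k)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[3] / sf[1]), 4)
})

test_that("size factors are symmetric, scale-equivariant and permutation-invariant", {
  set.seed(3)
  k <- matrix(rpois(60, 150), 12, 5,
              dimnames = list(paste0("h", 1:12), paste0("s", 1:5)))
  same <- k[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_true(all(abs(size_factors(same) - size_factors(same)[1]) < 1e-12))

  k2 <- k; k2[, 2] <- k[, 1] * 2L
  sf <- size_factors(k2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  perm <- k[sample(nrow(k)), ]
  expect_equal(unname(size_factors(perm)), unname(size_factors(k)))

  expect_error(size_factors(matrix(0L, 3, 2,
                                   dimnames = list(letters[1:3], c("a", "b")))),
               "positive")
})

test_that("dispersion estimation recovers known truth", {
  set.seed(42)
  # Poisson counts: true dispersion 0
  k <- matrix(rpois(200 * 6, 1000), 200, 6,
              dimnames = list(paste0("h", 1:200), paste0("s", 1:6)))
  cond <- rep(c("T0", "T1"), each = 3)
  d <- estimate_dispersions(k, size_factors(k), cond)
  expect_lte(median(d$alpha), 0.05)

  # planted variance mu + 0.1 mu^2 over a range of means
  set.seed(43)
  mu <- 10 ^ runif(500, 1.5, 3.5)
  k2 <- matrix(rnbinom(500 * 6, mu = rep(mu, 6), size = 1 / 0.1), 500, 6,
               dimnames = list(paste0("h", 1:500), paste0("s", 1:6)))
  d2 <- estimate_dispersions(k2, size_factors(k2), cond)
  expect_gte(d2$coef[["a0"]], 0.05)
  expect_lte(d2$coef[["a0"]], 0.2)

  # max rule: a raw estimate below the curve is lifted to the fitted value
  below <- d2$alpha_raw < d2$coef[["a0"]] + d2$coef[["a1"]] / d2$mean
  expect_true(any(below))
  expect_equal(d2$alpha[below],
               (d2$coef[["a0"]] + d2$coef[["a1"]] / d2$mean)[below])

  expect_error(estimate_dispersions(k[, 1:4], size_factors(k[, 1:4]),
                                    c("T0", "T0", "T0", "T1")),
               "blind")
  # blind mode pools all samples and is accepted explicitly
  db <- estimate_dispersions(k[, 1:4], size_factors(k[, 1:4]),
                             c("T0", "T0", "T0", "T1"), method = "blind")
  expect_true(all(db$alpha >= 0))
})

test_that("exact test equals brute-force enumeration (randomized, K <= 200)", {
  set.seed(101)
  for (i in 1:40) {
    n0 <- sample(2:4, 1); n1 <- sample(2:4, 1)
    k0 <- rpois(n0, sample(5:30, 1))
    k1 <- rpois(n1, sample(5:30, 1))
    if (sum(k0) + sum(k1) > 200) next
    sf0 <- runif(n0, 0.5, 2); sf1 <- runif(n1, 0.5, 2)
    a <- sample(c(0, 0.01, 0.1, 1), 1)
    expect_equal(as.numeric(nb_exact_test(k0, k1, sf0, sf1, a)),
                 oracle_nb_p(k0, k1, sf0, sf1, a), tolerance = 1e-12)
  }
})

test_that("exact test handles symmetric, degenerate and small fixed cases", {
  # equal summed counts and equal factors: observed split is modal, p = 1
  p <- nb_exact_test(c(3, 3), c(3, 3), c(1, 1), c(1, 1), 0.1)
  expect_equal(as.numeric(p), 1)

  # K = 0 is flagged degenerate with p = 1
  p0 <- nb_exact_test(c(0, 0), c(0, 0), c(1, 1), c(1, 1), 0.1)
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "degenerate"))

  # 6 vs 0 with equal factors: matches enumeration over the 7 splits of K=6
  expect_equal(as.numeric(nb_exact_test(c(4, 2), c(0, 0),
                                        c(1, 1), c(1, 1), 0.1)),
               oracle_nb_p(c(4, 2), c(0, 0), c(1, 1), c(1, 1), 0.1),
               tolerance = 1e-12)

  # more overdispersion, less significance over the working range
  ps <- vapply(c(0.01, 0.05, 0.1, 0.5, 1), function(a)
    as.numeric(nb_exact_test(c(60, 55, 65), c(30, 35, 25),
                             rep(1, 3), rep(1, 3), a)), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("truncated enumeration above the switch agrees with the full sum", {
  set.seed(5)
  k0 <- rpois(3, 2000); k1 <- rpois(3, 1200)
  for (a in c(0, 0.02, 0.2)) {
    full <- nb_exact_test(k0, k1, rep(1, 3), rep(1, 3), a,
                          enum_limit = 10^7)
    trunc <- nb_exact_test(k0, k1, rep(1, 3), rep(1, 3), a,
                           enum_limit = 100L)
    expect_equal(as.numeric(trunc), as.numeric(full), tolerance = 1e-9)
  }
})

test_that("per-line depletion tables obey fold-change arithmetic and floors", {
  tab <- make_tiny_table(n_hairpins = 30)
  dep <- hairpin_depletion(tab, "A", floor = 0)
  r <- dep$results
  # fc must reproduce (m1 + c) / (m0 + c) with the default pseudocount
  expect_equal(r$fc, (r$mean_T1_norm + 0.5) / (r$mean_T0_norm + 0.5))
  expect_equal(r$log2fc, log2(r$fc))
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  expect_error(hairpin_depletion(tab, "nosuchline"), "unknown")

  # identical T0/T1 columns give fc exactly 1
  k <- matrix(rep(c(100L, 250L), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("h1", "h2"), NULL))
  samples <- data.frame(sample_id = paste0("s", 1:4), cell_line = "A",
                        timepoint = c("T0", "T0", "T1", "T1"),
                        replicate = c(1, 2, 1, 2))
  colnames(k) <- samples$sample_id
  d2 <- hairpin_depletion(count_table(k, samples), "A", floor = 0)
  expect_equal(d2$results$fc, c(1, 1))
  expect_equal(d2$results$log2fc, c(0, 0))

  # complete T1 dropout: fc = (0 + 0.5) / (mean_T0 + 0.5)
  k3 <- k; k3[1, 3:4] <- 0L
  d3 <- hairpin_depletion(count_table(k3, samples), "A", floor = 0)
  i <- d3$results$hairpin_id == "h1"
  expect_equal(d3$results$fc[i],
               0.5 / (d3$results$mean_T0_norm[i] + 0.5))

  # the abundance floor drops weak hairpins and reports them
  k4 <- rbind(k, h3 = c(3L, 4L, 3L, 5L))
  d4 <- hairpin_depletion(count_table(k4, samples), "A", floor = 30)
  expect_true("h3" %in% d4$dropped)
  expect_false("h3" %in% d4$results$hairpin_id)
})

test_that("size factors absorb sequencing-depth rescaling", {
  # multiplying one sample's column by a constant is absorbed by the size
  # factors: normalized fold changes (pseudocount 0) are exactly unchanged
  tab <- make_tiny_table(n_hairpins = 25)
  dep1 <- hairpin_depletion(tab, "A", floor = 0, pseudocount = 0)
  k <- tab$counts
  k[, 1] <- k[, 1] * 3L
  dep2 <- hairpin_depletion(count_table(k, tab$samples), "A",
                            floor = 0, pseudocount = 0)
  expect_equal(dep2$results$fc, dep1$results$fc, tolerance = 1e-12)
  expect_equal(dep2$results$log2fc, dep1$results$log2fc, tolerance = 1e-10)

  # the exact test itself is invariant to a common rescaling of the size
  # factors (the conditioning statistic, being the raw summed counts, is
  # untouched)
  p1 <- nb_exact_test(c(120, 110), c(60, 70), c(1, 1.2), c(0.9, 1.1), 0.05)
  p2 <- nb_exact_test(c(120, 110), c(60, 70), 5 * c(1, 1.2),
                      5 * c(0.9, 1.1), 0.05)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-12)
})

test_that("null p-values are close to uniform or conservative", {
  d <- sim_design(n_lines = 1, genotype = "wildtype", n_genes = 100,
                  coverage = 1000, dispersion = 0.05, seed = 77)
  lib <- simulate_library(d)
  sim <- simulate_screen(lib, d, effect_model(off_target_rate = 0))
  dep <- hairpin_depletion(sim$counts, "LINE01", lib)
  p <- dep$results$p_value
  expect_gte(length(p), 400L)
  ks <- suppressWarnings(ks.test(p, "punif"))
  conservative <- mean(p < 0.05) <= 0.05
  expect_true(unname(ks$statistic) <= 0.1 || conservative)
})
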