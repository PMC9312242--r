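test_that("locus statistics match closed forms on a fully heterozygous locus", {
  g <- toy_genotypes(list(p = matrix("86/90", nrow = 50, ncol = 1)))
  st <- locus_stats(g, hwe_mc = 0)
  expect_equal(st$na, 2L)
  expect_equal(st$ne, 2)
  expect_equal(st$ho, 1)
  expect_equal(st$he, (100 / 99) * 0.5)      # unbiased estimator, n = 50
  expect_equal(st$pic, oracle_pic(c(0.5, 0.5)))
  biased <- locus_stats(g, hwe_mc = 0, he = "biased")
  expect_equal(biased$he, 0.5)
})

test_that("He, Ne and PIC agree with direct-summation oracles", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:20, 1)
    p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
    expect_equal(pic(p), oracle_pic(p), tolerance = 1e-12)
    s2 <- sum(p^2)
    expect_equal(1 / s2, 1 / sum(vapply(p, function(x) x * x, 1)),
                 tolerance = 1e-12)
  }
  # k equifrequent alleles have the closed form 1 - 1/k - (k-1)/k^3
  for (k in 2:12) {
    p <- rep(1 / k, k)
    expect_equal(pic(p), 1 - 1 / k - (k - 1) / k^3, tolerance = 1e-12)
  }
  expect_equal(pic(1), 0)
  expect_error(pic(c(-0.1, 1.1)), "negative")
})

test_that("the unbiased-He identity holds on every computed locus", {
  sim <- simulate_genotypes(island_model_spec(), seed = 77)
  st <- locus_stats(sim$genotypes, hwe_mc = 0)
  expect_true(all(abs(st$he - (2 * st$n / (2 * st$n - 1)) * (1 - 1 / st$ne))
                  < 1e-9))
  # algebraic bounds: PIC never exceeds the biased gene diversity 1 - 1/Ne
  expect_true(all(st$pic <= 1 - 1 / st$ne + 1e-12))
  expect_true(all(st$ho >= 0 & st$ho <= 1 & st$he >= 0 & st$he <= 1))
  expect_true(all(st$ne <= st$na + 1e-12))
})

test_that("statistics are invariant under allele relabelling", {
  g <- toy_genotypes(list(p = rbind("86/90", "86/86", "90/94", "94/94")))
  relab <- toy_genotypes(list(p = rbind("201/105", "201/201", "105/309",
                                        "309/309")))
  s1 <- locus_stats(g, hwe_mc = 500, seed = 9)
  s2 <- locus_stats(relab, hwe_mc = 500, seed = 9)
  expect_equal(s1[, c("na", "ne", "ho", "he", "pic", "p_hwe")],
               s2[, c("na", "ne", "ho", "he", "pic", "p_hwe")])
})

test_that("adding a singleton allele raises Na and lowers homozygosity", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    alleles <- sample(4:8, 1)
    a1 <- sample(seq_len(alleles), n, replace = TRUE)
    a2 <- sample(seq_len(alleles), n, replace = TRUE)
    g0 <- genotype_matrix(matrix(a1, ncol = 1), matrix(a2, ncol = 1),
                          pop = rep("p", n))
    g1 <- genotype_matrix(matrix(c(a1, 99L), ncol = 1),
                          matrix(c(a2, 99L), ncol = 1),
                          pop = rep("p", n + 1))
    s0 <- locus_stats(g0, hwe_mc = 0)
    s1 <- locus_stats(g1, hwe_mc = 0)
    expect_equal(s1$na, s0$na + 1L)
    expect_lt(1 / s1$ne, 1 / s0$ne)      # sum(p^2) strictly decreases
  }
})

test_that("PIC classification bands are left-inclusive", {
  expect_equal(as.character(classify_pic(c(0.901, 0.25, 0.5, 0.249, 0))),
               c("high", "moderate", "high", "low", "low"))
  expect_error(classify_pic(1.2), "\\[0, 1\\)")
})

test_that("the HWE exact test behaves at both extremes", {
  # genotype counts at exact Hardy-Weinberg proportions: the modal table
  a1 <- c(rep(1, 25), rep(1, 50), rep(2, 25))
  a2 <- c(rep(1, 25), rep(2, 50), rep(2, 25))
  expect_gte(hwe_exact_test(a1, a2, n_mc = 2000, seed = 1), 0.9)
  # complete heterozygote deficit
  b <- c(rep(1, 50), rep(2, 50))
  expect_lt(hwe_exact_test(b, b, n_mc = 10000, seed = 2), 0.001)
  # monomorphic convention and configuration guard
  expect_equal(hwe_exact_test(rep(1, 10), rep(1, 10)), 1)
  expect_error(hwe_exact_test(a1, a2, n_mc = 50), "at least 100")
})

test_that("Monte-Carlo HWE p-values track full enumeration on small tables", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    a1 <- sample(1:2, n, replace = TRUE)
    a2 <- sample(1:2, n, replace = TRUE)
    if (length(unique(c(a1, a2))) < 2) next
    exact <- oracle_hwe_biallelic(a1, a2)
    mc <- hwe_exact_test(a1, a2, n_mc = 20000, seed = i)
    expect_lt(abs(mc - exact), 0.02)
  }
})

test_that("Nei's distance is zero for identical tables and infinite for disjoint ones", {
  g <- toy_genotypes(list(
    x = rbind(c("86/90", "100/104"), c("86/86", "104/104")),
    y = rbind(c("86/90", "100/104"), c("86/86", "104/104"))))
  fx <- allele_freqs(g, "x"); fy <- allele_freqs(g, "y")
  expect_equal(nei_distance(fx, fy), 0)
  expect_equal(nei_distance(fx, fx), 0)
  disjoint <- toy_genotypes(list(
    x = rbind(c("86/86", "100/100")),
    y = rbind(c("94/94", "112/112"))))
  d <- nei_distance(allele_freqs(disjoint, "x"), allele_freqs(disjoint, "y"))
  expect_true(is.infinite(d))
  expect_true(isTRUE(attr(d, "no_shared_alleles")))
})

test_that("Nei's distance matches a hand-computed two-locus example", {
  # pop x: locus1 p(86)=0.75, p(90)=0.25 ; locus2 p(100)=0.5, p(104)=0.5
  # pop y: locus1 p(86)=0.25, p(90)=0.75 ; locus2 p(100)=1.0
  g <- toy_genotypes(list(
    x = rbind(c("86/86", "100/100"), c("86/90", "104/104")),
    y = rbind(c("90/90", "100/100"), c("86/90", "100/100"))))
  jxy <- mean(c(0.75 * 0.25 + 0.25 * 0.75, 0.5 * 1.0 + 0.5 * 0.0))
  jx <- mean(c(0.75^2 + 0.25^2, 0.5^2 + 0.5^2))
  jy <- mean(c(0.25^2 + 0.75^2, 1.0))
  expect_equal(nei_distance(allele_freqs(g, "x"), allele_freqs(g, "y")),
               -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
  m <- nei_distance_matrix(g)
  expect_equal(m["x", "y"], m["y", "x"])
  expect_equal(diag(m), c(x = 0, y = 0))
})

test_that("population aggregation averages loci and counts departures", {
  st <- data.frame(na = c(4, 6), ne = c(2, 3), ho = c(0.4, 0.6),
                   he = c(0.5, 0.7), pic = c(0.45, 0.62),
                   p_hwe = c(0.01, 0.2))
  agg <- aggregate_population_stats(st, alpha = 0.05)
  expect_equal(agg$total_na, 10)
  expect_equal(agg$mean_pic, 0.535)
  expect_equal(agg$n_pic_high, 1L)
  expect_equal(agg$n_hwe_departures, 1L)
  # sequential Bonferroni can only reduce the departure count
  agg_holm <- aggregate_population_stats(st, alpha = 0.05, p_adjust = "holm")
  expect_lte(agg_holm$n_hwe_departures, agg$n_hwe_departures)
  # single locus: the mean is the locus value
  one <- aggregate_population_stats(st[1, ])
  expect_equal(one$mean_na, 4)
})
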