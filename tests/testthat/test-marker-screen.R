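test_that("nearest-neighbor Tm matches independently summed reference values", {
  # frozen from an independent nearest-neighbor summation (unified SantaLucia
  # table, 50 mM Na+, 250 nM total strand, CT/4)
  expect_equal(melting_temp("GCTAATGCCTGACCACCACT"), 56.4, tolerance = 1e-8)
  expect_equal(melting_temp("CAGGTCCCTGGAGAAGAGAGA"), 56.2, tolerance = 1e-8)
  expect_equal(melting_temp("AAAAAAAATTTTTTTTTT"), 34.7, tolerance = 1e-8)
  expect_equal(melting_temp("GGGGCCCCGGGGCCCCGGGG"), 75.1, tolerance = 1e-8)
  expect_equal(melting_temp("ATGCATGCATGCAT"), 43.7, tolerance = 1e-8)
  # self-complementary oligo takes the symmetry correction
  expect_equal(melting_temp("ACGTACGTACGTACGTACGT"), 55.2, tolerance = 1e-8)
})

test_that("Tm is a duplex property: both strands give the same value", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(15:28, 1))
    expect_equal(melting_temp(s), melting_temp(revcomp(s)))
  }
})

test_that("Tm input validation and the Wallace alternative", {
  expect_error(melting_temp("ACGTACG"), "shorter")
  expect_error(melting_temp("ACGTACGTN"), "non-ACGT")
  expect_equal(melting_temp("AATTGGCC", method = "wallace"), 2 * 4 + 4 * 4)
})

test_that("the published marker panel passes its own screening windows", {
  panel <- perca_marker_panel()
  lens <- nchar(c(panel$forward, panel$reverse))
  expect_true(all(lens >= 18 & lens <= 30))
  # amplified fragments were sized 86-265 bp, inside the 50-500 product window
  expect_true(all(panel$size_min >= 50 & panel$size_max <= 500))
  report <- screen_primer_table(panel, constraints = screen_constraints())
  expect_true(all(report$primer_len_ok))
  expect_true(all(report$product_len_ok))
  # the development windows accept the first panel primer's Tm
  tm <- melting_temp(panel$forward[panel$locus == "HLJHL007"])
  expect_gte(tm, 52); expect_lte(tm, 65)
})

test_that("violations are enumerated, not short-circuited", {
  r <- screen_primer_pair("ACGTACGTAC", "ACGTACGTAC", product_len = 600)
  expect_false(r$pass)
  expect_true(all(c("primer_len", "product_len") %in% r$violations))
  ok <- screen_primer_pair("GCTAATGCCTGACCACCACT", "CAGGTCCCTGGAGAAGAGAGA",
                           product_len = 120)
  expect_true(ok$pass)
  expect_length(ok$violations, 0)
})

test_that("widening any window never turns a pass into a fail", {
  set.seed(5)
  for (i in 1:15) {
    f <- random_dna(sample(12:32, 1)); r <- random_dna(sample(12:32, 1))
    prod <- sample(40:700, 1)
    narrow <- screen_primer_pair(f, r, prod, screen_constraints())
    wide <- screen_primer_pair(f, r, prod,
                               screen_constraints(product_len = c(10, 1000),
                                                  primer_len = c(10, 40),
                                                  tm = c(20, 95)))
    if (narrow$pass) expect_true(wide$pass)
  }
})

test_that("flank extraction slices coordinates exactly", {
  genome <- c(chrA = paste0(strrep("G", 100), strrep("ACAG", 10),
                            strrep("T", 100)))
  locus <- list(seq_id = "chrA", start = 100L, end = 140L)
  fl <- extract_flanks(genome, locus, 50)
  expect_equal(fl$left, strrep("G", 50))
  expect_equal(fl$tract, strrep("ACAG", 10))
  expect_equal(fl$right, strrep("T", 50))
  expect_equal(paste0(fl$left, fl$tract, fl$right),
               substr(genome[[1]], 51, 190))
  # truncation at the sequence start is silent, with lengths reported
  fl0 <- extract_flanks(genome, list(seq_id = "chrA", start = 0L, end = 8L), 30)
  expect_equal(fl0$left, "")
  expect_equal(fl0$left_len, 0L)
  expect_error(extract_flanks(genome, list(seq_id = "nope", start = 0, end = 4),
                              10), "not found")
})

test_that("in-silico PCR finds planted amplicons exactly", {
  fwd <- "GCTAATGCCTGACCACCACT"; rev <- "CAGGTCCCTGGAGAAGAGAGA"
  sim <- simulate_genome(planted_genome_spec(
    length = 3000L,
    amplicons = data.frame(forward = fwd, reverse = rev, product_len = 150)),
    seed = 3)
  hits <- in_silico_pcr(sim$sequences, fwd, rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_len, 150L)
  expect_equal(hits$start, sim$amplicon_truth$start)
  product <- substr(sim$sequences[[hits$seq_id]], hits$start + 1, hits$end)
  expect_true(startsWith(product, fwd))
  expect_true(endsWith(product, revcomp(rev)))
  # absent primer: no product
  expect_equal(nrow(in_silico_pcr(sim$sequences, "ACGTACGTACGTACGTAT", rev)),
               0L)
  # two planted sites give two products
  sim2 <- simulate_genome(planted_genome_spec(
    length = 4000L,
    amplicons = data.frame(forward = fwd, reverse = rev,
                           product_len = c(150, 220))), seed = 4)
  expect_equal(nrow(in_silico_pcr(sim2$sequences, fwd, rev,
                                  max_product = 300L)), 2L)
})
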