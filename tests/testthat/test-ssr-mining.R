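test_that("canonical_motif picks the smallest rotation of either strand", {
  # AC class absorbs its rotations and complements; derived cases were
  # frozen from brute-force enumeration over rotations of both strands
  expect_identical(canonical_motif("GT"), "AC")
  expect_identical(canonical_motif("AC"), "AC")
  expect_identical(canonical_motif("TC"), "AG")
  expect_identical(canonical_motif("GATA"), "AGAT")
  expect_identical(canonical_motif(c("CA", "TG")), c("AC", "AC"))
  # idempotent
  motifs <- c("ACAG", "AGAT", "AAAAT", "CG", "ATT")
  expect_identical(canonical_motif(canonical_motif(motifs)),
                   canonical_motif(motifs))
  expect_error(canonical_motif("ACGN"), "non-ACGT")
  expect_error(canonical_motif("ACGTACG"), "length")
})

test_that("canonicalization partitions dinucleotides into the four classes", {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  dinucs <- dinucs[!dinucs %in% c("AA", "CC", "GG", "TT")]
  expect_setequal(unique(canonical_motif(dinucs)), c("AC", "AG", "AT", "CG"))
  # the published tetranucleotide motif labels are already canonical
  tetra <- perca_tetra_motif_counts()$motif
  expect_identical(canonical_motif(tetra), tetra)
  expect_lte(length(unique(canonical_motif(tetra))), 33L)
})

test_that("find_ssrs recovers a planted tract and honours boundaries", {
  s <- paste0("GGTCC", strrep("ACAG", 20), "TTCAA")
  hit <- find_ssrs(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 85L)
  expect_equal(hit$period, 4L)
  expect_equal(hit$canonical_motif, "ACAG")
  expect_equal(hit$n_repeats, 20L)
  expect_equal(hit$tract_length, hit$period * hit$n_repeats)

  expect_equal(nrow(find_ssrs("")), 0L)
  # N terminates a run
  expect_equal(nrow(find_ssrs(paste0(strrep("AT", 3), "N", strrep("AT", 3)))),
               0L)
  expect_equal(find_ssrs(strrep("at", 6))$n_repeats, 6L)  # soft-masked input
})

test_that("one tract is reported once, under its smallest period", {
  # (AT)6 is also (ATAT)3 but only the period-2 record is emitted
  hit <- find_ssrs(paste0("GCC", strrep("AT", 6), "GCC"))
  expect_equal(hit$period, 2L)
  expect_equal(hit$n_repeats, 6L)
  # thresholds are configurable: demand 7 copies and the tract disappears
  expect_equal(nrow(find_ssrs(paste0("GCC", strrep("AT", 6), "GCC"),
                              thresholds = ssr_thresholds(di = 7))), 0L)
})

test_that("find_ssrs agrees with the naive scanning oracle", {
  set.seed(421)
  for (rep in 1:10) {
    spec <- planted_genome_spec(
      length = 2000L,
      ssrs = data.frame(motif = c("AC", "ATT", "ACAG", "AGAT", "AATGC"),
                        n_repeats = c(7, 5, 6, 12, 3)))
    sim <- simulate_genome(spec)
    got <- find_ssrs(sim$sequences[[1]])
    want <- oracle_find_ssrs(sim$sequences[[1]])
    expect_equal(got[, c("start", "end", "period", "motif", "n_repeats")],
                 want, ignore_attr = TRUE)
    # every planted tract is among the detected loci
    expect_true(all(paste(sim$ssr_truth$start, sim$ssr_truth$end) %in%
                      paste(got$start, got$end)))
  }
})

test_that("reported loci are maximal", {
  set.seed(99)
  s <- simulate_genome(planted_genome_spec(
    length = 3000L,
    ssrs = data.frame(motif = c("AG", "AGAT"), n_repeats = c(9, 8))))$sequences[[1]]
  hits <- find_ssrs(s)
  for (i in seq_len(nrow(hits))) {
    p <- hits$period[i]; st <- hits$start[i]; en <- hits$end[i]
    motif <- hits$motif[i]
    if (st - p >= 0)
      expect_false(substr(s, st - p + 1, st) == motif)
    if (en + p <= nchar(s))
      expect_false(substr(s, en + 1, en + p) == substr(s, en - p + 1, en))
  }
})

test_that("motif summaries conserve counts and normalize within period class", {
  set.seed(7)
  sim <- simulate_genome(planted_genome_spec(
    length = 4000L,
    ssrs = data.frame(motif = c("AC", "AC", "AG", "AGAT", "ACAG", "AATGC"),
                      n_repeats = c(6, 8, 7, 5, 5, 3))))
  loci <- find_ssrs(sim$sequences[[1]])
  sm <- summarize_ssrs(loci)
  expect_equal(sum(sm$count), nrow(loci))
  for (p in unique(sm$period))
    expect_equal(sum(sm$prop_period[sm$period == p]), 1, tolerance = 1e-9)
  expect_equal(sum(sm$prop_total), 1, tolerance = 1e-9)
  # single locus degenerates to proportion 1
  one <- summarize_ssrs(loci[1, ])
  expect_equal(one$prop_period, 1)
})

test_that("mining a multi-record FASTA file tags hits with their record", {
  sim <- simulate_genome(planted_genome_spec(
    n_sequences = 2L, length = 1200L,
    ssrs = data.frame(motif = c("ACAG", "AGAT"), n_repeats = c(8, 9))),
    seed = 17)
  fa <- tempfile(fileext = ".fa")
  write_fasta(sim$sequences, fa)
  expect_identical(read_fasta(fa), sim$sequences)
  hits <- find_ssrs_fasta(fa)
  key <- function(d) paste(d$seq_id, d$start, d$end)
  expect_true(all(key(sim$ssr_truth) %in% key(hits)))
})

test_that("ssr tables round-trip through TSV with 1-based starts", {
  loci <- find_ssrs(paste0("GG", strrep("AGAT", 6), "CC"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ssr_table(loci, path)
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(back$start, loci$start + 1L)
  expect_equal(back$end, loci$end)
})
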