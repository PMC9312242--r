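#' Round half away from zero
#'
#' Table-style rounding (0.0745 -> 0.075) used when mirroring published
#' 3-decimal tables; R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Botstein polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed through the
#' algebraic identity `sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4`.
#' Invariant under permutation of alleles; 0 for a monomorphic locus.
#'
#' @param p Numeric vector of allele frequencies summing to 1 (tolerance
#'   1e-9 relative).
#' @return PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("negative allele frequency")
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Classify a PIC value into polymorphism bands
#'
#' Botstein's bands: `high` for PIC >= 0.5, `moderate` for 0.25 <= PIC < 0.5,
#' `low` below 0.25 (boundaries left-inclusive).
#'
#' @param x Numeric vector of PIC values in `[0, 1)`.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
classify_pic <- function(x) {
  if (any(x < 0 | x >= 1)) stop("PIC must lie in [0, 1)")
  cut(x, breaks = c(-Inf, 0.25, 0.5, Inf), right = FALSE,
      labels = c("low", "moderate", "high"))
}

# log conditional probability (up to a constant fixed by the allele counts)
# of a diploid genotype table: H * log 2 - sum(log n_ij!)
.log_table_weight <- function(i1, i2, k) {
  het <- sum(i1 != i2)
  code <- (pmin.int(i1, i2) - 1L) * k + pmax.int(i1, i2)
  cnt <- tabulate(code, nbins = k * k)
  het * log(2) - sum(lgamma(cnt + 1))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Guo-Thompson style test: conditioning on the observed allele counts, the
#' allele pool is randomly re-paired into diploid genotypes `n_mc` times and
#' the p-value is the proportion of tables (the observed table included in
#' numerator and denominator) whose conditional probability is less than or
#' equal to that of the observed table. Suited to multiallelic
#' microsatellites where chi-square cells are sparse.
#'
#' @param a1,a2 Integer vectors of the two allele copies per individual
#'   (missing calls `NA` in both are dropped).
#' @param n_mc Number of Monte-Carlo tables (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return p-value in `(0, 1]`; 1 by convention for a monomorphic locus.
#' @export
hwe_exact_test <- function(a1, a2, n_mc = 10000L, seed = NULL) {
  if (n_mc < 100L) stop("n_mc must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 2L) stop("need at least 2 non-missing genotypes")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) return(1)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  obs <- .log_table_weight(i1, i2, k)
  pool <- c(i1, i2)
  m2 <- 2L * n
  count <- 0L
  for (b in seq_len(n_mc)) {
    perm <- pool[sample.int(m2)]
    s1 <- perm[seq_len(n)]; s2 <- perm[n + seq_len(n)]
    if (.log_table_weight(s1, s2, k) <= obs + 1e-9) count <- count + 1L
  }
  (count + 1) / (n_mc + 1)
}

#' Per-locus diversity statistics
#'
#' For each locus, over one population or the pooled sample: the observed
#' allele number `Na`; the effective allele number `Ne = 1 / sum(p^2)`
#' (Kimura-Crow); the observed heterozygosity `Ho` (fraction of non-missing
#' genotypes carrying two distinct alleles); the expected heterozygosity `He`,
#' by default Nei's unbiased estimator `(2n/(2n-1)) (1 - sum p^2)`; the
#' Botstein [pic()]; and the Monte-Carlo exact Hardy-Weinberg p-value. Sample
#' size `n` is complete-case per locus.
#'
#' @param g A [genotype_matrix()].
#' @param pool Population label or `"ALL"` (pooled).
#' @param he `"unbiased"` (default) or `"biased"` (`1 - sum p^2`).
#' @param hwe_mc Monte-Carlo tables for the HWE test; set to 0 to skip
#'   (p_hwe column becomes `NA`).
#' @param seed Optional seed for the HWE resampling.
#' @return Data frame (class `locus_stats`) with columns `locus`, `n`, `na`,
#'   `ne`, `ho`, `he`, `pic`, `p_hwe`. Loci with no non-missing calls are
#'   dropped with a warning.
#' @export
locus_stats <- function(g, pool = "ALL", he = c("unbiased", "biased"),
                        hwe_mc = 10000L, seed = NULL) {
  he <- match.arg(he)
  if (!is.null(seed)) set.seed(seed)
  if (!identical(pool, "ALL")) {
    g <- subset_populations(g, pool)
  }
  fr <- allele_freqs(g, "ALL")
  empty <- vapply(fr, function(f) f$n == 0L, logical(1))
  if (any(empty))
    warning("dropping ", sum(empty), " locus/loci with no non-missing calls")
  rows <- lapply(which(!empty), function(l) {
    f <- fr[[l]]
    p <- as.vector(f$freq)
    s2 <- sum(p^2)
    ne <- 1 / s2
    n <- f$n
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    ok <- !is.na(a1)
    ho <- mean(a1[ok] != a2[ok])
    he_val <- if (he == "unbiased") (2 * n / (2 * n - 1)) * (1 - s2) else 1 - s2
    p_hwe <- if (hwe_mc >= 100L)
      hwe_exact_test(a1, a2, n_mc = hwe_mc) else NA_real_
    data.frame(locus = g$loci[l], n = n, na = length(p), ne = ne, ho = ho,
               he = he_val, pic = pic(p), p_hwe = p_hwe,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Aggregate per-locus statistics into a population summary
#'
#' Arithmetic means of Na, Ne, Ho, He and PIC over loci, the total allele
#' count, the number of loci classified highly polymorphic (PIC >= 0.5), and
#' the number of loci departing from Hardy-Weinberg proportions at `alpha`
#' after the configured multiple-testing adjustment.
#'
#' @param stats A `locus_stats` data frame (columns `na`, `ne`, `ho`, `he`,
#'   `pic`, optionally `p_hwe`).
#' @param alpha Significance level for HWE departures.
#' @param p_adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"none"`, i.e. per-locus uncorrected; `"holm"` gives sequential
#'   Bonferroni).
#' @return One-row data frame with `n_loci`, `total_na`, `mean_na`, `mean_ne`,
#'   `mean_ho`, `mean_he`, `mean_pic`, `n_pic_high`, `n_hwe_departures`.
#' @export
aggregate_population_stats <- function(stats, alpha = 0.05,
                                       p_adjust = "none") {
  hwe_dep <- if ("p_hwe" %in% names(stats) && !all(is.na(stats$p_hwe))) {
    sum(stats::p.adjust(stats$p_hwe, method = p_adjust) < alpha, na.rm = TRUE)
  } else NA_integer_
  data.frame(n_loci = nrow(stats),
             total_na = sum(stats$na),
             mean_na = mean(stats$na),
             mean_ne = mean(stats$ne),
             mean_ho = mean(stats$ho),
             mean_he = mean(stats$he),
             mean_pic = mean(stats$pic),
             n_pic_high = sum(classify_pic(stats$pic) == "high"),
             n_hwe_departures = hwe_dep)
}

#' Per-population summaries of diversity statistics
#'
#' Runs [locus_stats()] within each population and aggregates with
#' [aggregate_population_stats()].
#'
#' @param g A [genotype_matrix()].
#' @param ... Passed to [locus_stats()].
#' @param alpha,p_adjust Passed to [aggregate_population_stats()].
#' @return Data frame with one row per population.
#' @export
population_stats <- function(g, ..., alpha = 0.05, p_adjust = "none") {
  rows <- lapply(levels(g$pop), function(p) {
    st <- locus_stats(g, pool = p, ...)
    cbind(data.frame(population = p),
          aggregate_population_stats(st, alpha = alpha, p_adjust = p_adjust))
  })
  do.call(rbind, rows)
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx Jy) )`, where `Jxy` is the mean over loci of the
#' probability of allele identity between the two populations
#' (`sum_i p_xi p_yi`), and `Jx`, `Jy` are the mean within-population
#' identities (`sum p^2`). Means are taken across loci first and the log is
#' applied once. Zero for identical frequency tables; `Inf` (flagged) when
#' the populations share no alleles at any locus.
#'
#' @param fx,fy `allele_freqs` objects for the two populations over the same
#'   loci (loci with data in both are used).
#' @return Nonnegative distance (possibly `Inf`).
#' @export
nei_distance <- function(fx, fy) {
  loci <- intersect(names(fx), names(fy))
  if (length(loci) == 0L) stop("no shared loci")
  jxy <- jx <- jy <- numeric(0)
  for (l in loci) {
    ex <- fx[[l]]; ey <- fy[[l]]
    if (ex$n == 0L || ey$n == 0L) next
    alleles <- union(names(ex$freq), names(ey$freq))
    px <- ifelse(alleles %in% names(ex$freq), ex$freq[alleles], 0)
    py <- ifelse(alleles %in% names(ey$freq), ey$freq[alleles], 0)
    jxy <- c(jxy, sum(px * py))
    jx <- c(jx, sum(px^2))
    jy <- c(jy, sum(py^2))
  }
  if (length(jxy) == 0L) stop("no locus with data in both populations")
  i_xy <- mean(jxy)
  if (i_xy == 0) {
    res <- Inf
    attr(res, "no_shared_alleles") <- TRUE
    return(res)
  }
  -log(i_xy / sqrt(mean(jx) * mean(jy)))
}

#' Pairwise Nei distance matrix between populations
#'
#' @param g A [genotype_matrix()].
#' @return Symmetric labelled matrix of Nei's standard distances.
#' @export
nei_distance_matrix <- function(g) {
  pops <- levels(g$pop)
  fr <- lapply(pops, function(p) allele_freqs(g, p))
  names(fr) <- pops
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- nei_distance(fr[[i]], fr[[j]])
  }
  d
}
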