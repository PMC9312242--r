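#' Squared inter-individual genetic distances for codominant genotypes
#'
#' Distance between two diploid multilocus genotypes is the number of allele
#' differences summed over loci (0, 1 or 2 per locus: the count of allele
#' copies that cannot be matched between the two genotypes). Loci missing in
#' either individual are skipped pairwise. These counts serve directly as the
#' squared distances of the molecular variance decomposition.
#'
#' @param g A [genotype_matrix()].
#' @return An `n x n` symmetric numeric matrix of squared distances.
#' @export
genotype_distance_matrix <- function(g) {
  n <- n_individuals(g)
  D <- matrix(0, n, n)
  for (l in seq_len(n_loci(g))) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    miss <- is.na(a1)
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) == 0L) next
    C <- matrix(0L, n, length(alleles))
    ok <- which(!miss)
    C[cbind(ok, match(a1[ok], alleles))] <-
      C[cbind(ok, match(a1[ok], alleles))] + 1L
    C[cbind(ok, match(a2[ok], alleles))] <-
      C[cbind(ok, match(a2[ok], alleles))] + 1L
    Dl <- as.matrix(stats::dist(C, method = "manhattan")) / 2
    if (any(miss)) { Dl[miss, ] <- 0; Dl[, miss] <- 0 }
    D <- D + Dl
  }
  dimnames(D) <- list(g$ind, g$ind)
  D
}

# squared distances between the 2N allele copies: rows 1..N are the first
# copy of each individual, rows N+1..2N the second; copies of one individual
# stay adjacent under any individual permutation
.copy_distance_matrix <- function(g) {
  V <- rbind(g$a1, g$a2)
  M <- nrow(V)
  D <- matrix(0, M, M)
  for (l in seq_len(ncol(V))) {
    v <- V[, l]
    Dl <- outer(v, v, "!=") * 1
    Dl[is.na(Dl)] <- 0          # missing loci skipped pairwise
    D <- D + Dl
  }
  D
}

# sum over groups of within-group squared distances / group size, from a
# full symmetric distance matrix over allele copies; idx_of[[p]] gives the
# individual rows of population p and copies live at idx and idx + N
.ss_within_copies <- function(D, idx_of, N) {
  s <- 0
  for (idx in idx_of) {
    rows <- c(idx, idx + N)
    s <- s + sum(D[rows, rows]) / 2 / length(rows)
  }
  s
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style AMOVA on the allele mismatch distances among the `2N`
#' gene copies of a codominant diploid dataset: the squared distance between
#' two copies is the number of loci at which their alleles differ (loci
#' missing in either copy are skipped pairwise). With `P` populations holding
#' `m_k = 2 N_k` copies out of `m = 2N`:
#' `SS_total = sum_{a<b} d2_ab / m`, `SS_within = sum_k sum_{a<b in k}
#' d2_ab / m_k`, variance components `sigma2_w = SS_within / (m - P)` and
#' `sigma2_a = (SS_among / (P - 1) - sigma2_w) / n'` with the unequal-size
#' coefficient `n' = (m - sum(m_k^2)/m) / (P - 1)`; `Fst = sigma2_a /
#' (sigma2_a + sigma2_w)`. Significance comes from permuting whole
#' individuals among populations (sizes preserved, the two copies of an
#' individual moving together) and counting permuted Fst greater than or
#' equal to the observed, with the `(b + 1)/(m + 1)` correction. A negative
#' among-population component is reported as-is with a warning.
#'
#' @param g A [genotype_matrix()] with at least two populations.
#' @param n_perm Number of label permutations for the p-value (0 skips it).
#' @param seed Optional integer seed.
#' @return An `amova` object: list with `df`, `ss`, `variance_components`,
#'   `pct_variation`, `fst`, `p_value`, `n_permutations`, `seed`, `n_prime`.
#' @export
amova <- function(g, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- droplevels(g$pop)
  P <- nlevels(pop)
  if (P < 2L) stop("AMOVA needs at least two populations")
  N <- n_individuals(g)
  M <- 2L * N
  mk <- 2L * tabulate(pop)
  D <- .copy_distance_matrix(g)
  idx_of <- split(seq_len(N), pop)
  ss_total <- sum(D) / 2 / M
  ss_within <- .ss_within_copies(D, idx_of, N)
  ss_among <- ss_total - ss_within
  df_among <- P - 1L
  df_within <- M - P
  s2_w <- ss_within / df_within
  n_prime <- (M - sum(mk^2) / M) / (P - 1)
  s2_a <- (ss_among / df_among - s2_w) / n_prime
  if (s2_a < 0)
    warning("negative among-population variance component (", signif(s2_a, 3),
            "); reported as-is")
  s2_t <- s2_a + s2_w
  fst <- if (s2_t > 0) s2_a / s2_t else NA_real_
  p_value <- NA_real_
  if (n_perm > 0L) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx_b <- split(sample.int(N), pop)
      ssw_b <- .ss_within_copies(D, idx_b, N)
      s2w_b <- ssw_b / df_within
      s2a_b <- ((ss_total - ssw_b) / df_among - s2w_b) / n_prime
      fst_b <- s2a_b / (s2a_b + s2w_b)
      if (fst_b >= fst - 1e-12) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_perm + 1)
  }
  structure(list(
    df = c(among = df_among, within = df_within, total = M - 1L),
    ss = c(among = ss_among, within = ss_within, total = ss_total),
    variance_components = c(among = s2_a, within = s2_w, total = s2_t),
    pct_variation = c(among = 100 * s2_a / s2_t, within = 100 * s2_w / s2_t),
    fst = fst, p_value = p_value, n_permutations = as.integer(n_perm),
    seed = seed, n_prime = n_prime), class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  tab <- data.frame(
    df = x$df,
    SS = round_half_up(x$ss, digits),
    variance = round_half_up(c(x$variance_components), digits),
    pct = c(round_half_up(x$pct_variation, 2), NA))
  rownames(tab) <- c("Among populations", "Within populations", "Total")
  print(tab, ...)
  cat(sprintf("Fst = %s (%s), permutation p = %s (%d permutations)\n",
              format(round_half_up(x$fst, digits)), classify_fst(max(x$fst, 0)),
              format(x$p_value), x$n_permutations))
  invisible(x)
}

#' Percentages of variation and Fst from printed variance components
#'
#' Exposed separately so a published AMOVA table can be checked without the
#' underlying genotypes: `pct_among = 100 sigma2_a / (sigma2_a + sigma2_w)`
#' and `Fst = sigma2_a / (sigma2_a + sigma2_w)`.
#'
#' @param var_among,var_within Variance components (within must be > 0).
#' @return List with `pct_among`, `pct_within`, `fst` (unrounded).
#' @examples
#' pct_from_components(0.784, 9.752)
#' @export
pct_from_components <- function(var_among, var_within) {
  if (var_within <= 0 && var_among <= 0) stop("undefined: both components <= 0")
  if (var_within <= 0) stop("var_within must be positive")
  tot <- var_among + var_within
  list(pct_among = 100 * var_among / tot,
       pct_within = 100 * var_within / tot,
       fst = var_among / tot)
}

#' Wright's genetic differentiation bands
#'
#' `[0, 0.05)` low, `[0.05, 0.15)` moderate, `[0.15, 0.25)` high, `>= 0.25`
#' very high (left-inclusive boundaries).
#'
#' @param fst Numeric vector of fixation indices (negative estimates are
#'   floored at 0 for classification).
#' @return Factor with levels `low`, `moderate`, `high`, `very high`.
#' @export
classify_fst <- function(fst) {
  cut(pmax(fst, 0), breaks = c(-Inf, 0.05, 0.15, 0.25, Inf), right = FALSE,
      labels = c("low", "moderate", "high", "very high"))
}

#' Pairwise Fst matrix with permutation tests
#'
#' Each population pair is analysed as a two-population [amova()]. Pairs in
#' which a population has fewer than two individuals are flagged unreliable
#' (`NA` entries).
#'
#' @param g A [genotype_matrix()].
#' @param n_perm Permutations per pair.
#' @param seed Optional integer seed.
#' @param alpha Significance level for the `significant` flags.
#' @return A `pairwise_fst` object: list of symmetric matrices `fst` and
#'   `p_value`, logical matrix `significant`, and `alpha`.
#' @export
pairwise_fst <- function(g, n_perm = 1000L, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(g$pop)
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  diag(m) <- 0
  pmat <- m; diag(pmat) <- NA
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    sub <- subset_populations(g, c(pops[i], pops[j]))
    if (min(tabulate(sub$pop)) < 2L) next   # flagged unreliable: stays NA
    a <- amova(sub, n_perm = n_perm)
    m[i, j] <- m[j, i] <- a$fst
    pmat[i, j] <- pmat[j, i] <- a$p_value
  }
  structure(list(fst = m, p_value = pmat, significant = pmat < alpha,
                 alpha = alpha, n_permutations = as.integer(n_perm)),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat("Pairwise Fst (permutation p in parentheses; * p <", x$alpha, ")\n")
  m <- round_half_up(x$fst, digits)
  star <- ifelse(!is.na(x$significant) & x$significant, "*", "")
  out <- matrix(paste0(format(m), star), nrow(m), dimnames = dimnames(m))
  diag(out) <- "-"
  print(out, quote = FALSE, ...)
  invisible(x)
}
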