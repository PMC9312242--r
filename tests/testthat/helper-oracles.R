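# Independent brute-force oracles used to freeze expected values.
# These deliberately use naive algorithms, not the package's code paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

oracle_primitive <- function(m) {
  p <- nchar(m)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && m == strrep(substr(m, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

# naive O(n * period * copies) scan over every start position and period
oracle_find_ssrs <- function(s, thresholds = c("2" = 5, "3" = 4, "4" = 3, "5" = 2)) {
  s <- toupper(s)
  n <- nchar(s)
  rows <- list()
  for (p in as.integer(names(thresholds))) {
    tmin <- thresholds[[as.character(p)]]
    i <- 1L
    while (i + p - 1L <= n) {
      motif <- substr(s, i, i + p - 1L)
      if (grepl("[^ACGT]", motif)) { i <- i + 1L; next }
      r <- 1L
      while (i + (r + 1L) * p - 1L <= n &&
             substr(s, i + r * p, i + (r + 1L) * p - 1L) == motif) r <- r + 1L
      leftmost <- i == 1L ||
        substr(s, i - 1L, i - 1L) != substr(s, i + p - 1L, i + p - 1L)
      if (r >= tmin && leftmost && oracle_primitive(motif)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + p * r, period = p, motif = motif,
          n_repeats = r, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      motif = character(), n_repeats = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$period), ]
}

# PIC by the literal double loop over allele pairs
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
  }
  s
}

# full-enumeration exact HWE p-value for a biallelic locus
oracle_hwe_biallelic <- function(a1, a2) {
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  stopifnot(length(alleles) == 2L)
  nA <- sum(a1 == alleles[1]) + sum(a2 == alleles[1])
  n_het_obs <- sum(a1 != a2)
  hets <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logw <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    if (naa < 0 || nbb < 0) return(-Inf)
    h * log(2) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1)
  }, numeric(1))
  pr <- exp(logw - max(logw))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het_obs, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# copy-level AMOVA by explicit loops (no matrix algebra), one value per call
oracle_amova <- function(g) {
  N <- length(g$ind)
  v1 <- g$a1; v2 <- g$a2
  alleles <- function(i) rbind(v1[i, ], v2[i, ])
  copies <- do.call(rbind, lapply(seq_len(N), alleles))  # 2N x L interleaved
  cpop <- rep(as.character(g$pop), each = 2)
  M <- nrow(copies)
  d <- function(a, b) {
    s <- 0
    for (l in seq_len(ncol(copies))) {
      x <- copies[a, l]; y <- copies[b, l]
      if (!is.na(x) && !is.na(y) && x != y) s <- s + 1
    }
    s
  }
  ss_tot <- 0
  for (a in seq_len(M - 1)) for (b in (a + 1):M) ss_tot <- ss_tot + d(a, b)
  ss_tot <- ss_tot / M
  ss_w <- 0
  for (p in unique(cpop)) {
    idx <- which(cpop == p)
    s <- 0
    for (a in idx) for (b in idx) if (a < b) s <- s + d(a, b)
    ss_w <- ss_w + s / length(idx)
  }
  P <- length(unique(cpop))
  mk <- table(cpop)
  s2w <- ss_w / (M - P)
  nprime <- (M - sum(mk^2) / M) / (P - 1)
  s2a <- ((ss_tot - ss_w) / (P - 1) - s2w) / nprime
  list(ss_among = ss_tot - ss_w, ss_within = ss_w, ss_total = ss_tot,
       s2a = s2a, s2w = s2w, fst = s2a / (s2a + s2w))
}

# small genotype_matrix builder from a list of "a/b" strings per population
toy_genotypes <- function(pops) {
  a1 <- c(); a2 <- c(); lab <- c()
  for (p in names(pops)) {
    m <- pops[[p]]                         # individuals x loci matrix of "a/b"
    for (i in seq_len(nrow(m))) {
      parts <- strsplit(m[i, ], "/")
      a1 <- rbind(a1, as.integer(vapply(parts, `[`, "", 1)))
      a2 <- rbind(a2, as.integer(vapply(parts, `[`, "", 2)))
      lab <- c(lab, p)
    }
  }
  genotype_matrix(a1, a2, pop = lab,
                  ind = paste0(lab, "_", seq_along(lab)),
                  loci = paste0("L", seq_len(ncol(a1))))
}
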