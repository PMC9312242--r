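#' Specification for a genome with planted SSR tracts and amplicons
#'
#' Describes the synthetic test genomes: i.i.d. background sequence at a
#' given GC content, perfect SSR tracts planted at random non-overlapping
#' positions, and optional primer-delimited amplicons for in-silico PCR
#' checks.
#'
#' @param n_sequences Number of FASTA records.
#' @param length Length of each record in bp (scalar or vector).
#' @param gc Background GC fraction.
#' @param ssrs Data frame with columns `motif` and `n_repeats`, one planted
#'   tract per row (assigned to records round-robin), or `NULL`.
#' @param amplicons Data frame with columns `forward`, `reverse`,
#'   `product_len`, or `NULL`.
#' @param min_gap Minimum background gap between planted features in bp.
#' @return A `planted_genome_spec` list.
#' @export
planted_genome_spec <- function(n_sequences = 1L, length = 10000L, gc = 0.41,
                                ssrs = NULL, amplicons = NULL, min_gap = 30L) {
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  structure(list(n_sequences = as.integer(n_sequences),
                 length = rep_len(as.integer(length), n_sequences),
                 gc = gc, ssrs = ssrs, amplicons = amplicons,
                 min_gap = as.integer(min_gap)),
            class = "planted_genome_spec")
}

.random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.pick_base_not <- function(exclude, gc) {
  pool <- setdiff(c("A", "C", "G", "T"), exclude)
  sample(pool, 1L)
}

# plant features into one background sequence; feats: list of list(kind,
# string, period (SSR only), ...). Returns char vector + per-feature starts.
.place_features <- function(len, feat_len, min_gap) {
  nf <- length(feat_len)
  free <- len - sum(feat_len) - (nf + 1L) * min_gap
  if (free < 0) stop("infeasible packing: features do not fit in sequence")
  extra <- if (nf >= 0L) as.vector(stats::rmultinom(1, free, rep(1, nf + 1L)))
  gaps <- min_gap + extra
  starts <- integer(nf)
  pos <- 0L
  for (i in seq_len(nf)) {
    pos <- pos + gaps[i]
    starts[i] <- pos          # 0-based
    pos <- pos + feat_len[i]
  }
  starts
}

#' Simulate a genome with planted SSRs and amplicons
#'
#' Background bases are drawn i.i.d. at the specified GC content; planted
#' tracts are inserted verbatim with guard bases chosen so a tract cannot be
#' extended by one motif-phase base, keeping truth coordinates exact. The
#' neighbourhood of each planted feature (within two motif periods) is
#' rejection-sampled until it contains no accidental SSR meeting the default
#' thresholds; background farther away may still contain chance SSRs, which
#' the truth table deliberately excludes.
#'
#' @param spec A [planted_genome_spec()].
#' @param seed Optional integer seed; fixed seed gives identical sequences.
#' @param thresholds Detection thresholds used for the neighbourhood check.
#' @return List with `sequences` (named character vector), `ssr_truth` (data
#'   frame `seq_id`, `start`, `end`, `period`, `motif`, `canonical_motif`,
#'   `n_repeats`) and `amplicon_truth` (data frame `seq_id`, `start`, `end`,
#'   `product_len`, `forward`, `reverse`).
#' @export
simulate_genome <- function(spec = planted_genome_spec(), seed = NULL,
                            thresholds = ssr_thresholds()) {
  if (!is.null(seed)) set.seed(seed)
  ssrs <- spec$ssrs
  amps <- spec$amplicons
  feats <- list()
  if (!is.null(ssrs)) for (i in seq_len(nrow(ssrs))) {
    motif <- toupper(ssrs$motif[i])
    if (!.is_primitive(motif)) stop("planted motif must be primitive: ", motif)
    feats[[length(feats) + 1L]] <-
      list(kind = "ssr", string = strrep(motif, ssrs$n_repeats[i]),
           motif = motif, period = nchar(motif),
           n_repeats = as.integer(ssrs$n_repeats[i]))
  }
  if (!is.null(amps)) for (i in seq_len(nrow(amps))) {
    fwd <- toupper(amps$forward[i]); rev <- toupper(amps$reverse[i])
    filler_len <- amps$product_len[i] - nchar(fwd) - nchar(rev)
    if (filler_len < 0) stop("product_len shorter than the two primers")
    feats[[length(feats) + 1L]] <-
      list(kind = "amplicon", fwd = fwd, rev = rev,
           filler_len = filler_len,
           product_len = as.integer(amps$product_len[i]))
  }
  # round-robin assignment of features to records
  rec_of <- if (length(feats)) rep_len(seq_len(spec$n_sequences),
                                       length(feats)) else integer(0)
  seqs <- character(spec$n_sequences)
  ssr_rows <- list(); amp_rows <- list()
  for (r in seq_len(spec$n_sequences)) {
    id <- paste0("chr", r)
    fidx <- which(rec_of == r)
    # amplicon filler drawn per record so seeds stay reproducible
    strings <- lapply(feats[fidx], function(f) {
      if (f$kind == "ssr") f$string
      else paste0(f$fwd, paste(.random_bases(f$filler_len, spec$gc),
                               collapse = ""), revcomp(f$rev))
    })
    feat_len <- vapply(strings, nchar, integer(1))
    starts <- .place_features(spec$length[r], feat_len, spec$min_gap)
    for (attempt in seq_len(50L)) {
      ch <- .random_bases(spec$length[r], spec$gc)
      for (j in seq_along(fidx))
        ch[(starts[j] + 1L):(starts[j] + feat_len[j])] <-
          strsplit(strings[[j]], "")[[1]]
      # guard bases: planted SSR tracts must not extend by one phase base
      for (j in seq_along(fidx)) {
        f <- feats[[fidx[j]]]
        if (f$kind != "ssr") next
        st <- starts[j] + 1L; en <- starts[j] + feat_len[j]; p <- f$period
        if (st > 1L && ch[st - 1L] == ch[st + p - 1L])
          ch[st - 1L] <- .pick_base_not(ch[st + p - 1L], spec$gc)
        if (en < spec$length[r] && ch[en + 1L] == ch[en + 1L - p])
          ch[en + 1L] <- .pick_base_not(ch[en + 1L - p], spec$gc)
      }
      s <- paste(ch, collapse = "")
      # neighbourhood rejection check around planted SSRs
      ok <- TRUE
      hits <- find_ssrs(s, seq_id = id, thresholds = thresholds)
      for (j in seq_along(fidx)) {
        f <- feats[[fidx[j]]]
        if (f$kind != "ssr") next
        st0 <- starts[j]; en0 <- st0 + feat_len[j]; p <- f$period
        near <- hits$start < en0 + 2L * p & hits$end > st0 - 2L * p
        exact <- hits$start == st0 & hits$end == en0 & hits$period == p
        if (any(near & !exact) || !any(exact)) { ok <- FALSE; break }
      }
      if (ok) break
      if (attempt == 50L)
        stop("infeasible packing: could not isolate planted features")
    }
    seqs[r] <- s
    for (j in seq_along(fidx)) {
      f <- feats[[fidx[j]]]
      if (f$kind == "ssr") {
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          seq_id = id, start = starts[j], end = starts[j] + feat_len[j],
          period = f$period, motif = f$motif,
          canonical_motif = canonical_motif(f$motif),
          n_repeats = f$n_repeats, stringsAsFactors = FALSE)
      } else {
        amp_rows[[length(amp_rows) + 1L]] <- data.frame(
          seq_id = id, start = starts[j], end = starts[j] + feat_len[j],
          product_len = f$product_len, forward = f$fwd, reverse = f$rev,
          stringsAsFactors = FALSE)
      }
    }
  }
  names(seqs) <- paste0("chr", seq_len(spec$n_sequences))
  empty_ssr <- .empty_ssr_table()[, 1:7][0, ]
  list(sequences = seqs,
       ssr_truth = if (length(ssr_rows)) do.call(rbind, ssr_rows) else
         data.frame(seq_id = character(), start = integer(), end = integer(),
                    period = integer(), motif = character(),
                    canonical_motif = character(), n_repeats = integer()),
       amplicon_truth = if (length(amp_rows)) do.call(rbind, amp_rows) else
         data.frame(seq_id = character(), start = integer(), end = integer(),
                    product_len = integer(), forward = character(),
                    reverse = character()))
}

#' Specification for a multi-population island-model genotype dataset
#'
#' Balding-Nichols model: per-locus ancestral allele frequencies are drawn
#' Dirichlet-uniform; each population's frequencies are drawn from a
#' Dirichlet centred on the ancestral vector with concentration `(1 - F)/F`,
#' so `F` is the expected differentiation; individuals are two independent
#' allele copies (Hardy-Weinberg within populations). Defaults emulate a
#' four-population wild survey: sample sizes 34/77/68/89, 29 multiallelic
#' tetranucleotide-like loci with moderate differentiation (F = 0.074), and
#' allele codes laid out as plausible fragment sizes on a 4-bp ladder.
#'
#' @param sizes Named integer vector of population sizes.
#' @param n_loci Number of loci.
#' @param n_alleles Ancestral allele count per locus (scalar or vector).
#' @param F Balding-Nichols divergence in `[0, 1)` (scalar or per population).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param base_size_range Range the per-locus base fragment size is drawn
#'   from; allele `k` gets code `base + 4 (k - 1)`.
#' @return An `island_model_spec` list.
#' @export
island_model_spec <- function(sizes = c(KR = 34L, WR = 77L, JL = 68L, WL = 89L),
                              n_loci = 29L, n_alleles = 12L, F = 0.074,
                              missing_rate = 0.02,
                              base_size_range = c(86L, 150L)) {
  if (any(F < 0) || any(F >= 1)) stop("F must lie in [0, 1)")
  if (any(sizes < 1L)) stop("population sizes must be >= 1")
  if (any(n_alleles < 1L)) stop("allele counts must be >= 1")
  if (is.null(names(sizes))) names(sizes) <- paste0("pop", seq_along(sizes))
  structure(list(sizes = sizes, n_loci = as.integer(n_loci),
                 n_alleles = rep_len(as.integer(n_alleles), n_loci),
                 F = rep_len(F, length(sizes)),
                 missing_rate = missing_rate,
                 base_size_range = base_size_range),
            class = "island_model_spec")
}

.rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  g / sum(g)
}

#' Simulate a multi-population genotype dataset with known truth
#'
#' Draws a [genotype_matrix()] under the Balding-Nichols island model of
#' [island_model_spec()], plus a truth record holding the ancestral and
#' per-population allele frequencies and the divergence parameter.
#'
#' @param spec An [island_model_spec()].
#' @param seed Optional integer seed.
#' @return List with `genotypes` (a `genotype_matrix`) and `truth` (list
#'   with `ancestral`, `pop_freqs`, `F`, `allele_codes`).
#' @export
simulate_genotypes <- function(spec = island_model_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- names(spec$sizes)
  N <- sum(spec$sizes)
  L <- spec$n_loci
  loci <- sprintf("locus%02d", seq_len(L))
  a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
  ancestral <- vector("list", L); pop_freqs <- vector("list", L)
  codes <- vector("list", L)
  pop_label <- rep(pops, times = spec$sizes)
  for (l in seq_len(L)) {
    k <- spec$n_alleles[l]
    base <- sample(spec$base_size_range[1]:spec$base_size_range[2], 1L)
    codes[[l]] <- base + 4L * (seq_len(k) - 1L)
    p0 <- .rdirichlet1(rep(1, k))
    ancestral[[l]] <- stats::setNames(p0, codes[[l]])
    pf <- matrix(0, length(pops), k, dimnames = list(pops, codes[[l]]))
    for (j in seq_along(pops)) {
      Fj <- spec$F[j]
      pf[j, ] <- if (Fj == 0) p0 else .rdirichlet1(p0 * (1 - Fj) / Fj)
    }
    pop_freqs[[l]] <- pf
    for (j in seq_along(pops)) {
      rows <- which(pop_label == pops[j])
      a1[rows, l] <- sample(codes[[l]], length(rows), replace = TRUE,
                            prob = pf[j, ])
      a2[rows, l] <- sample(codes[[l]], length(rows), replace = TRUE,
                            prob = pf[j, ])
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(N * L) < spec$missing_rate, N, L)
    # keep at least one call per locus
    for (l in seq_len(L)) if (all(mask[, l])) mask[1L, l] <- FALSE
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  ind <- sprintf("%s_%03d", pop_label, stats::ave(seq_len(N), pop_label,
                                                  FUN = seq_along))
  names(ancestral) <- names(pop_freqs) <- names(codes) <- loci
  list(genotypes = genotype_matrix(a1, a2,
                                   pop = factor(pop_label, levels = pops),
                                   ind = ind, loci = loci),
       truth = list(ancestral = ancestral, pop_freqs = pop_freqs,
                    F = stats::setNames(spec$F, pops), allele_codes = codes))
}
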