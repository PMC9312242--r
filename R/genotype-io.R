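#' Construct a codominant diploid genotype matrix
#'
#' The central container for the statistics modules: per individual a
#' population label and, per locus, an unordered pair of positive integer
#' allele codes (conventionally fragment sizes in bp). Missing calls are `NA`
#' in both allele slots.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   copies; `NA` marks a missing call (both slots must agree).
#' @param pop Population label per individual (character or factor).
#' @param ind Individual ids; defaults to rownames of `a1`.
#' @param loci Locus ids; defaults to colnames of `a1`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(a1, a2, pop, ind = rownames(a1), loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have identical shape")
  if (length(pop) != nrow(a1)) stop("one population label per individual required")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("a missing call must be missing in both allele slots")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers")
  if (is.null(ind)) ind <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  dimnames(a1) <- dimnames(a2) <- list(ind, loci)
  structure(list(ind = as.character(ind), pop = factor(pop),
                 loci = as.character(loci),
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ind), "individuals x", length(x$loci),
      "loci\n")
  cat("populations:",
      paste(sprintf("%s (%d)", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of populations / individuals helpers
#' @param g A `genotype_matrix`.
#' @return Integer.
#' @rdname genotype_matrix_dims
#' @export
n_individuals <- function(g) length(g$ind)

#' @rdname genotype_matrix_dims
#' @export
n_loci <- function(g) length(g$loci)

#' Subset a genotype matrix by population
#'
#' @param g A `genotype_matrix`.
#' @param pops Character vector of population labels to keep.
#' @return A `genotype_matrix` restricted to those individuals.
#' @export
subset_populations <- function(g, pops) {
  keep <- g$pop %in% pops
  if (!any(keep)) stop("no individuals in requested populations")
  genotype_matrix(g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE],
                  droplevels(g$pop[keep]), ind = g$ind[keep], loci = g$loci)
}

#' Read a GenePop genotype file
#'
#' Parses the standard GenePop 4.x dialect: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separators, and individual
#' lines `id , g1 g2 ...` with 2- or 3-digit allele encoding per allele copy.
#' An all-zero genotype is a missing call. Populations are named by the label
#' of their first individual, the usual GenePop convention.
#'
#' @param path Path to a GenePop file.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GenePop file (fewer than 3 lines): ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  pop_breaks <- which(is_pop)
  pop_id <- cumsum(is_pop)
  a1 <- list(); a2 <- list(); ids <- character(); poplab <- character()
  pop_names <- rep(NA_character_, length(pop_breaks))
  digits <- NA_integer_
  for (i in seq_along(lines)) {
    if (i < first_pop || is_pop[i]) next
    line <- lines[i]
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("line ", i, ": expected 'id , genotypes' with a comma")
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != length(loci))
      stop("line ", i, ": ", length(gts), " genotypes for ", length(loci),
           " loci")
    w <- unique(nchar(gts))
    if (length(w) != 1L || !w %in% c(4L, 6L))
      stop("line ", i, ": genotype fields must be uniformly 4 (2-digit) or 6 ",
           "(3-digit) characters")
    if (is.na(digits)) digits <- w / 2L
    else if (digits != w / 2L) stop("line ", i, ": mixed allele encodings")
    if (any(grepl("[^0-9]", gts)))
      stop("line ", i, ": non-numeric genotype field")
    x1 <- as.integer(substr(gts, 1L, digits))
    x2 <- as.integer(substr(gts, digits + 1L, 2L * digits))
    miss <- x1 == 0L & x2 == 0L
    if (any(xor(x1 == 0L, x2 == 0L)))
      stop("line ", i, ": half-missing genotype (one allele coded 0)")
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id)
    block <- pop_id[i]
    if (is.na(pop_names[block])) pop_names[block] <- id
    poplab <- c(poplab, pop_names[block])
    a1[[length(a1) + 1L]] <- x1
    a2[[length(a2) + 1L]] <- x2
  }
  genotype_matrix(do.call(rbind, a1), do.call(rbind, a2),
                  pop = factor(poplab, levels = unique(poplab)),
                  ind = ids, loci = loci)
}

#' Write a genotype matrix in GenePop format
#'
#' Allele codes are written verbatim as zero-padded 3-digit fields (fragment
#' sizes up to 999 bp), so files round-trip without a recoding table. Missing
#' calls are written `000000`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "ssrpopgen export") {
  if (any(g$a1 > 999, na.rm = TRUE) || any(g$a2 > 999, na.rm = TRUE))
    stop("allele codes above 999 cannot be written as 3-digit GenePop")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  enc <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  for (p in levels(g$pop)) {
    writeLines("Pop", con)
    for (i in which(g$pop == p)) {
      gt <- paste0(enc(g$a1[i, ]), enc(g$a2[i, ]), collapse = " ")
      writeLines(paste(g$ind[i], ",", gt), con)
    }
  }
  invisible(path)
}

#' Export genotypes as a long-format TSV
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  long <- data.frame(
    individual = rep(g$ind, times = n_loci(g)),
    population = rep(as.character(g$pop), times = n_loci(g)),
    locus = rep(g$loci, each = n_individuals(g)),
    allele1 = as.vector(g$a1), allele2 = as.vector(g$a2))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequencies per locus
#'
#' Counts the `2n` non-missing allele copies per locus over one population
#' (or the pooled sample) and normalizes to relative frequencies. A locus
#' with zero non-missing calls is flagged empty rather than propagating NaN.
#'
#' @param g A [genotype_matrix()].
#' @param pool A population label, or `"ALL"` for the pooled sample.
#' @return An `allele_freqs` object: a list with one element per locus, each
#'   holding `counts` (named integer), `freq` (named numeric summing to 1),
#'   and `n` (diploid individuals with a non-missing call); empty loci have
#'   `n = 0` and zero-length tables.
#' @export
allele_freqs <- function(g, pool = "ALL") {
  if (!identical(pool, "ALL")) {
    if (!pool %in% levels(g$pop)) stop("unknown population: ", pool)
    keep <- g$pop == pool
  } else keep <- rep(TRUE, n_individuals(g))
  out <- lapply(seq_along(g$loci), function(l) {
    alleles <- c(g$a1[keep, l], g$a2[keep, l])
    alleles <- alleles[!is.na(alleles)]
    n <- length(alleles) / 2
    if (n == 0)
      return(list(counts = integer(0), freq = numeric(0), n = 0L, empty = TRUE))
    counts <- table(alleles)
    cnt <- as.integer(counts); names(cnt) <- names(counts)
    list(counts = cnt, freq = cnt / sum(cnt), n = as.integer(n), empty = FALSE)
  })
  names(out) <- g$loci
  attr(out, "pool") <- pool
  class(out) <- "allele_freqs"
  out
}
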