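#' Minimum repeat-count thresholds for SSR detection
#'
#' Thresholds follow the common marker-development convention for perfect
#' microsatellites: at least 5 dinucleotide, 4 trinucleotide, 3 tetranucleotide
#' and 2 pentanucleotide repeat units. Mononucleotide and hexanucleotide runs
#' are not searched.
#'
#' @param di,tri,tetra,penta Minimum number of complete repeat units for
#'   periods 2, 3, 4 and 5. All must be `>= 2`.
#' @return An `ssr_thresholds` object: a named integer vector keyed by period.
#' @examples
#' ssr_thresholds()
#' ssr_thresholds(di = 6)
#' @export
ssr_thresholds <- function(di = 5L, tri = 4L, tetra = 3L, penta = 2L) {
  x <- c("2" = as.integer(di), "3" = as.integer(tri),
         "4" = as.integer(tetra), "5" = as.integer(penta))
  if (anyNA(x) || any(x < 2L))
    stop("all repeat-count thresholds must be integers >= 2")
  structure(x, class = "ssr_thresholds")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T, case-insensitive; N is
#'   preserved).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  flipped <- vapply(strsplit(chartr("ACGTacgt", "TGCATGCA", x), ""),
                    function(ch) paste(rev(ch), collapse = ""), character(1))
  unname(flipped)
}

.rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n), function(i)
    paste0(substr(m, i, n), substr(m, 1, i - 1)), character(1))
}

.is_primitive <- function(m) {
  p <- nchar(m)
  if (p == 1L) return(TRUE)
  divs <- which(p %% seq_len(p - 1L) == 0L)
  for (d in divs) {
    if (m == strrep(substr(m, 1L, d), p / d)) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of a microsatellite repeat unit
#'
#' Two repeat units describe the same tandem-repeat tract if one is a cyclic
#' rotation of the other or of its reverse complement (a tract read on the
#' opposite strand or in a different phase). The canonical representative is
#' the lexicographically smallest string over all cyclic rotations of the
#' motif and of its reverse complement, so e.g. GT, TG, CA and AC all map to
#' AC, and GATA maps to AGAT.
#'
#' @param motif Character vector of repeat units, each 1-6 bp over A/C/G/T.
#' @return Character vector of canonical motifs, same length as `motif`.
#' @examples
#' canonical_motif(c("GT", "TC", "GATA"))
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- toupper(m)
    if (!nzchar(m) || nchar(m) > 6L)
      stop("motif length must be between 1 and 6: ", m)
    if (grepl("[^ACGT]", m))
      stop("motif contains non-ACGT characters: ", m)
    min(c(.rotations(m), .rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

.empty_ssr_table <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             period = integer(), motif = character(),
             canonical_motif = character(), n_repeats = integer(),
             tract_length = integer(), stringsAsFactors = FALSE)
}

#' Find perfect microsatellites in a DNA sequence
#'
#' Scans one sequence for maximal perfect tandem repeats of period 2-5 whose
#' number of complete repeat units meets the period's threshold. A tract is
#' maximal when it cannot be extended by one motif-phase base on either side;
#' only complete repeat units are counted, so coordinates satisfy
#' `end - start == period * n_repeats`. Reported motifs are primitive (a
#' (ACAC)n hit is reported once, as period-2 AC), which also suppresses
#' duplicate reports of one tract under a multiple of its period. N (or any
#' non-ACGT base) never matches inside a tract; soft-masked lowercase bases
#' are uppercased before scanning.
#'
#' @param sequence A single DNA string (may be empty).
#' @param seq_id Sequence identifier recorded in the output.
#' @param thresholds An [ssr_thresholds()] object.
#' @return A data frame of class `ssr_table`, sorted by start, with columns
#'   `seq_id`, `start`, `end` (0-based half-open), `period`, `motif` (as read
#'   from the leftmost repeat unit), `canonical_motif`, `n_repeats`,
#'   `tract_length`.
#' @seealso [find_ssrs_fasta()] for multi-record input, [summarize_ssrs()].
#' @examples
#' find_ssrs(paste0("GGT", strrep("ACAG", 8), "TTCA"))
#' @export
find_ssrs <- function(sequence, seq_id = "seq1", thresholds = ssr_thresholds()) {
  stopifnot(length(sequence) == 1L)
  s <- toupper(sequence)
  n <- nchar(s)
  periods <- as.integer(names(thresholds))
  if (n < min(periods) * min(thresholds)) return(.empty_ssr_table())
  ch <- strsplit(s, "")[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  rows <- vector("list", 32L)
  nrow_used <- 0L
  for (p in periods) {
    tmin <- thresholds[[as.character(p)]]
    if (n < p * tmin) next
    idx <- seq_len(n - p)
    match_next <- ch[idx] == ch[idx + p] & acgt[idx] & acgt[idx + p]
    r <- rle(match_next)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (h in which(r$values)) {
      tract_len <- r$lengths[h] + p
      n_rep <- tract_len %/% p
      if (n_rep < tmin) next
      st <- run_start[h]                      # 1-based tract start
      motif <- substr(s, st, st + p - 1L)
      if (!.is_primitive(motif)) next
      nrow_used <- nrow_used + 1L
      rows[[nrow_used]] <- list(seq_id = seq_id, start = st - 1L,
                                end = st - 1L + p * n_rep, period = p,
                                motif = motif, n_repeats = n_rep)
    }
  }
  if (nrow_used == 0L) return(.empty_ssr_table())
  out <- do.call(rbind, lapply(rows[seq_len(nrow_used)], as.data.frame))
  out$canonical_motif <- canonical_motif(out$motif)
  out$tract_length <- out$end - out$start
  out <- out[order(out$start, out$period),
             c("seq_id", "start", "end", "period", "motif",
               "canonical_motif", "n_repeats", "tract_length")]
  rownames(out) <- NULL
  class(out) <- c("ssr_table", "data.frame")
  out
}

#' Find perfect microsatellites in every record of a FASTA file or record set
#'
#' @param fasta Path to a (possibly gzipped) FASTA file, or a named character
#'   vector of sequences as returned by [read_fasta()].
#' @param thresholds An [ssr_thresholds()] object.
#' @return One `ssr_table` data frame over all records (see [find_ssrs()]).
#' @export
find_ssrs_fasta <- function(fasta, thresholds = ssr_thresholds()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  hits <- lapply(names(seqs), function(id)
    find_ssrs(seqs[[id]], seq_id = id, thresholds = thresholds))
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .empty_ssr_table()
  class(out) <- c("ssr_table", "data.frame")
  out
}

#' Summarize SSR loci by period and canonical motif class
#'
#' Tabulates detected loci into per-motif counts with two proportions: within
#' the motif's period class (e.g. the share of AGAT among all tetranucleotide
#' loci) and among all loci. Proportions are exact fractions; rounding is left
#' to presentation.
#'
#' @param loci An `ssr_table` from [find_ssrs()], or any data frame with
#'   columns `period` and `canonical_motif`.
#' @return A `motif_summary` data frame with columns `period`,
#'   `canonical_motif`, `count`, `prop_period` and `prop_total`, sorted by
#'   period then decreasing count.
#' @examples
#' loci <- find_ssrs(paste0(strrep("AC", 7), "GGG", strrep("AGAT", 5)))
#' summarize_ssrs(loci)
#' @export
summarize_ssrs <- function(loci) {
  counts <- as.data.frame(table(period = loci$period,
                                canonical_motif = loci$canonical_motif),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, , drop = FALSE]
  names(counts)[names(counts) == "Freq"] <- "count"
  counts$period <- as.integer(counts$period)
  motif_summary(counts)
}

#' Build a motif summary from pre-tabulated counts
#'
#' The same summary as [summarize_ssrs()] but starting from a table of motif
#' counts, e.g. a published genome-wide inventory.
#'
#' @param counts Data frame with columns `canonical_motif` (or `motif`) and
#'   `count`; `period` is inferred from motif length when absent.
#' @return A `motif_summary` data frame (see [summarize_ssrs()]).
#' @export
motif_summary <- function(counts) {
  counts <- as.data.frame(counts)
  if (!"canonical_motif" %in% names(counts)) {
    if (!"motif" %in% names(counts)) stop("need a motif column")
    counts$canonical_motif <- canonical_motif(counts$motif)
  }
  if (!"period" %in% names(counts))
    counts$period <- nchar(counts$canonical_motif)
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be nonnegative integers")
  total <- sum(counts$count)
  period_tot <- tapply(counts$count, counts$period, sum)
  out <- data.frame(period = as.integer(counts$period),
                    canonical_motif = counts$canonical_motif,
                    count = as.integer(counts$count),
                    stringsAsFactors = FALSE)
  out$prop_period <- out$count / as.vector(period_tot[as.character(out$period)])
  out$prop_total <- if (total > 0) out$count / total else NA_real_
  out <- out[order(out$period, -out$count, out$canonical_motif), ]
  rownames(out) <- NULL
  attr(out, "period_totals") <- period_tot
  attr(out, "total") <- total
  class(out) <- c("motif_summary", "data.frame")
  out
}

#' Write an SSR table as TSV (1-based inclusive coordinates)
#'
#' @param loci An `ssr_table` from [find_ssrs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  out <- as.data.frame(loci)
  out$start <- out$start + 1L          # 1-based inclusive in the file
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ssrpopgen SSR table; coordinates 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
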