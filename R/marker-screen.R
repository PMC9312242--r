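#' Primer screening constraint windows
#'
#' The default windows are the ones used to shortlist tetranucleotide marker
#' candidates: PCR product length 50-500 bp, primer length 18-30 nt, melting
#' temperature 52-65 degrees Celsius.
#'
#' @param product_len Numeric length-2 vector, allowed product size in bp.
#' @param primer_len Numeric length-2 vector, allowed primer length in nt.
#' @param tm Numeric length-2 vector, allowed melting temperature in Celsius.
#' @return A `screen_constraints` list.
#' @export
screen_constraints <- function(product_len = c(50, 500),
                               primer_len = c(18, 30),
                               tm = c(52, 65)) {
  win <- list(product_len = product_len, primer_len = primer_len, tm = tm)
  for (nm in names(win)) {
    w <- win[[nm]]
    if (length(w) != 2L || anyNA(w) || w[1] > w[2])
      stop("constraint window '", nm, "' must be c(lower, upper) with lower <= upper")
  }
  structure(win, class = "screen_constraints")
}

# SantaLucia unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K), keyed by the 5'->3' top-strand dimer.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor duplex Tm with the SantaLucia unified parameter set:
#' dimer stacking terms plus terminal A/T (dH 2.3, dS 4.1) and terminal G/C
#' (dH 0.1, dS -2.8) initiation corrections, a -1.4 cal/(mol K) entropy
#' penalty for self-complementary oligos, and the entropic salt correction
#' 0.368 (N-1) ln[Na+]. The strand-concentration divisor is CT/4 for
#' non-self-complementary duplexes (CT/2 when self-complementary). A 2+4
#' Wallace rule is available for quick checks. The duplex is symmetric, so a
#' primer and its reverse complement give the same Tm.
#'
#' @param primer Character vector of primer sequences, each >= 8 nt, ACGT only.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_uM Total strand concentration in micromolar (default 0.25).
#' @param method `"santalucia"` (nearest-neighbor, default) or `"wallace"`.
#' @return Numeric vector of melting temperatures in Celsius, reported to
#'   0.1 degree.
#' @examples
#' melting_temp("GCTAATGCCTGACCACCACT")
#' @export
melting_temp <- function(primer, na_mM = 50, oligo_uM = 0.25,
                         method = c("santalucia", "wallace")) {
  method <- match.arg(method)
  vapply(primer, function(s) {
    s <- toupper(s)
    if (nchar(s) < 8L) stop("primer shorter than 8 nt: ", s)
    if (grepl("[^ACGT]", s))
      stop("primer contains non-ACGT (degenerate bases are rejected): ", s)
    if (method == "wallace") {
      ch <- strsplit(s, "")[[1]]
      return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
    }
    n <- nchar(s)
    dimers <- substring(s, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    dh <- sum(.nn_dh[dimers])
    ds <- sum(.nn_ds[dimers])
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else                       { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    selfcomp <- identical(s, revcomp(s))
    ct <- oligo_uM * 1e-6
    if (selfcomp) { ds <- ds - 1.4; k <- ct / 2 } else k <- ct / 4
    ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
    round(1000 * dh / (ds + 1.987 * log(k)) - 273.15, 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Screen a primer pair against constraint windows
#'
#' Checks both primer lengths, both melting temperatures and (when known) the
#' predicted product length against their windows. All constraints are
#' evaluated; violations are enumerated rather than short-circuited.
#'
#' @param forward,reverse Primer sequences, 5'->3' (the reverse primer in
#'   reverse-strand orientation, as synthesized).
#' @param product_len Predicted product length in bp, or `NA` if unknown.
#' @param constraints A [screen_constraints()] object.
#' @param ... Passed to [melting_temp()].
#' @return A list with `pass` (logical), `violations` (character vector drawn
#'   from `"primer_len"`, `"tm"`, `"product_len"`), and a one-row data frame
#'   `detail` holding lengths and Tms.
#' @export
screen_primer_pair <- function(forward, reverse, product_len = NA,
                               constraints = screen_constraints(), ...) {
  inside <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  len <- nchar(c(forward, reverse))
  tm <- melting_temp(c(forward, reverse), ...)
  violations <- character()
  if (!all(inside(len, constraints$primer_len))) violations <- c(violations, "primer_len")
  if (!all(inside(tm, constraints$tm))) violations <- c(violations, "tm")
  if (!is.na(product_len) && !inside(product_len, constraints$product_len))
    violations <- c(violations, "product_len")
  list(pass = length(violations) == 0L,
       violations = violations,
       detail = data.frame(forward_len = len[1], reverse_len = len[2],
                           forward_tm = tm[1], reverse_tm = tm[2],
                           product_len = product_len))
}

#' Screen a table of primer pairs
#'
#' @param primers Data frame with columns `locus`, `forward`, `reverse` and
#'   optionally `product_len`.
#' @param constraints A [screen_constraints()] object.
#' @param ... Passed to [melting_temp()].
#' @return Data frame with one row per pair: per-constraint booleans, Tms and
#'   overall `pass`.
#' @export
screen_primer_table <- function(primers, constraints = screen_constraints(), ...) {
  prod <- if ("product_len" %in% names(primers)) primers$product_len else NA
  rows <- lapply(seq_len(nrow(primers)), function(i) {
    r <- screen_primer_pair(primers$forward[i], primers$reverse[i],
                            product_len = if (length(prod) > 1) prod[i] else prod,
                            constraints = constraints, ...)
    cbind(data.frame(locus = primers$locus[i]), r$detail,
          data.frame(primer_len_ok = !"primer_len" %in% r$violations,
                     tm_ok = !"tm" %in% r$violations,
                     product_len_ok = !"product_len" %in% r$violations,
                     pass = r$pass))
  })
  do.call(rbind, rows)
}

#' Extract the flanking regions of an SSR locus
#'
#' @param genome Named character vector of sequences (see [read_fasta()]).
#' @param locus One-row `ssr_table` entry, or a list with `seq_id`, `start`,
#'   `end` (0-based half-open).
#' @param flank_len Number of flanking bases requested on each side; flanks
#'   are truncated at sequence ends.
#' @return List with `left`, `tract`, `right` strings and the realized
#'   `left_len`/`right_len`. The concatenation of the three parts equals the
#'   genomic slice.
#' @export
extract_flanks <- function(genome, locus, flank_len) {
  stopifnot(flank_len >= 0)
  id <- as.character(locus$seq_id)
  if (!id %in% names(genome)) stop("sequence not found in genome: ", id)
  s <- genome[[id]]
  n <- nchar(s)
  start <- as.integer(locus$start); end <- as.integer(locus$end)
  if (start < 0 || end > n || start > end)
    stop("locus coordinates outside sequence bounds")
  lf_start <- max(0L, start - as.integer(flank_len))
  rt_end <- min(n, end + as.integer(flank_len))
  list(left = substr(s, lf_start + 1L, start),
       tract = substr(s, start + 1L, end),
       right = substr(s, end + 1L, rt_end),
       left_len = start - lf_start,
       right_len = rt_end - end)
}

#' Exact-match in-silico PCR
#'
#' Finds all products in which the forward primer matches the plus strand
#' exactly and the reverse complement of the reverse primer matches exactly
#' downstream, up to a maximum product length. Products include both primer
#' sites.
#'
#' @param genome Named character vector of sequences.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_product Maximum product length in bp.
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and `product_len`; zero rows when there is no hit.
#' @export
in_silico_pcr <- function(genome, forward, reverse, max_product = 2000L) {
  forward <- toupper(forward); rev_site <- revcomp(toupper(reverse))
  hits <- lapply(names(genome), function(id) {
    s <- genome[[id]]
    f <- gregexpr(forward, s, fixed = TRUE)[[1]]
    r <- gregexpr(rev_site, s, fixed = TRUE)[[1]]
    if (f[1] == -1L || r[1] == -1L) return(NULL)
    grid <- expand.grid(f = as.integer(f), r = as.integer(r))
    grid$end <- grid$r + nchar(rev_site) - 1L
    grid$len <- grid$end - grid$f + 1L
    grid <- grid[grid$r > grid$f & grid$len <= max_product, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    data.frame(seq_id = id, start = grid$f - 1L, end = grid$end,
               product_len = grid$len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), product_len = integer())
  rownames(out) <- NULL
  out
}
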