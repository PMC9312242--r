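#' Bundled reference tables from a published Perca fluviatilis survey
#'
#' Small plain-text tables from a published microsatellite study of four wild
#' Eurasian perch (Perca fluviatilis) populations in Xinjiang (Kalaeerqisi
#' River KR, Wulungu River WR, Jili Lake JL, Wulungu Lake WL; 268 individuals
#' genotyped at 29 tetranucleotide loci). They serve as worked-example inputs
#' and as fixed points for validating the statistics in this package:
#'
#' * `perca_marker_panel()` — the 29-marker primer panel (locus, forward and
#'   reverse primer, repeat motif and unit count, fragment size range in bp).
#' * `perca_locus_summary()` — per-locus Na, Ne, Ho, He and PIC as printed.
#' * `perca_tetra_motif_counts()` — genome-wide tetranucleotide motif counts.
#' * `perca_genome_ssr_counts()` — SSR counts per motif period (2-5 bp).
#' * `perca_primer_screen_counts()` — marker development funnel (synthesized,
#'   clear bands, polymorphic, selected).
#' * `perca_amova_components()` — the published AMOVA table (df, sums of
#'   squares, variance components, percent variation).
#' * `perca_pairwise_table()` — pairwise Nei distance `d` and `fst` with
#'   significance flags.
#' * `perca_distance_matrix()` — the pairwise Nei distances as a labelled
#'   symmetric matrix ready for [upgma()].
#'
#' @return A data frame (or, for `perca_distance_matrix()`, a symmetric
#'   labelled matrix).
#' @name perca_tables
NULL

.perca_file <- function(name) {
  path <- system.file("extdata", name, package = "ssrpopgen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname perca_tables
#' @export
perca_marker_panel <- function() .perca_file("perca_marker_panel.tsv")

#' @rdname perca_tables
#' @export
perca_locus_summary <- function() .perca_file("perca_locus_stats.tsv")

#' @rdname perca_tables
#' @export
perca_tetra_motif_counts <- function() .perca_file("perca_tetra_motif_counts.tsv")

#' @rdname perca_tables
#' @export
perca_genome_ssr_counts <- function() .perca_file("perca_genome_ssr_counts.tsv")

#' @rdname perca_tables
#' @export
perca_primer_screen_counts <- function() .perca_file("perca_primer_screen_counts.tsv")

#' @rdname perca_tables
#' @export
perca_amova_components <- function() .perca_file("perca_amova_table.tsv")

#' @rdname perca_tables
#' @export
perca_pairwise_table <- function() .perca_file("perca_pairwise.tsv")

#' @rdname perca_tables
#' @export
perca_distance_matrix <- function() {
  tab <- perca_pairwise_table()
  pops <- unique(c(tab$pop_a, tab$pop_b))
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(nrow(tab)))
    d[tab$pop_a[i], tab$pop_b[i]] <- d[tab$pop_b[i], tab$pop_a[i]] <- tab$d[i]
  d
}
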