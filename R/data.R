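#' Per-clone MAP2+ neuron counts from the high-content experiments
#'
#' Numbers of MAP2-positive neurons identified per clone by the automated
#' analysis in the four high-content imaging experiments (postsynaptic GluN1
#' staining, presynaptic VGLUT1 staining, ribosomal RPS6 puncta, and the
#' SUnSET puromycin assay), together with the totals reported for each
#' experiment. Six clones per experiment: two wild-type, two heterozygous
#' and two homozygous exon-3-deletion lines.
#'
#' @return data.frame with columns experiment, clone, genotype,
#'   n_map2_cells, reported_total.
#' @export
map2_cell_counts <- function() {
  utils::read.csv(system.file("extdata", "map2_cell_counts.csv",
                              package = "compartquant"),
                  stringsAsFactors = FALSE)
}

#' Aggregate per-clone MAP2+ counts into experiment totals
#'
#' Sums the six per-clone counts of each experiment and compares them with
#' the reported totals. The SUnSET experiment's clone counts sum to 34,930
#' against a reported total of 35,461; the three staining experiments
#' reconcile exactly.
#'
#' @param counts optionally a data.frame as returned by
#'   [map2_cell_counts()].
#' @return data.frame with experiment, computed_total, reported_total,
#'   matches.
#' @export
map2_cell_totals <- function(counts = map2_cell_counts()) {
  tot <- stats::aggregate(n_map2_cells ~ experiment + reported_total,
                          data = counts, FUN = sum)
  data.frame(experiment = tot$experiment,
             computed_total = tot$n_map2_cells,
             reported_total = tot$reported_total,
             matches = tot$n_map2_cells == tot$reported_total,
             stringsAsFactors = FALSE)
}
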