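#' Normalize a per-well puncta count to its compartment denominator
#'
#' Converts a raw per-well puncta count (PC) to a density (delta-PC) using
#' the compartment-appropriate denominator: somatic puncta per detected soma,
#' whole-cell puncta per MAP2+ cell, and neurite puncta per micrometre of
#' total neurite length. Wells with a zero (or missing) denominator are
#' flagged missing (NA) rather than divided through, and are excluded from
#' downstream statistics.
#'
#' @param puncta_count non-negative puncta count for the well and channel.
#' @param compartment one of "soma", "whole_cell", "neurite".
#' @param somata_count,cell_count,neurite_length_um denominators; only the one
#'   matching `compartment` is used.
#' @return delta-PC (count per denominator unit), or NA if the denominator is
#'   zero or missing.
#' @export
normalize_puncta <- function(puncta_count, compartment,
                             somata_count = NA, cell_count = NA,
                             neurite_length_um = NA) {
  compartment <- match.arg(compartment, c("soma", "whole_cell", "neurite"))
  stopifnot(is.numeric(puncta_count), puncta_count >= 0)
  denom <- switch(compartment,
                  soma = somata_count,
                  whole_cell = cell_count,
                  neurite = neurite_length_um)
  if (is.na(denom) || denom <= 0) {
    warning("zero or missing denominator for compartment '", compartment,
            "': well flagged missing")
    return(NA_real_)
  }
  puncta_count / denom
}

#' Plate-matched fold change of a normalized puncta density
#'
#' delta-delta-PC = delta-PC(target) / delta-PC(wild-type reference from the
#' same plate and compartment). When several wild-type reference values are
#' supplied (multiple wild-type clones on one plate), their mean is the
#' reference.
#'
#' @param dpc_target normalized density for the target well.
#' @param dpc_reference normalized density (or densities) of wild-type
#'   reference wells on the same plate.
#' @return dimensionless fold change; NA with a warning if the reference is
#'   zero or missing.
#' @export
fold_change_vs_reference <- function(dpc_target, dpc_reference) {
  ref <- mean(dpc_reference, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) {
    warning("zero or missing reference density: fold change flagged missing")
    return(NA_real_)
  }
  dpc_target / ref
}

#' Fold change of mean staining intensity relative to same-plate wild type
#'
#' Used for the SUnSET readout: delta-MI = MI(target) / MI(wild type from the
#' same plate), mitigating plate-level batch effects.
#'
#' @param mi_target mean intensity of the target condition (a.u.).
#' @param mi_reference mean intensity (or intensities) of the wild-type
#'   condition on the same plate.
#' @return dimensionless fold change, or NA when the reference is not positive.
#' @export
sunset_fold_change <- function(mi_target, mi_reference) {
  ref <- mean(mi_reference, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) {
    warning("zero or missing reference intensity: fold change flagged missing")
    return(NA_real_)
  }
  mi_target / ref
}

#' Western blot densitometry normalization
#'
#' delta-ID = ID(target) / ID(housekeeping, same lane);
#' delta-delta-ID = delta-ID(target) / delta-ID(wild type, same membrane).
#'
#' @param id_target integrated density of the target band (a.u.).
#' @param id_housekeeping integrated density of the housekeeping band
#'   (e.g. GAPDH) in the same lane.
#' @param did_wildtype wild-type delta-ID from the same membrane; omit to get
#'   delta-ID only.
#' @return list with `did` and (when `did_wildtype` given) `ddid`.
#' @export
blot_fold_change <- function(id_target, id_housekeeping, did_wildtype = NULL) {
  if (!is.finite(id_housekeeping) || id_housekeeping <= 0) {
    warning("non-positive housekeeping density: lane flagged missing")
    return(list(did = NA_real_, ddid = NA_real_))
  }
  did <- id_target / id_housekeeping
  if (is.null(did_wildtype)) return(list(did = did, ddid = NULL))
  wt <- mean(did_wildtype, na.rm = TRUE)
  if (!is.finite(wt) || wt <= 0) {
    warning("non-positive wild-type delta-ID: fold change flagged missing")
    return(list(did = did, ddid = NA_real_))
  }
  list(did = did, ddid = did / wt)
}

#' Relative qPCR quantification (log10 of 2^-ddCt)
#'
#' delta-Ct = Ct(target) - mean(housekeeping Cts); the three housekeeping
#' genes are combined by the arithmetic mean of their Ct values, equivalent to
#' the geometric mean of their expression. delta-delta-Ct subtracts the
#' reference condition's delta-Ct, and the returned value is
#' log10(2^-ddCt), the scale used for plotting and statistics.
#'
#' @param ct_target target-gene Ct of the sample.
#' @param ct_housekeeping numeric vector of housekeeping Cts for the sample.
#' @param dct_reference delta-Ct of the reference condition.
#' @return list with `dct`, `ddct`, `expr` (2^-ddCt) and `log10_expr`.
#' @export
ddct <- function(ct_target, ct_housekeeping, dct_reference) {
  if (anyNA(c(ct_target, ct_housekeeping, dct_reference)) ||
      !all(is.finite(c(ct_target, ct_housekeeping, dct_reference)))) {
    warning("missing Ct value: record flagged")
    return(list(dct = NA_real_, ddct = NA_real_, expr = NA_real_,
                log10_expr = NA_real_))
  }
  dct <- ct_target - mean(ct_housekeeping)
  dd <- dct - dct_reference
  expr <- 2^(-dd)
  list(dct = dct, ddct = dd, expr = expr, log10_expr = log10(expr))
}

#' Average technical replicates into one value per biological replicate
#'
#' Wells from the same (clone, biological replicate) group are arithmetic
#' means; downstream statistics consume only the averaged values, avoiding
#' pseudo-replication. Empty groups (all values missing) are dropped with a
#' warning.
#'
#' @param values numeric vector of per-well values.
#' @param clone,replicate grouping keys, recycled against `values`.
#' @param ... further grouping columns (e.g. genotype, compartment) carried
#'   through unchanged; must be constant within a group.
#' @return data.frame with one row per (clone, replicate, ...) group and the
#'   averaged `value`.
#' @export
average_technical_replicates <- function(values, clone, replicate, ...) {
  extras <- list(...)
  keys <- data.frame(clone = clone, replicate = replicate,
                     stringsAsFactors = FALSE)
  for (nm in names(extras)) keys[[nm]] <- extras[[nm]]
  key_str <- do.call(paste, c(keys, sep = "\r"))
  ok <- !is.na(values)
  n_ok <- tapply(ok, key_str, sum)
  if (any(n_ok == 0)) {
    warning(sum(n_ok == 0), " group(s) with no observed wells dropped")
  }
  agg <- tapply(values[ok], key_str[ok], mean)
  first <- keys[match(names(agg), key_str), , drop = FALSE]
  first$value <- as.numeric(agg)
  rownames(first) <- NULL
  first
}
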