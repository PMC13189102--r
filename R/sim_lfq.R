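#' Configuration for the label-free proteomics simulator
#'
#' Log2 abundances are drawn per protein around a log-normal backbone (a
#' protein-level base abundance plus compartment/genotype shifts plus
#' within-group noise). Non-detection is abundance-dependent: the probability
#' of a missing entry follows a logistic curve that increases as log2
#' abundance decreases, emulating left-censored DIA non-detection.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per compartment x genotype cell.
#' @param genotypes character vector of genotype labels.
#' @param log2_mean,log2_sd mean and SD of protein base log2 abundances.
#' @param within_sd within-group residual SD on the log2 scale.
#' @param n_neurite_exclusive,n_soma_exclusive planted compartment-exclusive
#'   protein counts (never detected in the opposite compartment).
#' @param n_differential number of planted neurite-vs-soma differential
#'   proteins (disjoint from the exclusives).
#' @param differential_log2fc planted log2 effect size (neurite - soma).
#' @param missing_midpoint,missing_slope logistic missingness model:
#'   P(missing) = plogis(-(x - midpoint) * slope); a midpoint of -Inf
#'   disables missingness entirely.
#' @param rng_seed integer seed.
#' @return object of class `lfq_sim_config`.
#' @export
lfq_sim_config <- function(n_proteins = 400, n_per_group = 3,
                           genotypes = c("wildtype", "het", "hom"),
                           log2_mean = 25, log2_sd = 2, within_sd = 0.3,
                           n_neurite_exclusive = 12, n_soma_exclusive = 5,
                           n_differential = 20, differential_log2fc = 3,
                           missing_midpoint = 20, missing_slope = 1.2,
                           rng_seed = 1) {
  if (n_neurite_exclusive + n_soma_exclusive + n_differential > n_proteins)
    stop("planted protein counts exceed n_proteins")
  structure(as.list(environment()), class = "lfq_sim_config")
}

#' Generate a wide LFQ table with planted ground truth
#'
#' Planted exclusives carry signal only in their own compartment (the
#' opposite compartment is structurally missing); planted differential
#' proteins carry the configured log2 shift between neurites and somata.
#' Remaining missingness follows the abundance-dependent logistic model.
#' Deterministic under the config seed.
#'
#' @param config an [lfq_sim_config()].
#' @return list of class `lfq_sim`: `table` (an [lfq_table()]) and `truth`
#'   (lists of planted neurite/soma exclusives and differential proteins).
#' @export
generate_lfq_table <- function(config) {
  stopifnot(inherits(config, "lfq_sim_config"))
  with_seed(config$rng_seed, {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    idx <- seq_len(config$n_proteins)
    nx <- idx[seq_len(config$n_neurite_exclusive)]
    sx <- idx[config$n_neurite_exclusive + seq_len(config$n_soma_exclusive)]
    de <- idx[config$n_neurite_exclusive + config$n_soma_exclusive +
                seq_len(config$n_differential)]
    meta <- expand.grid(replicate = seq_len(config$n_per_group),
                        genotype = config$genotypes,
                        compartment = c("neurite", "soma"),
                        stringsAsFactors = FALSE)
    meta$clone <- paste0(meta$genotype, "_c1")
    meta$sample <- sprintf("%s_%s_rep%d", meta$compartment, meta$genotype,
                           meta$replicate)
    base <- stats::rnorm(config$n_proteins, config$log2_mean, config$log2_sd)
    m <- matrix(NA_real_, config$n_proteins, nrow(meta),
                dimnames = list(prot, meta$sample))
    for (j in seq_len(nrow(meta))) {
      mu <- base
      if (meta$compartment[j] == "neurite") mu[de] <- mu[de] +
          config$differential_log2fc
      x <- stats::rnorm(config$n_proteins, mu, config$within_sd)
      p_miss <- stats::plogis(-(x - config$missing_midpoint) *
                                config$missing_slope)
      x[stats::runif(config$n_proteins) < p_miss] <- NA_real_
      # structural missingness for the opposite-compartment exclusives
      if (meta$compartment[j] == "neurite") x[sx] <- NA_real_ else x[nx] <- NA_real_
      m[, j] <- x
    }
    # exclusives must be detectable at least once in their own compartment
    for (set in list(list(rows = nx, comp = "neurite"),
                     list(rows = sx, comp = "soma"))) {
      cols <- which(meta$compartment == set$comp)
      for (r in set$rows) {
        if (all(is.na(m[r, cols])))
          m[r, cols[1]] <- stats::rnorm(1, base[r], config$within_sd)
      }
    }
    structure(list(
      table = lfq_table(m, meta),
      truth = list(neurite_exclusive = prot[nx], soma_exclusive = prot[sx],
                   differential = prot[de],
                   differential_log2fc = config$differential_log2fc),
      config = config), class = "lfq_sim")
  })
}
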