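#' Configuration for the calcium trace simulator
#'
#' Describes a cohort of ROI-level fluorescence recordings around a single
#' depolarizing stimulus. Each group (e.g. genotype) has its own transient
#' amplitude distribution; the transient kernel is a difference of
#' exponentials normalized to unit peak, so the configured amplitude is the
#' true peak dF/F0.
#'
#' @param n_rois named integer vector: ROIs per group.
#' @param frame_rate_hz sampling rate (> 0).
#' @param duration_s total recording length in seconds.
#' @param baseline_f0 baseline raw fluorescence (a.u., > 0).
#' @param amplitude_mean,amplitude_sd named numeric vectors (same names as
#'   `n_rois`): per-group peak dF/F0 mean and SD; per-ROI amplitudes are
#'   drawn from a normal truncated at 0.
#' @param onset_time_s stimulus onset (s).
#' @param rise_tau_s,decay_tau_s kernel time constants (s); may be single
#'   values or named per-group vectors. decay must exceed rise.
#' @param noise_sd additive Gaussian noise SD in dF/F0 units.
#' @param rng_seed integer seed.
#' @return object of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_rois = c(control = 12, mutant = 12),
                               frame_rate_hz = 20, duration_s = 40,
                               baseline_f0 = 100,
                               amplitude_mean = c(control = 1.0, mutant = 1.3),
                               amplitude_sd = c(control = 0.2, mutant = 0.25),
                               onset_time_s = 10,
                               rise_tau_s = 0.2, decay_tau_s = 2,
                               noise_sd = 0.02, rng_seed = 1) {
  groups <- names(n_rois)
  stopifnot(!is.null(groups), all(groups %in% names(amplitude_mean)),
            all(groups %in% names(amplitude_sd)))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (any(amplitude_sd < 0)) stop("amplitude SD must be >= 0")
  rise <- expand_by_group(rise_tau_s, groups)
  decay <- expand_by_group(decay_tau_s, groups)
  if (any(rise <= 0) || any(decay <= 0)) stop("kernel taus must be positive")
  if (any(decay <= rise))
    stop("decay_tau must exceed rise_tau (degenerate kernel)")
  structure(list(n_rois = n_rois, frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s, baseline_f0 = baseline_f0,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 onset_time_s = onset_time_s, rise_tau_s = rise,
                 decay_tau_s = decay, noise_sd = noise_sd,
                 rng_seed = rng_seed),
            class = "calcium_sim_config")
}

expand_by_group <- function(x, groups) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(x, length(groups)), groups))
  stopifnot(all(groups %in% names(x)))
  x[groups]
}

#' Named presets for the calcium simulator
#'
#' `"d7_kcl"` reproduces the day-7 depolarization experiment conditions:
#' two groups of 4 ROIs with true mean peak dF/F0 of 1.222 (wild type) and
#' 1.383 (homozygous mutant), peak SDs back-computed from the reported
#' mean +/- SEM at n = 4, and a prolonged decay in the mutant group.
#'
#' @param name preset name.
#' @param rng_seed integer seed.
#' @return a `calcium_sim_config`.
#' @export
calcium_preset <- function(name = "d7_kcl", rng_seed = 1) {
  name <- match.arg(name)
  calcium_sim_config(
    n_rois = c(wildtype = 4, mutant = 4),
    frame_rate_hz = 20, duration_s = 40, baseline_f0 = 100,
    amplitude_mean = c(wildtype = 1.222, mutant = 1.383),
    amplitude_sd = c(wildtype = 0.029 * 2, mutant = 0.067 * 2),
    onset_time_s = 10,
    rise_tau_s = c(wildtype = 0.2, mutant = 0.2),
    decay_tau_s = c(wildtype = 1.0, mutant = 6.0),
    noise_sd = 0.02, rng_seed = rng_seed)
}

#' Difference-of-exponentials transient kernel (unit peak)
#'
#' k(t) = (exp(-t/decay) - exp(-t/rise)) / M for t >= 0, where M normalizes
#' the analytic maximum to 1, reached at
#' t* = rise * decay / (decay - rise) * log(decay / rise).
#'
#' @param t times since transient onset (s); values < 0 give 0.
#' @param rise_tau,decay_tau time constants (s), decay > rise > 0.
#' @return kernel values, peak exactly 1 at t*.
#' @export
calcium_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  tp <- kernel_peak_time(rise_tau, decay_tau)
  m <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  k <- ifelse(t < 0, 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / m)
  k
}

#' Analytic peak time of the difference-of-exponentials kernel
#' @param rise_tau,decay_tau time constants (s).
#' @return time of the kernel maximum (s after onset).
#' @export
kernel_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

#' Generate a cohort of stimulus-evoked calcium traces
#'
#' Raw fluorescence is baseline_f0 * (1 + A * k(t - onset)) plus Gaussian
#' noise, where A is the per-ROI amplitude (normal truncated at 0) and k the
#' unit-peak difference-of-exponentials kernel. Deterministic under the
#' config seed.
#'
#' @param config a [calcium_sim_config()].
#' @return list of class `calcium_trace_set`: `traces` (long data.frame:
#'   roi_id, group, t, f) and `truth` (roi_id, group, amplitude, onset_s,
#'   rise_tau_s, decay_tau_s).
#' @export
generate_calcium_traces <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  t <- seq(0, config$duration_s, by = 1 / config$frame_rate_hz)
  with_seed(config$rng_seed, {
    traces <- list(); truth <- list()
    roi <- 0L
    for (g in names(config$n_rois)) {
      kern <- calcium_kernel(t - config$onset_time_s,
                             config$rise_tau_s[[g]], config$decay_tau_s[[g]])
      for (i in seq_len(config$n_rois[[g]])) {
        roi <- roi + 1L
        a <- -1
        while (a < 0) a <- stats::rnorm(1, config$amplitude_mean[[g]],
                                        config$amplitude_sd[[g]])
        f <- config$baseline_f0 * (1 + a * kern) +
          stats::rnorm(length(t), 0, config$noise_sd * config$baseline_f0)
        id <- sprintf("roi_%03d", roi)
        traces[[roi]] <- data.frame(roi_id = id, group = g, t = t, f = f,
                                    stringsAsFactors = FALSE)
        truth[[roi]] <- data.frame(roi_id = id, group = g, amplitude = a,
                                   onset_s = config$onset_time_s,
                                   rise_tau_s = config$rise_tau_s[[g]],
                                   decay_tau_s = config$decay_tau_s[[g]],
                                   stringsAsFactors = FALSE)
      }
    }
    structure(list(traces = do.call(rbind, traces),
                   truth = do.call(rbind, truth),
                   config = config),
              class = "calcium_trace_set")
  })
}
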