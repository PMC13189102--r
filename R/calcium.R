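#' Baseline-normalize a fluorescence trace (dF/F0)
#'
#' F0 is the mean raw fluorescence over the baseline (prestimulus) window;
#' the returned series is (F - F0) / F0. Traces whose baseline mean is not
#' positive cannot be normalized and are rejected.
#'
#' @param f raw fluorescence values (a.u.).
#' @param t frame times in seconds (strictly increasing, same length as `f`).
#' @param baseline_window length-2 numeric, start and end (s) of the baseline
#'   window; frames with `t >= start & t <= end` are used (>= 2 required).
#' @return list with `dff` (numeric series), `f0`, `baseline_mean` and
#'   `baseline_sd` of the dF/F0 values inside the baseline window.
#' @export
dff <- function(f, t, baseline_window) {
  stopifnot(length(f) == length(t), all(diff(t) > 0),
            length(baseline_window) == 2)
  in_base <- t >= baseline_window[1] & t <= baseline_window[2]
  if (sum(in_base) < 2) stop("baseline window must contain >= 2 frames")
  f0 <- mean(f[in_base])
  if (!is.finite(f0) || f0 <= 0) stop("non-positive baseline F0: trace rejected")
  series <- (f - f0) / f0
  list(dff = series, f0 = f0,
       baseline_mean = mean(series[in_base]),
       baseline_sd = stats::sd(series[in_base]))
}

#' Detect stimulus onset from the cross-ROI mean dF/F0 trace
#'
#' Onset is the time of the maximal first difference of the mean trace
#' (the frame at which the sharpest rise begins); ties are broken to the
#' earliest frame. A constant mean trace has no defined onset and requires an
#' explicit stimulus time instead.
#'
#' @param mean_dff cross-ROI mean dF/F0 series (>= 3 frames).
#' @param t frame times in seconds.
#' @return onset time t0 in seconds.
#' @export
detect_stimulus_onset <- function(mean_dff, t) {
  stopifnot(length(mean_dff) == length(t), length(t) >= 3)
  d <- diff(mean_dff)
  if (all(d == 0)) stop("constant mean trace: onset undefined, supply t0 explicitly")
  t[which.max(d)]
}

#' Extract per-ROI calcium response features
#'
#' Within the poststimulus window (default 0-20 s after t0): peak dF/F0
#' (maximum), baseline-subtracted AUC (trapezoidal integral of the series
#' minus the baseline mean), peak latency (t0 to peak) and 10-90% rise time
#' on the rising segment preceding the peak, with linear interpolation
#' between frames. An all-zero series reports peak 0, AUC 0 and latency 0
#' with `quality_flag = "flat"`; a non-positive peak leaves the rise time
#' missing.
#'
#' @param dff_series dF/F0 values.
#' @param t frame times (s).
#' @param t0 stimulus onset (s).
#' @param window length-2 poststimulus window in seconds relative to t0.
#' @param baseline_mean,baseline_sd baseline statistics of the dF/F0 series
#'   (from [dff()]).
#' @return list of class `calcium_features`: peak, auc, latency_s,
#'   rise_time_s, responder, baseline_mean, baseline_sd, quality_flag.
#' @export
extract_features <- function(dff_series, t, t0, window = c(0, 20),
                             baseline_mean = 0, baseline_sd = 0) {
  stopifnot(length(dff_series) == length(t), length(window) == 2)
  lo <- t0 + window[1]; hi <- t0 + window[2]
  if (lo < min(t) - 1e-9 || hi > max(t) + 1e-9)
    stop("poststimulus window extends beyond the recording")
  in_win <- t >= lo - 1e-9 & t <= hi + 1e-9
  tw <- t[in_win]; yw <- dff_series[in_win]
  peak <- max(yw)
  ipk <- which.max(yw)
  y_sub <- yw - baseline_mean
  auc <- sum(diff(tw) * (head(y_sub, -1) + y_sub[-1]) / 2)
  flag <- "ok"
  if (all(yw == 0)) {
    peak <- 0; auc <- 0
    latency <- 0
    flag <- "flat"
  } else {
    latency <- tw[ipk] - t0
  }
  rise <- NA_real_
  if (peak > 0) {
    # rising segment: from the last frame at/below 10% of peak before the
    # peak, up to the first crossing of 90%
    y_rise <- yw[seq_len(ipk)]
    t_rise <- tw[seq_len(ipk)]
    t10 <- cross_time(t_rise, y_rise, 0.1 * peak)
    t90 <- cross_time(t_rise, y_rise, 0.9 * peak)
    if (is.finite(t10) && is.finite(t90)) rise <- t90 - t10
  }
  res <- list(peak = peak, auc = auc, latency_s = latency,
              rise_time_s = rise,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              quality_flag = flag)
  res$responder <- classify_responder(res)
  class(res) <- "calcium_features"
  res
}

# Last upward crossing time of `level` before the maximum, linearly
# interpolated between frames. Returns the first time the rising segment
# reaches `level`, scanning back from the peak.
cross_time <- function(t, y, level) {
  n <- length(y)
  if (n == 1) return(if (y >= level) t[1] else NA_real_)
  below <- which(y[-n] <= level & y[-1] > level)
  if (length(below) == 0) {
    # series starts above the level
    return(if (y[1] >= level) t[1] else NA_real_)
  }
  i <- below[length(below)]
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

#' Classify an ROI as a responder
#'
#' An ROI responds iff its peak dF/F0 strictly exceeds
#' baseline mean + 3 x baseline SD.
#'
#' @param features a `calcium_features` list (or any list with `peak`,
#'   `baseline_mean`, `baseline_sd`).
#' @return logical flag.
#' @export
classify_responder <- function(features) {
  isTRUE(features$peak > features$baseline_mean + 3 * features$baseline_sd)
}

#' Compare a calcium feature between genotypes
#'
#' Two-sided Wilcoxon rank-sum test treating ROIs as independent
#' observations; exact for small untied samples (both n <= 25), normal
#' approximation with tie correction otherwise.
#'
#' @param values numeric feature values.
#' @param groups group labels (exactly 2 levels present).
#' @return list with `p`, `statistic` (W) and the group medians.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       medians = stats::setNames(c(stats::median(a), stats::median(b)),
                                 levels(groups)))
}

#' Full per-ROI calcium analysis of a trace set
#'
#' Runs [dff()], onset detection (on the cross-ROI mean unless `t0` is
#' given) and [extract_features()] for every ROI of a trace set as produced
#' by [generate_calcium_traces()] or read from a long-format CSV with
#' columns roi_id, group, t, f.
#'
#' @param traces data.frame with columns `roi_id`, `group`, `t`, `f`.
#' @param t0 stimulus onset in seconds, or NULL to detect it.
#' @param window poststimulus feature window (s, relative to t0).
#' @param baseline_margin_s the baseline window ends this many seconds before
#'   t0 (default 1).
#' @return data.frame with one row per ROI: group, peak, auc, latency_s,
#'   rise_time_s, responder.
#' @export
calcium_features_table <- function(traces, t0 = NULL, window = c(0, 20),
                                   baseline_margin_s = 1) {
  stopifnot(all(c("roi_id", "group", "t", "f") %in% names(traces)))
  rois <- split(traces, traces$roi_id)
  tgrid <- rois[[1]]$t
  # dF/F0 per ROI against a provisional full-prestimulus baseline requires t0;
  # detect t0 from raw-mean differences first when not supplied.
  if (is.null(t0)) {
    fmat <- vapply(rois, function(r) r$f, numeric(length(tgrid)))
    t0 <- detect_stimulus_onset(rowMeans(fmat), tgrid)
  }
  bw <- c(min(tgrid), t0 - baseline_margin_s)
  rows <- lapply(rois, function(r) {
    nd <- dff(r$f, r$t, baseline_window = bw)
    ft <- extract_features(nd$dff, r$t, t0, window = window,
                           baseline_mean = nd$baseline_mean,
                           baseline_sd = nd$baseline_sd)
    data.frame(roi_id = r$roi_id[1], group = r$group[1],
               peak = ft$peak, auc = ft$auc, latency_s = ft$latency_s,
               rise_time_s = ft$rise_time_s, responder = ft$responder,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "t0") <- t0
  out
}
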