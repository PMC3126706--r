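# The analysis chain for the pressure-decline lysis readout: resampling to a
# common grid, biased-error (drift) estimation from the POM control arms,
# error adjustment, normalization to the initial decline, and replicate
# aggregation as mean +/- SEM.

#' Pressure decline of a recording on the 1 Hz analysis grid
#'
#' Computes `dP = P1 - P2` from the 10 Hz pressure channels and block-averages
#' it into 1-s bins (cycle-scale averaging), the common grid on which the
#' drift correction and normalization operate.
#'
#' @param rec an [simulate_experiment()] recording (or any list with a
#'   `pressure` data.frame `time_s`, `p1_mmHg`, `p2_mmHg`).
#' @param bin_s bin width in s.
#' @return data.frame `time_s` (bin start), `delta_p_mmHg`, with the arm
#'   metadata attached as attribute `"meta"`.
#' @export
decline_series <- function(rec, bin_s = 1) {
  p <- rec$pressure
  dp <- p$p1_mmHg - p$p2_mmHg
  bin <- floor(p$time_s / bin_s)
  agg <- rowsum(dp, bin) / tabulate(bin - min(bin) + 1L)
  out <- data.frame(time_s = as.numeric(rownames(agg)) * bin_s,
                    delta_p_mmHg = as.numeric(agg))
  attr(out, "meta") <- rec$meta
  out
}

.check_shared_grid <- function(series_list) {
  t0 <- series_list[[1]]$time_s
  for (s in series_list[-1])
    if (length(s$time_s) != length(t0) || any(s$time_s != t0))
      stop("series do not share a common time grid", call. = FALSE)
  t0
}

#' Biased error (drift) of a control group
#'
#' The slow drift common to an experimental condition, estimated from the
#' rigid-POM control arms: the control-mean pressure decline's excursion from
#' its own starting value, `D(t) = <dP_POM>(t) - <dP_POM>(0)`. By
#' construction `D(0) = 0`, so the correction removes drift only, not the
#' carrier's static offset.
#'
#' @param controls list of control [decline_series()] on a shared grid
#'   (n >= 2).
#' @return data.frame `time_s`, `drift_mmHg`.
#' @export
biased_error <- function(controls) {
  if (length(controls) < 2) stop("need >= 2 control series", call. = FALSE)
  t0 <- .check_shared_grid(controls)
  m <- rowMeans(vapply(controls, function(s) s$delta_p_mmHg,
                       numeric(length(t0))))
  data.frame(time_s = t0, drift_mmHg = m - m[1])
}

#' Error-adjust a clot series
#'
#' Subtracts the control-group drift from a clot recording's decline:
#' `adjusted(t) = dP(t) - D(t)`; since `D(0) = 0`, the initial value is
#' untouched.
#'
#' @param clot a clot [decline_series()].
#' @param drift the matching [biased_error()] output.
#' @return data.frame `time_s`, `delta_p_mmHg` (adjusted).
#' @export
error_adjust <- function(clot, drift) {
  .check_shared_grid(list(clot, drift))
  out <- data.frame(time_s = clot$time_s,
                    delta_p_mmHg = clot$delta_p_mmHg - drift$drift_mmHg)
  attr(out, "meta") <- attr(clot, "meta")
  out
}

#' Normalized pressure decline
#'
#' The dimensionless lysis readout `n(t) = adjusted(t) / adjusted(0)`:
#' exactly 1 at t = 0, falling as the clot's hydrodynamic resistance falls,
#' and bounded away from 0 by the empty carrier's own resistance. A
#' non-positive initial decline makes the recording unusable.
#'
#' @param adjusted an [error_adjust()]ed series (or raw decline series).
#' @return numeric vector of normalized declines on the same grid.
#' @export
normalize_decline <- function(adjusted) {
  d0 <- adjusted$delta_p_mmHg[1]
  if (!is.finite(d0) || d0 <= 0)
    stop("initial adjusted decline must be positive; unusable recording",
         call. = FALSE)
  adjusted$delta_p_mmHg / d0
}

#' Aggregate normalized replicates as mean +/- SEM
#'
#' @param normalized list (or matrix, columns = replicates) of normalized
#'   series on a shared grid; n >= 2.
#' @param time_s optional time grid to carry through.
#' @return object of class `normalized_decline`: data.frame `time_s`,
#'   `mean`, `sem`, `n`, with the per-replicate matrix as attribute
#'   `"replicates"`.
#' @export
aggregate_replicates <- function(normalized, time_s = NULL) {
  m <- if (is.matrix(normalized)) normalized else do.call(cbind, normalized)
  n <- ncol(m)
  if (n < 2) stop("SEM undefined for fewer than 2 replicates", call. = FALSE)
  out <- data.frame(
    time_s = if (is.null(time_s)) seq_len(nrow(m)) - 1 else time_s,
    mean = rowMeans(m),
    sem = apply(m, 1, stats::sd) / sqrt(n),
    n = n)
  class(out) <- c("normalized_decline", "data.frame")
  attr(out, "replicates") <- m
  out
}

#' Run the full drift-corrected normalization pipeline on a study
#'
#' For each group, estimates the biased error from the group's POM controls,
#' error-adjusts and normalizes every clot replicate, and aggregates to
#' mean +/- SEM.
#'
#' @param recordings a [generate_study()] result (or any named list of
#'   recordings with group/filling metadata).
#' @param bin_s analysis-grid bin width, s.
#' @return named list (one `normalized_decline` per group).
#' @export
analyze_study <- function(recordings, bin_s = 1) {
  meta <- lapply(recordings, function(r) r$meta)
  groups <- unique(vapply(meta, `[[`, "", "group"))
  out <- list()
  for (g in groups) {
    is_g <- vapply(meta, function(m) m$group == g, logical(1))
    is_pom <- vapply(meta, function(m) m$filling == "POM", logical(1))
    controls <- lapply(recordings[is_g & is_pom], decline_series, bin_s = bin_s)
    clots <- lapply(recordings[is_g & !is_pom], decline_series, bin_s = bin_s)
    if (length(controls) < 2 || length(clots) == 0)
      stop(sprintf("group %s lacks control or clot arms", g), call. = FALSE)
    drift <- biased_error(controls)
    norm <- lapply(clots, function(cl) normalize_decline(error_adjust(cl, drift)))
    out[[g]] <- aggregate_replicates(norm, time_s = drift$time_s)
  }
  out
}

#' Mean of a normalized-decline result over a time window
#'
#' Convenience summary (e.g. the late plateau): the mean of the group-mean
#' normalized decline over `window`.
#'
#' @param result a `normalized_decline`.
#' @param window `c(start, stop)` in s.
#' @return scalar.
#' @export
plateau_value <- function(result, window) {
  i <- result$time_s >= window[1] & result$time_s <= window[2]
  if (!any(i)) stop("window contains no samples", call. = FALSE)
  mean(result$mean[i])
}
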