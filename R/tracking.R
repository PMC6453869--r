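#' Track condensations backwards through a time series
#'
#' Condensations are identified at the final timepoint and tracked
#' backwards to their initial establishment: each tracked condensation is
#' linked to the nearest-position peak in the previous frame, greedily by
#' distance with exclusion (no two tracks may claim the same peak), and
#' only within a gating distance of
#' `max(gate_floor_um, 0.5 x current condensation length)`. A track ends
#' (going backwards) at the earliest frame in which it still has a match;
#' that frame's time is its establishment time.
#'
#' The number of tracks always equals the number of condensations in the
#' final frame.
#'
#' @param measurements_by_time list of per-timepoint data frames (as from
#'   [measure_groove_frame()]), ordered by time; each needs at least a
#'   `position_um` column.
#' @param times numeric vector of timepoints in hours (default
#'   `(seq - 1) * 0.5`, one frame per 30 min).
#' @param gate_floor_um minimum gating distance in um (default 10).
#' @return Data frame of class `condensation_tracks`: one row per track
#'   per matched timepoint, columns `track_id`, `t_h`, the measurement
#'   columns, and attribute `establishment` (data frame `track_id`,
#'   `establishment_time`).
#' @export
track_backwards <- function(measurements_by_time, times = NULL,
                            gate_floor_um = 10) {
  Tn <- length(measurements_by_time)
  stopifnot(Tn >= 1L)
  if (is.null(times)) times <- (seq_len(Tn) - 1) * 0.5
  stopifnot(length(times) == Tn, !is.unsorted(times, strictly = TRUE))
  final <- measurements_by_time[[Tn]]
  if (is.null(final) || nrow(final) == 0L) {
    out <- data.frame(track_id = integer(), t_h = numeric())
    attr(out, "establishment") <- data.frame(track_id = integer(),
                                             establishment_time = numeric())
    class(out) <- c("condensation_tracks", class(out))
    return(out)
  }
  n_tracks <- nrow(final)
  rows <- vector("list", Tn)
  final$track_id <- seq_len(n_tracks)
  final$t_h <- times[Tn]
  rows[[Tn]] <- final
  ## state per track: current position/length, active flag
  cur_pos <- final$position_um
  cur_len <- if ("length_um" %in% names(final)) final$length_um else rep(0, n_tracks)
  active <- rep(TRUE, n_tracks)
  if (Tn > 1L) {
    for (k in seq(Tn - 1L, 1L)) {
      if (!any(active)) break
      cand <- measurements_by_time[[k]]
      if (is.null(cand) || nrow(cand) == 0L) { active[] <- FALSE; break }
      tr_idx <- which(active)
      pairs <- expand.grid(tr = tr_idx, cd = seq_len(nrow(cand)))
      pairs$d <- abs(cur_pos[pairs$tr] - cand$position_um[pairs$cd])
      gate <- pmax(gate_floor_um, 0.5 * ifelse(is.na(cur_len[pairs$tr]), 0,
                                               cur_len[pairs$tr]))
      pairs <- pairs[pairs$d <= gate, , drop = FALSE]
      pairs <- pairs[order(pairs$d), , drop = FALSE]
      matched_tr <- logical(n_tracks)
      matched_cd <- logical(nrow(cand))
      links <- list()
      for (q in seq_len(nrow(pairs))) {
        tr <- pairs$tr[q]; cd <- pairs$cd[q]
        if (matched_tr[tr] || matched_cd[cd]) next
        matched_tr[tr] <- TRUE; matched_cd[cd] <- TRUE
        links[[length(links) + 1L]] <- c(tr = tr, cd = cd)
      }
      active[!matched_tr] <- FALSE
      if (length(links) > 0L) {
        lk <- do.call(rbind, links)
        taken <- cand[lk[, "cd"], , drop = FALSE]
        taken$track_id <- lk[, "tr"]
        taken$t_h <- times[k]
        rows[[k]] <- taken
        cur_pos[lk[, "tr"]] <- taken$position_um
        if ("length_um" %in% names(taken)) cur_len[lk[, "tr"]] <- taken$length_um
      }
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$track_id, out$t_h), , drop = FALSE]
  rownames(out) <- NULL
  est <- stats::aggregate(t_h ~ track_id, data = out, FUN = min)
  names(est) <- c("track_id", "establishment_time")
  attr(out, "establishment") <- est
  class(out) <- c("condensation_tracks", class(out))
  out
}

#' Earliest time a metric enters its final plateau band
#'
#' The plateau time is the earliest timepoint from which the metric stays
#' within +/- `band` (relative) of its final value through to the end of
#' the series.
#'
#' @param t timepoints (hours), increasing.
#' @param v metric values at those timepoints.
#' @param band relative half-width of the plateau band (default 0.10).
#' @return The plateau time in hours (`NA` if fewer than 2 finite
#'   points).
#' @export
plateau_time <- function(t, v, band = 0.10) {
  ok <- is.finite(v)
  t <- t[ok]; v <- v[ok]
  n <- length(v)
  if (n < 2L) return(NA_real_)
  final <- v[n]
  tol <- band * max(abs(final), .Machine$double.eps)
  inband <- abs(v - final) <= tol
  ## last index before which some point is out of band
  k <- n
  while (k > 1L && inband[k - 1L]) k <- k - 1L
  t[k]
}

#' Per-timepoint summary of a tracked series
#'
#' Means and dispersion of length, width, aspect ratio and prominence per
#' timepoint (averaging over condensations), the condensation count per
#' timepoint, and the plateau time of each metric (earliest time after
#' which it stays within +/-10% of its final value).
#'
#' @param tracks a `condensation_tracks` data frame (or any data frame
#'   with `t_h` and metric columns).
#' @param metrics metric columns to summarize (defaults to those present
#'   among `length_um`, `width_um`, `aspect_ratio`, `prominence`).
#' @param band plateau band, see [plateau_time()].
#' @return List with `summary` (data frame: `t_h`, `n`, `<metric>_mean`,
#'   `<metric>_sd`) and `plateau_times` (named vector, including
#'   `count`).
#' @export
summarize_series <- function(tracks,
                             metrics = NULL,
                             band = 0.10) {
  stopifnot("t_h" %in% names(tracks))
  if (is.null(metrics))
    metrics <- intersect(c("length_um", "width_um", "aspect_ratio", "prominence"),
                         names(tracks))
  ts <- sort(unique(tracks$t_h))
  if (length(ts) == 0L) stop("no timepoints to summarize")
  summ <- data.frame(t_h = ts,
                     n = vapply(ts, function(tt) sum(tracks$t_h == tt), numeric(1)))
  for (m in metrics) {
    if (all(!is.finite(tracks[[m]]))) {
      warning("metric ", m, " is entirely missing; summary is NA")
      summ[[paste0(m, "_mean")]] <- NA_real_
      summ[[paste0(m, "_sd")]] <- NA_real_
      next
    }
    summ[[paste0(m, "_mean")]] <-
      vapply(ts, function(tt) mean(tracks[[m]][tracks$t_h == tt], na.rm = TRUE),
             numeric(1))
    summ[[paste0(m, "_sd")]] <-
      vapply(ts, function(tt) sd(tracks[[m]][tracks$t_h == tt], na.rm = TRUE),
             numeric(1))
  }
  pt <- vapply(metrics, function(m)
    plateau_time(summ$t_h, summ[[paste0(m, "_mean")]], band), numeric(1))
  pt <- c(pt, count = plateau_time(summ$t_h, summ$n, band))
  list(summary = summ, plateau_times = pt)
}

#' Analytic plateau-entry time of a logistic growth curve
#'
#' For a metric growing as `final / (1 + exp(-rate * (t - t_mid)))`
#' observed until `t_end`, returns the exact time at which the curve
#' enters the band within `band` (relative) of its value at `t_end` --
#' the ground truth against which [plateau_time()] estimates are
#' compared on synthetic series.
#'
#' @param t_mid,rate logistic midpoint (h) and rate (1/h).
#' @param t_end final observed time (h).
#' @param band relative band half-width (default 0.10).
#' @return Crossing time in hours (never below 0).
#' @export
logistic_plateau_time <- function(t_mid, rate, t_end, band = 0.10) {
  f_end <- 1 / (1 + exp(-rate * (t_end - t_mid)))
  target <- (1 - band) * f_end
  if (target >= 1) return(0)
  ## solve 1/(1+exp(-r(t-m))) = target
  t <- t_mid - log(1 / target - 1) / rate
  max(0, t)
}
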