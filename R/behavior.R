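#' Per-frame motion filter
#'
#' A frame is "in motion" when the fish moved at least one-third of its
#' body length since the previous frame; the first frame inherits the
#' second frame's state. Fish that spend less than 10% of the assay in
#' motion are excluded from downstream social metrics (see
#' [exclude_inactive()]).
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @return List with logical `moving` per frame and `pct_in_motion`
#'   (percentage of frames in motion).
#' @export
motion_mask <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$body_length))
    stop("body_length is required for the motion filter", call. = FALSE)
  pos <- traj$positions
  n <- nrow(pos)
  if (n < 2L) stop("motion filter needs at least 2 frames", call. = FALSE)
  disp <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                          pos[-n, , drop = FALSE])^2))
  moving <- c(NA, disp >= traj$body_length / 3)
  moving[1L] <- moving[2L]
  list(moving = moving, pct_in_motion = 100 * mean(moving))
}

#' Social-orienting metrics for a dyad-assay trajectory
#'
#' Quantifies sociality towards the transparent divider that separates the
#' focal fish from its partner: `relative_proximity` is the per-frame mean
#' of `1 - d/L`, where `d` is the perpendicular distance to the divider
#' wall and `L` the arena extent perpendicular to it (1 = at the divider);
#' `pct_orienting_45_90` is the percentage of heading-defined frames whose
#' heading, folded against the divider line into \[0, 90\] degrees, falls
#' in \[45, 90\]; `swim_speed` is mean frame displacement times fps (mm/s).
#'
#' When the trajectory carries no heading channel, headings are taken from
#' frame displacements of moving frames; stationary frames carry the last
#' defined heading, and frames before the first movement are dropped from
#' the orienting denominator.
#'
#' @param traj a [trajectory()].
#' @return List of class `"social_metrics"`: `relative_proximity`,
#'   `mean_divider_distance` (mm), `pct_orienting_45_90`, `pct_in_motion`,
#'   `swim_speed`, `n_heading_frames`, `included` (set by
#'   [exclude_inactive()], `NA` here).
#' @export
social_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  geom <- divider_geometry(traj)
  pos <- traj$positions
  n <- nrow(pos)
  mm <- motion_mask(traj)
  heading <- traj$heading
  if (is.null(heading)) {
    heading <- rep(NA_real_, n)
    if (n >= 2L) {
      dx <- c(NA, diff(pos[, 1]))
      dy <- c(NA, diff(pos[, 2]))
      move <- mm$moving & !is.na(dx) & (dx != 0 | dy != 0)
      heading[move] <- atan2(dy[move], dx[move]) * 180 / pi
      # carry last defined heading through stationary frames
      for (i in seq_len(n)[-1L])
        if (is.na(heading[i])) heading[i] <- heading[i - 1L]
    }
  }
  ok <- !is.na(heading)
  theta <- folded_divider_angle(heading[ok], geom$dir)
  pct_orient <- if (any(ok)) 100 * mean(theta >= 45 & theta <= 90) else NA_real_
  disp <- sqrt(rowSums((pos[-1L, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
  structure(list(
    relative_proximity = mean(1 - geom$d / geom$L),
    mean_divider_distance = mean(geom$d),
    pct_orienting_45_90 = pct_orient,
    pct_in_motion = mm$pct_in_motion,
    swim_speed = mean(disp) * traj$fps,
    n_heading_frames = sum(ok),
    included = NA), class = "social_metrics")
}

# angle between heading (degrees) and the divider line, folded into [0, 90]
folded_divider_angle <- function(heading_deg, divider_dir) {
  h <- heading_deg * pi / 180
  dotp <- abs(cos(h) * divider_dir[1] + sin(h) * divider_dir[2])
  acos(pmin(1, dotp)) * 180 / pi
}

#' @export
print.social_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<social_metrics> proximity %.3f | orienting 45-90: %.1f%% | ",
    "in motion %.1f%% | speed %.2f mm/s%s\n"),
    x$relative_proximity, x$pct_orienting_45_90, x$pct_in_motion,
    x$swim_speed,
    if (isFALSE(x$included)) " | EXCLUDED" else ""))
  invisible(x)
}

#' Exclude fish inactive for most of the assay
#'
#' Marks fish that spent less than `min_pct` percent of the experiment in
#' motion as excluded (strict inequality: a fish at exactly the threshold
#' is retained).
#'
#' @param metrics list of [social_metrics()] results, or a data frame with
#'   a `pct_in_motion` column.
#' @param min_pct threshold percentage (default 10).
#' @return Same structure with the `included` flag set.
#' @export
exclude_inactive <- function(metrics, min_pct = 10) {
  check_scalar(min_pct, "min_pct", lower = 0, upper = 100)
  if (is.data.frame(metrics)) {
    metrics$included <- metrics$pct_in_motion >= min_pct
    return(metrics)
  }
  lapply(metrics, function(m) {
    m$included <- m$pct_in_motion >= min_pct
    m
  })
}

#' Social-metrics table for many fish
#'
#' @param trajs list of [trajectory()] objects.
#' @param ids,condition optional per-fish identifiers and condition labels.
#' @param min_pct motion-filter threshold passed to [exclude_inactive()].
#' @return Data frame with one row per fish: `fish_id`, optional
#'   `condition`, `relative_proximity`, `pct_orienting_45_90`,
#'   `pct_in_motion`, `swim_speed_mm_s`, `included`.
#' @export
behavior_table <- function(trajs, ids = NULL, condition = NULL, min_pct = 10) {
  ms <- lapply(trajs, social_metrics)
  df <- data.frame(
    fish_id = ids %||% seq_along(trajs),
    relative_proximity = vapply(ms, `[[`, 0, "relative_proximity"),
    pct_orienting_45_90 = vapply(ms, `[[`, 0, "pct_orienting_45_90"),
    pct_in_motion = vapply(ms, `[[`, 0, "pct_in_motion"),
    swim_speed_mm_s = vapply(ms, `[[`, 0, "swim_speed"))
  if (!is.null(condition)) df <- cbind(df[1], condition = condition, df[-1])
  exclude_inactive(df, min_pct = min_pct)
}

#' Optomotor response curve and magnitude
#'
#' Averages distance-to-center traces over trials aligned on stimulus
#' onset and reports the response magnitude: mean distance at stimulus
#' onset minus mean distance at stimulus offset (net centerward
#' displacement during the stimulus window).
#'
#' @param trials list of optomotor trials as produced by
#'   [gen_optomotor()]: each a list with numeric `distance_to_center`
#'   (mm per frame), `fps`, and `stimulus_window` = c(t_on, t_off) seconds.
#' @return List with `time` (s), `mean_distance` (mm), `response_mm`, and
#'   `n_trials`.
#' @export
optomotor_curve <- function(trials) {
  if (!length(trials)) stop("no optomotor trials supplied", call. = FALSE)
  nf <- min(vapply(trials, function(tr) length(tr$distance_to_center), 0L))
  fps <- trials[[1]]$fps
  win <- trials[[1]]$stimulus_window
  if (win[1] >= win[2]) stop("stimulus window must satisfy t_on < t_off",
                             call. = FALSE)
  m <- vapply(trials, function(tr) tr$distance_to_center[seq_len(nf)],
              numeric(nf))
  avg <- rowMeans(m)
  t <- (seq_len(nf) - 1L) / fps
  i_on <- which.min(abs(t - win[1]))
  i_off <- which.min(abs(t - win[2]))
  list(time = t, mean_distance = avg,
       response_mm = avg[i_on] - avg[i_off], n_trials = length(trials))
}
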