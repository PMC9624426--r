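#' Parameters for the synthetic dyad-assay generator
#'
#' Two sibling fish swim in adjoining 50 x 50 mm arenas separated by a
#' transparent divider and are imaged at 10 fps for 10 minutes, mirroring
#' the dyad social-orienting assay. Swimming is bout-structured: bout
#' onsets are Poisson at `bout_rate`, each bout moves the fish for half a
#' second at per-frame steps drawn around `swim_speed_mean / fps`, and the
#' fish is stationary between bouts (so the in-motion filter has
#' non-trivial behaviour). On each bout the fish behaves socially with
#' probability `sociality`: it heads for the divider-adjacent strip and,
#' once there, draws a heading whose folded angle against the divider is
#' uniform on \[45, 90\] degrees; otherwise it draws a uniform random
#' heading. Socially engaged fish are also more active: the effective bout
#' rate is `bout_rate * (1 + 0.5 * sociality)`, so activity and speed rise
#' with sociality as they do in socially engaged larvae.
#'
#' @param sociality fraction of social bouts, in \[0, 1\].
#' @param swim_speed_mean mean swim speed while moving (mm/s).
#' @param bout_rate baseline bout onset rate (bouts/s).
#' @param arena_width,arena_length arena size (mm).
#' @param fps frames per second.
#' @param duration assay duration (s).
#' @param body_length fish body length (mm).
#' @param strip_mm depth of the divider-adjacent strip (mm).
#' @param seed integer RNG seed.
#' @return Validated list of class `"dyad_params"`.
#' @export
dyad_params <- function(sociality = 0.5, swim_speed_mean = 25, bout_rate = 1,
                        arena_width = 50, arena_length = 50, fps = 10,
                        duration = 600, body_length = 4, strip_mm = 5,
                        seed = 1) {
  check_scalar(sociality, "sociality", lower = 0, upper = 1)
  check_scalar(swim_speed_mean, "swim_speed_mean", lower = 0, strict_lower = TRUE)
  check_scalar(bout_rate, "bout_rate", lower = 0, strict_lower = TRUE)
  check_scalar(arena_width, "arena_width", lower = 0, strict_lower = TRUE)
  check_scalar(arena_length, "arena_length", lower = 0, strict_lower = TRUE)
  check_scalar(fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(body_length, "body_length", lower = 0, strict_lower = TRUE)
  check_scalar(strip_mm, "strip_mm", lower = 0, strict_lower = TRUE)
  check_scalar(seed, "seed")
  structure(as.list(environment()), class = "dyad_params")
}

#' Generate a synthetic dyad of fish trajectories
#'
#' @param params a [dyad_params()] object.
#' @return List of two [trajectory()] objects. Fish 1 has its divider on
#'   the `"+x"` wall, fish 2 (the mirrored arena) on `"-x"`.
#' @export
gen_dyad <- function(params) {
  stopifnot(inherits(params, "dyad_params"))
  list(with_seed(sub_seed(params$seed, 1L), gen_one_fish(params, "+x")),
       with_seed(sub_seed(params$seed, 2L), gen_one_fish(params, "-x")))
}

gen_one_fish <- function(p, divider) {
  n <- as.integer(round(p$duration * p$fps))
  w <- p$arena_width; l <- p$arena_length
  rate <- p$bout_rate * (1 + 0.5 * p$sociality)
  p_bout <- min(1, rate / p$fps)
  move_frames <- max(1L, as.integer(round(0.5 * p$fps)))
  step_mean <- p$swim_speed_mean / p$fps
  div_x <- if (divider == "+x") w else 0
  in_strip <- function(x) abs(x - div_x) <= p$strip_mm
  pos <- matrix(0, n, 2L)
  heading <- rep(NA_real_, n)
  x <- stats::runif(1, 0, w); y <- stats::runif(1, 0, l)
  h <- stats::runif(1, 0, 2 * pi)
  pos[1L, ] <- c(x, y)
  moving_left <- 0L
  for (f in 2:n) {
    if (stats::runif(1) < p_bout) {
      moving_left <- move_frames
      if (stats::runif(1) < p$sociality) {
        if (in_strip(x)) {
          # folded angle against the divider line (the y axis) in [45, 90]
          th <- stats::runif(1, 45, 90) * pi / 180
          sx <- sample(c(-1, 1), 1L); sy <- sample(c(-1, 1), 1L)
          h <- atan2(sy * cos(th), sx * sin(th))
        } else {
          # turn towards the divider, roughly perpendicular to it
          tgt <- c(div_x + (if (divider == "+x") -1 else 1) *
                     stats::runif(1, 0, p$strip_mm),
                   min(max(y + stats::rnorm(1, 0, 2), 0), l))
          h <- atan2(tgt[2] - y, tgt[1] - x)
        }
      } else {
        h <- stats::runif(1, 0, 2 * pi)
      }
    }
    if (moving_left > 0L) {
      step <- abs(stats::rnorm(1, step_mean, 0.2 * step_mean))
      nx <- x + step * cos(h); ny <- y + step * sin(h)
      # reflective walls (preserves the folded heading-vs-divider angle)
      refl_x <- FALSE; refl_y <- FALSE
      if (nx < 0) { nx <- -nx; refl_x <- TRUE }
      if (nx > w) { nx <- 2 * w - nx; refl_x <- TRUE }
      if (ny < 0) { ny <- -ny; refl_y <- TRUE }
      if (ny > l) { ny <- 2 * l - ny; refl_y <- TRUE }
      nx <- min(max(nx, 0), w); ny <- min(max(ny, 0), l)
      if (refl_x || refl_y) {
        hx <- cos(h) * (if (refl_x) -1 else 1)
        hy <- sin(h) * (if (refl_y) -1 else 1)
        h <- atan2(hy, hx)
      }
      x <- nx; y <- ny
      moving_left <- moving_left - 1L
    }
    pos[f, ] <- c(x, y)
    heading[f] <- h * 180 / pi
  }
  heading[1L] <- heading[2L]
  trajectory(pos, fps = p$fps, body_length = p$body_length,
             arena = list(width = w, length = l, divider = divider),
             heading = heading)
}

#' Generate synthetic optomotor trials
#'
#' Each trial is a distance-to-center trace at 30 frames/s: 20 s of
#' stimulus during which the radial position decays centerward at
#' `attraction` mm/s plus noise, then a 20 s refractory period of outward
#' drift, matching the concentric-ring assay in which rings simulate
#' motion toward the dish center. The number of trials per fish in the
#' original assay ranged from 46 to 59; passing `n_trials = NULL` draws a
#' count uniformly from that range.
#'
#' @param attraction centerward drift during stimulus (mm/s, >= 0).
#' @param n_trials number of trials, or `NULL` to draw from 46:59.
#' @param seed integer RNG seed.
#' @param start_radius_mm starting distance to center (mm).
#' @param noise_sd_mm per-frame radial noise SD (mm); 0 gives the
#'   noiseless closed-form trace.
#' @param outward_mm_s outward drift rate during the refractory period.
#' @param fps frames per second (30 in the assay).
#' @param stim_s,refractory_s stimulus and refractory durations (s).
#' @return List of trials, each with `distance_to_center`, `fps`, and
#'   `stimulus_window`.
#' @export
gen_optomotor <- function(attraction, n_trials = NULL, seed = 1,
                          start_radius_mm = 30, noise_sd_mm = 0.5,
                          outward_mm_s = 0.5, fps = 30, stim_s = 20,
                          refractory_s = 20) {
  check_scalar(attraction, "attraction", lower = 0)
  check_scalar(start_radius_mm, "start_radius_mm", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd_mm, "noise_sd_mm", lower = 0)
  check_scalar(seed, "seed")
  with_seed(seed, {
    if (is.null(n_trials)) n_trials <- sample(46:59, 1L)
    check_scalar(n_trials, "n_trials", lower = 1)
    n_stim <- as.integer(round(stim_s * fps))
    n_ref <- as.integer(round(refractory_s * fps))
    lapply(seq_len(n_trials), function(i) {
      dr <- c(rep(-attraction / fps, n_stim), rep(outward_mm_s / fps, n_ref))
      if (noise_sd_mm > 0)
        dr <- dr + stats::rnorm(length(dr), 0, noise_sd_mm / fps)
      r <- start_radius_mm + cumsum(c(0, dr))
      r <- pmax(r, 0)
      list(distance_to_center = r, fps = fps,
           stimulus_window = c(0, stim_s))
    })
  })
}
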