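#' Fish trajectory objects and CSV input/output
#'
#' A `trajectory` holds the per-frame 2D position of one fish in a known
#' rectangular arena, with an optional per-frame heading (degrees). The
#' arena records which wall carries the transparent divider to the partner
#' fish: `"+x"` (wall at `x = width`), `"-x"` (`x = 0`), `"+y"` or `"-y"`.
#'
#' @param positions numeric matrix or data frame with columns x, y (mm).
#' @param fps frames per second (behavioural recordings here are 10 fps).
#' @param body_length fish body length (mm), required by the motion filter.
#' @param arena list with `width`, `length` (mm) and `divider` side.
#' @param heading optional per-frame heading in degrees (NA where
#'   undefined); derived from displacements when absent.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(positions, fps = 10, body_length = 4,
                       arena = list(width = 50, length = 50, divider = "+x"),
                       heading = NULL) {
  pos <- as.matrix(positions)[, 1:2, drop = FALSE]
  colnames(pos) <- c("x", "y")
  if (!is.numeric(pos) || anyNA(pos) || !all(is.finite(pos)))
    stop("positions must be finite numeric x,y per frame", call. = FALSE)
  check_scalar(fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar(body_length, "body_length", lower = 0, strict_lower = TRUE)
  stopifnot(is.list(arena), all(c("width", "length", "divider") %in% names(arena)))
  if (!arena$divider %in% c("+x", "-x", "+y", "-y"))
    stop('arena$divider must be one of "+x", "-x", "+y", "-y"', call. = FALSE)
  tol <- 1e-9
  if (any(pos[, 1] < -tol | pos[, 1] > arena$width + tol |
          pos[, 2] < -tol | pos[, 2] > arena$length + tol))
    stop("positions fall outside the arena", call. = FALSE)
  if (!is.null(heading)) {
    heading <- as.numeric(heading)
    if (length(heading) != nrow(pos))
      stop("heading must have one value per frame", call. = FALSE)
  }
  structure(list(positions = pos, heading = heading, fps = fps,
                 body_length = body_length, arena = arena),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames at %g fps (%.1f s), arena %g x %g mm, divider %s\n",
    nrow(x$positions), x$fps, nrow(x$positions) / x$fps,
    x$arena$width, x$arena$length, x$arena$divider))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @param file CSV path. Columns written: `frame`, `t_s`, `x_mm`, `y_mm`,
#'   `heading_deg`.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$positions)
  df <- data.frame(frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1L) / traj$fps,
                   x_mm = traj$positions[, 1], y_mm = traj$positions[, 2],
                   heading_deg = if (is.null(traj$heading)) NA_real_ else traj$heading)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname trajectory
#' @export
read_trajectory_csv <- function(file, fps = 10, body_length = 4,
                                arena = list(width = 50, length = 50,
                                             divider = "+x")) {
  df <- utils::read.csv(file)
  req <- c("x_mm", "y_mm")
  if (!all(req %in% names(df)))
    stop("trajectory CSV must contain x_mm and y_mm columns", call. = FALSE)
  heading <- if ("heading_deg" %in% names(df) && !all(is.na(df$heading_deg)))
    df$heading_deg else NULL
  trajectory(cbind(df$x_mm, df$y_mm), fps = fps, body_length = body_length,
             arena = arena, heading = heading)
}

# signed perpendicular distance of every frame to the divider wall, plus
# the arena extent perpendicular to the divider and the divider direction
# (unit vector along the divider line).
divider_geometry <- function(traj) {
  a <- traj$arena
  pos <- traj$positions
  switch(a$divider,
    "+x" = list(d = a$width - pos[, 1], L = a$width, dir = c(0, 1)),
    "-x" = list(d = pos[, 1], L = a$width, dir = c(0, 1)),
    "+y" = list(d = a$length - pos[, 2], L = a$length, dir = c(1, 0)),
    "-y" = list(d = pos[, 2], L = a$length, dir = c(1, 0)))
}
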