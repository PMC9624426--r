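#' Parameters for the branching-process arbor generator
#'
#' Arbors grow from a soma as a discrete branching process: at every
#' elongation step of `step_um` micrometres, each growing tip branches with
#' probability `branch_prob_per_um * step_um`, terminates with probability
#' `terminate_prob_per_um * step_um`, and otherwise elongates. Daughters of
#' a branch event deflect from the parent direction by a fixed angle
#' (default 40 degrees) at independent random azimuths; the trunk direction
#' is uniform on the sphere. Growth stops at `max_depth` bifurcations on a
#' path or when total cable length would exceed `max_total_um`.
#'
#' @param branch_prob_per_um branching rate per micrometre of growth.
#' @param step_um elongation step (um).
#' @param terminate_prob_per_um termination rate per micrometre.
#' @param max_depth maximum bifurcations allowed on any path.
#' @param max_total_um hard cap on total cable length (um).
#' @param min_total_um minimum outgrowth before termination events are
#'   allowed (um); models the obligatory extension of a primary neurite.
#' @param branch_angle_deg fixed daughter deflection angle (degrees).
#' @param wiggle_deg tortuosity: each elongation step deflects the growth
#'   direction by this fixed angle at a random azimuth (degrees); 0 grows
#'   perfectly straight neurites.
#' @param confine_radius_um radius of the spherical territory around the
#'   soma that confines growth (um); growth reaching the boundary is
#'   redirected inward, as arbors are confined to their brain region.
#' @param trunk_dir length-3 initial trunk direction, or `NULL` for a
#'   uniform random orientation. A fixed direction emulates neurons
#'   registered to a common reference frame.
#' @param seed integer RNG seed.
#' @return A validated list of class `"arbor_params"`.
#' @export
arbor_params <- function(branch_prob_per_um = 0.04, step_um = 1,
                         terminate_prob_per_um = 0.005, max_depth = 12,
                         max_total_um = 400, min_total_um = 0,
                         branch_angle_deg = 40, wiggle_deg = 15,
                         confine_radius_um = 150, trunk_dir = NULL,
                         seed = 1) {
  check_scalar(branch_prob_per_um, "branch_prob_per_um", lower = 0)
  check_scalar(step_um, "step_um", lower = 0, strict_lower = TRUE)
  check_scalar(terminate_prob_per_um, "terminate_prob_per_um", lower = 0)
  check_scalar(max_depth, "max_depth", lower = 0)
  check_scalar(max_total_um, "max_total_um", lower = 0, strict_lower = TRUE)
  check_scalar(min_total_um, "min_total_um", lower = 0, upper = max_total_um)
  check_scalar(branch_angle_deg, "branch_angle_deg", lower = 0, upper = 90)
  check_scalar(wiggle_deg, "wiggle_deg", lower = 0, upper = 90)
  check_scalar(confine_radius_um, "confine_radius_um", lower = 0,
               strict_lower = TRUE)
  if (!is.null(trunk_dir)) {
    stopifnot(is.numeric(trunk_dir), length(trunk_dir) == 3L,
              sum(trunk_dir^2) > 0)
    trunk_dir <- trunk_dir / sqrt(sum(trunk_dir^2))
  }
  check_scalar(seed, "seed")
  if (branch_prob_per_um * step_um > 1)
    stop("branch probability per step exceeds 1; reduce branch_prob_per_um or step_um",
         call. = FALSE)
  if (terminate_prob_per_um * step_um > 1)
    stop("termination probability per step exceeds 1", call. = FALSE)
  if ((branch_prob_per_um + terminate_prob_per_um) * step_um > 1)
    stop("branch + termination probability per step exceeds 1", call. = FALSE)
  structure(list(branch_prob_per_um = branch_prob_per_um, step_um = step_um,
                 terminate_prob_per_um = terminate_prob_per_um,
                 max_depth = max_depth, max_total_um = max_total_um,
                 min_total_um = min_total_um,
                 branch_angle_deg = branch_angle_deg,
                 wiggle_deg = wiggle_deg,
                 confine_radius_um = confine_radius_um,
                 trunk_dir = trunk_dir, seed = seed),
            class = "arbor_params")
}

# unit vector uniform on the sphere
runif_sphere <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

# rotate `dir` by `angle` radians towards a random azimuth around itself
deflect <- function(dir, angle) {
  # orthonormal frame around dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  az <- stats::runif(1, 0, 2 * pi)
  cos(angle) * dir + sin(angle) * (cos(az) * u + sin(az) * v)
}

#' Generate synthetic neuron arbors
#'
#' Draws `n` arbors from the branching process described in
#' [arbor_params()]. Stands in for reconstructed ventral telencephalic
#' neurons so that morphometry, Sholl analysis and morphotype clustering
#' can be exercised with a known, tunable branching rate.
#'
#' @param params an [arbor_params()] object.
#' @param n number of arbors.
#' @return List of `n` [neuron_arbor()] objects.
#' @export
gen_arbors <- function(params, n = 1) {
  stopifnot(inherits(params, "arbor_params"))
  check_scalar(n, "n", lower = 1)
  lapply(seq_len(n), function(i)
    with_seed(sub_seed(params$seed, i), gen_one_arbor(params)))
}

gen_one_arbor <- function(p) {
  step <- p$step_um
  p_branch <- p$branch_prob_per_um * step
  p_term <- p$terminate_prob_per_um * step
  angle <- p$branch_angle_deg * pi / 180
  wiggle <- p$wiggle_deg * pi / 180
  rmax <- p$confine_radius_um
  # redirect a direction inward when a step would leave the territory
  confine <- function(pos, dir) {
    if (sqrt(sum((pos + step * dir)^2)) <= rmax) return(dir)
    inward <- -pos / sqrt(sum(pos^2))
    deflect(inward, stats::runif(1, 0, wiggle + 0.2))
  }
  xs <- 0; ys <- 0; zs <- 0; par <- -1L
  total <- 0
  # active tips: node index, direction, bifurcation depth
  trunk <- if (is.null(p$trunk_dir)) runif_sphere() else p$trunk_dir
  tips <- list(list(node = 1L, dir = trunk, depth = 0L))
  while (length(tips) > 0 && total + step <= p$max_total_um + 1e-12) {
    # grow tips breadth-first so the length cap is shared fairly
    tip <- tips[[1]]
    tips <- tips[-1]
    u <- stats::runif(1)
    if (u < p_term) {
      if (total >= p$min_total_um) next
      u <- 1  # termination suppressed during initial outgrowth: elongate
    }
    newpos <- c(xs[tip$node], ys[tip$node], zs[tip$node]) + step * tip$dir
    if (u < p_term + p_branch && u >= p_term && tip$depth < p$max_depth) {
      # bifurcation: the step is taken by two daughters (first one here)
      pos0 <- c(xs[tip$node], ys[tip$node], zs[tip$node])
      d1 <- confine(pos0, deflect(tip$dir, angle))
      d2 <- confine(pos0, deflect(tip$dir, angle))
      for (d in list(d1, d2)) {
        if (total + step > p$max_total_um + 1e-12) break
        np <- pos0 + step * d
        xs <- c(xs, np[1]); ys <- c(ys, np[2]); zs <- c(zs, np[3])
        par <- c(par, tip$node)
        total <- total + step
        tips <- c(tips, list(list(node = length(xs), dir = d,
                                  depth = tip$depth + 1L)))
      }
    } else {
      pos0 <- c(xs[tip$node], ys[tip$node], zs[tip$node])
      newdir <- if (wiggle > 0) deflect(tip$dir, wiggle) else tip$dir
      newdir <- confine(pos0, newdir)
      newpos <- pos0 + step * newdir
      xs <- c(xs, newpos[1]); ys <- c(ys, newpos[2]); zs <- c(zs, newpos[3])
      par <- c(par, tip$node)
      total <- total + step
      tips <- c(tips, list(list(node = length(xs), dir = newdir,
                                depth = tip$depth)))
    }
  }
  n <- length(xs)
  neuron_arbor(data.frame(
    id = seq_len(n), type = c(1L, rep.int(3L, n - 1L)),
    x = xs, y = ys, z = zs, radius = c(2, rep.int(0.5, n - 1L)),
    parent = par))
}

#' Planted two-morphotype arbor populations
#'
#' Generates the benchmark used to validate morphotype recovery: two
#' populations of arbors that differ only in branching rate (default
#' 0.02/um "simple" vs 0.10/um "complex"), grown under a shared regime —
#' guaranteed outgrowth drawn per neuron from `size_range_um` (biological
#' size heterogeneity), strong termination afterwards, tortuous growth
#' confined to a 150 um territory, and a common trunk orientation (as for
#' neurons registered to a reference brain). The high branching rate yields longer,
#' deeper, bushier arbors, mirroring the exuberant morphotypes
#' overrepresented in microbiota-depleted larvae.
#'
#' @param branch_simple,branch_complex branching rates (1/um).
#' @param n arbors per population.
#' @param size_range_um range of per-arbor guaranteed outgrowth (um).
#' @param seed integer RNG seed.
#' @return List with `arbors` (length `2n`) and `group` (factor,
#'   `"simple"`/`"complex"`).
#' @export
gen_morphotype_groups <- function(branch_simple = 0.02,
                                  branch_complex = 0.10, n = 60,
                                  size_range_um = c(750, 850), seed = 1) {
  gen_group <- function(b, sd_off) {
    sizes <- with_seed(sub_seed(seed, sd_off),
                       stats::runif(n, size_range_um[1], size_range_um[2]))
    lapply(seq_len(n), function(i)
      gen_arbors(arbor_params(branch_prob_per_um = b,
                              terminate_prob_per_um = 0.2,
                              min_total_um = sizes[i], max_total_um = 2500,
                              max_depth = 25, wiggle_deg = 15,
                              confine_radius_um = 150, trunk_dir = c(1, 0, 0),
                              seed = sub_seed(seed, sd_off * 1000 + i)), 1)[[1]])
  }
  list(arbors = c(gen_group(branch_simple, 1L), gen_group(branch_complex, 2L)),
       group = factor(rep(c("simple", "complex"), each = n),
                      levels = c("simple", "complex")))
}
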