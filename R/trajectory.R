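#' Variable-density Cartesian trajectory with spiral profile order
#'
#' Generates phase-encode points on the ky-kz grid with density decreasing
#' from the centre: a central ellipse (relative radius `center_frac`) is
#' always fully sampled, and outer points are kept by a seeded
#' radius-weighted score with polynomial decay `density_decay`. The selected
#' points are grouped into spiral-like arms, one per heartbeat: points are
#' sorted centre-out in elliptical radius, and each consecutive radius shell
#' assigns one point per arm by angular rank against golden-angle-rotated
#' target angles. Within an arm the acquisition order is therefore centric
#' (k-space-centre-most point first). Successive arms are rotated by the
#' golden angle; the nominal arm angles are stored as metadata.
#'
#' @param matrix_ky,matrix_kz phase-encode grid sizes
#' @param acceleration undersampling factor (>= 1); used to pick
#'   `n_heartbeats` when that is NULL
#' @param n_segments points acquired per heartbeat
#' @param n_heartbeats number of arms (heartbeats per contrast); default
#'   `round(matrix_ky * matrix_kz / acceleration / n_segments)`
#' @param seed RNG seed for the density draw
#' @param center_frac fully sampled central elliptical radius (0..1)
#' @param density_decay polynomial decay exponent of the sampling density
#' @param twist_per_shell spiral twist of the arm angle per radius shell (rad)
#' @return object of class `caspr_trajectory`: data.frame `points` with
#'   columns hb, seg, ky, kz (signed grid coordinates), plus `arm_angles`,
#'   grid geometry and the golden angle
#' @export
generate_vdcaspr <- function(matrix_ky, matrix_kz, acceleration = 4,
                             n_segments = 16, n_heartbeats = NULL,
                             seed = 1L, center_frac = 0.12,
                             density_decay = 3, twist_per_shell = 0.35) {
  stopifnot(acceleration >= 1)
  if (is.null(n_heartbeats))
    n_heartbeats <- max(1L, round(matrix_ky * matrix_kz / acceleration / n_segments))
  n_arms <- as.integer(n_heartbeats)
  N <- n_arms * as.integer(n_segments)
  ky <- k_freqs(matrix_ky); kz <- k_freqs(matrix_kz)
  pts <- expand.grid(ky = ky, kz = kz, KEEP.OUT.ATTRS = FALSE)
  if (N > nrow(pts))
    stop("requested more points than ky-kz grid slots", call. = FALSE)
  rho <- sqrt((pts$ky / (matrix_ky / 2))^2 + (pts$kz / (matrix_kz / 2))^2)
  set.seed(seed)
  u <- stats::runif(nrow(pts))
  ## central ellipse always wins; outside, low radius strongly favoured
  score <- ifelse(rho <= center_frac, rho - 2, rho^density_decay * u)
  sel <- order(score)[seq_len(N)]
  pts <- pts[sel, ]
  rho <- rho[sel]
  phi <- atan2(pts$kz / max(matrix_kz / 2, 1), pts$ky / (matrix_ky / 2))
  ord <- order(rho)
  pts <- pts[ord, ]; phi <- phi[ord]

  golden <- pi * (3 - sqrt(5))           # golden angle step
  arm_angles <- ((seq_len(n_arms) - 1) * golden) %% (2 * pi)
  hb_of <- integer(N); seg_of <- integer(N)
  for (s in seq_len(n_segments)) {       # radius shell s: one point per arm
    shell <- ((s - 1) * n_arms + 1):(s * n_arms)
    target <- (arm_angles + (s - 1) * twist_per_shell) %% (2 * pi)
    ## rank-match shell point angles to rotated arm target angles
    pt_order <- order(phi[shell] %% (2 * pi))
    assign_arm <- integer(n_arms)
    assign_arm[pt_order] <- order(target)
    hb_of[shell] <- assign_arm
    seg_of[shell] <- s
  }
  points <- data.frame(hb = hb_of, seg = seg_of, ky = pts$ky, kz = pts$kz)
  points <- points[order(points$hb, points$seg), ]
  rownames(points) <- NULL
  structure(list(points = points, arm_angles = arm_angles,
                 matrix_ky = matrix_ky, matrix_kz = matrix_kz,
                 n_segments = as.integer(n_segments), n_heartbeats = n_arms,
                 acceleration = acceleration, golden_angle = golden,
                 center_frac = center_frac, seed = as.integer(seed)),
            class = "caspr_trajectory")
}

#' @exportS3Method base::print
print.caspr_trajectory <- function(x, ...) {
  cat("VD-CASPR trajectory:", nrow(x$points), "points on",
      x$matrix_ky, "x", x$matrix_kz, "grid;",
      x$n_heartbeats, "arms x", x$n_segments, "segments\n")
  invisible(x)
}

## logical ky-kz sampling mask (native FFT index order) for a set of arms
traj_mask <- function(traj, hbs = NULL) {
  m <- matrix(FALSE, traj$matrix_ky, traj$matrix_kz)
  p <- traj$points
  if (!is.null(hbs)) p <- p[p$hb %in% hbs, ]
  m[cbind(k_index(p$ky, traj$matrix_ky), k_index(p$kz, traj$matrix_kz))] <- TRUE
  m
}
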