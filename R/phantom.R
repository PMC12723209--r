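#' Digital phantom specification and construction
#'
#' Builds deterministic tissue-parameter volumes and region masks for the
#' validation phantoms: a 9-vial T1-mapping plate (`t1mes_like`), a 10-vial
#' joint T1/T1rho plate with NiCl2/agar-like parameter spread
#' (`inhouse_t1t1rho`), an 8-vial water-fat plate with fat fractions
#' 0--100\% (`waterfat`), and a simple `cardiac` phantom (torso, myocardial
#' annulus, blood pool, liver). Vial relaxation values are representative
#' defaults spanning T1 50--3000 ms and T1rho 5--300 ms (the physical
#' phantoms' compositions are not tabulated anywhere); they can be
#' overridden via `values`.
#'
#' @param kind phantom kind (see above)
#' @param dims volume dimensions (FH, RL, AP voxels)
#' @param spacing voxel spacing in mm (scalar or length 3, default 2 mm)
#' @param vial_diameter_mm vial diameter (vial phantoms)
#' @param values optional data.frame overriding the per-region table
#'   (columns region, t1_ms, t1rho_ms, m0, fat_fraction)
#' @param seed RNG seed (geometry is deterministic; the seed feeds only
#'   optional jitter-free reproducibility bookkeeping)
#' @return object of class `digital_phantom`: arrays `t1_ms`, `t1rho_ms`,
#'   `m0`, `fat_fraction`; list `masks`; data.frame `regions`; geometry
#' @export
make_phantom <- function(kind = c("inhouse_t1t1rho", "t1mes_like",
                                  "waterfat", "cardiac"),
                         dims = c(96, 96, 8), spacing = 2,
                         vial_diameter_mm = 28, values = NULL, seed = 1L) {
  kind <- match.arg(kind)
  spacing <- rep_len(spacing, 3)
  fov <- dims[1:2] * spacing[1:2]
  rad_vox <- vial_diameter_mm / 2 / spacing[1]
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  circle_mask <- function(x0, y0, r) {
    xi <- matrix(seq_len(dims[1]), dims[1], dims[2])
    yi <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    m2 <- (xi - x0)^2 + (yi - y0)^2 <= r^2
    array(rep(m2, dims[3]), dims)
  }
  ring_centers <- function(n, R) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(cx + R * cos(th), cy + R * sin(th))
  }
  defaults <- switch(kind,
    t1mes_like = {
      cs <- as.matrix(expand.grid(cx + c(-1, 0, 1) * 3 * rad_vox,
                                  cy + c(-1, 0, 1) * 3 * rad_vox))
      list(centers = cs,
           tab = data.frame(region = paste0("vial", 1:9),
                            t1_ms = c(250, 400, 600, 800, 1000, 1200,
                                      1500, 2000, 2600),
                            t1rho_ms = c(40, 50, 60, 70, 80, 90,
                                         100, 120, 140),
                            m0 = 1, fat_fraction = 0))
    },
    inhouse_t1t1rho = {
      list(centers = ring_centers(10, 0.62 * dims[1] / 2),
           tab = data.frame(region = paste0("vial", 1:10),
                            t1_ms = c(200, 350, 500, 650, 800, 950,
                                      1100, 1300, 1700, 2200),
                            t1rho_ms = c(25, 35, 45, 55, 65, 75,
                                         90, 120, 180, 250),
                            m0 = 1, fat_fraction = 0))
    },
    waterfat = {
      list(centers = ring_centers(8, 0.60 * dims[1] / 2),
           tab = data.frame(region = paste0("vial", 1:8),
                            t1_ms = 1000, t1rho_ms = 100, m0 = 1,
                            fat_fraction = c(0, .1, .2, .3, .5, .7, .9, 1)))
    },
    cardiac = NULL)
  if (kind == "cardiac") {
    ellipse <- function(x0, y0, rx, ry) {
      xi <- matrix(seq_len(dims[1]), dims[1], dims[2])
      yi <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
      m2 <- ((xi - x0) / rx)^2 + ((yi - y0) / ry)^2 <= 1
      array(rep(m2, dims[3]), dims)
    }
    torso <- ellipse(cx, cy, 0.45 * dims[1], 0.40 * dims[2])
    epi <- ellipse(cx - 0.08 * dims[1], cy - 0.05 * dims[2],
                   0.20 * dims[1], 0.20 * dims[2])
    endo <- ellipse(cx - 0.08 * dims[1], cy - 0.05 * dims[2],
                    0.12 * dims[1], 0.12 * dims[2])
    liver <- ellipse(cx + 0.25 * dims[1], cy + 0.22 * dims[2],
                     0.12 * dims[1], 0.10 * dims[2]) & torso
    myo <- epi & !endo
    blood <- endo
    body <- torso & !epi & !liver
    masks <- list(body = body, myocardium = myo, blood = blood, liver = liver)
    tab <- data.frame(region = c("body", "myocardium", "blood", "liver"),
                      t1_ms = c(350, 700, 1500, 500),
                      t1rho_ms = c(30, 56, 90, 45),
                      m0 = c(0.7, 1, 1, 0.9), fat_fraction = c(0.3, 0, 0, 0.1))
  } else {
    tab <- defaults$tab
    cs <- defaults$centers
    if (any(cs[, 1] - rad_vox < 1 | cs[, 1] + rad_vox > dims[1] |
            cs[, 2] - rad_vox < 1 | cs[, 2] + rad_vox > dims[2]))
      stop("vials do not fit in the field of view", call. = FALSE)
    masks <- lapply(seq_len(nrow(cs)), function(i)
      circle_mask(cs[i, 1], cs[i, 2], rad_vox))
    names(masks) <- tab$region
    ov <- Reduce(`+`, lapply(masks, as.numeric))
    if (any(ov > 1)) stop("vial masks overlap", call. = FALSE)
  }
  if (!is.null(values)) {
    stopifnot(nrow(values) == nrow(tab))
    tab[names(values)] <- values
  }
  t1 <- array(0, dims); t1r <- array(0, dims)
  m0 <- array(0, dims); ff <- array(0, dims)
  for (i in seq_len(nrow(tab))) {
    m <- masks[[i]]
    t1[m] <- tab$t1_ms[i]; t1r[m] <- tab$t1rho_ms[i]
    m0[m] <- tab$m0[i]; ff[m] <- tab$fat_fraction[i]
  }
  structure(list(kind = kind, t1_ms = t1, t1rho_ms = t1r, m0 = m0,
                 fat_fraction = ff, masks = masks, regions = tab,
                 dims = dims, spacing = spacing, seed = as.integer(seed)),
            class = "digital_phantom")
}

#' @exportS3Method base::print
print.digital_phantom <- function(x, ...) {
  cat("digital phantom '", x$kind, "' ", paste(x$dims, collapse = "x"),
      " voxels @ ", paste(x$spacing, collapse = "x"), " mm\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Smooth synthetic coil sensitivity maps
#'
#' Complex Gaussian-profile sensitivities for coils placed around the
#' in-plane circumference, with a smooth linear phase per coil, normalised
#' to unit sum-of-squares. A single coil returns a uniform map.
#'
#' @param dims volume dimensions
#' @param n_coils number of coils
#' @param seed seed for the phase draw
#' @return complex array (dims, n_coils)
#' @export
coil_maps <- function(dims, n_coils = 8, seed = 1L) {
  if (n_coils == 1) return(array(1 + 0i, c(dims, 1)))
  set.seed(seed)
  xi <- array(rep(seq_len(dims[1])), dims)
  yi <- array(rep(seq_len(dims[2]), each = dims[1]), dims)
  zi <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  S <- array(0 + 0i, c(dims, n_coils))
  R <- 0.55 * max(dims[1:2])
  sig <- 0.35 * max(dims[1:2])
  for (ci in seq_len(n_coils)) {
    th <- 2 * pi * (ci - 1) / n_coils
    x0 <- (dims[1] + 1) / 2 + R * cos(th)
    y0 <- (dims[2] + 1) / 2 + R * sin(th)
    mag <- exp(-((xi - x0)^2 + (yi - y0)^2) / (2 * sig^2))
    ph <- 2 * pi * (stats::runif(1, -0.5, 0.5) * xi / dims[1] +
                    stats::runif(1, -0.5, 0.5) * yi / dims[2]) +
      stats::runif(1, 0, 2 * pi)
    S[, , , ci] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(Mod(S)^2, 1:3, sum))
  for (ci in seq_len(n_coils)) S[, , , ci] <- S[, , , ci] / sos
  S
}

#' Respiratory motion specification for simulated acquisitions
#'
#' A periodic breathing trace: resp(t) = (1 - cos(2 pi t / period)) / 2 in
#' [0, 1] with 0 = end-expiration. Foot-head and right-left translations
#' scale linearly with the trace; an optional smooth nonrigid deformation
#' (a Gaussian-bump displacement field) scales with the trace as well and is
#' discretised to `n_states` amplitude levels so the simulated k-space and
#' the reported ground-truth fields agree exactly.
#'
#' @param amp_fh_mm,amp_rl_mm translation amplitudes (mm)
#' @param period_s breathing period (s)
#' @param nonrigid_amp_mm peak nonrigid displacement (mm); 0 disables
#' @param n_states nonrigid amplitude quantisation levels
#' @return object of class `motion_spec`
#' @export
motion_spec <- function(amp_fh_mm = 8, amp_rl_mm = 2, period_s = 4.2,
                        nonrigid_amp_mm = 0, n_states = 3L) {
  structure(list(amp_fh_mm = amp_fh_mm, amp_rl_mm = amp_rl_mm,
                 period_s = period_s, nonrigid_amp_mm = nonrigid_amp_mm,
                 n_states = as.integer(n_states)),
            class = "motion_spec")
}

## smooth base displacement field (unit amplitude, voxels) for the nonrigid
## component: FH-directed Gaussian bump with a weaker RL coupling
nonrigid_base_field <- function(dims, amp_vox) {
  xi <- array(rep(seq_len(dims[1])), dims)
  yi <- array(rep(seq_len(dims[2]), each = dims[1]), dims)
  g <- exp(-(((xi - dims[1] * 0.55) / (0.30 * dims[1]))^2 +
             ((yi - dims[2] * 0.5) / (0.35 * dims[2]))^2))
  list(amp_vox * g, 0.3 * amp_vox * g, array(0, dims))
}

#' Simulate a full multi-contrast multi-coil k-space acquisition
#'
#' Forward model: per heartbeat, the contrast-weighted complex echo images
#' (steady-state Bloch signal per tissue; fat as a second single-peak
#' species with its own short T1, carrying the chemical-shift phase at each
#' TE) are deformed by the heartbeat's nonrigid motion state, multiplied by
#' the coil sensitivities, Fourier-transformed and sampled at the
#' heartbeat's trajectory arm; the beat's rigid translation is applied as an
#' exact k-space phase ramp (the sensitivities ride with the object), and
#' complex white Gaussian noise is added. Synthetic coronal-projection
#' iNAVs are rendered from the same motion state. The returned ground-truth
#' bundle carries the parameter maps, masks, sensitivities, per-heartbeat
#' motion and the noiseless contrast images.
#'
#' @param phantom [make_phantom()]
#' @param seq,timing sequence and timing objects
#' @param traj [generate_vdcaspr()] trajectory (its ky/kz grid must match
#'   the phantom's dims 1 and 3)
#' @param motion [motion_spec()] or NULL for a static acquisition
#' @param n_coils number of synthetic coils
#' @param noise_sd complex noise SD per real/imaginary component, in units
#'   of the (m0 = 1) k-space scale
#' @param seed RNG seed
#' @param dixon [dixon_config()] supplying TEs and the fat shift
#' @param fat_t1_ms,fat_t1rho_ms relaxation constants of the fat species
#' @return object of class `jointmap_sim`: list with `kspace`
#'   (`jointmap_kspace`), `inavs` (array FH x RL x n_heartbeats), `truth`
#' @export
simulate_acquisition <- function(phantom, seq, timing, traj, motion = NULL,
                                 n_coils = 8, noise_sd = 0, seed = 1L,
                                 dixon = dixon_config(),
                                 fat_t1_ms = 170, fat_t1rho_ms = 50) {
  dims <- phantom$dims
  if (traj$matrix_ky != dims[1] || traj$matrix_kz != dims[3])
    stop("trajectory grid does not match phantom geometry", call. = FALSE)
  set.seed(seed)
  tab <- phantom$regions
  nr <- nrow(tab)
  wsig <- bloch_signals(seq, timing, tab$t1_ms / 1000, tab$t1rho_ms / 1000,
                        m0 = 1)$signals
  fsig <- bloch_signals(seq, timing, fat_t1_ms / 1000, fat_t1rho_ms / 1000,
                        m0 = 1)$signals
  ## noiseless echo images per contrast/echo (reference position)
  W <- lapply(1:4, function(v) {
    img <- array(0, dims)
    for (i in seq_len(nr))
      img[phantom$masks[[i]]] <- wsig[i, v] * tab$m0[i] * (1 - tab$fat_fraction[i])
    img
  })
  Fimg <- lapply(1:4, function(v) {
    img <- array(0, dims)
    for (i in seq_len(nr))
      img[phantom$masks[[i]]] <- fsig[1, v] * tab$m0[i] * tab$fat_fraction[i]
    img
  })
  tes <- c(dixon$te1, dixon$te2)
  I0 <- lapply(1:4, function(v) lapply(1:2, function(e)
    W[[v]] + Fimg[[v]] * exp(2i * pi * dixon$delta_f * tes[e])))

  sens <- coil_maps(dims, n_coils, seed = seed)
  n_arms <- traj$n_heartbeats
  n_hb <- 4L * n_arms
  rr <- rep_len(timing$rr_intervals, n_hb)
  t_hb <- cumsum(c(0, rr))[seq_len(n_hb)]
  if (is.null(motion)) motion <- motion_spec(0, 0, nonrigid_amp_mm = 0)
  resp <- (1 - cos(2 * pi * t_hb / motion$period_s)) / 2
  if (motion$amp_fh_mm == 0 && motion$amp_rl_mm == 0 &&
      motion$nonrigid_amp_mm == 0) resp <- rep(0, n_hb)
  fh_mm <- motion$amp_fh_mm * resp
  rl_mm <- motion$amp_rl_mm * resp
  ## quantised nonrigid states
  if (motion$nonrigid_amp_mm > 0) {
    qlev <- seq(0, 1, length.out = motion$n_states)
    state <- vapply(resp, function(r) which.min(abs(qlev - r)), 1L)
    base <- nonrigid_base_field(dims, motion$nonrigid_amp_mm / phantom$spacing[1])
  } else {
    qlev <- 0; state <- rep(1L, n_hb); base <- NULL
  }
  n_states <- length(qlev)
  ## k-space of each (state, contrast, echo, coil)
  Kst <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    if (!is.null(base) && qlev[s] > 0) {
      u <- lapply(base, function(comp) comp * qlev[s])
      warp <- function(img) warp_volume(img, u)
    } else warp <- identity
    Kst[[s]] <- lapply(1:4, function(v) lapply(1:2, function(e) {
      img <- warp(I0[[v]][[e]])
      ks <- array(0 + 0i, c(dims, n_coils))
      for (ci in seq_len(n_coils)) ks[, , , ci] <- fftn(sens[, , , ci] * img)
      ks
    }))
  }
  ## assemble sampled lines: global hb h = (block-1)*4 + contrast
  pts <- traj$points
  npts <- nrow(pts)
  f1 <- k_freqs(dims[1]) / dims[1]
  f2 <- k_freqs(dims[2]) / dims[2]
  data <- lapply(1:4, function(v) lapply(1:2, function(e)
    array(0 + 0i, c(npts, dims[2], n_coils))))
  hb_meta <- data.frame(hb = seq_len(n_hb),
                        block = rep(seq_len(n_arms), each = 4),
                        contrast = rep(1:4, n_arms),
                        fh_mm = fh_mm, rl_mm = rl_mm, state = state,
                        time_s = t_hb)
  for (h in seq_len(n_hb)) {
    a <- hb_meta$block[h]; v <- hb_meta$contrast[h]; s <- hb_meta$state[h]
    rows <- which(pts$hb == a)
    i1 <- k_index(pts$ky[rows], dims[1])
    i3 <- k_index(pts$kz[rows], dims[3])
    ph1 <- exp(-2i * pi * f1[i1] * fh_mm[h] / phantom$spacing[1])
    ph2 <- exp(-2i * pi * f2 * rl_mm[h] / phantom$spacing[2])
    ramp <- outer(ph1, ph2)
    for (e in 1:2) {
      K <- Kst[[s]][[v]][[e]]
      for (ci in seq_len(n_coils)) {
        lines <- K[, , , ci][cbind(rep(i1, dims[2]),
                                   rep(seq_len(dims[2]), each = length(rows)),
                                   rep(i3, dims[2]))]
        data[[v]][[e]][rows, , ci] <- matrix(lines, length(rows)) * ramp
      }
    }
  }
  if (noise_sd > 0) {
    for (v in 1:4) for (e in 1:2) {
      nsamp <- length(data[[v]][[e]])
      data[[v]][[e]] <- data[[v]][[e]] +
        complex(real = stats::rnorm(nsamp, 0, noise_sd),
                imaginary = stats::rnorm(nsamp, 0, noise_sd))
    }
  }
  ## synthetic coronal-projection iNAVs (3 deg excitation weighting)
  proj0 <- apply(phantom$m0 * sin(3 * pi / 180), c(1, 2), sum)
  Fp <- stats::fft(proj0)
  g1 <- k_freqs(dims[1]) / dims[1]; g2 <- k_freqs(dims[2]) / dims[2]
  inavs <- array(0, c(dims[1], dims[2], n_hb))
  for (h in seq_len(n_hb)) {
    ph <- exp(-2i * pi * (outer(g1 * fh_mm[h] / phantom$spacing[1],
                                g2 * rl_mm[h] / phantom$spacing[2], `+`)))
    inavs[, , h] <- Re(stats::fft(Fp * ph, inverse = TRUE)) / length(proj0)
  }
  kspace <- structure(list(data = data, traj = traj, sens = sens,
                           dims = dims, spacing = phantom$spacing,
                           hb_meta = hb_meta, noise_sd = noise_sd,
                           seq = seq, timing = timing, dixon = dixon),
                      class = "jointmap_kspace")
  truth <- list(phantom = phantom, sens = sens,
                water_signals = wsig, fat_signals = fsig,
                images = I0, hb_meta = hb_meta,
                nonrigid_base = base, state_levels = qlev,
                motion = motion)
  structure(list(kspace = kspace, inavs = inavs, truth = truth),
            class = "jointmap_sim")
}

#' Ground-truth per-bin displacement fields from a simulated acquisition
#'
#' Combines the quantised nonrigid state and the residual rigid translation
#' at each bin's median heartbeat into the dense field mapping the reference
#' bin to bin b, for injection into [estimate_nonrigid_fields()] /
#' [motion_corrected_recon()].
#'
#' @param sim `jointmap_sim`
#' @param motion `motion_fields` from [bin_and_correct()]
#' @return list of per-bin fields (voxel displacements)
#' @export
ground_truth_bin_fields <- function(sim, motion) {
  dims <- sim$kspace$dims
  sp <- sim$kspace$spacing
  tr <- motion$translations
  med <- motion$bin_medians
  ref <- motion$ref_bin
  base <- sim$truth$nonrigid_base
  hbm <- sim$truth$hb_meta
  fields <- vector("list", motion$B)
  for (b in seq_len(motion$B)) {
    ## median nonrigid amplitude of the bin's heartbeats
    hbs <- tr$hb[tr$bin == b]
    amp_b <- stats::median(sim$truth$state_levels[hbm$state[hbs]])
    amp_r <- stats::median(sim$truth$state_levels[hbm$state[tr$hb[tr$bin == ref]]])
    dfh <- (med$fh_mm[b] - med$fh_mm[ref]) / sp[1]
    drl <- (med$rl_mm[b] - med$rl_mm[ref]) / sp[2]
    u <- zero_field(dims)
    if (!is.null(base)) {
      damp <- amp_b - amp_r
      u <- lapply(base, function(comp) comp * damp)
    }
    ## pull-back convention: bin image (shifted by +d) samples the reference
    ## volume at v - d
    u[[1]] <- u[[1]] - dfh
    u[[2]] <- u[[2]] - drl
    fields[[b]] <- u
  }
  fields[[ref]] <- zero_field(dims)
  fields
}
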