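## --- interpolation helpers -------------------------------------------------

## Trilinear gather: values of `arr` at fractional coordinates `pts` (n x 3),
## zero outside the volume. Works for real and complex arrays.
interp3 <- function(arr, pts) {
  dims <- dim(arr)
  f0 <- floor(pts); fr <- pts - f0
  out <- if (is.complex(arr)) complex(nrow(pts)) else numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    px <- f0[, 1] + cx; py <- f0[, 2] + cy; pz <- f0[, 3] + cz
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
         (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
         (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2] &
          pz >= 1 & pz <= dims[3] & w > 0
    if (any(ok)) {
      flat <- (pz[ok] - 1) * dims[1] * dims[2] + (py[ok] - 1) * dims[1] + px[ok]
      out[ok] <- out[ok] + w[ok] * arr[flat]
    }
  }
  out
}

## Warp a volume by a dense displacement field u (list of 3 arrays, voxels):
## out(v) = x(v + u(v)).
warp_volume <- function(x, u) {
  dims <- dim(x)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  pts <- idx + cbind(as.numeric(u[[1]]), as.numeric(u[[2]]), as.numeric(u[[3]]))
  array(interp3(x, pts), dims)
}

zero_field <- function(dims) list(array(0, dims), array(0, dims), array(0, dims))

## central-difference gradient of a 3D array (zero-padded edges)
gradient3 <- function(x) {
  d <- dim(x)
  g <- vector("list", 3)
  for (ax in 1:3) {
    xp <- x; xm <- x
    n <- d[ax]
    iplus <- c(2:n, n); iminus <- c(1, 1:(n - 1))
    perm <- function(i) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[ax]] <- i
      do.call(`[`, c(list(x), ix))
    }
    g[[ax]] <- array((perm(iplus) - perm(iminus)) / 2, d)
  }
  g
}

## --- translational motion --------------------------------------------------

#' Beat-to-beat translation estimation from 2D image navigators
#'
#' Normalised cross-correlation of each iNAV against the reference over all
#' circular shifts (computed by FFT on mean-removed images), with quadratic
#' sub-pixel interpolation of the correlation peak along each axis.
#' Axis 1 of the iNAV is foot-head (FH), axis 2 right-left (RL).
#'
#' @param inav_reference 2D reference image
#' @param inavs 3D array (ny, nx, n_heartbeats) or list of 2D images
#' @param spacing_mm iNAV pixel size in mm (scalar or length 2)
#' @param max_shift maximum credible shift in pixels (peak search radius)
#' @return data.frame with columns hb, fh_mm, rl_mm
#' @export
estimate_translations <- function(inav_reference, inavs, spacing_mm = 1,
                                  max_shift = NULL) {
  if (is.list(inavs)) inavs <- array(unlist(inavs),
                                     c(dim(inavs[[1]]), length(inavs)))
  d <- dim(inav_reference)
  stopifnot(identical(dim(inavs)[1:2], d))
  if (stats::sd(inav_reference) == 0)
    stop("flat reference image: translation estimation impossible", call. = FALSE)
  spacing_mm <- rep_len(spacing_mm, 2)
  if (is.null(max_shift)) max_shift <- floor(min(d) / 4)
  Fr <- stats::fft(inav_reference - mean(inav_reference))
  n <- dim(inavs)[3]
  res <- matrix(0, n, 2)
  sub <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm1 - cp1) / den
  }
  for (i in seq_len(n)) {
    im <- inavs[, , i]
    if (stats::sd(im) == 0)
      stop("flat iNAV image at heartbeat ", i, call. = FALSE)
    cc <- Re(stats::fft(stats::fft(im - mean(im)) * Conj(Fr), inverse = TRUE))
    ## restrict the peak search to plausible shifts
    s1 <- k_freqs(d[1]); s2 <- k_freqs(d[2])
    ok <- outer(abs(s1) <= max_shift, abs(s2) <= max_shift)
    cc[!ok] <- -Inf
    pk <- arrayInd(which.max(cc), d)
    wrap <- function(j, nn) ((j - 1 + nn) %% nn) + 1
    d1 <- sub(cc[wrap(pk[1] - 1, d[1]), pk[2]], cc[pk[1], pk[2]],
              cc[wrap(pk[1] + 1, d[1]), pk[2]])
    d2 <- sub(cc[pk[1], wrap(pk[2] - 1, d[2])], cc[pk[1], pk[2]],
              cc[pk[1], wrap(pk[2] + 1, d[2])])
    res[i, ] <- c(s1[pk[1]] + d1, s2[pk[2]] + d2)
  }
  data.frame(hb = seq_len(n), fh_mm = res[, 1] * spacing_mm[1],
             rl_mm = res[, 2] * spacing_mm[2])
}

#' Respiratory binning and intra-bin translational k-space correction
#'
#' Heartbeats are assigned to `B` equal-count bins by their foot-head
#' displacement. Within each bin, every heartbeat's k-space lines receive the
#' linear phase ramp that shifts the acquired object to the bin's median
#' (FH, RL) position (Fourier shift theorem); the reference bin is the
#' end-expiration bin (smallest median FH displacement). Binned sampling
#' masks are disjoint across bins and reassemble the full per-contrast mask.
#'
#' @param kspace a `jointmap_kspace` object (see [simulate_acquisition()])
#' @param translations data.frame (hb, fh_mm, rl_mm) for every global
#'   heartbeat, e.g. from [estimate_translations()]
#' @param B number of respiratory bins
#' @return list with `kspace` (corrected copy) and `motion`, a
#'   `motion_fields` object carrying bin assignments, bin median positions,
#'   reference bin index and (initially NULL) nonrigid fields
#' @export
bin_and_correct <- function(kspace, translations, B = 5) {
  stopifnot(B >= 1)
  n_hb <- nrow(translations)
  if (n_hb < B) stop("fewer heartbeats than bins", call. = FALSE)
  rk <- rank(translations$fh_mm, ties.method = "first")
  bin <- ceiling(rk * B / n_hb)
  med <- do.call(rbind, lapply(seq_len(B), function(b) {
    data.frame(bin = b,
               fh_mm = stats::median(translations$fh_mm[bin == b]),
               rl_mm = stats::median(translations$rl_mm[bin == b]))
  }))
  ref_bin <- med$bin[which.min(med$fh_mm)]
  dims <- kspace$dims; sp <- kspace$spacing
  f1 <- k_freqs(dims[1]) / dims[1]   # FH = dim 1 (ky)
  f2 <- k_freqs(dims[2]) / dims[2]   # RL = dim 2 (readout)
  ks <- kspace
  pts <- kspace$traj$points
  for (ci in seq_along(ks$data)) {
    for (e in seq_along(ks$data[[ci]])) {
      dat <- ks$data[[ci]][[e]]
      nc <- dim(dat)[3]
      for (a in seq_len(kspace$traj$n_heartbeats)) {
        hb <- kspace$hb_meta$hb[kspace$hb_meta$block == a &
                                kspace$hb_meta$contrast == ci]
        b <- bin[hb]
        dfh <- (med$fh_mm[b] - translations$fh_mm[hb]) / sp[1]
        drl <- (med$rl_mm[b] - translations$rl_mm[hb]) / sp[2]
        rows <- which(pts$hb == a)
        ph1 <- exp(-2i * pi * f1[k_index(pts$ky[rows], dims[1])] * dfh)
        ph2 <- exp(-2i * pi * f2 * drl)
        ramp <- array(outer(ph1, ph2), c(length(rows), dims[2], nc))
        dat[rows, , ] <- dat[rows, , , drop = FALSE] * ramp
      }
      ks$data[[ci]][[e]] <- dat
    }
  }
  motion <- structure(list(translations = cbind(translations, bin = bin),
                           bin_medians = med, ref_bin = ref_bin, B = B,
                           fields = NULL),
                      class = "motion_fields")
  list(kspace = ks, motion = motion)
}

#' @exportS3Method base::print
print.motion_fields <- function(x, ...) {
  cat("motion fields:", x$B, "bins over", nrow(x$translations),
      "heartbeats; reference bin", x$ref_bin, "\n")
  print(x$bin_medians)
  invisible(x)
}

## --- nonrigid registration -------------------------------------------------

## one demons registration: displacement u with moving(v+u(v)) ~= fixed(v)
register_demons <- function(fixed, moving, u = NULL, n_iter = 40,
                            smooth_sigma = 1.5, step_cap = 1.0) {
  dims <- dim(fixed)
  if (is.null(u)) u <- zero_field(dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  for (it in seq_len(n_iter)) {
    pts <- idx + cbind(as.numeric(u[[1]]), as.numeric(u[[2]]), as.numeric(u[[3]]))
    mw <- array(interp3(moving, pts), dims)
    diff <- fixed - mw
    g <- gradient3(mw)
    g2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
    denom <- g2 + diff^2 + 1e-9 * max(g2)
    for (ax in 1:3) {
      du <- diff * g[[ax]] / denom
      du <- pmax(pmin(du, step_cap), -step_cap)
      u[[ax]] <- gauss_smooth(u[[ax]] + du, smooth_sigma)
    }
  }
  u
}

downsample2 <- function(x) {
  d <- dim(x)
  xs <- gauss_smooth(x, 1)
  xs[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
}

upsample_field2 <- function(u, dims) {
  lapply(u, function(comp) {
    idx <- arrayInd(seq_len(prod(dims)), dims)
    pts <- (idx - 1) / 2 + 1
    array(interp3(comp, pts), dims) * 2
  })
}

#' Estimate per-bin nonrigid displacement fields
#'
#' Dense displacement fields mapping each respiratory bin image to the
#' reference bin, by a multi-resolution demons-style engine: at each
#' iteration the reference image is warped by the current field, an additive
#' intensity-driven update is computed, and the field is Gaussian-smoothed.
#' Any registration engine respecting the same convention may be substituted,
#' and ground-truth fields can be injected (bypassing registration) via
#' `inject` -- used for validation against simulated motion.
#'
#' The convention is pull-back: `U_b x` evaluates the reference-position
#' volume `x` at `v + u_b(v)`, producing the volume at bin-b position.
#'
#' @param bin_images list of 3D magnitude images, one per bin
#' @param reference_bin index of the reference (end-expiration) bin
#' @param inject optional list of fields (each a list of 3 displacement
#'   arrays in voxels) to use verbatim instead of registering
#' @param n_iter demons iterations per resolution level
#' @param smooth_sigma field smoothing (voxels)
#' @param multires use a coarse-to-fine (2x) pyramid if the volume allows
#' @return list of fields, one per bin; the reference bin has the zero field
#' @export
estimate_nonrigid_fields <- function(bin_images, reference_bin = 1,
                                     inject = NULL, n_iter = 40,
                                     smooth_sigma = 1.5, multires = TRUE) {
  nb <- length(bin_images)
  if (nb < 2 && is.null(inject))
    stop("need at least two bins to register", call. = FALSE)
  dims <- dim(bin_images[[reference_bin]])
  if (!is.null(inject)) {
    stopifnot(length(inject) == nb)
    inject[[reference_bin]] <- zero_field(dims)
    return(inject)
  }
  ref <- Mod(bin_images[[reference_bin]])
  sc <- max(ref)
  if (sc > 0) ref <- ref / sc
  fields <- vector("list", nb)
  for (b in seq_len(nb)) {
    if (b == reference_bin) { fields[[b]] <- zero_field(dims); next }
    fix <- Mod(bin_images[[b]])
    if (sc > 0) fix <- fix / sc
    can_half <- multires && all(dims >= 8) && all(dims %% 2 == 0)
    if (can_half) {
      uc <- register_demons(downsample2(fix), downsample2(ref),
                            n_iter = n_iter, smooth_sigma = smooth_sigma / 2)
      u0 <- upsample_field2(uc, dims)
      u <- register_demons(fix, ref, u = u0, n_iter = n_iter,
                           smooth_sigma = smooth_sigma)
    } else {
      u <- register_demons(fix, ref, n_iter = n_iter,
                           smooth_sigma = smooth_sigma)
    }
    fields[[b]] <- u
  }
  fields
}
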