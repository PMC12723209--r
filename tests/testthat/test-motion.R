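make_inav_series <- function(base, shifts) {
  d <- dim(base)
  F0 <- stats::fft(base)
  g1 <- jointmap:::k_freqs(d[1]) / d[1]
  g2 <- jointmap:::k_freqs(d[2]) / d[2]
  out <- array(0, c(d, nrow(shifts)))
  for (h in seq_len(nrow(shifts))) {
    ph <- exp(-2i * pi * outer(g1 * shifts[h, 1], g2 * shifts[h, 2], `+`))
    out[, , h] <- Re(stats::fft(F0 * ph, inverse = TRUE)) / length(base)
  }
  out
}

test_inav <- function(n = 32) {
  set.seed(8)
  b <- matrix(0, n, n)
  b[10:22, 12:20] <- 1
  b[14:18, 15:17] <- 2.5
  jointmap:::gauss_smooth(b + 0.05 * matrix(stats::runif(n * n), n), 1)
}

test_that("translation estimation recovers zero, integer and subpixel shifts", {
  base <- test_inav()
  ## identical images -> (0, 0)
  e0 <- estimate_translations(base, array(base, c(dim(base), 1)))
  expect_equal(c(e0$fh_mm, e0$rl_mm), c(0, 0), tolerance = 1e-9)
  ## exact integer 3-pixel FH shift
  s <- make_inav_series(base, rbind(c(3, 0)))
  e3 <- estimate_translations(base, s)
  expect_equal(e3$fh_mm, 3, tolerance = 1e-6)
  ## known 1.4-pixel shift recovered within 0.2 pixels
  s14 <- make_inav_series(base, rbind(c(1.4, -0.7)))
  e14 <- estimate_translations(base, s14)
  expect_lt(abs(e14$fh_mm - 1.4), 0.2)
  expect_lt(abs(e14$rl_mm + 0.7), 0.2)
  ## spacing scales the output to mm
  e_mm <- estimate_translations(base, s, spacing_mm = 2)
  expect_equal(e_mm$fh_mm, 6, tolerance = 1e-5)
  expect_error(estimate_translations(matrix(1, 8, 8),
                                     array(1, c(8, 8, 1))), "flat")
})

test_that("equal-count binning partitions heartbeats by FH displacement", {
  tr <- data.frame(hb = 1:100,
                   fh_mm = sin(seq(0, 6 * pi, length.out = 100)) * 8,
                   rl_mm = 0)
  sq <- default_seq(); tm <- hr60()
  ph <- make_phantom("t1mes_like", dims = c(16, 16, 4), vial_diameter_mm = 6)
  tj <- generate_vdcaspr(16, 4, n_heartbeats = 25, n_segments = 2, seed = 1)
  sim <- simulate_acquisition(ph, sq, tm, tj, n_coils = 1)
  bc <- bin_and_correct(sim$kspace, tr, B = 5)
  counts <- table(bc$motion$translations$bin)
  expect_true(max(counts) - min(counts) <= 1)
  ## monotone displacement -> monotone bin index
  ord <- order(tr$fh_mm)
  expect_true(all(diff(bc$motion$translations$bin[ord]) >= 0))
  ## reference bin is end-expiration (smallest median FH)
  expect_equal(bc$motion$ref_bin,
               which.min(bc$motion$bin_medians$fh_mm))
  expect_error(bin_and_correct(sim$kspace, tr[1:3, ], B = 5), "fewer")
})

test_that("intra-bin phase correction shifts every line to the bin median", {
  ## Fourier shift theorem round trip: after correction, each heartbeat's
  ## sampled lines equal the k-space of the truth image translated to the
  ## bin's median position, so recovered per-bin images align exactly
  sq <- default_seq(); tm <- hr60()
  dims <- c(32, 32, 4)
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 4)
  tj <- generate_vdcaspr(32, 4, acceleration = 1, n_segments = 16, seed = 3)
  mo <- motion_spec(amp_fh_mm = 6, amp_rl_mm = 2, period_s = 4.3)
  sim <- simulate_acquisition(ph, sq, tm, tj, motion = mo, n_coils = 1,
                              seed = 4)
  truth_tr <- sim$truth$hb_meta[, c("hb", "fh_mm", "rl_mm")]
  bc <- bin_and_correct(sim$kspace, truth_tr, B = 4)
  med <- bc$motion$bin_medians
  g1 <- jointmap:::k_freqs(32) / 32
  pts <- tj$points
  ci <- 2
  F0 <- jointmap::fftn(sim$truth$images[[ci]][[1]] + 0i)
  for (a in unique(pts$hb)) {
    hb <- sim$kspace$hb_meta$hb[sim$kspace$hb_meta$block == a &
                                sim$kspace$hb_meta$contrast == ci]
    b <- bc$motion$translations$bin[hb]
    rows <- which(pts$hb == a)
    i1 <- jointmap:::k_index(pts$ky[rows], 32)
    i3 <- jointmap:::k_index(pts$kz[rows], 4)
    ## expected: truth k-space with the bin-median shift applied
    ph1 <- exp(-2i * pi * g1[i1] * med$fh_mm[b] / 2)
    ph2 <- exp(-2i * pi * g1 * med$rl_mm[b] / 2)
    want <- F0[cbind(rep(i1, 32), rep(1:32, each = length(rows)),
                     rep(i3, 32))] *
      as.vector(outer(ph1, ph2))
    got <- as.vector(bc$kspace$data[[ci]][[1]][rows, , 1])
    expect_lt(max(Mod(got - want)) / max(Mod(F0)), 1e-10)
  }
})

test_that("demons registration recovers simple fields and reduces MSE", {
  dims <- c(24, 24, 8)
  ph <- make_phantom("cardiac", dims = dims)
  img <- jointmap:::gauss_smooth(ph$m0, 1)
  ## identical images: zero field within regulariser tolerance
  f0 <- estimate_nonrigid_fields(list(img, img), reference_bin = 1)
  expect_lt(max(abs(f0[[2]][[1]])), 0.1)
  expect_equal(f0[[1]][[1]], array(0, dims))
  ## pure 2-voxel translation between bins
  u_true <- list(array(2, dims), array(0, dims), array(0, dims))
  moved <- jointmap:::warp_volume(img, u_true)
  f <- estimate_nonrigid_fields(list(img, moved), reference_bin = 1)
  core <- img > 0.3
  expect_lt(mean(abs(f[[2]][[1]][core] - 2)), 0.3)
  ## warping by the estimated field must halve the intensity MSE
  mw <- jointmap:::warp_volume(img, f[[2]])
  expect_lt(mean((moved - mw)^2), 0.5 * mean((moved - img)^2))
  ## smooth synthetic deformation
  set.seed(5)
  u_s <- lapply(1:3, function(a)
    jointmap:::gauss_smooth(array(rnorm(prod(dims)), dims), 4) * 6)
  u_s[[3]] <- u_s[[3]] * 0
  warped <- jointmap:::warp_volume(img, u_s)
  fs <- estimate_nonrigid_fields(list(img, warped), reference_bin = 1)
  ws <- jointmap:::warp_volume(img, fs[[2]])
  expect_lt(mean((warped - ws)^2), 0.5 * mean((warped - img)^2))
})

test_that("ground-truth injection bypasses registration verbatim", {
  dims <- c(8, 8, 4)
  inj <- list(NULL, list(array(1, dims), array(0, dims), array(0, dims)))
  f <- estimate_nonrigid_fields(list(array(0, dims), array(0, dims)),
                                reference_bin = 1, inject = inj)
  expect_equal(f[[2]][[1]], array(1, dims))
  expect_equal(f[[1]][[1]], array(0, dims))  # reference forced to identity
})
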