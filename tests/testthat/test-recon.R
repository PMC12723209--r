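test_that("fully sampled single uniform coil reconstruction is the identity", {
  dims <- c(16, 16, 4)
  sens <- array(1 + 0i, c(dims, 1))
  op <- encoding_op(sens, list(matrix(TRUE, dims[1], dims[3])))
  set.seed(1)
  x0 <- crnorm(dims)
  r <- cg_sense(op, op$forward(x0), n_iter = 15, tol = 1e-10)
  expect_lt(nrmse(r$image, x0), 1e-6)
})

test_that("encoding operator passes randomised adjoint tests", {
  set.seed(2)
  dims <- c(16, 16, 8)
  sens <- coil_maps(dims, 4, seed = 2)
  tr <- generate_vdcaspr(16, 8, acceleration = 3, n_segments = 8, seed = 2)
  mask <- jointmap:::traj_mask(tr)
  ## without warps
  op <- encoding_op(sens, list(mask))
  for (k in 1:3) {
    x <- crnorm(dims); y <- crnorm(c(dims, 4))
    gap <- Mod(sum(Conj(op$forward(x)) * y) - sum(Conj(x) * op$adjoint(y)))
    expect_lt(gap / (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))), 1e-6)
  }
  ## with warps: interpolation transpose as the warp adjoint
  m1 <- jointmap:::traj_mask(tr, hbs = seq_len(tr$n_heartbeats %/% 2))
  m2 <- mask & !m1
  flds <- lapply(1:2, function(b) lapply(1:3, function(a)
    jointmap:::gauss_smooth(array(rnorm(prod(dims)), dims), 2) * 1.5))
  opw <- encoding_op(sens, list(m1, m2), fields = flds)
  for (k in 1:3) {
    x <- crnorm(dims); y <- crnorm(c(dims, 4))
    gap <- Mod(sum(Conj(opw$forward(x)) * y) - sum(Conj(x) * opw$adjoint(y)))
    expect_lt(gap / (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))), 1e-5)
  }
})

test_that("the encoding operator is linear", {
  set.seed(3)
  dims <- c(12, 12, 4)
  sens <- coil_maps(dims, 3, seed = 1)
  tr <- generate_vdcaspr(12, 4, acceleration = 2, n_segments = 6, seed = 1)
  op <- encoding_op(sens, list(jointmap:::traj_mask(tr)))
  x <- crnorm(dims); y <- crnorm(dims)
  a <- 1.3 - 0.4i; b <- -0.7 + 2i
  expect_lt(nrmse(op$forward(a * x + b * y),
                  a * op$forward(x) + b * op$forward(y)), 1e-12)
})

test_that("CG residuals decrease monotonically over iterations", {
  set.seed(4)
  dims <- c(16, 16, 4)
  sens <- coil_maps(dims, 4, seed = 4)
  tr <- generate_vdcaspr(16, 4, acceleration = 2, n_segments = 8, seed = 4)
  op <- encoding_op(sens, list(jointmap:::traj_mask(tr)))
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 5)
  y <- op$forward(ph$m0 + 0i)
  r <- cg_sense(op, y, n_iter = 3, tol = 0)
  expect_true(all(diff(r$residuals) <= 1e-10))
})

test_that("undersampled multi-coil CG beats zero-filled reconstruction", {
  sq <- default_seq(); tm <- hr60()
  dims <- c(32, 32, 8)
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 10)
  tr <- generate_vdcaspr(32, 8, acceleration = 4, n_segments = 16, seed = 5)
  sim <- simulate_acquisition(ph, sq, tm, tr, n_coils = 8, seed = 5)
  rec <- recon_binned(sim$kspace, contrast = 2, n_iter = 15)
  zf <- recon_zero_filled(sim$kspace, contrast = 2)
  ref <- sim$truth$images[[2]][[1]]
  expect_lt(nrmse(Mod(rec), Mod(ref)), nrmse(Mod(zf), Mod(ref)))
})

test_that("binned masks reassemble the full sampling mask", {
  sq <- default_seq(); tm <- hr60()
  dims <- c(24, 24, 4)
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 7)
  tr <- generate_vdcaspr(24, 4, acceleration = 2, n_segments = 8, seed = 6)
  mo <- motion_spec(amp_fh_mm = 6, period_s = 3.7)
  sim <- simulate_acquisition(ph, sq, tm, tr, motion = mo, n_coils = 2,
                              seed = 6)
  bc <- bin_and_correct(sim$kspace,
                        sim$truth$hb_meta[, c("hb", "fh_mm", "rl_mm")], B = 3)
  full <- jointmap:::traj_mask(tr)
  for (ci in 1:4) {
    acc <- matrix(0, dims[1], dims[3])
    for (b in 1:3) {
      hbs <- jointmap:::arms_in_bin(bc$kspace, bc$motion, ci, b)
      acc <- acc + jointmap:::traj_mask(tr, hbs)
    }
    expect_equal(acc, full + 0)  # disjoint and complete
  }
})

test_that("with zero motion the corrected recon equals pooled SENSE", {
  sq <- default_seq(); tm <- hr60()
  dims <- c(24, 24, 4)
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 7)
  tr <- generate_vdcaspr(24, 4, acceleration = 2, n_segments = 8, seed = 7)
  sim <- simulate_acquisition(ph, sq, tm, tr, motion = NULL, n_coils = 4,
                              seed = 7)
  zero_tr <- data.frame(hb = seq_len(4 * tr$n_heartbeats), fh_mm = 0,
                        rl_mm = 0)
  bc <- bin_and_correct(sim$kspace, zero_tr, B = 2)
  bc$motion$fields <- NULL
  rec <- motion_corrected_recon(bc$kspace, bc$motion, n_iter = 5)
  pooled <- recon_binned(sim$kspace, contrast = 1, n_iter = 5, tol = 0)
  expect_lt(nrmse(rec$images[[1]][[1]], pooled), 1e-8)
})

test_that("motion-corrected recon with identity motion and full sampling is exact", {
  sq <- default_seq(); tm <- hr60()
  dims <- c(16, 16, 4)
  ph <- make_phantom("t1mes_like", dims = dims, vial_diameter_mm = 5)
  tr <- generate_vdcaspr(16, 4, acceleration = 1, n_segments = 16, seed = 8)
  sim <- simulate_acquisition(ph, sq, tm, tr, motion = NULL, n_coils = 1,
                              seed = 8)
  zero_tr <- data.frame(hb = seq_len(4 * tr$n_heartbeats), fh_mm = 0,
                        rl_mm = 0)
  bc <- bin_and_correct(sim$kspace, zero_tr, B = 1)
  rec <- motion_corrected_recon(bc$kspace, bc$motion, n_iter = 10, tol = 1e-12)
  for (v in c(1, 4)) {
    expect_lt(nrmse(rec$images[[v]][[1]],
                    sim$truth$images[[v]][[1]] + 0i), 1e-6)
  }
})
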