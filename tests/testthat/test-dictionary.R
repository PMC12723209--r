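test_that("printed parameter grids enumerate to 291 x 122 = 35502 atoms", {
  g <- dictionary_grid()
  expect_length(g$t1_values, 291)
  expect_length(g$t1rho_values, 122)
  d <- generate_dictionary(default_seq(), hr60(), g)
  expect_equal(nrow(d$atoms), 35502)
  expect_equal(nrow(d$params), 35502)
})

test_that("atoms are unit norm and consistent with the simulator", {
  d <- generate_dictionary(default_seq(), hr60(), small_grid())
  expect_true(all(abs(sqrt(rowSums(d$atoms^2)) - 1) < 1e-9))
  i <- which(d$params$t1 == 700 & d$params$t1rho == 58)
  s <- simulate_signals(default_seq(), hr60(),
                        tissue_params(0.7, 0.058))$signals
  ## grid-wide and single-tissue runs stop at slightly different blocks of
  ## the shared 1e-6 fixed-point criterion
  expect_equal(d$atoms[i, ], s / sqrt(sum(s^2)), tolerance = 1e-5)
})

test_that("noiseless on-grid signals self-match exactly with zero SSD", {
  d <- generate_dictionary(default_seq(), hr60(), small_grid())
  set.seed(42)
  idx <- sample(nrow(d$atoms), 200)
  m <- match_signals(d$atoms[idx, ] * 7.3, d)  # scaling must not matter
  expect_equal(m$atom, idx)
  expect_equal(m$t1, d$params$t1[idx])
  expect_equal(m$t1rho, d$params$t1rho[idx])
  expect_true(all(m$ssd < 1e-12))
})

test_that("matching is scale invariant and equals brute-force SSD search", {
  sq <- default_seq(); tm <- hr60()
  d <- generate_dictionary(sq, tm, small_grid())
  ## off-grid tissue: T1 = 702 ms between the 700/720 nodes
  s <- simulate_signals(sq, tm, tissue_params(0.702, 0.058))$signals
  m1 <- match_signals(s, d)
  m5 <- match_signals(5 * s, d)
  expect_equal(m1$atom, m5$atom)
  bf <- brute_force_match(s, d)
  expect_equal(m1$atom, bf$atom)
  expect_equal(m1$ssd, bf$ssd, tolerance = 1e-10)
  expect_lte(abs(m1$t1 - 702), 20)  # within one grid step of this grid
})

test_that("off-grid match on the full mapping grid lands within one step", {
  sq <- default_seq(); tm <- hr60()
  d <- generate_dictionary(sq, tm)
  s <- simulate_signals(sq, tm, tissue_params(0.702, 0.056))$signals
  m <- match_signals(s, d)
  expect_lte(abs(m$t1 - 702), 5)
  bf <- brute_force_match(s, d)
  expect_equal(m$atom, bf$atom)
})

test_that("SSD equals 2 - 2 * inner product for unit vectors", {
  d <- generate_dictionary(default_seq(), hr60(), small_grid())
  set.seed(3)
  s <- rnorm(4)
  m <- match_signals(s, d)
  su <- s / sqrt(sum(s^2))
  ip <- sum(su * d$atoms[m$atom, ])
  expect_equal(m$ssd, 2 - 2 * ip, tolerance = 1e-12)
  expect_equal(m$ssd, sum((su - d$atoms[m$atom, ])^2), tolerance = 1e-12)
})

test_that("degenerate voxels give sentinels, not NaN", {
  d <- generate_dictionary(default_seq(), hr60(), small_grid())
  sig <- rbind(c(0, 0, 0, 0), d$atoms[10, ])
  m <- match_signals(sig, d)
  expect_true(is.na(m$t1[1]))
  expect_false(anyNA(m$t1[2]))
  vols <- lapply(1:4, function(v) array(0, c(4, 4, 2)))
  for (v in 1:4) vols[[v]][2, 2, 1] <- d$atoms[10, v]
  maps <- match_maps(vols, d, sentinel = -1)
  expect_equal(maps$t1[2, 2, 1], d$params$t1[10])
  expect_equal(maps$t1[1, 1, 1], -1)  # zero voxel -> sentinel
})

test_that("polarity restoration undoes smooth background phase", {
  sq <- default_seq(); tm <- hr60()
  dims <- c(16, 16, 4)
  ## signed ground truth: volume-1-like image with a negative region
  gt <- array(0.5, dims); gt[6:10, 6:10, ] <- -0.3
  ## zero phase: output is |water| with the ground-truth sign
  w0 <- list(gt + 0i)
  out0 <- restore_polarity(w0, list(array(0.5 + 0i, dims)))
  expect_equal(out0[[1]], gt, tolerance = 1e-12)
  ## uniform 2 rad background applied to image and Ps-IP alike
  bg <- exp(2i)
  out <- restore_polarity(list(gt * bg), list(array(0.5 + 0i, dims) * bg))
  expect_equal(sign(out[[1]]), sign(gt))
  expect_equal(out[[1]], gt, tolerance = 1e-12)
})

test_that("long-T1 volume-1 signal stays negative after polarity restoration", {
  sq <- default_seq(); tm <- hr60()
  s <- bloch_signals(sq, tm, t1 = c(0.4, 1.8), t1rho = 0.06)$signals
  expect_lt(s[2, 1], 0)  # inverted magnetisation at TI = 245 ms for long T1
  dims <- c(12, 12, 2)
  vols <- lapply(1:4, function(v) {
    a <- array(s[1, v], dims); a[4:9, 4:9, ] <- s[2, v]; a + 0i
  })
  bg <- exp(1i * 0.7)
  sw <- restore_polarity(lapply(vols, `*`, bg), lapply(vols, `*`, bg),
                         sigma = 6)
  expect_true(all(sw[[1]][4:9, 4:9, ] < 0))
  expect_equal(sw[[1]], Re(vols[[1]]), tolerance = 1e-9)
})

test_that("geometry mismatches are rejected", {
  expect_error(restore_polarity(list(array(1 + 0i, c(4, 4, 2))),
                                list(array(1 + 0i, c(4, 4, 3)))),
               "geometries differ")
})
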