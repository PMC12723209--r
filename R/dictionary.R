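#' Dictionary parameter grid for joint (T1, T1rho) matching
#'
#' Default grids follow the piecewise ranges used for mapping:
#' T1 = [50:5:1400, 1400:50:1800, 1800:100:3000] ms and
#' T1rho = [5:5:20, 20:1:80, 80:4:300, 300:100:600] ms, de-duplicated at the
#' shared endpoints (291 x 122 = 35,502 combinations).
#'
#' @param t1_values T1 grid in ms (strictly positive, de-duplicated, sorted)
#' @param t1rho_values T1rho grid in ms
#' @return object of class `dictionary_grid`
#' @export
dictionary_grid <- function(
    t1_values = c(seq(50, 1400, 5), seq(1400, 1800, 50), seq(1800, 3000, 100)),
    t1rho_values = c(seq(5, 20, 5), seq(20, 80, 1), seq(80, 300, 4),
                     seq(300, 600, 100))) {
  t1_values <- sort(unique(t1_values))
  t1rho_values <- sort(unique(t1rho_values))
  stopifnot(all(t1_values > 0), all(t1rho_values > 0))
  structure(list(t1_values = t1_values, t1rho_values = t1rho_values),
            class = "dictionary_grid")
}

#' Generate the (T1, T1rho) signal dictionary
#'
#' One atom per (T1, T1rho) pair, simulated with [bloch_signals()] at the
#' subject's heart rate and acquisition window and L2-normalised across the
#' four contrasts. Atom rows are ordered by T1 then T1rho ascending so that
#' first-maximum matching breaks ties toward the smaller T1, then smaller
#' T1rho.
#'
#' @param seq [sequence_params()]
#' @param timing [cardiac_timing()]
#' @param grid [dictionary_grid()]
#' @return object of class `signal_dictionary` with `atoms` (n_atoms x 4,
#'   unit L2 rows), `params` (data.frame t1, t1rho in ms), `grid`, `hr`,
#'   `acq_window`, `norms` (pre-normalisation L2 norms)
#' @export
generate_dictionary <- function(seq, timing, grid = dictionary_grid()) {
  ## t1 varies slowest: rows sorted by (t1, t1rho)
  par <- expand.grid(t1rho = grid$t1rho_values, t1 = grid$t1_values,
                     KEEP.OUT.ATTRS = FALSE)[, c("t1", "t1rho")]
  sim <- bloch_signals(seq, timing, t1 = par$t1 / 1000,
                       t1rho = par$t1rho / 1000, m0 = 1)
  nrm <- sqrt(rowSums(sim$signals^2))
  if (any(nrm == 0)) stop("degenerate zero atom in dictionary", call. = FALSE)
  atoms <- sim$signals / nrm
  structure(list(atoms = atoms, params = par, grid = grid,
                 hr = timing$hr, acq_window = seq$acq_window,
                 sample_times = sim$sample_times, norms = nrm),
            class = "signal_dictionary")
}

#' @exportS3Method base::print
print.signal_dictionary <- function(x, ...) {
  cat("signal dictionary:", nrow(x$atoms), "atoms (",
      length(x$grid$t1_values), "T1 x", length(x$grid$t1rho_values),
      "T1rho ), HR", round(x$hr, 1), "bpm\n")
  invisible(x)
}

#' Match signed 4-point signals to a dictionary
#'
#' Each signal row is L2-normalised and matched by maximum inner product with
#' the unit-norm dictionary atoms (computed in chunked matrix products). For
#' unit vectors SSD = 2 - 2 * inner product, so this is equivalent to
#' minimising the sum of squared differences. All-zero rows return NA.
#'
#' @param signals n x 4 matrix of signed signals (a single signal may be
#'   given as a length-4 vector)
#' @param dict [generate_dictionary()] result
#' @param chunk rows per matching chunk (memory bound)
#' @return data.frame with t1 (ms), t1rho (ms), ssd, atom index
#' @export
match_signals <- function(signals, dict, chunk = 5000L) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  stopifnot(ncol(signals) == ncol(dict$atoms))
  n <- nrow(signals)
  nrm <- sqrt(rowSums(signals^2))
  ok <- nrm > 0 & is.finite(nrm)
  idx <- rep(NA_integer_, n)
  best <- rep(NA_real_, n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    rows <- (s:e)[ok[s:e]]
    if (!length(rows)) next
    r <- cpp_argmax_inner(signals[rows, , drop = FALSE] / nrm[rows], dict$atoms)
    idx[rows] <- r$idx
    best[rows] <- r$best
  }
  data.frame(t1 = dict$params$t1[idx], t1rho = dict$params$t1rho[idx],
             ssd = pmax(2 - 2 * best, 0), atom = idx)
}

#' Restore signal polarity from pseudo-in-phase echo phase
#'
#' Estimates a smooth background phase by low-pass filtering the Ps-IP
#' complex image of a polarity-free reference contrast (by default the
#' contrast with the largest mean magnitude, i.e. a no-preparation volume
#' whose steady-state magnetisation is always positive), removes it from
#' each water-image phase, and returns |water| signed by the cosine of the
#' residual phase. Voxels whose residual phase is closer to pi than to 0
#' (inverted magnetisation at short TI) come out negative. Using a
#' positive-polarity reference keeps the background estimate from absorbing
#' genuine sign flips in regions that are uniformly inverted.
#'
#' @param water_volumes list of complex 3D arrays (one per contrast)
#' @param psip_volumes list of complex 3D arrays (Ps-IP echo, same geometry)
#' @param sigma Gaussian kernel SD in voxels for the background-phase
#'   estimate
#' @param reference index of the reference contrast in `psip_volumes`
#'   (NULL: largest mean magnitude)
#' @return list of signed real arrays
#' @export
restore_polarity <- function(water_volumes, psip_volumes, sigma = 8,
                             reference = NULL) {
  if (!is.list(water_volumes)) water_volumes <- list(water_volumes)
  if (!is.list(psip_volumes)) psip_volumes <- list(psip_volumes)
  stopifnot(length(water_volumes) == length(psip_volumes))
  for (v in seq_along(water_volumes))
    if (!identical(dim(water_volumes[[v]]), dim(psip_volumes[[v]])))
      stop("water and Ps-IP volume geometries differ", call. = FALSE)
  if (is.null(reference))
    reference <- which.max(vapply(psip_volumes, function(p) mean(Mod(p)), 0))
  p <- psip_volumes[[reference]]
  ## smooth the magnitude-weighted phasor, not the wrapped phase
  bg <- gauss_smooth(p, sigma)
  bgu <- bg / pmax(Mod(bg), .Machine$double.eps)
  out <- vector("list", length(water_volumes))
  for (v in seq_along(water_volumes)) {
    w <- water_volumes[[v]]
    resid <- Arg(w * Conj(bgu))
    out[[v]] <- Mod(w) * sign(cos(resid))
  }
  out
}

#' Sentinel-filled T1/T1rho/SSD maps by dictionary matching
#'
#' Per masked voxel the 4-point signed signal is matched with
#' [match_signals()]; voxels outside the mask, or with an all-zero signal,
#' receive the sentinel value.
#'
#' @param signed_water list of 4 signed real 3D arrays (or a 4D array with
#'   contrast as the last dimension)
#' @param dict [generate_dictionary()] result
#' @param mask logical 3D array (default: all voxels)
#' @param sentinel value for unmatched voxels (default NA)
#' @param spacing voxel spacing in mm (scalar or length 3)
#' @param chunk rows per matching chunk
#' @return object of class `parameter_maps`: list with 3D arrays `t1`,
#'   `t1rho`, `ssd` (ms, ms, dimensionless), `mask`, `spacing`, `hr`
#' @export
match_maps <- function(signed_water, dict, mask = NULL, sentinel = NA_real_,
                       spacing = 2, chunk = 2000L) {
  if (is.list(signed_water)) {
    dims <- dim(signed_water[[1]])
    X <- vapply(signed_water, as.numeric, numeric(prod(dims)))
  } else {
    nd <- length(dim(signed_water))
    dims <- dim(signed_water)[-nd]
    X <- matrix(signed_water, ncol = dim(signed_water)[nd])
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  mvec <- as.logical(mask)
  maps <- list(t1 = array(sentinel, dims), t1rho = array(sentinel, dims),
               ssd = array(sentinel, dims))
  if (any(mvec)) {
    m <- match_signals(X[mvec, , drop = FALSE], dict, chunk = chunk)
    fill <- function(a, v) { a[mvec] <- ifelse(is.na(v), sentinel, v); a }
    maps$t1 <- fill(maps$t1, m$t1)
    maps$t1rho <- fill(maps$t1rho, m$t1rho)
    maps$ssd <- fill(maps$ssd, m$ssd)
  }
  structure(c(maps, list(mask = mask, spacing = rep_len(spacing, 3),
                         hr = dict$hr)),
            class = "parameter_maps")
}

#' @exportS3Method base::print
print.parameter_maps <- function(x, ...) {
  cat("parameter maps", paste(dim(x$t1), collapse = "x"),
      "voxels @", paste(x$spacing, collapse = "x"), "mm\n")
  ok <- x$mask & !is.na(x$t1)
  if (any(ok))
    cat("  masked voxels:", sum(ok),
        " median T1", round(stats::median(x$t1[ok]), 1), "ms,",
        " median T1rho", round(stats::median(x$t1rho[ok]), 1), "ms\n")
  invisible(x)
}

#' Persist / load a dictionary
#'
#' Stored with R's native serialisation together with its generation
#' settings.
#' @param dict `signal_dictionary`
#' @param path file path
#' @return `path` (write) or the dictionary (read)
#' @export
write_dictionary <- function(dict, path) { saveRDS(dict, path); invisible(path) }

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) readRDS(path)
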