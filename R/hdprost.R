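#' Patch-tensor low-rank denoising parameters
#'
#' Defaults follow the reconstruction settings used with the sequence:
#' regularisation weight 0.07, 5x5x5 voxel patches, 20x20x20 search window,
#' 20 similar patches.
#'
#' @param lambda soft-threshold weight relative to each mode's leading
#'   singular value (0 disables shrinkage)
#' @param patch_size cubic patch edge (voxels)
#' @param search_window cubic search window edge (voxels)
#' @param n_similar number of similar patches stacked per group
#' @param stride patch-centre stride (voxels)
#' @param cand_stride stride of candidate locations inside the window
#' @param threshold "hard" (default) zeroes singular values below
#'   lambda x (mode leading value) and keeps the rest intact, preserving
#'   noiseless low-rank structure exactly; "soft" subtracts the threshold
#'   from every retained value
#' @return object of class `hdprost_params`
#' @export
hdprost_params <- function(lambda = 0.07, patch_size = 5, search_window = 20,
                           n_similar = 20, stride = 2, cand_stride = 2,
                           threshold = c("hard", "soft")) {
  stopifnot(patch_size <= search_window, n_similar >= 1, lambda >= 0,
            stride >= 1, cand_stride >= 1)
  structure(list(lambda = lambda, patch_size = as.integer(patch_size),
                 search_window = as.integer(search_window),
                 n_similar = as.integer(n_similar),
                 stride = as.integer(stride),
                 cand_stride = as.integer(cand_stride),
                 threshold = match.arg(threshold)),
            class = "hdprost_params")
}

## threshold singular values of each mode unfolding at
## lambda * (that mode's leading singular value); average the three
## reconstructions
shrink_tensor <- function(Tn, d1, d2, d3, lambda, type = "hard") {
  if (lambda <= 0) return(Tn)
  ## mode-1 unfolding: d1 x (d2 d3) is the native layout
  M1 <- matrix(Tn, d1, d2 * d3)
  ## mode-2: d2 x (d1 d3)
  M2 <- matrix(aperm(array(Tn, c(d1, d2, d3)), c(2, 1, 3)), d2, d1 * d3)
  ## mode-3: d3 x (d1 d2)
  M3 <- matrix(aperm(array(Tn, c(d1, d2, d3)), c(3, 1, 2)), d3, d1 * d2)
  st <- function(M) {
    sv <- svd(M)
    thr <- lambda * sv$d[1]
    dd <- if (type == "soft") pmax(sv$d - thr, 0)
          else ifelse(sv$d >= thr, sv$d, 0)
    sv$u %*% (dd * Conj(t(sv$v)))
  }
  R1 <- array(st(M1), c(d1, d2, d3))
  R2 <- aperm(array(st(M2), c(d2, d1, d3)), c(2, 1, 3))
  R3 <- aperm(array(st(M3), c(d3, d1, d2)), c(2, 3, 1))
  (R1 + R2 + R3) / 3
}

#' Multi-contrast patch-based higher-order low-rank denoising
#'
#' For each reference patch on the stride grid, the most similar patches in
#' the search window (similarity: summed squared distance across all
#' contrasts) are stacked into a third-order tensor
#' (patch-voxels x n_similar x contrasts). The singular values of each mode
#' unfolding are thresholded at `lambda` times that mode's leading singular
#' value (hard by default, so retained structure passes through unchanged;
#' soft shrinkage available), the three reconstructions are averaged, and
#' overlapping patch estimates are aggregated by uniform weighted averaging.
#' With `lambda = 0` the output equals the input.
#'
#' @param volumes 4D array (x, y, z, contrast), real or complex, or a list
#'   of 3D arrays
#' @param params [hdprost_params()]
#' @return denoised array of the same shape as the input (list in, list out)
#' @export
hdprost_denoise <- function(volumes, params = hdprost_params()) {
  was_list <- is.list(volumes)
  if (was_list) {
    d3 <- dim(volumes[[1]])
    if (!all(vapply(volumes, function(v) identical(dim(v), d3), TRUE)))
      stop("contrast volumes must share geometry", call. = FALSE)
    volumes <- array(unlist(volumes), c(d3, length(volumes)))
  }
  dims <- dim(volumes)[1:3]
  C <- dim(volumes)[4]
  p <- params$patch_size
  if (any(dims < p)) stop("volume smaller than patch", call. = FALSE)
  half_w <- params$search_window %/% 2
  num <- array(if (is.complex(volumes)) 0 + 0i else 0, dim(volumes))
  den <- array(0, dims)
  centers <- function(n) {
    cs <- seq(1, n - p + 1, by = params$stride)
    if (cs[length(cs)] != n - p + 1) cs <- c(cs, n - p + 1)
    cs
  }
  cx <- centers(dims[1]); cy <- centers(dims[2]); cz <- centers(dims[3])
  off <- as.matrix(expand.grid(0:(p - 1), 0:(p - 1), 0:(p - 1)))
  patch_at <- function(x0, y0, z0) {
    ## (p^3 x C) patch with corner (x0, y0, z0)
    v <- volumes[x0:(x0 + p - 1), y0:(y0 + p - 1), z0:(z0 + p - 1), ,
                 drop = FALSE]
    dim(v) <- c(p^3, C)
    v
  }
  for (x0 in cx) for (y0 in cy) for (z0 in cz) {
    ref <- patch_at(x0, y0, z0)
    gx <- seq(max(1, x0 - half_w), min(dims[1] - p + 1, x0 + half_w),
              by = params$cand_stride)
    gy <- seq(max(1, y0 - half_w), min(dims[2] - p + 1, y0 + half_w),
              by = params$cand_stride)
    gz <- seq(max(1, z0 - half_w), min(dims[3] - p + 1, z0 + half_w),
              by = params$cand_stride)
    cand <- as.matrix(expand.grid(gx, gy, gz))
    ## always include the reference location itself
    if (!any(cand[, 1] == x0 & cand[, 2] == y0 & cand[, 3] == z0))
      cand <- rbind(c(x0, y0, z0), cand)
    dsim <- numeric(nrow(cand))
    pats <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      pt <- patch_at(cand[i, 1], cand[i, 2], cand[i, 3])
      pats[[i]] <- pt
      dsim[i] <- sum(Mod(pt - ref)^2)
    }
    keep <- order(dsim)[seq_len(min(params$n_similar, length(dsim)))]
    K <- length(keep)
    Tn <- array(unlist(pats[keep]), c(p^3, C, K))
    Tn <- aperm(Tn, c(1, 3, 2))            # p^3 x K x C
    R <- shrink_tensor(Tn, p^3, K, C, params$lambda,
                       type = params$threshold %||% "hard")
    ## aggregate every member patch estimate back into the volume
    for (ik in seq_len(K)) {
      ci <- cand[keep[ik], ]
      est <- array(R[, ik, ], c(p, p, p, C))
      xs <- ci[1]:(ci[1] + p - 1); ys <- ci[2]:(ci[2] + p - 1)
      zs <- ci[3]:(ci[3] + p - 1)
      num[xs, ys, zs, ] <- num[xs, ys, zs, , drop = FALSE] + est
      den[xs, ys, zs] <- den[xs, ys, zs] + 1
    }
  }
  covered <- den > 0
  out <- volumes
  denC <- array(rep(den, C), dim(volumes))
  sel <- array(rep(covered, C), dim(volumes))
  out[sel] <- num[sel] / denC[sel]
  if (was_list) lapply(seq_len(C), function(i) out[, , , i]) else out
}
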