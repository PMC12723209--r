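#' Per-ROI mean/SD/CV statistics of a parameter map
#'
#' @param map 3D array (or `parameter_maps` component)
#' @param masks list of logical ROI masks
#' @return data.frame with region, n_voxels, mean, sd, cv_pct, median
#' @export
roi_stats <- function(map, masks) {
  rows <- lapply(seq_along(masks), function(i) {
    v <- map[masks[[i]]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("empty ROI ", i, " excluded")
      return(NULL)
    }
    data.frame(region = names(masks)[i] %||% paste0("roi", i),
               n_voxels = length(v), mean = mean(v), sd = stats::sd(v),
               cv_pct = 100 * stats::sd(v) / mean(v),
               median = stats::median(v))
  })
  do.call(rbind, rows)
}

#' Shrink ROI masks to centred circular ROIs of a given diameter
#'
#' Mimics drawing ~20 mm circular ROIs over the centre of each vial.
#'
#' @param masks list of logical 3D vial masks
#' @param diameter_mm ROI diameter
#' @param spacing voxel spacing (mm)
#' @return list of logical masks
#' @export
center_rois <- function(masks, diameter_mm = 20, spacing = 2) {
  lapply(masks, function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    cen <- colMeans(idx)
    xi <- array(rep(seq_len(d[1])), d)
    yi <- array(rep(seq_len(d[2]), each = d[1]), d)
    r <- diameter_mm / 2 / spacing
    ((xi - cen[1])^2 + (yi - cen[2])^2 <= r^2) & m
  })
}

#' Linear-regression and Bland-Altman agreement between two maps over ROIs
#'
#' Computes per-vial ROI means of maps `a` and `b`, applies the analysis
#' filter (keep vials whose reference T1 <= `t1_max_ms` and T1rho <=
#' `t1rho_max_ms`), then reports the regression of a on b, the coefficient
#' of determination, and the Bland-Altman bias with 1.96 SD limits of
#' agreement, for T1 and T1rho separately.
#'
#' @param maps_a `parameter_maps` (or list with t1/t1rho arrays): test
#' @param maps_b same, reference (filter is evaluated on these)
#' @param masks list of ROI masks
#' @param t1_max_ms,t1rho_max_ms analysis-range filter on the reference
#' @return object of class `agreement_report`: per-parameter list with
#'   slope, intercept, r_squared, bias, loa_low, loa_high, n_points, and the
#'   per-vial table
#' @export
roi_compare <- function(maps_a, maps_b, masks,
                        t1_max_ms = 1300, t1rho_max_ms = 150) {
  pars <- intersect(c("t1", "t1rho"), intersect(names(maps_a), names(maps_b)))
  stopifnot(length(pars) >= 1)
  tabs <- lapply(pars, function(p) {
    sa <- roi_stats(maps_a[[p]], masks)
    sb <- roi_stats(maps_b[[p]], masks)
    merge(sa, sb, by = "region", suffixes = c("_a", "_b"), sort = FALSE)
  })
  names(tabs) <- pars
  ## joint filter on the reference values
  ref_t1 <- if ("t1" %in% pars) tabs$t1$mean_b else NULL
  ref_t1rho <- if ("t1rho" %in% pars) tabs$t1rho$mean_b else NULL
  nvial <- nrow(tabs[[1]])
  keep <- rep(TRUE, nvial)
  if (!is.null(ref_t1)) keep <- keep & ref_t1 <= t1_max_ms
  if (!is.null(ref_t1rho)) keep <- keep & ref_t1rho <= t1rho_max_ms
  out <- lapply(pars, function(p) {
    tab <- tabs[[p]]
    a <- tab$mean_a[keep]; b <- tab$mean_b[keep]
    if (length(a) >= 2 && stats::sd(b) > 0) {
      fit <- stats::lm(a ~ b)
      slope <- unname(stats::coef(fit)[2])
      icept <- unname(stats::coef(fit)[1])
      ## suppress the degenerate perfect-fit warning from summary.lm
      r2 <- suppressWarnings(summary(fit)$r.squared)
    } else slope <- icept <- r2 <- NA_real_
    diffs <- a - b
    list(slope = slope, intercept = icept, r_squared = r2,
         bias = mean(diffs),
         loa_low = mean(diffs) - 1.96 * stats::sd(diffs),
         loa_high = mean(diffs) + 1.96 * stats::sd(diffs),
         n_points = length(a), table = cbind(tab, kept = keep))
  })
  names(out) <- pars
  structure(c(out, list(filter = c(t1_max_ms = t1_max_ms,
                                   t1rho_max_ms = t1rho_max_ms))),
            class = "agreement_report")
}

#' @exportS3Method base::print
print.agreement_report <- function(x, ...) {
  for (p in intersect(c("t1", "t1rho"), names(x))) {
    r <- x[[p]]
    cat(sprintf("%s: y = %.3f x + %.1f (r2 = %.4f), bias %.1f ms [%.1f, %.1f], n = %d\n",
                toupper(p), r$slope, r$intercept, r$r_squared, r$bias,
                r$loa_low, r$loa_high, r$n_points))
  }
  invisible(x)
}
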