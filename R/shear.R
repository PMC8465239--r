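#' Momentum flux of the reverse non-equilibrium shear protocol
#'
#' The imposed flux is the total swapped x-momentum divided by twice the
#' accumulation time and the cross-sectional area: `j = px / (2 t Lx Ly)`.
#' The factor two reflects the periodic geometry, where the momentum flows
#' from the driven slab to the mid slab through both halves of the box.
#'
#' @param accumulated_px Total transferred x-momentum.
#' @param t Accumulation time in tau (> 0).
#' @param Lx,Ly Box cross-section lengths in rc.
#' @return Momentum flux (reduced units).
#' @examples
#' momentum_flux(9, 1, 3, 3)  # 0.5
#' @export
momentum_flux <- function(accumulated_px, t, Lx, Ly) {
  if (any(t <= 0)) abort("undefined flux: accumulation time must be > 0")
  accumulated_px / (2 * t * Lx * Ly)
}

#' Velocity profile and shear-rate fit
#'
#' Computes the time-averaged x-velocity per z-bin and fits the two linear
#' branches of the Muller-Plathe profile -- descending from the driven slab
#' at z = 0 to the mid slab, ascending back -- by least squares, excluding
#' bins inside the two driven slabs. The shear rate is the mean absolute
#' slope of the two branches; when the run carries swap bookkeeping the
#' momentum flux and the viscosity `eta = flux / shear_rate` are reported
#' as well.
#'
#' @param x A `dpd_run` (uses its accumulated vx profile and shear
#'   bookkeeping), or a list of trajectory frames (each with `pos`, `vel`).
#' @param box Box lengths; required for a bare frame list.
#' @param n_bins Number of z-bins when binning frames directly.
#' @param n_slabs Swap-slab count used for exclusion (taken from the run
#'   when available).
#' @return An object of class `shear_fit` with the binned profile, the
#'   per-branch fits, and scalar summaries. Use [tidy()] for per-branch
#'   slopes and [glance()] for the one-row summary.
#' @export
velocity_profile <- function(x, box = NULL, n_bins = 50, n_slabs = 20) {
  flux <- NA_real_
  window_t <- NA_real_
  acc_px <- NA_real_
  if (inherits(x, "dpd_run")) {
    box <- x$state$box
    n_slabs <- x$shear$n_slabs
    prof <- x$vx_profile
    if (!any(prof$n > 0))
      abort("insufficient data: the run recorded no velocity profile samples")
    shear_on <- is.finite(x$shear$swap_interval) && x$shear$swap_interval >= 1
    if (shear_on) {
      if (x$shear$n_swaps == 0)
        abort("insufficient data: window shorter than one swap interval")
      window_t <- x$shear$window_steps * x$params$dt
      acc_px <- x$shear$acc_px
      flux <- momentum_flux(acc_px, window_t, box[1], box[2])
    }
  } else if (is.list(x) && length(x) > 0) {
    if (is.null(box)) abort("`box` is required for a frame list")
    sums <- numeric(n_bins)
    cnts <- numeric(n_bins)
    for (fr in x) {
      b <- pmin(floor(fr$pos[, 3] / box[3] * n_bins) + 1, n_bins)
      sums <- sums + tapply2(fr$vel[, 1], b, n_bins)
      cnts <- cnts + tabulate(b, n_bins)
    }
    prof <- tibble(z = (seq_len(n_bins) - 0.5) * box[3] / n_bins,
                   vx = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                   n = cnts)
  } else {
    abort("insufficient data: empty trajectory window")
  }
  Lz <- box[3]
  hs <- Lz / n_slabs
  mid_lo <- (n_slabs %/% 2) * hs
  mid_hi <- mid_lo + hs
  prof <- prof |>
    mutate(driven = (.data$z < hs) | (.data$z >= mid_lo & .data$z < mid_hi),
           branch = ifelse(.data$z < mid_lo, "descending", "ascending"))
  fit_branch <- function(d) {
    d <- d[!d$driven & !is.na(d$vx), ]
    if (nrow(d) < 3)
      return(tibble(slope = NA_real_, std.error = NA_real_, n_bins = nrow(d)))
    f <- lm(vx ~ z, data = d)
    tibble(slope = coef(f)[["z"]],
           std.error = summary(f)$coefficients["z", "Std. Error"],
           n_bins = nrow(d))
  }
  branches <- prof |>
    group_by(.data$branch) |>
    dplyr::group_modify(~ fit_branch(.x)) |>
    ungroup()
  rate <- mean(abs(branches$slope), na.rm = TRUE)
  structure(list(profile = prof, branches = branches,
                 shear_rate = rate, flux = flux,
                 viscosity = if (is.na(flux)) NA_real_ else flux / rate,
                 acc_px = acc_px, window_time = window_t,
                 n_slabs = n_slabs, box = box),
            class = "shear_fit")
}

tapply2 <- function(v, idx, n) {
  out <- numeric(n)
  s <- tapply(v, factor(idx, levels = seq_len(n)), sum)
  out[as.integer(names(s))] <- ifelse(is.na(s), 0, s)
  out
}

#' @export
print.shear_fit <- function(x, ...) {
  cat("<shear_fit> shear rate ", signif(x$shear_rate, 4), sep = "")
  if (!is.na(x$flux))
    cat(", flux ", signif(x$flux, 4), ", viscosity ", signif(x$viscosity, 4),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @describeIn velocity_profile Per-branch slope estimates.
#' @param x A `shear_fit`.
#' @param ... Unused.
#' @export
tidy.shear_fit <- function(x, ...) x$branches

#' @describeIn velocity_profile One-row summary: shear rate, flux,
#'   viscosity, accumulated momentum, window time.
#' @export
glance.shear_fit <- function(x, ...) {
  tibble(shear_rate = x$shear_rate, flux = x$flux,
         viscosity = x$viscosity, acc_px = x$acc_px,
         window_time = x$window_time)
}
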