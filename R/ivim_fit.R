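#' Fit configuration for ADC / IVIM map computation
#'
#' @param segmented_threshold b-value (s/mm^2) separating the
#'   perfusion-sensitive low-b segment from the pure-diffusion high-b
#'   segment. 200 s/mm^2 is the conventional cut: pseudo-diffusion with
#'   D* >= 5e-3 mm^2/s has decayed by e^-1 by b = 200.
#' @param d_bounds allowed tissue diffusivity range (mm^2/s).
#' @param dstar_max upper bound for the pseudo-diffusion coefficient
#'   (mm^2/s); the lower bound is the fitted D.
#' @param f_bounds allowed perfusion-fraction range.
#' @param adc_b_pair b-values `(b_low, b_high)` used for the two-point ADC;
#'   `NULL` means (0, max b) and it is an error if either frame is absent.
#' @param max_iter,tol iteration cap and relative convergence tolerance for
#'   the segmented fit refinement.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(segmented_threshold = 200,
                       d_bounds = c(1e-5, 4e-3),
                       dstar_max = 0.5,
                       f_bounds = c(0, 1),
                       adc_b_pair = NULL,
                       max_iter = 50L, tol = 1e-10) {
  stopifnot(segmented_threshold > 0, d_bounds[1] > 0,
            d_bounds[1] < d_bounds[2], dstar_max > d_bounds[2])
  if (!is.null(adc_b_pair) && adc_b_pair[1] >= adc_b_pair[2])
    stop("adc_b_pair must satisfy b_low < b_high", call. = FALSE)
  structure(list(segmented_threshold = segmented_threshold,
                 d_bounds = d_bounds, dstar_max = dstar_max,
                 f_bounds = f_bounds, adc_b_pair = adc_b_pair,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "fit_config")
}

#' Is IVIM analysis feasible for a b-value scheme?
#'
#' The biexponential model has four unknowns and needs both decay regimes
#' sampled: at least 4 distinct b-values overall, with at least 2 distinct
#' values below the segmentation threshold (perfusion-sensitive) and at
#' least 2 at or above it (pure diffusion).
#'
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @param segmented_threshold segment cut in s/mm^2 (default 200).
#' @return A list of class `ivim_feasibility` with logical `feasible` and a
#'   human-readable `reason`.
#' @examples
#' check_ivim_feasibility(c(0, 50, 100, 150, 600, 1000))$feasible  # TRUE
#' @export
check_ivim_feasibility <- function(bvalues, segmented_threshold = 200) {
  stopifnot(length(bvalues) > 0)
  b <- sort(unique(bvalues))
  lo <- sum(b < segmented_threshold)
  hi <- sum(b >= segmented_threshold)
  verdict <- function(ok, reason)
    structure(list(feasible = ok, reason = reason,
                   n_distinct = length(b), n_low = lo, n_high = hi,
                   segmented_threshold = segmented_threshold),
              class = "ivim_feasibility")
  if (length(b) < 4L)
    return(verdict(FALSE, sprintf(
      "needs >=4 distinct b-values (got %d)", length(b))))
  if (hi < 2L)
    return(verdict(FALSE, sprintf(
      "needs >=2 b-values >= %g s/mm^2 (got %d)", segmented_threshold, hi)))
  if (lo < 2L)
    return(verdict(FALSE, sprintf(
      "needs >=2 b-values < %g s/mm^2 (got %d)", segmented_threshold, lo)))
  verdict(TRUE, sprintf(
    "%d distinct b-values: %d below and %d at/above %g s/mm^2",
    length(b), lo, hi, segmented_threshold))
}

#' @export
print.ivim_feasibility <- function(x, ...) {
  cat(sprintf("IVIM analysis %s: %s\n",
              if (x$feasible) "feasible" else "NOT feasible", x$reason))
  invisible(x)
}

#' Compute a two-point ADC map
#'
#' The apparent diffusion coefficient per voxel is the mono-exponential
#' decay rate between two b-values:
#' `ADC = ln(S(b_low) / S(b_high)) / (b_high - b_low)` (mm^2/s).
#' Voxels where either signal is not strictly positive become `NaN`, as do
#' (rare, noise-induced) voxels where the log-ratio is negative.
#'
#' @param dwi a [dwi_series()]; per-direction series are trace-combined
#'   first via [combine_directions()].
#' @param config a [fit_config()]; `adc_b_pair` selects the two frames
#'   (default: b = 0 and the maximum b).
#' @return A `parametric_map` of kind `"ADC"` in mm^2/s.
#' @export
compute_adc_map <- function(dwi, config = fit_config()) {
  dc <- combine_directions(dwi)
  pair <- config$adc_b_pair %||% c(0, max(dc$bvalues))
  i_lo <- match(pair[1], dc$bvalues)
  i_hi <- match(pair[2], dc$bvalues)
  if (is.na(i_lo) || is.na(i_hi))
    stop("requested ADC b-value pair (", pair[1], ", ", pair[2],
         ") not present in series (b = ",
         paste(dc$bvalues, collapse = ", "), ")", call. = FALSE)
  s_lo <- dc$signal[, , , i_lo]
  s_hi <- dc$signal[, , , i_hi]
  adc <- log(s_lo / s_hi) / (pair[2] - pair[1])
  adc[s_lo <= 0 | s_hi <= 0] <- NaN
  adc[!is.finite(adc) | adc < 0] <- NaN
  parametric_map(array(adc, dim = dim(dc$signal)[1:3]), kind = "ADC",
                 spacing = dc$spacing)
}

new_ivim_params <- function(S0 = NaN, D = NaN, Dstar = NaN, f = NaN,
                            status = "degenerate", iterations = 0L) {
  structure(list(S0 = S0, D = D, Dstar = Dstar, f = f, status = status,
                 iterations = iterations),
            class = "ivim_params")
}

loglin_fit <- function(b, s) {
  # least-squares line through (b, log s); returns c(intercept A, slope D)
  ls <- log(s)
  sl <- stats::cov(b, ls) / stats::var(b)
  a <- mean(ls) - sl * mean(b)
  c(A = exp(a), D = -sl)
}

ivim_model <- function(b, S0, D, Dstar, f)
  S0 * ((1 - f) * exp(-b * D) + f * exp(-b * (D + Dstar)))

#' Fit the IVIM biexponential model to one voxel
#'
#' Signal model: `S(b) = S0 * ((1 - f) * exp(-b D) + f * exp(-b (D + D*)))`.
#' The fit is segmented: (i) a log-linear fit over the high-b segment
#' (b >= threshold) gives the tissue diffusivity D and intercept A;
#' (ii) `f = 1 - A / S(0)`; (iii) with D and f held, D* is found by bounded
#' one-dimensional least squares over all b-values. Steps (i)-(iii) are then
#' iterated with the high-b signals corrected for the current perfusion
#' component, which makes the noise-free fit exact rather than merely
#' approximate (the perfusion tail has not fully decayed at b = 600 for slow
#' D*). The iteration is a fixed point at the true parameters and is
#' deterministic.
#'
#' @param signals positive signal per acquisition.
#' @param bvalues b-value per acquisition (s/mm^2); duplicated b-values
#'   (directions) are averaged geometrically first.
#' @param config a [fit_config()].
#' @return An `ivim_params` list: `S0`, `D`, `Dstar`, `f` plus a `status` of
#'   `"ok"`, `"degenerate"` (nonpositive signal), `"infeasible"`, or
#'   `"nonconverged"` (iteration cap hit or bound-clipped estimate).
#' @export
fit_ivim_voxel <- function(signals, bvalues, config = fit_config()) {
  feas <- check_ivim_feasibility(bvalues, config$segmented_threshold)
  if (!feas$feasible) return(new_ivim_params(status = "infeasible"))
  if (any(!is.finite(signals)) || any(signals <= 0))
    return(new_ivim_params(status = "degenerate"))
  # collapse duplicated b (directions) by geometric mean
  if (anyDuplicated(bvalues)) {
    s <- exp(tapply(log(signals), bvalues, mean))
    b <- as.numeric(names(s))
    signals <- as.numeric(s)[order(b)]
    bvalues <- sort(b)
  }
  thr <- config$segmented_threshold
  hi <- bvalues >= thr
  S0 <- signals[which.min(bvalues)]
  fit <- loglin_fit(bvalues[hi], signals[hi])
  D <- fit[["D"]]; f <- 1 - fit[["A"]] / S0
  Dstar <- NA_real_
  clipped <- FALSE
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    f_eff <- min(max(f, 0), 0.99)
    D_eff <- min(max(D, config$d_bounds[1]), config$d_bounds[2])
    if (f_eff < 1e-4) {
      Dstar <- D_eff  # perfusion-free limit: D* unidentifiable, pin to D
    } else {
      sse <- function(ds) sum((signals -
        ivim_model(bvalues, S0, D_eff, ds, f_eff))^2)
      Dstar <- stats::optimize(sse, c(D_eff, config$dstar_max),
                               tol = 1e-12)$minimum
    }
    corr <- signals[hi] - S0 * f_eff * exp(-bvalues[hi] * (D_eff + Dstar))
    if (any(corr <= 0)) break  # heavy noise: keep previous iterate
    fit <- loglin_fit(bvalues[hi], corr)
    D_new <- fit[["D"]]
    f_new <- 1 - fit[["A"]] / S0  # A = S0 (1 - f) at the fixed point
    dD <- abs(D_new - D) / max(abs(D), 1e-12)
    df <- abs(f_new - f)
    D <- D_new; f <- f_new
    if (dD < config$tol && df < config$tol) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
  }
  # clip to the physiological box; excursions beyond rounding error are
  # flagged, pure floating-point dust is clamped silently
  eps <- 1e-9
  if (D < config$d_bounds[1] - eps || D > config$d_bounds[2] + eps)
    clipped <- TRUE
  D <- min(max(D, config$d_bounds[1]), config$d_bounds[2])
  if (f < config$f_bounds[1] - eps || f > config$f_bounds[2] + eps)
    clipped <- TRUE
  f <- min(max(f, config$f_bounds[1]), config$f_bounds[2])
  if (Dstar < D) Dstar <- D
  status <- if (clipped || !converged) "nonconverged" else "ok"
  new_ivim_params(S0 = S0, D = D, Dstar = Dstar, f = f, status = status,
                  iterations = iter)
}

#' Compute IVIM parametric maps
#'
#' Applies [fit_ivim_voxel()] to every voxel of a direction-combined series
#' and returns the four IVIM maps. Voxels whose fit status is not `"ok"`
#' are `NaN` in all maps.
#'
#' @param dwi a [dwi_series()].
#' @param config a [fit_config()].
#' @param mask optional [roi_mask()] restricting the fit (all other voxels
#'   `NaN`); background can be skipped this way.
#' @return A named list of `parametric_map`s: `D`, `Dstar`, `f`, `S0`, plus
#'   a `status` character array of per-voxel fit statuses.
#' @export
fit_ivim_maps <- function(dwi, config = fit_config(), mask = NULL) {
  feas <- check_ivim_feasibility(dwi$bvalues, config$segmented_threshold)
  if (!feas$feasible)
    stop("IVIM analysis not feasible: ", feas$reason, call. = FALSE)
  dc <- combine_directions(dwi)
  d <- dim(dc$signal)
  nvox <- prod(d[1:3])
  sig <- matrix(dc$signal, nrow = nvox)
  todo <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask$mask)
  D <- Ds <- f <- S0 <- rep(NaN, nvox)
  status <- rep(if (is.null(mask)) "degenerate" else "masked", nvox)
  for (v in which(todo)) {
    p <- fit_ivim_voxel(sig[v, ], dc$bvalues, config)
    status[v] <- p$status
    if (p$status == "ok") {
      D[v] <- p$D; Ds[v] <- p$Dstar; f[v] <- p$f; S0[v] <- p$S0
    }
  }
  shape <- d[1:3]
  list(D = parametric_map(array(D, shape), "IVIM-D", dc$spacing),
       Dstar = parametric_map(array(Ds, shape), "IVIM-Dstar", dc$spacing),
       f = parametric_map(array(f, shape), "IVIM-f", dc$spacing),
       S0 = parametric_map(array(S0, shape), "S0", dc$spacing),
       status = array(status, shape))
}
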