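#' Arterial input function container
#'
#' @param times Frame times in seconds, strictly increasing.
#' @param cp Plasma contrast concentration in mM, non-negative, one value
#'   per frame.
#' @param n_voxels Number of voxels the curve was averaged over (for a
#'   measured AIF; `NA` for a population curve).
#' @return An object of class `aif`.
#' @export
aif <- function(times, cp, n_voxels = NA_integer_) {
  times <- as.numeric(times); cp <- as.numeric(cp)
  stopifnot("times must be strictly increasing" = all(diff(times) > 0),
            "times and cp must have equal length" = length(times) == length(cp),
            "cp must be non-negative" = all(cp >= -1e-12))
  structure(list(times = times, cp = pmax(cp, 0), n_voxels = n_voxels),
            class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("AIF: %d frames over %.0f s, peak %.2f mM at t = %.0f s\n",
              length(x$times), max(x$times) - min(x$times),
              max(x$cp), x$times[which.max(x$cp)]))
  invisible(x)
}

#' Population arterial input function
#'
#' Deterministic bolus-plus-washout plasma curve used when no sagittal-sinus
#' mask is available: zero before bolus arrival, then a difference of
#' exponentials
#' `cp(t) = A (exp(-m1 tau) - exp(-m2 tau))`, `tau = (t - t0)/60` minutes,
#' giving a fast upslope (rate `m2`) and a slow biexponential-style washout
#' (rate `m1`). With the defaults the curve peaks about 30 s after arrival
#' at roughly 6 mM, a typical plasma profile for a compact 0.1 mmol/kg
#' bolus at 3 T.
#'
#' @param times Frame times in seconds.
#' @param params List with elements `amplitude` (mM), `m1` and `m2`
#'   (1/min, washout and upslope rates), `t0` (bolus arrival, s).
#' @return An [aif()] on the supplied time grid.
#' @examples
#' a <- population_aif((0:44) * 8)
#' which.max(a$cp)
#' @export
population_aif <- function(times,
                           params = list(amplitude = 6.5, m1 = 0.17,
                                         m2 = 8, t0 = 40)) {
  stopifnot(all(diff(times) > 0), params$m2 > params$m1, params$m1 > 0)
  tau <- pmax(times - params$t0, 0) / 60
  cp <- params$amplitude * (exp(-params$m1 * tau) - exp(-params$m2 * tau))
  cp[times < params$t0] <- 0
  aif(times, cp)
}

#' Convert dynamic SPGR signal to contrast concentration
#'
#' Inverts the SPGR closed form per voxel and frame to obtain `R1(t)`,
#' then applies the linear relaxivity model
#' `C(t) = (R1(t) - R1(0)) / r1`. The pre-contrast relaxation rate
#' `R1(0)` comes from the VFA T1 map (`baseline = "t1map"`, the default,
#' since T1 mapping is acquired before injection) or is re-estimated per
#' voxel by inverting the mean of the first `n_baseline` dynamic frames
#' (`baseline = "signal"`).
#'
#' Signals at or beyond the SPGR saturation bound (`S >= M0 sin(a)`, where
#' the model is non-invertible) and voxels with `fit_ok = FALSE` yield
#' `NA`; the count of non-invertible samples is returned in the QC field.
#'
#' @param signal Dynamic signal: matrix (voxels x frames) or 4D array with
#'   time last.
#' @param maps A `t1_maps` object from [fit_t1_vfa()] on the same voxel
#'   grid.
#' @param protocol A [scan_protocol()]; uses `tr`, `flip_angle_dyn`,
#'   `relaxivity_r1`, `n_baseline`.
#' @param baseline `"t1map"` or `"signal"` (see Details).
#' @return List of class `conc_series`: `conc` (same shape as `signal`,
#'   mM), `times` (s), `qc` (list with `n_noninvertible`, `n_rejected_voxels`).
#' @export
signal_to_concentration <- function(signal, maps, protocol,
                                    baseline = c("t1map", "signal")) {
  baseline <- match.arg(baseline)
  dims <- NULL
  if (is.array(signal) && length(dim(signal)) == 4) {
    dims <- dim(signal)
    signal <- matrix(signal, ncol = dims[4])
  }
  signal <- as.matrix(signal)
  nf <- ncol(signal)
  stopifnot(protocol$n_baseline < nf)
  m0 <- as.vector(maps$m0); ok <- as.vector(maps$fit_ok)
  if (length(m0) != nrow(signal))
    stop("T1/M0 maps and dynamic series have different voxel counts")

  a <- protocol$flip_angle_dyn * pi / 180
  tr <- protocol$tr

  # E1 = (M0 sin a - S) / (M0 sin a - S cos a); invertible iff 0 < E1 < 1
  ms <- m0 * sin(a)
  num <- ms - signal
  den <- ms - signal * cos(a)
  e1 <- num / den
  invertible <- is.finite(e1) & e1 > 0 & e1 < 1
  r1 <- matrix(NA_real_, nrow(signal), nf)
  r1[invertible] <- -log(e1[invertible]) / tr

  r1_0 <- switch(baseline,
    t1map = 1000 / as.vector(maps$t1_ms),
    signal = {
      s0 <- rowMeans(signal[, seq_len(protocol$n_baseline), drop = FALSE])
      e10 <- (ms - s0) / (ms - s0 * cos(a))
      ifelse(is.finite(e10) & e10 > 0 & e10 < 1, -log(e10) / tr, NA_real_)
    })

  conc <- (r1 - r1_0) / protocol$relaxivity_r1
  conc[!ok, ] <- NA_real_

  qc <- list(n_noninvertible = sum(!invertible[ok, , drop = FALSE]),
             n_rejected_voxels = sum(!ok))
  if (!is.null(dims)) conc <- array(conc, dims)
  structure(list(conc = conc,
                 times = (seq_len(nf) - 1) * protocol$dt,
                 qc = qc),
            class = "conc_series")
}

#' Extract the input function from a sagittal-sinus mask
#'
#' Averages the whole-blood concentration curve over the mask voxels and
#' scales it to plasma concentration by `1 / (1 - hematocrit)`. The venous
#' sagittal-sinus curve is used directly as the kinetic-model input, with
#' no delay or dispersion correction. Mask voxels with missing
#' concentration (failed T1 fit or non-invertible signal) are excluded;
#' the usable-voxel count is reported on the returned object.
#'
#' @param conc A `conc_series` from [signal_to_concentration()].
#' @param sinus_mask Logical (or 0/1) mask matching the voxel grid.
#' @param hematocrit Hematocrit fraction in `[0, 1)`.
#' @return An [aif()]; its `n_voxels` field is the usable-voxel count.
#' @export
extract_aif <- function(conc, sinus_mask, hematocrit) {
  stopifnot(hematocrit >= 0, hematocrit < 1)
  cm <- conc$conc
  if (is.array(cm) && length(dim(cm)) == 4) cm <- matrix(cm, ncol = dim(cm)[4])
  mask <- as.logical(as.vector(sinus_mask))
  if (length(mask) != nrow(cm))
    stop("sinus mask does not match the concentration voxel grid")
  if (!any(mask)) stop("sinus mask is empty")
  sub <- cm[mask, , drop = FALSE]
  usable <- stats::complete.cases(sub)
  if (!any(usable)) stop("all sinus-mask voxels have missing concentration")
  cb <- colMeans(sub[usable, , drop = FALSE])
  # noise can push the averaged baseline a hair below zero; floor at 0
  aif(conc$times, pmax(cb, 0) / (1 - hematocrit), n_voxels = sum(usable))
}

#' Extended Tofts forward model
#'
#' Tissue concentration under the extended Tofts model,
#' `Ct(t) = Vp Cp(t) + Ktrans * integral_0^t Cp(u) exp(-kep (t - u)) du`
#' with `kep = Ktrans / Ve`. The convolution is evaluated by trapezoidal
#' quadrature on the frame grid, applied to the equivalent integral
#' equation `Ce(t) = Ktrans int Cp - kep int Ce` (solved by forward
#' recursion). This discretisation is exactly the one the linear estimator
#' [fit_extended_tofts_linear()] inverts, so noiseless round trips recover
#' the generating parameters to machine precision; against the continuous
#' model it is second-order accurate in the frame spacing.
#'
#' @param ktrans Volume transfer constant, 1/min (>= 0).
#' @param ve Extravascular-extracellular volume fraction in (0, 1]
#'   (required only when `ktrans > 0`).
#' @param vp Plasma volume fraction in `[0, 1]`.
#' @param aif An [aif()] on the target time grid (seconds).
#' @return Numeric vector `Ct` in mM, one value per frame.
#' @examples
#' a <- population_aif((0:44) * 8)
#' ct <- tofts_forward(0.1, 0.2, 0.02, a)
#' @export
tofts_forward <- function(ktrans, ve, vp, aif) {
  stopifnot(inherits(aif, "aif"), ktrans >= 0, vp >= 0, vp <= 1)
  if (ktrans > 0 && (is.na(ve) || ve <= 0 || ve > 1))
    stop("ve must lie in (0, 1] when ktrans > 0")
  if (ktrans > 0 && ve + vp > 1 + 1e-12)
    stop("ve + vp must not exceed 1")
  cp <- aif$cp; tt <- aif$times
  n <- length(tt)
  kt_s <- ktrans / 60
  kep_s <- if (ktrans > 0) (ktrans / ve) / 60 else 0
  ce <- numeric(n)
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1]
    ce[i] <- (ce[i - 1] +
                (h / 2) * (kt_s * (cp[i] + cp[i - 1]) - kep_s * ce[i - 1])) /
      (1 + kep_s * h / 2)
  }
  vp * cp + ce
}

#' Linear least-squares fit of the extended Tofts model
#'
#' Solves the linear reformulation of the model (Murase form):
#' `Ct(t) = b1 int_0^t Cp + b2 int_0^t Ct + b3 Cp(t)` with
#' `b2 = -kep`, `b3 = Vp`, `b1 = Ktrans + kep Vp`; the integrals are
#' cumulative trapezoids on the frame grid and the coefficients come from
#' ordinary least squares. Estimates that violate the parameter bounds
#' (`ktrans >= 0`, `0 < ve <= 1`, `0 <= vp <= 1`) are clipped to the bounds
#' and flagged rather than discarded, so ROI statistics downstream remain
#' computable.
#'
#' @param ct Tissue concentration curve, mM, one value per frame (frames
#'   with `NA` are dropped from the regression, minimum 4 usable).
#' @param aif An [aif()] on the same time grid.
#' @return A list of class `kinetic_params`: `ktrans`, `ve`, `vp` and the
#'   derived `kep` (1/min), `rss`, and `flags` (character vector naming any
#'   clipped bounds; empty when the unconstrained solution was admissible).
#' @export
fit_extended_tofts_linear <- function(ct, aif) {
  stopifnot(inherits(aif, "aif"))
  ct <- as.numeric(ct)
  if (length(ct) != length(aif$times))
    stop("ct and aif must share the time grid")
  if (all(abs(aif$cp) < 1e-300)) stop("degenerate (all-zero) AIF")
  tt <- aif$times
  icp <- pracma::cumtrapz(tt, aif$cp)[, 1]
  ict_full <- rep(NA_real_, length(ct))
  use <- is.finite(ct)
  if (sum(use) < 4) stop("need at least 4 usable frames")
  # cumulative trapezoid of Ct on the usable frames
  ict <- pracma::cumtrapz(tt[use], ct[use])[, 1]
  X <- cbind(icp[use], ict, aif$cp[use])
  fit <- stats::lm.fit(X, ct[use])
  b <- fit$coefficients
  b[is.na(b)] <- 0
  kep <- -b[2] * 60
  vp <- b[3]
  ktrans <- b[1] * 60 - kep * vp
  ve <- if (kep > 0) ktrans / kep else NA_real_

  flags <- character(0)
  if (ktrans < 0) { ktrans <- 0; flags <- c(flags, "ktrans_low") }
  if (kep < 0) { kep <- 0; flags <- c(flags, "kep_low") }
  if (vp < 0) { vp <- 0; flags <- c(flags, "vp_low") }
  if (vp > 1) { vp <- 1; flags <- c(flags, "vp_high") }
  if (ktrans > 0) {
    if (is.na(ve) || ve <= 0) { ve <- NA_real_; flags <- c(flags, "ve_undef") }
    else if (ve > 1) { ve <- 1; flags <- c(flags, "ve_high") }
  } else {
    ve <- NA_real_
    if (!("ktrans_low" %in% flags) && all(abs(ct[use]) < 1e-300))
      flags <- c(flags, "zero_curve")
  }
  kep <- if (!is.na(ve) && ve > 0) ktrans / ve else kep
  structure(list(ktrans = unname(ktrans), ve = unname(ve), vp = unname(vp),
                 kep = unname(kep), rss = sum(fit$residuals^2),
                 flags = flags, method = "linear"),
            class = "kinetic_params")
}

#' Nonlinear least-squares fit of the extended Tofts model
#'
#' Bounded Levenberg-Marquardt minimisation of
#' `||ct - tofts_forward(ktrans, ve, vp)||^2`, used as an independent
#' cross-check of the linear solver. Bounds: `ktrans` in `[0, 5]` /min,
#' `ve` in `(0, 1]`, `vp` in `[0, 1]`. Deterministic given the starting
#' point. On failure to converge the (flagged) initial estimate is
#' returned.
#'
#' @param ct Tissue concentration curve, mM.
#' @param aif An [aif()] on the same grid.
#' @param init Starting values: a `kinetic_params` (e.g. from
#'   [fit_extended_tofts_linear()]) or a list with `ktrans`, `ve`, `vp`.
#' @return A `kinetic_params` list (see [fit_extended_tofts_linear()]).
#' @export
fit_extended_tofts_nls <- function(ct, aif, init = NULL) {
  stopifnot(inherits(aif, "aif"))
  ct <- as.numeric(ct)
  use <- is.finite(ct)
  if (sum(use) < 4) stop("need at least 4 usable frames")
  if (all(abs(aif$cp) < 1e-300)) stop("degenerate (all-zero) AIF")
  if (is.null(init)) init <- fit_extended_tofts_linear(ct, aif)
  p0 <- c(ktrans = max(init$ktrans, 1e-4),
          ve = min(max(ifelse(is.na(init$ve), 0.2, init$ve), 1e-3), 1),
          vp = min(max(init$vp, 0), 1))
  lower <- c(0, 1e-6, 0); upper <- c(5, 1, 1)
  resid_fn <- function(p) {
    pred <- tofts_forward(p[1], p[2], p[3], aif)
    ct[use] - pred[use]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    out <- init
    out$flags <- unique(c(out$flags, "nls_nonconvergent"))
    return(out)
  }
  p <- fit$par
  ktrans <- p[1]; ve <- p[2]; vp <- p[3]
  flags <- character(0)
  if (ktrans <= lower[1] + 1e-12) flags <- c(flags, "ktrans_at_bound")
  structure(list(ktrans = unname(ktrans),
                 ve = unname(if (ktrans > 0) ve else NA_real_),
                 vp = unname(vp),
                 kep = unname(if (ktrans > 0) ktrans / ve else 0),
                 rss = sum(fit$fvec^2), flags = flags, method = "nls"),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Extended Tofts fit (%s): Ktrans %.4f /min, Ve %s, Vp %.4f, kep %.3f /min, rss %.3g\n",
              x$method, x$ktrans,
              ifelse(is.na(x$ve), "NA", sprintf("%.3f", x$ve)),
              x$vp, x$kep, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Voxelwise extended Tofts fitting
#'
#' Applies [fit_extended_tofts_linear()] (optionally refined by
#' [fit_extended_tofts_nls()]) to every voxel of a concentration series.
#'
#' @param conc A `conc_series` or a voxels-by-frames matrix of mM values.
#' @param aif An [aif()] on the matching time grid.
#' @param method `"linear"` (default) or `"nls"` (linear start, nonlinear
#'   polish).
#' @param mask Optional logical vector/array restricting the fit.
#' @return A data frame with one row per voxel: `voxel`, `ktrans`, `ve`,
#'   `vp`, `kep`, `rss`, `fit_ok` (no flags raised and all frames usable),
#'   `flags` (collapsed, `;`-separated).
#' @export
fit_tofts_map <- function(conc, aif, method = c("linear", "nls"), mask = NULL) {
  method <- match.arg(method)
  cm <- if (inherits(conc, "conc_series")) conc$conc else conc
  if (is.array(cm) && length(dim(cm)) == 4) cm <- matrix(cm, ncol = dim(cm)[4])
  cm <- as.matrix(cm)
  idx <- seq_len(nrow(cm))
  if (!is.null(mask)) idx <- idx[as.logical(as.vector(mask))]
  out <- data.frame(voxel = idx, ktrans = NA_real_, ve = NA_real_,
                    vp = NA_real_, kep = NA_real_, rss = NA_real_,
                    fit_ok = FALSE, flags = "", stringsAsFactors = FALSE)
  for (j in seq_along(idx)) {
    ct <- cm[idx[j], ]
    if (sum(is.finite(ct)) < 4) { out$flags[j] <- "too_few_frames"; next }
    p <- fit_extended_tofts_linear(ct, aif)
    if (method == "nls") p <- fit_extended_tofts_nls(ct, aif, init = p)
    out$ktrans[j] <- p$ktrans; out$ve[j] <- p$ve; out$vp[j] <- p$vp
    out$kep[j] <- p$kep; out$rss[j] <- p$rss
    out$fit_ok[j] <- length(p$flags) == 0 && all(is.finite(ct))
    out$flags[j] <- paste(p$flags, collapse = ";")
  }
  out
}

#' ROI statistics for a parameter map
#'
#' Mean, SD and voxel count of a fitted parameter over a lesion ROI and its
#' contralateral mirror ROI, plus their paired difference. The two masks
#' are expected to have equal voxel counts (same-size ROIs); unequal
#' counts raise a warning, not an error. Only voxels whose fit raised no
#' flags enter the statistics unless `use_flagged = TRUE`, in which case
#' clipped (flagged) estimates are included as well.
#'
#' @param values Parameter values, one per voxel (e.g. the `ktrans` column
#'   of [fit_tofts_map()] expanded to the grid), vector or array.
#' @param roi_mask,mirror_mask Logical (or 0/1) masks on the same grid.
#' @param fit_ok Optional logical vector marking usable voxels.
#' @param use_flagged Include flagged voxels (default `FALSE` when a
#'   `fit_ok` vector is supplied).
#' @return A list with `lesion` and `mirror` (each `mean`, `sd`, `n`) and
#'   `difference` (lesion mean - mirror mean).
#' @export
roi_ktrans_stats <- function(values, roi_mask, mirror_mask, fit_ok = NULL,
                             use_flagged = FALSE) {
  v <- as.vector(values)
  roi <- as.logical(as.vector(roi_mask))
  mir <- as.logical(as.vector(mirror_mask))
  if (!any(roi)) stop("lesion ROI mask is empty")
  if (!any(mir)) stop("mirror ROI mask is empty")
  if (sum(roi) != sum(mir))
    warning(sprintf("ROI masks differ in size (%d vs %d voxels)",
                    sum(roi), sum(mir)))
  ok <- if (is.null(fit_ok) || use_flagged) rep(TRUE, length(v))
        else as.logical(as.vector(fit_ok))
  stat1 <- function(sel) {
    x <- v[sel & ok & is.finite(v)]
    if (!length(x)) stop("no usable voxels in ROI")
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  lesion <- stat1(roi); mirror <- stat1(mir)
  list(lesion = lesion, mirror = mirror,
       difference = lesion$mean - mirror$mean)
}
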