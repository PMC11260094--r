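# Angle-resolved reflectance analysis: specular masking, diffraction-spot
# detection, and grating-equation fits of the photonic-crystal lattice
# constant d.  Convention: angles are measured from the surface normal,
# incident beam at theta_in (default -45 degrees), diffracted angles
# positive on the opposite side; the reflection-grating relation is
# m * lambda = d * (sin theta_in + sin theta_out).

.deg2rad <- function(x) x * pi / 180

#' Construct an angle-resolved spectra matrix
#'
#' @param wavelengths ascending wavelengths (nm).
#' @param angles strictly monotone detection angles (degrees).
#' @param intensity non-negative matrix, wavelengths x angles.
#' @param theta_in fixed incident angle (degrees), |theta_in| < 90.
#' @param specular_mask angle interval `c(lo, hi)` excluded from analysis
#'   (the specular reflection around `-theta_in`), or NULL.
#' @return object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(wavelengths, angles, intensity, theta_in = -45,
                           specular_mask = NULL) {
  intensity <- as.matrix(intensity)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be ascending")
  if (length(unique(sign(diff(angles)))) > 1L)
    stop("angles must be strictly monotone")
  if (nrow(intensity) != length(wavelengths) ||
      ncol(intensity) != length(angles))
    stop("intensity dimensions must match the axes")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  if (abs(theta_in) >= 90) stop("|theta_in| must be < 90 degrees")
  structure(list(wavelengths = as.numeric(wavelengths),
                 angles = as.numeric(angles), intensity = intensity,
                 theta_in = theta_in, specular_mask = specular_mask),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "angle-resolved spectra: %d wavelengths (%g-%g nm) x %d angles (%g-%g deg), incidence %g deg\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    length(x$angles), min(x$angles), max(x$angles), x$theta_in))
  invisible(x)
}

#' Read/write a spectra TSV grid
#'
#' Layout: first row holds the detection angles, first column the
#' wavelengths; the top-left cell holds the incident angle.
#'
#' @param path file path.
#' @param theta_in,specular_mask metadata for the constructed object (the
#'   incident angle defaults to the top-left cell).
#' @return a [spectra_matrix()].
#' @export
read_spectra_tsv <- function(path, theta_in = NULL, specular_mask = NULL) {
  d <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  angles <- as.numeric(d[1, -1])
  wl <- as.numeric(d[-1, 1])
  if (is.null(theta_in)) theta_in <- as.numeric(d[1, 1])
  spectra_matrix(wl, angles, d[-1, -1, drop = FALSE], theta_in = theta_in,
                 specular_mask = specular_mask)
}

#' @rdname read_spectra_tsv
#' @param x a [spectra_matrix()].
#' @export
write_spectra_tsv <- function(x, path) {
  grid <- rbind(c(x$theta_in, x$angles), cbind(x$wavelengths, x$intensity))
  write.table(grid, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Detect diffraction spots in an angle-resolved spectrum
#'
#' Per detection angle outside the specular mask, local intensity maxima
#' along the wavelength axis exceeding `prominence` times the median
#' intensity of the unmasked matrix are reported as spots.
#'
#' @param spectra a [spectra_matrix()].
#' @param prominence multiple of the median background an intensity maximum
#'   must exceed.
#' @return data.frame with `theta_out`, `lambda_peak`, `intensity`, `m`
#'   (order, NA until assigned by [fit_lattice_constant()]).
#' @export
detect_diffraction_spots <- function(spectra, prominence = 5) {
  ang <- spectra$angles
  masked <- if (!is.null(spectra$specular_mask))
    ang >= min(spectra$specular_mask) & ang <= max(spectra$specular_mask)
  else rep(FALSE, length(ang))
  bg <- median(spectra$intensity[, !masked, drop = FALSE])
  cutoff <- prominence * bg
  out <- list()
  for (ai in which(!masked)) {
    v <- spectra$intensity[, ai]
    n <- length(v)
    if (n < 3L) next
    loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    loc <- loc[v[loc] > cutoff]
    if (length(loc))
      out[[length(out) + 1L]] <- data.frame(
        theta_out = ang[ai], lambda_peak = spectra$wavelengths[loc],
        intensity = v[loc], m = NA_integer_)
  }
  if (!length(out))
    return(data.frame(theta_out = numeric(0), lambda_peak = numeric(0),
                      intensity = numeric(0), m = integer(0)))
  do.call(rbind, out)
}

#' Fit the grating equation to diffraction spots
#'
#' Least squares through the origin of `m * lambda` against
#' `sin(theta_in) + sin(theta_out)`: `d = sum(xy) / sum(x^2)`. With
#' several allowed orders, each spot is assigned the order minimizing its
#' residual (initialized from the median per-spot estimate, then refit).
#'
#' @param spots data.frame as from [detect_diffraction_spots()].
#' @param theta_in incident angle (degrees).
#' @param orders candidate diffraction orders (non-zero integers).
#' @return object of class `grating_fit`: `d` (nm), `residual_rms` (nm),
#'   `n_spots`, and the spots with assigned orders.
#' @export
fit_lattice_constant <- function(spots, theta_in = -45, orders = 1L) {
  if (nrow(spots) < 1L) stop("need at least one spot")
  if (any(orders == 0L)) stop("orders must be non-zero")
  x <- sin(.deg2rad(theta_in)) + sin(.deg2rad(spots$theta_out))
  usable <- abs(x) > 1e-9
  if (!any(usable)) stop("all spots at sin(theta_in) + sin(theta_out) = 0; d unidentifiable")
  m <- spots$m
  if (all(is.na(m))) {
    if (length(orders) == 1L) {
      m <- rep(orders, nrow(spots))
    } else {
      # initialize from the per-spot order whose implied d is closest to
      # the median implied d under order +/-1, then iterate assignment/fit
      m <- rep(orders[1], nrow(spots))
      cand_d <- outer(spots$lambda_peak * ifelse(usable, 1, NA) / x, 1 / orders)
      d0 <- median(abs(cand_d), na.rm = TRUE)
      for (it in 1:3) {
        resid <- abs(outer(spots$lambda_peak, rep(1, length(orders))) -
                       d0 * outer(x, 1 / orders))
        m <- orders[apply(resid, 1, which.min)]
        ok <- usable & sign(m * spots$lambda_peak) == sign(x)
        if (!any(ok)) ok <- usable
        d0 <- sum((m * spots$lambda_peak * x)[ok]) / sum(x[ok]^2)
      }
    }
  }
  y <- m * spots$lambda_peak
  d <- sum(y[usable] * x[usable]) / sum(x[usable]^2)
  if (d <= 0) stop("fitted lattice constant is not positive")
  resid <- (y - d * x) / m                 # residual in wavelength units
  structure(list(d = d,
                 residual_rms = sqrt(mean(resid[usable]^2)),
                 n_spots = sum(usable),
                 spots = transform(spots, m = m)),
            class = "grating_fit")
}

#' @export
print.grating_fit <- function(x, ...) {
  cat(sprintf("grating fit: d = %.1f nm (residual RMS %.2f nm, %d spots)\n",
              x$d, x$residual_rms, x$n_spots))
  invisible(x)
}

#' Predicted diffraction wavelength
#'
#' Inverse of the grating relation: `lambda = d * (sin theta_in +
#' sin theta_out) / m`; `NA` when the wavelength falls outside `(0, 2d]`
#' (no physical diffraction spot).
#'
#' @param d lattice constant (nm), > 0.
#' @param theta_in,theta_out angles in degrees.
#' @param m diffraction order (non-zero).
#' @return wavelength in nm, or `NA`.
#' @export
predict_spot_wavelength <- function(d, theta_in, theta_out, m = 1L) {
  if (d <= 0) stop("d must be > 0")
  if (m == 0L) stop("m must be non-zero")
  lam <- d * (sin(.deg2rad(theta_in)) + sin(.deg2rad(theta_out))) / m
  if (is.na(lam) || lam <= 0 || lam > 2 * d) return(NA_real_)
  lam
}
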