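#' Optical constants for the modified Beer-Lambert law
#'
#' Bundles the probe and chromophore constants needed to convert
#' optical-density changes into hemoglobin concentration changes: the two
#' wavelengths of the continuous-wave imager, their differential path-length
#' factors (DPF), the emitter-detector separation, and the 2x2 table of
#' extinction coefficients of oxy- (HbO) and deoxy-hemoglobin (HbR).
#'
#' The default extinction coefficients come from a standard published
#' compilation of hemoglobin spectra, converted to base-e absorption per
#' micromole per litre per centimetre, and are shipped as an editable CSV
#' (`system.file("extdata", "extinction_coefficients.csv", package =
#' "fnirsbluff")`).  All downstream conversions are algebraically invertible,
#' so analyses that only compare lie vs. truth are invariant to the exact
#' coefficient table.
#'
#' @param lambda_nm Two wavelengths in nanometres (default 640 and 910).
#' @param dpf Differential path-length factors for the two wavelengths
#'   (dimensionless; defaults 6.63 and 2.765, paired in wavelength order).
#' @param l_cm Emitter-detector distance in centimetres (default 3).
#' @param alpha 2x2 numeric matrix of extinction coefficients in
#'   (umol/L)^-1 cm^-1; rows = wavelengths, columns = `c("hbo", "hbr")`.
#'   Defaults to the shipped table looked up at `lambda_nm`.
#' @return An object of class `optical_constants`.
#' @examples
#' oc <- optical_constants()
#' build_system_matrix(oc)
#' @export
optical_constants <- function(lambda_nm = c(640, 910),
                              dpf = c(6.63, 2.765),
                              l_cm = 3,
                              alpha = NULL) {
  stopifnot(length(lambda_nm) == 2, length(dpf) == 2, length(l_cm) == 1)
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop_cfg("wavelengths must be positive and finite")
  }
  if (any(dpf <= 0) || l_cm <= 0) stop_cfg("dpf and l_cm must be positive")
  if (is.null(alpha)) alpha <- default_extinction(lambda_nm)
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(2, 2))) stop_cfg("alpha must be a 2x2 matrix")
  if (any(alpha <= 0)) stop_cfg("extinction coefficients must be positive")
  colnames(alpha) <- c("hbo", "hbr")
  rownames(alpha) <- paste0("lambda", 1:2)
  out <- structure(
    list(lambda_nm = lambda_nm, dpf = dpf, l_cm = l_cm, alpha = alpha),
    class = "optical_constants"
  )
  a <- build_system_matrix(out)  # validates nonsingularity
  invisible(a)
  out
}

#' Read an extinction-coefficient table and look up two wavelengths
#'
#' @param lambda_nm Wavelengths (nm) to look up; must be present in the table.
#' @param path CSV with columns `lambda_nm, alpha_hbo, alpha_hbr` in
#'   (umol/L)^-1 cm^-1 (base e).  Defaults to the table shipped with the
#'   package.
#' @return 2x2 matrix, rows = wavelengths, columns = `c("hbo","hbr")`.
#' @export
default_extinction <- function(lambda_nm = c(640, 910), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "fnirsbluff")
  }
  tab <- utils::read.csv(path)
  idx <- match(lambda_nm, tab$lambda_nm)
  if (anyNA(idx)) {
    stop_cfg("wavelength(s) %s not in extinction table %s",
             paste(lambda_nm[is.na(idx)], collapse = ", "), path)
  }
  m <- as.matrix(tab[idx, c("alpha_hbo", "alpha_hbr")])
  dimnames(m) <- list(paste0("lambda", 1:2), c("hbo", "hbr"))
  m
}

#' Build the 2x2 modified Beer-Lambert system matrix
#'
#' Row i of the matrix maps `(dHbO, dHbR)` (umol/L) to the optical-density
#' change at wavelength i: `A[i, ] = l * dpf[i] * (alpha_HbO^i, alpha_HbR^i)`.
#' Inverting this system per sample is the concentration conversion.
#'
#' @param constants An [optical_constants()] object.
#' @return 2x2 numeric matrix.
#' @export
build_system_matrix <- function(constants) {
  stopifnot(inherits(constants, "optical_constants"))
  a <- constants$l_cm * constants$dpf * constants$alpha
  if (abs(det(a)) <= 1e-12) {
    stop_cfg("modified Beer-Lambert system matrix is singular (det = %g); %s",
             det(a), "extinction rows must not be proportional")
  }
  a
}
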