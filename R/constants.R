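#' Physical constants
#'
#' Bundle of the Faraday constant, gas constant and absolute temperature used
#' throughout the electrodiffusive formulas. CODATA values are used for `F`
#' and `R`; the default temperature is the model's 309.15 K (36 C).
#'
#' @param temperature_K absolute temperature in kelvin (> 0).
#' @return an object of class `phys_constants` with fields `F` (C/mol),
#'   `R` (J/(mol K)), `T` (K) and the derived `RT` (J/mol) and `RT_over_F`
#'   expressed in mV.
#' @examples
#' k <- phys_constants()
#' k$RT_over_F_mV  # ~26.64 mV at 309.15 K
#' @export
phys_constants <- function(temperature_K = 309.15) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  Fd <- 96485.33   # C/mol
  Rg <- 8.314      # J/(mol K)
  structure(list(F = Fd, R = Rg, T = temperature_K,
                 RT = Rg * temperature_K,
                 RT_over_F_mV = 1000 * Rg * temperature_K / Fd),
            class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat(sprintf("Physical constants: F = %.2f C/mol, R = %.3f J/(mol K), T = %.2f K\n",
              x$F, x$R, x$T))
  cat(sprintf("  RT/F = %.4f mV\n", x$RT_over_F_mV))
  invisible(x)
}

# Unit conversions fixed at the public/internal boundary:
# internal SI (V, mol/m^3 == mM, A/m^2, S/m^2); public mV, mM, uA/cm^2, mS/cm^2.
A_per_m2_to_uA_per_cm2 <- function(x) 100 * x
S_per_m2_to_mS_per_cm2 <- function(x) 0.1 * x
mV_to_V <- function(x) x / 1000

# g(x) = -expm1(-x)/x = (1 - exp(-x))/x, the entire function with g(0) = 1.
# Every removable singularity in the GHK family reduces to ratios of g.
.gfun <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 6
  out[!small] <- -expm1(-x[!small]) / x[!small]
  out
}
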