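#' Tissue parameters governing ventricular conductivity
#'
#' The conductivity of the ventricular tissue is controlled by three
#' parameters: the cell radius `R` (um), quantifying cellular hypertrophy; the
#' extracellular volume fraction `ECV` (0-1), the imaging-derived volume of
#' the extracellular space; and the extracellular conductivity factor `ECF`
#' (0-1), which scales the conductivity of the extracellular space from 0 (not
#' altered) down to fully non-conductive at 1 and serves as a proxy for
#' diffuse fibrotic content.
#'
#' @param r_um cell radius in micrometres. During personalization the radius
#'   is constrained to `r_bounds_um()` (9.6-17.8 um, the range observed
#'   histologically in aortic-stenosis patients); outside that range a warning
#'   is raised unless `strict = FALSE`.
#' @param ecv extracellular volume fraction in (0, 1).
#' @param ecf extracellular conductivity factor in \[0, 1\].
#' @param strict warn when `r_um` is outside the personalization bounds.
#' @return an object of class `tissue_parameters`.
#' @examples
#' tissue_parameters()                    # reference state
#' tissue_parameters(12.0, 0.30, 0.05)
#' @export
tissue_parameters <- function(r_um = 15.45, ecv = 0.258, ecf = 0,
                              strict = TRUE) {
  stopifnot(is.numeric(r_um), length(r_um) == 1L, is.finite(r_um), r_um > 0,
            is.numeric(ecv), length(ecv) == 1L, ecv > 0, ecv < 1,
            is.numeric(ecf), length(ecf) == 1L, ecf >= 0, ecf <= 1)
  if (strict && (r_um < r_bounds_um()[1] - 1e-9 ||
                 r_um > r_bounds_um()[2] + 1e-9))
    warning(sprintf("cell radius %.2f um outside the personalization range [%g, %g] um",
                    r_um, r_bounds_um()[1], r_bounds_um()[2]))
  structure(list(r_um = r_um, ecv = ecv, ecf = ecf),
            class = "tissue_parameters")
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat(sprintf("Tissue parameters: R = %.2f um, ECV = %.1f%%, ECF = %.0f%%\n",
              x$r_um, 100 * x$ecv, 100 * x$ecf))
  invisible(x)
}

#' Admissible cell-radius range for personalization (um)
#'
#' Mean cell radius observed in aortic-stenosis patients plus/minus one
#' standard deviation (9.6-17.8 um).
#' @return numeric length-2 vector.
#' @export
r_bounds_um <- function() c(9.6, 17.8)

#' Baseline conductivities and reference tissue state
#'
#' Reads the versioned parameter file holding per-axis intracellular and
#' extracellular conductivities (S/m), the membrane capacitance per unit area
#' (uF/cm^2) and the reference `(R, ECV)` used to normalize the tissue
#' parametrization. With the default file, the reference tissue state
#' `R = 15.45 um, ECV = 25.8%, ECF = 0` reproduces the baseline monodomain
#' conductivities exactly.
#'
#' @param file YAML file; defaults to the parameter file shipped with the
#'   package.
#' @return object of class `baseline_conductivities`.
#' @export
baseline_conductivities <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "baseline_conductivities.yaml",
                        package = "cardiotwin", mustWork = TRUE)
  raw <- yaml::read_yaml(file)
  need <- c("sigma_i", "sigma_e", "cm_uF_cm2", "ecv_ref", "r_ref_um")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("baseline conductivity file missing fields: ",
         paste(missing, collapse = ", "))
  ax <- c("fiber", "transverse", "normal")
  out <- list(
    sigma_i = unlist(raw$sigma_i)[ax],
    sigma_e = unlist(raw$sigma_e)[ax],
    cm_uF_cm2 = raw$cm_uF_cm2,
    ecv_ref = raw$ecv_ref,
    r_ref_um = raw$r_ref_um)
  if (any(!is.finite(out$sigma_i)) || any(!is.finite(out$sigma_e)) ||
      any(out$sigma_i <= 0) || any(out$sigma_e <= 0))
    stop("baseline conductivities must be positive for all three axes")
  structure(out, class = "baseline_conductivities")
}

#' Map tissue parameters to monodomain conductivity and diffusivity
#'
#' Implements the tissue parametrization at the heart of the personalization
#' method. Per axis a (fiber, transverse, sheet-normal):
#' \deqn{\sigma_e^{eff} = \sigma_{e,0}\,(ECV/ECV_{ref})\,(1 - ECF), \quad
#'       \sigma_i^{eff} = \sigma_{i,0},}
#' \deqn{\sigma_{mono} = \frac{\sigma_i^{eff}\sigma_e^{eff}}
#'                            {\sigma_i^{eff}+\sigma_e^{eff}},}
#' with surface-to-volume ratio \eqn{\beta = 2/R} for cylindrical myocytes and
#' diffusivity \eqn{D = \sigma_{mono} / (\beta C_m)}. A larger cell radius
#' therefore accelerates conduction (scaling D linearly in R), a larger ECV
#' raises extracellular conductivity, and ECF depresses it; at `ECF = 1` the
#' extracellular space is non-conductive and the tissue does not propagate
#' (returned with `propagating = FALSE`, not an error).
#'
#' @param params [tissue_parameters()].
#' @param baseline [baseline_conductivities()].
#' @return object of class `monodomain_conductivity` with elements
#'   `sigma_mono_S_m` (per axis), `beta_per_cm`, `diffusivity_cm2_ms` (per
#'   axis) and `propagating`.
#' @examples
#' effective_conductivity(tissue_parameters(), baseline_conductivities())
#' @export
effective_conductivity <- function(params, baseline = baseline_conductivities()) {
  stopifnot(inherits(params, "tissue_parameters"),
            inherits(baseline, "baseline_conductivities"))
  sig_e <- baseline$sigma_e * (params$ecv / baseline$ecv_ref) * (1 - params$ecf)
  sig_i <- baseline$sigma_i
  denom <- sig_i + sig_e
  sig_mono <- ifelse(denom > 0, sig_i * sig_e / denom, 0)
  r_cm <- params$r_um * 1e-4
  beta <- 2 / r_cm                                   # 1/cm
  # sigma [S/m] -> [S/cm] is /100; D = sigma/(beta*Cm) with Cm in F/cm^2
  d_cm2_s <- (sig_mono / 100) / (beta * baseline$cm_uF_cm2 * 1e-6)
  structure(list(
    sigma_mono_S_m = sig_mono,
    sigma_e_eff_S_m = sig_e,
    sigma_i_eff_S_m = sig_i,
    beta_per_cm = beta,
    diffusivity_cm2_ms = d_cm2_s / 1000,
    propagating = all(sig_mono > 0)),
    class = "monodomain_conductivity")
}

#' @export
print.monodomain_conductivity <- function(x, ...) {
  cat("Monodomain conductivity (S/m):",
      paste(sprintf("%s=%.4f", names(x$sigma_mono_S_m), x$sigma_mono_S_m),
            collapse = ", "), "\n")
  cat(sprintf("beta = %.1f 1/cm; D (cm^2/ms): %s; propagating: %s\n",
              x$beta_per_cm,
              paste(sprintf("%.3e", x$diffusivity_cm2_ms), collapse = ", "),
              x$propagating))
  invisible(x)
}
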