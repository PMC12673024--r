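#' Fit settings for tissue-parameter personalization
#'
#' @param r_tol_um bisection tolerance of the cell-radius search (um).
#' @param ecf_step ECF grid step (default 0.05, i.e. 5% increments).
#' @param r_bounds_um admissible cell-radius range (um).
#' @param engine QRS evaluation engine: `"eikonal"` (calibrated, default) or
#'   `"monodomain"` (reference; requires a fine mesh).
#' @param calib_h_cm strand spacing for CV calibration.
#' @return a `fit_settings` object.
#' @export
fit_settings <- function(r_tol_um = 0.05, ecf_step = 0.05,
                         r_bounds_um = cardiotwin::r_bounds_um(),
                         engine = c("eikonal", "monodomain"),
                         calib_h_cm = 0.01) {
  engine <- match.arg(engine)
  stopifnot(r_tol_um > 0, ecf_step > 0, ecf_step <= 1,
            length(r_bounds_um) == 2L, diff(r_bounds_um) > 0)
  structure(list(r_tol_um = r_tol_um, ecf_step = ecf_step,
                 r_bounds_um = r_bounds_um, engine = engine,
                 calib_h_cm = calib_h_cm), class = "fit_settings")
}

#' Assemble a digital twin model
#'
#' Bundles a biventricular mesh with its ventricular coordinates, rule-based
#' fibers, stimulation landmarks and baseline conductivities into the model
#' object consumed by the forward QRS evaluation and the personalization
#' routines.
#'
#' @param mesh a `bv_mesh`; fibers are (re)assigned from the Laplace frame.
#' @param baseline [baseline_conductivities()].
#' @param eas_spec optional EAS table forwarded to [place_landmarks()].
#' @param settings [fit_settings()].
#' @return a `twin_model`.
#' @export
build_twin <- function(mesh, baseline = baseline_conductivities(),
                       eas_spec = NULL, settings = fit_settings()) {
  coords <- compute_ventricular_coordinates(mesh)
  mesh <- assign_fibers(mesh, coords)
  landmarks <- place_landmarks(mesh, coords, eas_spec = eas_spec)
  id <- sprintf("twin%06d", local({
    cnt <- get0("twin_counter", envir = .ct_env, ifnotfound = 0L) + 1L
    assign("twin_counter", cnt, envir = .ct_env)
    cnt
  }))
  structure(list(id = id, mesh = mesh, coords = coords,
                 landmarks = landmarks, baseline = baseline,
                 settings = settings),
            class = "twin_model")
}

#' @export
print.twin_model <- function(x, ...) {
  cat(sprintf("Digital twin %s (%d nodes, %d elements, engine %s)\n", x$id,
              nrow(x$mesh$nodes), nrow(x$mesh$elems), x$settings$engine))
  invisible(x)
}

#' Model QRS duration for a tissue parameter set
#'
#' Forward evaluation: map the tissue parameters to per-axis conduction
#' velocities (strand calibration), activate the ventricles from the five
#' early activation sites, and report the total activation time as the
#' model's QRS duration.
#'
#' @param model a [build_twin()] model.
#' @param params [tissue_parameters()].
#' @param pacing `"eas"` (physiological five-site pacing) or `"rv_apex"`.
#' @return QRS surrogate in ms (attribute `map` carries the activation map).
#' @export
model_qrs <- function(model, params, pacing = c("eas", "rv_apex")) {
  pacing <- match.arg(pacing)
  key <- sprintf("qrs|%s|%s|%.6f|%.6f|%.6f|%s|%.5f", model$id, pacing,
                 params$r_um, params$ecv, params$ecf, model$settings$engine,
                 model$settings$calib_h_cm)
  hit <- .ct_env[[key]]
  if (!is.null(hit)) return(hit)
  map <- .activate(model, params, pacing)
  out <- total_activation_time(map)
  attr(out, "map") <- map
  .ct_env[[key]] <- out
  out
}

.twin_sites <- function(model, pacing) {
  if (pacing == "eas") {
    lapply(model$landmarks$eas, function(s)
      list(center = s$center, onset_ms = s$onset_ms))
  } else {
    list(list(center = model$landmarks$rv_apex$center, onset_ms = 0))
  }
}

# Normalized eikonal map: solved once per (model, pacing, ECV, ECF) at unit
# fiber speed with the anisotropy ratio calibrated at the reference radius.
# Because R rescales the fiber and cross-fiber diffusivities by the same
# factor, activation times scale as 1/CV_fiber(R) while the activation order
# is R-invariant (the residual drift of the calibrated anisotropy ratio
# across the admissible radius range is well below 1%; see the methods
# vignette), so radius sweeps reuse one solve.
.norm_map <- function(model, pacing, ecv, ecf) {
  key <- sprintf("norm|%s|%s|%.6f|%.6f|%.5f", model$id, pacing, ecv, ecf,
                 model$settings$calib_h_cm)
  hit <- .ct_env[[key]]
  if (!is.null(hit)) return(hit)
  ref <- tissue_parameters(model$baseline$r_ref_um, ecv, ecf, strict = FALSE)
  vf <- as.numeric(calibrate_cv(ref, model$baseline, "fiber",
                                h_cm = model$settings$calib_h_cm))
  vt <- as.numeric(calibrate_cv(ref, model$baseline, "transverse",
                                h_cm = model$settings$calib_h_cm))
  if (vf <= 0 || vt <= 0)
    stop("tissue parameters give non-propagating tissue (zero CV)")
  sites <- .twin_sites(model, pacing)
  if (any(vapply(sites, function(s) s$onset_ms, numeric(1)) != 0))
    stop("normalized maps require simultaneous (onset 0) sites")
  # unit fiber speed (1 mm/ms), calibrated anisotropy ratio
  map <- run_eikonal(model$mesh, list(fiber = 100, transverse = 100 * vt / vf),
                     sites)
  .ct_env[[key]] <- map
  map
}

.activate <- function(model, params, pacing = "eas") {
  if (model$settings$engine == "eikonal") {
    nm <- .norm_map(model, pacing, params$ecv, params$ecf)
    vf <- as.numeric(calibrate_cv(params, model$baseline, "fiber",
                                  h_cm = model$settings$calib_h_cm))
    if (vf <= 0)
      stop("tissue parameters give non-propagating tissue (zero CV)")
    structure(nm / (vf / 100), onsets_ms = attr(nm, "onsets_ms"),
              class = "activation_map")
  } else {
    cond <- effective_conductivity(params, model$baseline)
    nodes <- sort(unique(unlist(lapply(
      if (pacing == "eas") model$landmarks$eas else list(model$landmarks$rv_apex),
      function(s) s$nodes))))
    run_monodomain(model$mesh, cond, sites = nodes)
  }
}

#' Relative change in cell radius from wall thickness and ECV
#'
#' The pre-to-post ratio of the cell radius implied by conservation of the
#' myocyte population: total myocyte volume is proportional to wall thickness
#' times (1 - ECV), and with an unchanged number and length of cylindrical
#' cells the radius scales with its square root:
#' \deqn{\rho = \sqrt{\frac{WT_{post}(1-ECV_{post})}{WT_{pre}(1-ECV_{pre})}}.}
#'
#' @param wt_pre,wt_post LV-average wall thickness (mm).
#' @param ecv_pre,ecv_post extracellular volume fraction in (0, 1).
#' @return the radius ratio rho (dimensionless).
#' @examples
#' relative_radius_change(11.6, 9.5, 0.242, 0.280)  # ~0.882
#' @export
relative_radius_change <- function(wt_pre, wt_post, ecv_pre, ecv_post) {
  if (any(c(wt_pre, wt_post) <= 0)) stop("wall thickness must be positive")
  if (any(c(ecv_pre, ecv_post) <= 0) || any(c(ecv_pre, ecv_post) >= 1))
    stop("ECV must lie strictly inside (0, 1)")
  sqrt((wt_post * (1 - ecv_post)) / (wt_pre * (1 - ecv_pre)))
}

#' Fit the cell radius under the pre/post ratio constraint
#'
#' First step of the personalization: find the smallest cell radius R_pre
#' such that both the pre- and the post-intervention model produce a QRS
#' duration no longer than their respective targets, with the post radius
#' tied to the pre radius by `R_post = rho * R_pre`. The QRS duration is
#' strictly decreasing in R, so the feasible set is an interval ending at the
#' upper bound and bisection applies. When even the largest admissible radius
#' leaves a model too slow, the upper bound is returned with a flag (the ECF
#' stage is then skipped for that model).
#'
#' @param model_pre,model_post [build_twin()] models.
#' @param qrs_target_pre,qrs_target_post patient QRS durations (ms).
#' @param rho radius ratio from [relative_radius_change()].
#' @param ecv_pre,ecv_post patient ECV (fractions) entering the conductivity.
#' @param settings [fit_settings()].
#' @return list with `r_pre_um`, `r_post_um`, `at_upper`, `at_lower`,
#'   `r_post_out_of_bounds`, and the model QRS at the fit.
#' @export
fit_radius <- function(model_pre, model_post, qrs_target_pre, qrs_target_post,
                       rho, ecv_pre, ecv_post, settings = fit_settings()) {
  stopifnot(rho > 0, qrs_target_pre > 0, qrs_target_post > 0)
  lo_b <- settings$r_bounds_um[1]; hi_b <- settings$r_bounds_um[2]
  # keep both radii inside the admissible range where possible
  lo <- max(lo_b, lo_b / rho); hi <- min(hi_b, hi_b / rho)
  if (lo >= hi) stop("radius ratio leaves no admissible radius window")
  feasible <- function(r) {
    q1 <- model_qrs(model_pre, tissue_parameters(r, ecv_pre, 0, strict = FALSE))
    q2 <- model_qrs(model_post,
                    tissue_parameters(rho * r, ecv_post, 0, strict = FALSE))
    q1 <= qrs_target_pre + 1e-9 && q2 <= qrs_target_post + 1e-9
  }
  at_upper <- FALSE; at_lower <- FALSE
  if (!feasible(hi)) {
    r <- hi; at_upper <- TRUE
  } else if (feasible(lo)) {
    r <- lo; at_lower <- TRUE
  } else {
    a <- lo; b <- hi  # a infeasible, b feasible
    while (b - a > settings$r_tol_um) {
      mid <- (a + b) / 2
      if (feasible(mid)) b <- mid else a <- mid
    }
    r <- b
  }
  qrs_pre <- model_qrs(model_pre, tissue_parameters(r, ecv_pre, 0, strict = FALSE))
  qrs_post <- model_qrs(model_post,
                        tissue_parameters(rho * r, ecv_post, 0, strict = FALSE))
  list(r_pre_um = r, r_post_um = rho * r, at_upper = at_upper,
       at_lower = at_lower,
       r_post_out_of_bounds = rho * r < lo_b - 1e-9 | rho * r > hi_b + 1e-9,
       qrs_pre_ms = as.numeric(qrs_pre), qrs_post_ms = as.numeric(qrs_post))
}

#' Fit the extracellular conductivity factor
#'
#' Second step of the personalization: with the cell radius fixed, increase
#' ECF on the 5% grid to minimize the absolute difference between the model
#' and the patient QRS duration. QRS is non-decreasing in ECF, so the walk
#' stops at the first step that no longer improves; ties break towards the
#' smaller ECF. If the model QRS already exceeds the target at ECF = 0 the
#' step is skipped by contract (`ecf = 0` with the residual reported).
#'
#' @param model a [build_twin()] model.
#' @param r_um fitted cell radius (um).
#' @param qrs_target_ms patient QRS duration (ms).
#' @param ecv patient ECV (fraction).
#' @param settings [fit_settings()].
#' @return list with `ecf`, `qrs_ms`, `error_ms` (model - target), and
#'   `skipped` (TRUE when QRS(ECF = 0) was already above the target).
#' @export
fit_ecf <- function(model, r_um, qrs_target_ms, ecv,
                    settings = fit_settings()) {
  qrs_of <- function(ecf)
    as.numeric(model_qrs(model,
                         tissue_parameters(r_um, ecv, ecf, strict = FALSE)))
  q0 <- qrs_of(0)
  if (q0 > qrs_target_ms + 1e-9)
    return(list(ecf = 0, qrs_ms = q0, error_ms = q0 - qrs_target_ms,
                skipped = TRUE))
  best_ecf <- 0; best_q <- q0
  grid <- seq(settings$ecf_step, 1, by = settings$ecf_step)
  for (ecf in grid) {
    if (ecf > 1 - 1e-9) break  # ECF = 1 is non-propagating
    q <- qrs_of(ecf)
    if (abs(q - qrs_target_ms) < abs(best_q - qrs_target_ms) - 1e-12) {
      best_ecf <- ecf; best_q <- q
    } else break  # QRS(ECF) is monotone; first worsening step ends the walk
  }
  list(ecf = best_ecf, qrs_ms = best_q, error_ms = best_q - qrs_target_ms,
       skipped = FALSE)
}

#' Personalize a pre/post patient pair
#'
#' Full two-step personalization for one patient: the radius ratio is
#' computed from the pre/post wall thicknesses and ECVs, the shortest
#' admissible radius satisfying both QRS targets is found under the ratio
#' constraint, ECF is fitted per timepoint on the 5% grid, and finally the
#' septal conduction velocity is measured in each personalized model during
#' simulated RV apical pacing.
#'
#' @param record_pre,record_post patient records: lists/rows with fields
#'   `qrs_ms`, `ecv`, `wt_mm` (QRS must satisfy the <= 110 ms inclusion
#'   criterion).
#' @param model_pre,model_post [build_twin()] models of the two timepoints.
#' @param settings [fit_settings()].
#' @return a `personalization_result`.
#' @export
personalize_pair <- function(record_pre, record_post, model_pre, model_post,
                             settings = fit_settings()) {
  for (rec in list(record_pre, record_post)) {
    if (!all(c("qrs_ms", "ecv", "wt_mm") %in% names(rec)))
      stop("patient records need fields qrs_ms, ecv, wt_mm")
    if (rec$qrs_ms > 110)
      stop("QRS duration > 110 ms violates the inclusion criterion (physiological depolarization cannot be assumed)")
  }
  rho <- relative_radius_change(record_pre$wt_mm, record_post$wt_mm,
                                record_pre$ecv, record_post$ecv)
  fr <- fit_radius(model_pre, model_post, record_pre$qrs_ms,
                   record_post$qrs_ms, rho, record_pre$ecv, record_post$ecv,
                   settings)
  fe_pre <- if (fr$at_upper && fr$qrs_pre_ms > record_pre$qrs_ms) {
    list(ecf = 0, qrs_ms = fr$qrs_pre_ms,
         error_ms = fr$qrs_pre_ms - record_pre$qrs_ms, skipped = TRUE)
  } else fit_ecf(model_pre, fr$r_pre_um, record_pre$qrs_ms, record_pre$ecv,
                 settings)
  fe_post <- if (fr$at_upper && fr$qrs_post_ms > record_post$qrs_ms) {
    list(ecf = 0, qrs_ms = fr$qrs_post_ms,
         error_ms = fr$qrs_post_ms - record_post$qrs_ms, skipped = TRUE)
  } else fit_ecf(model_post, fr$r_post_um, record_post$qrs_ms,
                 record_post$ecv, settings)

  cv_of <- function(model, r, ecf, ecv) {
    map <- .activate(model, tissue_parameters(r, ecv, ecf, strict = FALSE),
                     pacing = "rv_apex")
    measure_cv(map, model$landmarks)
  }
  cv_pre <- cv_of(model_pre, fr$r_pre_um, fe_pre$ecf, record_pre$ecv)
  cv_post <- cv_of(model_post, fr$r_post_um, fe_post$ecf, record_post$ecv)

  structure(list(
    rho = rho, r_pre_um = fr$r_pre_um, r_post_um = fr$r_post_um,
    ecf_pre = fe_pre$ecf, ecf_post = fe_post$ecf,
    qrs_model_pre_ms = fe_pre$qrs_ms, qrs_model_post_ms = fe_post$qrs_ms,
    qrs_error_pre_ms = fe_pre$error_ms, qrs_error_post_ms = fe_post$error_ms,
    cv_pre_cm_s = cv_pre$cv_cm_s, cv_post_cm_s = cv_post$cv_cm_s,
    flags = list(r_at_upper = fr$at_upper, r_at_lower = fr$at_lower,
                 r_post_out_of_bounds = fr$r_post_out_of_bounds,
                 ecf_pre_skipped = fe_pre$skipped,
                 ecf_post_skipped = fe_post$skipped),
    provenance = list(settings = unclass(settings),
                      settings_hash = rlang::hash(unclass(settings)),
                      engine = settings$engine,
                      model_pre = model_pre$id, model_post = model_post$id)),
    class = "personalization_result")
}

#' @export
print.personalization_result <- function(x, ...) {
  cat(sprintf("Personalization: rho = %.4f\n", x$rho))
  cat(sprintf("  R    pre %.2f um  post %.2f um\n", x$r_pre_um, x$r_post_um))
  cat(sprintf("  ECF  pre %.0f%%      post %.0f%%\n",
              100 * x$ecf_pre, 100 * x$ecf_post))
  cat(sprintf("  QRS  pre %.1f ms (err %+.2f)  post %.1f ms (err %+.2f)\n",
              x$qrs_model_pre_ms, x$qrs_error_pre_ms, x$qrs_model_post_ms,
              x$qrs_error_post_ms))
  cat(sprintf("  CV   pre %.1f cm/s  post %.1f cm/s\n",
              x$cv_pre_cm_s, x$cv_post_cm_s))
  fl <- x$flags[unlist(x$flags)]
  if (length(fl)) cat("  flags:", paste(names(fl), collapse = ", "), "\n")
  invisible(x)
}
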