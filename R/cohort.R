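#' Specification of a synthetic pre/post-AVR cohort
#'
#' Distributional defaults emulate the paired structure of a small surgical
#' aortic-valve-replacement cohort: ECV rising by about 4 percentage points
#' after surgery, wall thickness shrinking (more strongly in females than in
#' males), QRS essentially unchanged, and cell radii inside the histological
#' range. All continuous quantities are truncated normals (sampled by
#' inversion, so generation never fails); the true ECF lives on the 5% grid.
#'
#' Ground-truth tissue parameters are drawn in the canonical identifiable
#' form of the two-step inverse method: one timepoint (drawn at random) is
#' the "binding" one and carries ECF = 0, the other draws a positive ECF.
#' See the methods vignette for why recovery is only well-posed on this
#' manifold.
#'
#' @param n number of patients.
#' @param prop_female fraction of female patients.
#' @param wt_pre_mm named list `female`/`male` of c(mean, sd) for
#'   pre-surgical LV-average wall thickness (mm).
#' @param wt_reduction named list `female`/`male` of c(mean, sd) for the
#'   relative wall-thickness reduction.
#' @param ecv_pre,ecv_delta c(mean, sd) of the pre ECV fraction and of the
#'   post-pre ECV increase.
#' @param r_pre_um c(mean, sd) of the true pre cell radius (um).
#' @param ecf_values,ecf_probs distribution of the true ECF on the 5% grid
#'   (applied to the non-binding timepoint).
#' @param qrs_noise_sd_ms measurement noise added to the forward-model QRS
#'   (0 by default: targets are exact model outputs).
#' @param lv_volume_ml,bsa_m2 c(mean, sd) for LV volume and (per sex) body
#'   surface area.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n = 12,
                        prop_female = 0.5,
                        wt_pre_mm = list(female = c(10.3, 0.8),
                                         male = c(12.7, 1.2)),
                        wt_reduction = list(female = c(0.21, 0.05),
                                            male = c(0.08, 0.04)),
                        ecv_pre = c(0.242, 0.030),
                        ecv_delta = c(0.040, 0.015),
                        r_pre_um = c(14.0, 1.8),
                        ecf_values = c(0, 0.05, 0.10, 0.15),
                        ecf_probs = c(0.50, 0.25, 0.15, 0.10),
                        qrs_noise_sd_ms = 0,
                        lv_volume_ml = c(115, 20),
                        bsa_m2 = list(female = c(1.75, 0.12),
                                      male = c(2.00, 0.15))) {
  stopifnot(n >= 1, prop_female >= 0, prop_female <= 1,
            length(ecf_values) == length(ecf_probs),
            all(abs(ecf_values / 0.05 - round(ecf_values / 0.05)) < 1e-9),
            qrs_noise_sd_ms >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# truncated normal by inversion (deterministic given the RNG stream)
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic paired cohort with ground truth
#'
#' Draws patient characteristics from [cohort_spec()], builds a digital twin
#' for each patient and timepoint (wall thickness personalizes the mesh), and
#' produces the "patient" QRS durations by running the forward model at the
#' true tissue parameters (plus optional measurement noise). The ground-truth
#' radius ratio is computed with [relative_radius_change()] from the
#' generated wall thicknesses and ECVs, so the generator's myocyte-volume
#' bookkeeping and the inverse method's constraint close exactly.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bit-for-bit.
#' @param geometry named list of [build_idealized_biventricle()] arguments
#'   shared by all patients (the per-patient wall thickness is filled in).
#' @param settings [fit_settings()] used for the forward QRS engine.
#' @param build_models build the twin models (needed for QRS targets and for
#'   downstream personalization). With `FALSE` only the tabular draws are
#'   returned and QRS columns are `NA` (useful for distribution-level tests).
#' @return a `synthetic_cohort`: list with `records` (one row per patient and
#'   timepoint), `truth` (per patient), `models` (named list, or NULL).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            geometry = list(), settings = fit_settings(),
                            build_models = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n
  n_f <- round(spec$prop_female * n)
  sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  geo <- modifyList(list(lv_radius = 18, lv_length = 36, rv_wall = 3.5,
                         rv_gap = 5, edge_length = 3.0), geometry)

  p2 <- function(par) c(par[1], par[2])
  wt_pre <- ecv_pre <- ecv_post <- wt_post <- bsa <- numeric(n)
  for (s in c("female", "male")) {
    sel <- sex == s
    if (!any(sel)) next
    pw <- p2(spec$wt_pre_mm[[s]])
    wt_pre[sel] <- .rtnorm(sum(sel), pw[1], pw[2], 8.5, 15.5)
    pb <- p2(spec$bsa_m2[[s]])
    bsa[sel] <- .rtnorm(sum(sel), pb[1], pb[2], 1.4, 2.4)
  }
  ecv_pre <- .rtnorm(n, spec$ecv_pre[1], spec$ecv_pre[2], 0.16, 0.34)
  dec <- .rtnorm(n, spec$ecv_delta[1], spec$ecv_delta[2], -0.02, 0.10)
  ecv_post <- pmin(0.42, ecv_pre + dec)
  for (i in seq_len(n)) {
    pr <- p2(spec$wt_reduction[[sex[i]]])
    red_hi <- min(0.35, 1 - (2.3 * geo$edge_length) / wt_pre[i])
    red <- .rtnorm(1, pr[1], pr[2], 0, red_hi)
    wt_post[i] <- wt_pre[i] * (1 - red)
  }
  rho <- mapply(relative_radius_change, wt_pre, wt_post, ecv_pre, ecv_post)
  rb <- r_bounds_um()
  r_lo <- pmax(rb[1], rb[1] / rho) + 0.15
  r_hi <- pmin(rb[2], rb[2] / rho) - 0.15
  r_pre <- mapply(function(lo, hi) .rtnorm(1, spec$r_pre_um[1],
                                           spec$r_pre_um[2], lo, hi),
                  r_lo, r_hi)
  r_post <- rho * r_pre
  binding <- sample(c("pre", "post"), n, replace = TRUE)
  ecf_extra <- sample(spec$ecf_values, n, replace = TRUE, prob = spec$ecf_probs)
  ecf_pre <- ifelse(binding == "pre", 0, ecf_extra)
  ecf_post <- ifelse(binding == "post", 0, ecf_extra)
  lv_vol_pre <- .rtnorm(n, spec$lv_volume_ml[1], spec$lv_volume_ml[2], 80, 180)
  lv_vol_post <- lv_vol_pre * wt_post / wt_pre
  noise <- matrix(rnorm(2 * n, 0, spec$qrs_noise_sd_ms), n, 2)

  models <- NULL
  qrs_pre <- qrs_post <- qrs_model_pre <- qrs_model_post <- rep(NA_real_, n)
  if (build_models) {
    models <- vector("list", 2L * n)
    names(models) <- paste0("p", rep(seq_len(n), each = 2), "_",
                            rep(c("pre", "post"), n))
    for (i in seq_len(n)) {
      for (tp in c("pre", "post")) {
        wt <- if (tp == "pre") wt_pre[i] else wt_post[i]
        mesh <- do.call(build_idealized_biventricle,
                        modifyList(geo, list(lv_wall = wt)))
        models[[paste0("p", i, "_", tp)]] <-
          build_twin(mesh, settings = settings)
      }
      tq_pre <- as.numeric(model_qrs(models[[paste0("p", i, "_pre")]],
        tissue_parameters(r_pre[i], ecv_pre[i], ecf_pre[i], strict = FALSE)))
      tq_post <- as.numeric(model_qrs(models[[paste0("p", i, "_post")]],
        tissue_parameters(r_post[i], ecv_post[i], ecf_post[i], strict = FALSE)))
      qrs_model_pre[i] <- tq_pre; qrs_model_post[i] <- tq_post
      qrs_pre[i] <- min(110, tq_pre + noise[i, 1])
      qrs_post[i] <- min(110, tq_post + noise[i, 2])
    }
  }

  records <- data.frame(
    patient_id = rep(seq_len(n), each = 2),
    sex = rep(sex, each = 2),
    timepoint = rep(c("pre", "post"), n),
    qrs_ms = as.vector(rbind(qrs_pre, qrs_post)),
    ecv = as.vector(rbind(ecv_pre, ecv_post)),
    wt_mm = as.vector(rbind(wt_pre, wt_post)),
    lv_volume_ml = as.vector(rbind(lv_vol_pre, lv_vol_post)),
    bsa_m2 = rep(bsa, each = 2),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    patient_id = seq_len(n), sex = sex, rho = rho,
    r_pre_um = r_pre, r_post_um = r_post,
    ecf_pre = ecf_pre, ecf_post = ecf_post, binding = binding,
    qrs_model_pre_ms = qrs_model_pre, qrs_model_post_ms = qrs_model_post,
    stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, models = models,
                 spec = spec, seed = as.integer(seed), geometry = geo),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic pre/post cohort: %d patients (seed %d)%s\n",
              nrow(x$truth), x$seed,
              if (is.null(x$models)) ", tabular only" else ""))
  invisible(x)
}

#' Derived left-ventricular volumes and mass
#'
#' Extracellular matrix volume = LV volume x ECV; cell volume = LV volume x
#' (1 - ECV); LV mass = LV volume x 1.05 g/mL (specific gravity of
#' myocardium). All three are also indexed to body surface area.
#'
#' @param lv_volume_ml LV volume (mL).
#' @param ecv extracellular volume fraction.
#' @param bsa_m2 body surface area (m^2).
#' @return list with absolute and indexed quantities.
#' @examples
#' derived_volumes(100, 0.25, 2)  # matrix 12.5, cell 37.5 mL/m^2; 52.5 g/m^2
#' @export
derived_volumes <- function(lv_volume_ml, ecv, bsa_m2) {
  stopifnot(all(lv_volume_ml > 0), all(ecv > 0 & ecv < 1), all(bsa_m2 > 0))
  matrix_ml <- lv_volume_ml * ecv
  cell_ml <- lv_volume_ml - matrix_ml   # = volume * (1 - ECV), exact partition
  mass_g <- lv_volume_ml * 1.05
  list(matrix_ml = matrix_ml, cell_ml = cell_ml, mass_g = mass_g,
       matrix_ml_m2 = matrix_ml / bsa_m2, cell_ml_m2 = cell_ml / bsa_m2,
       mass_g_m2 = mass_g / bsa_m2)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics (type 7), the
#' documented convention throughout the package.
#'
#' @param x numeric vector (NAs dropped).
#' @return named vector: median, q25, q75, n.
#' @export
summarize_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no data to summarize")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3], n = length(x))
}

#' Bull's-eye summary of wall thickness before/after intervention
#'
#' @param wt_pre,wt_post `wall_thickness_map`s of the two timepoints.
#' @return data.frame with one row per AHA segment: pre, post and the
#'   post-minus-pre difference (mm); missing segments propagate as NA.
#' @export
bulls_eye <- function(wt_pre, wt_post) {
  stopifnot(inherits(wt_pre, "wall_thickness_map"),
            inherits(wt_post, "wall_thickness_map"))
  data.frame(segment = 1:17,
             pre_mm = wt_pre$thickness_mm,
             post_mm = wt_post$thickness_mm,
             diff_mm = wt_post$thickness_mm - wt_pre$thickness_mm)
}
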