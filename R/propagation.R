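#' Stimulus protocol
#'
#' Pacing protocol for tissue simulations: a quiescent interval with no
#' electrical stimulation to let internal model states equilibrate, followed
#' by S1 pacing at a fixed cycle length. The activation map is taken from the
#' last paced beat.
#'
#' @param quiescent_ms unpaced equilibration interval (ms).
#' @param cl_ms S1 cycle length (ms).
#' @param n_beats number of paced beats (1-5); the default 3 approximates
#'   "until steady state" at this cycle length.
#' @param stim_amp_pApF,stim_dur_ms stimulus strength and duration.
#' @return a `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(quiescent_ms = 1000, cl_ms = 600, n_beats = 3,
                              stim_amp_pApF = 50, stim_dur_ms = 2) {
  stopifnot(quiescent_ms >= 0, cl_ms > 0, n_beats >= 1, n_beats <= 5)
  structure(list(quiescent_ms = quiescent_ms, cl_ms = cl_ms,
                 n_beats = n_beats, stim_amp_pApF = stim_amp_pApF,
                 stim_dur_ms = stim_dur_ms), class = "stimulus_protocol")
}

#' One-dimensional strand domain
#'
#' @param length_cm strand length (cm).
#' @param h_cm node spacing (cm).
#' @return a `strand_mesh` object.
#' @export
strand_mesh <- function(length_cm = 2, h_cm = 0.01) {
  stopifnot(length_cm > 0, h_cm > 0)
  structure(list(n = as.integer(round(length_cm / h_cm)) + 1L, h_cm = h_cm,
                 length_cm = length_cm), class = "strand_mesh")
}

#' Run a monodomain simulation
#'
#' Reference full-ionic monodomain solver (ten Tusscher-Panfilov 2006
#' membrane). Reaction stepping is per node; diffusion uses linear finite
#' elements with mass lumping (explicit, sub-stepped at `dt_diff_ms`). The
#' quiescent interval is integrated as a single cell and broadcast, which is
#' exact for uniform resting tissue. Activation is the first upward crossing
#' of `vthresh_mV` during the last paced beat.
#'
#' @param x a [strand_mesh()] or a tetrahedral `bv_mesh`-like object (fields
#'   `nodes` in mm, `elems`, `fibers`).
#' @param conductivity for a strand, the diffusivity D (cm^2/ms); for a
#'   tetrahedral mesh, the `monodomain_conductivity` from
#'   [effective_conductivity()] (per-element anisotropy follows the fibers).
#' @param protocol a [stimulus_protocol()].
#' @param sites stimulated node indices (1-based); for a strand the default
#'   stimulates a 1 mm segment at the left end.
#' @param variant ionic variant.
#' @param dt_ms reaction time step (ms).
#' @param dt_diff_ms diffusion sub-step (ms, tetrahedral solver).
#' @param vthresh_mV activation threshold.
#' @param last_beat_only stop integrating once every node has activated on
#'   the last beat (keeps calibration runs short).
#' @param ... unused.
#' @return an `activation_map`: per-node activation time in ms relative to
#'   the last-beat stimulus onset (`NA` when unactivated), with the stimulus
#'   onsets as an attribute.
#' @export
run_monodomain <- function(x, ...) UseMethod("run_monodomain")

#' @rdname run_monodomain
#' @export
run_monodomain.strand_mesh <- function(x, conductivity,
                                       protocol = stimulus_protocol(),
                                       sites = NULL, variant = "epicardial",
                                       dt_ms = 0.02, vthresh_mV = 0,
                                       last_beat_only = TRUE, ...) {
  D <- as.numeric(conductivity)
  stopifnot(length(D) == 1L, D >= 0)
  n <- x$n
  if (is.null(sites)) sites <- seq_len(max(3L, round(0.1 / x$h_cm)))
  # keep the explicit diffusion update stable
  dt_eff <- if (D > 0) min(dt_ms, 0.3 * x$h_cm^2 / D) else dt_ms
  state0 <- .equilibrated_state(protocol$quiescent_ms, dt_ms, variant)
  onsets <- (seq_len(protocol$n_beats) - 1) * protocol$cl_ms
  act_start <- onsets[protocol$n_beats]
  t_end <- act_start + protocol$cl_ms
  run <- strand_run_cpp(n, x$h_cm, D, state0, dt_eff,
                        as.integer(sites) - 1L, onsets,
                        protocol$stim_dur_ms, protocol$stim_amp_pApF,
                        t_end, act_start, vthresh_mV, last_beat_only)
  act <- run$activation - act_start
  if (all(is.na(act[-sites]))) warning("no capture beyond the stimulus site")
  structure(act, onsets_ms = 0, class = "activation_map")
}

#' @rdname run_monodomain
#' @export
run_monodomain.default <- function(x, conductivity,
                                   protocol = stimulus_protocol(),
                                   sites, variant = "epicardial",
                                   dt_ms = 0.02, dt_diff_ms = 0.1,
                                   vthresh_mV = 0, last_beat_only = TRUE,
                                   ...) {
  stopifnot(!is.null(x$nodes), !is.null(x$elems))
  ed <- mesh_edges(x$elems)
  maxlen <- max(sqrt(rowSums((x$nodes[ed[, 1], ] - x$nodes[ed[, 2], ])^2)))
  if (maxlen > 1.0)
    stop(sprintf(paste0("mesh edges up to %.2f mm are too coarse for the ",
                        "full-ionic monodomain solver (limit 1.0 mm); use ",
                        "the eikonal engine or refine the mesh"), maxlen))
  stopifnot(inherits(conductivity, "monodomain_conductivity"))
  if (!conductivity$propagating)
    warning("zero monodomain conductivity: tissue will not propagate")
  D <- conductivity$diffusivity_cm2_ms * 100  # mm^2/ms
  f <- x$fibers
  if (is.null(f)) stop("mesh has no fiber field")
  tensor <- .aniso_tensor(f, D[1], D[2], D[3])
  geom <- tet_geometry(x$nodes, x$elems)
  K <- assemble_stiffness(x$nodes, x$elems, tensor = tensor, geom = geom)
  mass <- lumped_mass(x$nodes, x$elems, geom = geom)
  # stability estimate (Gershgorin on the lumped system)
  lam <- max(Matrix::rowSums(abs(K)) / mass)
  diff_every <- max(1L, as.integer(floor(dt_diff_ms / dt_ms)))
  while (diff_every > 1L && diff_every * dt_ms > 1.6 / lam)
    diff_every <- diff_every - 1L
  if (dt_ms * diff_every > 2 / lam)
    stop("explicit diffusion unstable at this resolution; reduce dt_diff_ms")
  Kc <- methods::as(K, "RsparseMatrix")
  state0 <- .equilibrated_state(protocol$quiescent_ms, dt_ms, variant)
  onsets <- (seq_len(protocol$n_beats) - 1) * protocol$cl_ms
  act_start <- onsets[protocol$n_beats]
  t_end <- act_start + protocol$cl_ms
  run <- tet_monodomain_cpp(Kc@p, Kc@j, Kc@x, mass, state0, dt_ms,
                            diff_every, as.integer(sites) - 1L, onsets,
                            protocol$stim_dur_ms, protocol$stim_amp_pApF,
                            t_end, act_start, vthresh_mV, last_beat_only)
  act <- run$activation - act_start
  structure(act, onsets_ms = 0, class = "activation_map")
}

# symmetric per-element slowness/diffusion tensor helpers ---------------------

# diffusion tensor D_t I + (D_f - D_t) f f' (per element, 6 columns)
.aniso_tensor <- function(fibers, d_f, d_t, d_n = d_t) {
  if (abs(d_n - d_t) > 1e-12 * max(d_t, d_n))
    warning("sheet-normal diffusivity differs from transverse; without sheet directions it is folded into the transverse plane")
  m <- nrow(fibers)
  df <- d_f - d_t
  cbind(d_t + df * fibers[, 1]^2,
        d_t + df * fibers[, 2]^2,
        d_t + df * fibers[, 3]^2,
        df * fibers[, 1] * fibers[, 2],
        df * fibers[, 1] * fibers[, 3],
        df * fibers[, 2] * fibers[, 3])
}

# slowness-squared metric for the eikonal solver (speeds in mm/ms)
.slowness_metric <- function(fibers, v_f, v_t, v_n = v_t) {
  if (abs(v_n - v_t) > 1e-12 * max(v_t, v_n))
    warning("sheet-normal speed differs from transverse; folded into the transverse plane")
  st <- 1 / v_t^2
  dfs <- 1 / v_f^2 - st
  cbind(st + dfs * fibers[, 1]^2,
        st + dfs * fibers[, 2]^2,
        st + dfs * fibers[, 3]^2,
        dfs * fibers[, 1] * fibers[, 2],
        dfs * fibers[, 1] * fibers[, 3],
        dfs * fibers[, 2] * fibers[, 3])
}

#' Calibrate conduction velocity for a tissue parameter set
#'
#' Runs a fine-resolution one-dimensional monodomain strand at the
#' direction's diffusivity and measures the conduction velocity between
#' probes at 25% and 75% of the strand. Results are cached (keyed by
#' diffusivity and discretization), so repeated personalization queries are
#' free. The strand resolution adapts to the diffusivity (h scaled with
#' sqrt(D)) so that the wavefront is resolved equally well across the whole
#' parameter range; `adapt_h = FALSE` with an explicit `h_cm` reproduces the
#' discrete dispersion of a target mesh instead (used when comparing against
#' a coarse tetrahedral monodomain run).
#'
#' @param params [tissue_parameters()].
#' @param baseline [baseline_conductivities()].
#' @param direction `"fiber"`, `"transverse"` or `"normal"`.
#' @param h_cm strand spacing (cm) before adaptation.
#' @param dt_ms reaction step (ms).
#' @param adapt_h scale `h_cm` with sqrt(D) (see above).
#' @param protocol quiescent interval reused from this protocol; calibration
#'   itself propagates a single front.
#' @return conduction velocity in cm/s (0 with attribute `captured = FALSE`
#'   when the tissue does not propagate).
#' @export
calibrate_cv <- function(params, baseline = baseline_conductivities(),
                         direction = c("fiber", "transverse", "normal"),
                         h_cm = 0.01, dt_ms = 0.02, adapt_h = TRUE,
                         protocol = stimulus_protocol(n_beats = 1)) {
  direction <- match.arg(direction)
  cond <- effective_conductivity(params, baseline)
  D <- cond$diffusivity_cm2_ms[[direction]]
  if (D <= 0) return(structure(0, captured = FALSE))
  h_eff <- if (adapt_h) min(0.02, max(0.0025, h_cm * sqrt(D / 1.05e-3))) else h_cm
  key <- sprintf("cv|%.8e|%.5f|%.4f|%g|%g", D, h_eff, dt_ms,
                 protocol$quiescent_ms, protocol$n_beats)
  hit <- .ct_env[[key]]
  if (!is.null(hit)) return(hit)
  sm <- strand_mesh(length_cm = 2, h_cm = h_eff)
  map <- suppressWarnings(
    run_monodomain(sm, D, protocol = protocol, dt_ms = dt_ms))
  i1 <- round(0.25 * sm$n); i2 <- round(0.75 * sm$n)
  cv <- if (is.na(map[i1]) || is.na(map[i2]) || map[i2] <= map[i1]) {
    structure(0, captured = FALSE)
  } else {
    structure(1000 * (i2 - i1) * h_eff / (map[i2] - map[i1]), captured = TRUE)
  }
  .ct_env[[key]] <- cv
  cv
}

#' Solve anisotropic first-arrival activation on a tetrahedral mesh
#'
#' Fast eikonal engine: per-element conduction velocities along the fiber,
#' transverse and sheet-normal axes define a slowness metric, and activation
#' times are first arrivals from the stimulation sites. With
#' `method = "factored"` each point source is solved separately and the map
#' is the pointwise minimum over sites, making first-arrival superposition
#' exact by construction; the default `"fim"` method solves all sites in one
#' pass and matches that envelope up to the first-order seam error where
#' fronts collide.
#'
#' @param mesh tetrahedral mesh (`nodes` mm, `elems`, `fibers`).
#' @param cv_cm_s named list or vector with `fiber`, `transverse` (and
#'   optionally `normal`) conduction velocities in cm/s; all must be > 0.
#' @param sites list of stimulation sites, each a list with `center` (node
#'   index) and `onset_ms`; a bare integer vector is treated as simultaneous
#'   point sources at onset 0.
#' @param method `"fim"` (default): fast-iterative solver with the
#'   closed-form piecewise-linear local update — robust on any geometry,
#'   first-order accurate. `"factored"`: single-source source-factored
#'   solver, exact on convex homogeneous regions independent of resolution,
#'   but unsuitable for strongly non-convex anatomy (the straight-line
#'   factorization can cut across unmeshed cavities).
#' @param tol_ms convergence tolerance of the solver (ms).
#' @return an `activation_map` (ms; `NA` for unreachable nodes).
#' @export
run_eikonal <- function(mesh, cv_cm_s, sites, method = c("fim", "factored"),
                        tol_ms = 1e-4) {
  method <- match.arg(method)
  stopifnot(!is.null(mesh$nodes), !is.null(mesh$elems), !is.null(mesh$fibers))
  cv <- as.list(cv_cm_s)
  if (is.null(cv$normal)) cv$normal <- cv$transverse
  if (any(unlist(cv[c("fiber", "transverse", "normal")]) <= 0))
    stop("all conduction velocities must be positive for the eikonal engine")
  if (is.numeric(sites) && is.null(names(sites)))
    sites <- lapply(as.integer(sites), function(i)
      list(center = i, onset_ms = 0))
  metric <- .slowness_metric(mesh$fibers, cv$fiber / 100, cv$transverse / 100,
                             cv$normal / 100)
  tets0 <- mesh$elems - 1L
  act <- NULL
  if (method == "factored") {
    for (s in sites) {
      Ti <- eikonal_factored_cpp(mesh$nodes, tets0, metric,
                                 as.integer(s$center) - 1L,
                                 as.numeric(s$onset_ms), tol_ms, 200L)
      act <- if (is.null(act)) Ti else pmin(act, Ti, na.rm = TRUE)
    }
  } else {
    act <- eikonal_fim_cpp(mesh$nodes, tets0, metric,
                           vapply(sites, function(s)
                             as.integer(s$center), integer(1)) - 1L,
                           vapply(sites, function(s)
                             as.numeric(s$onset_ms), numeric(1)),
                           tol_ms, 200L)
  }
  onsets <- vapply(sites, function(s) as.numeric(s$onset_ms), numeric(1))
  structure(act, onsets_ms = onsets, class = "activation_map")
}

#' Total activation time (QRS surrogate)
#'
#' The model's QRS duration is approximated by the total activation time of
#' the ventricles: the latest activation minus the earliest stimulus onset.
#'
#' @param map an `activation_map`.
#' @param min_fraction minimal fraction of nodes that must have activated.
#' @return total activation time (ms).
#' @export
total_activation_time <- function(map, min_fraction = 0.99) {
  frac <- mean(!is.na(map))
  if (frac < min_fraction)
    stop(sprintf("only %.1f%% of nodes activated (%d unactivated); cannot report total activation time",
                 100 * frac, sum(is.na(map))))
  onsets <- attr(map, "onsets_ms")
  if (is.null(onsets)) onsets <- 0
  max(map, na.rm = TRUE) - min(onsets)
}

#' Measure conduction velocity between two probes
#'
#' CV between the septal probe pair of a [place_landmarks()] landmark set,
#' using the geodesic probe separation along the septal surface and the
#' activation-time difference of a map paced from the RV apex.
#'
#' @param map an `activation_map`.
#' @param landmarks a `landmark_set`.
#' @return a `cv_measurement`: list with `cv_cm_s`, `distance_cm`,
#'   `dt_ms`, and `valid` (FALSE when the downstream probe activates first;
#'   the magnitude is still reported).
#' @export
measure_cv <- function(map, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pa <- landmarks$cv_probes$a; pb <- landmarks$cv_probes$b
  ta <- map[pa]; tb <- map[pb]
  if (is.na(ta) || is.na(tb)) stop("a CV probe did not activate")
  d_cm <- landmarks$cv_probes$separation_mm / 10
  dt <- tb - ta
  valid <- dt > 0
  if (!valid)
    warning("downstream probe activated first; wavefront arrived from the wrong side")
  structure(list(cv_cm_s = abs(d_cm / dt) * 1000, distance_cm = d_cm,
                 dt_ms = dt, valid = valid), class = "cv_measurement")
}

#' @export
print.cv_measurement <- function(x, ...) {
  cat(sprintf("CV = %.1f cm/s over %.2f cm (dt = %.2f ms)%s\n", x$cv_cm_s,
              x$distance_cm, x$dt_ms, if (x$valid) "" else " [INVALID]"))
  invisible(x)
}
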