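#' Resting state of the ten Tusscher-Panfilov 2006 myocyte model
#'
#' Published steady resting state (epicardial variant after long quiescence).
#' State layout: membrane potential `V` (mV), intracellular ionic
#' concentrations (mM), and the dimensionless gating variables in \[0, 1\].
#'
#' @return named numeric vector of length 19.
#' @export
myocyte_state <- function() ttp06_initial_state_cpp()

.variant_code <- function(variant) {
  v <- match.arg(variant, c("epicardial", "endocardial", "mid"))
  c(epicardial = 0L, endocardial = 1L, mid = 2L)[[v]]
}

#' Advance the myocyte state by one time step
#'
#' One integration step of the ten Tusscher-Panfilov 2006 human ventricular
#' myocyte model: Rush-Larsen exponential updates for the gating variables,
#' forward updates for the potential and concentrations.
#'
#' @param state named state vector, see [myocyte_state()].
#' @param stimulus depolarizing stimulus current (pA/pF; positive raises V).
#' @param dt time step (ms); must be positive, and at most 0.05 ms for
#'   full-accuracy integration (larger steps raise a warning).
#' @param variant `"epicardial"` (default), `"endocardial"` or `"mid"`.
#' @return the advanced state vector; gates clamped to \[0, 1\].
#' @export
step_membrane <- function(state, stimulus = 0, dt = 0.02,
                          variant = "epicardial") {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar (ms)")
  if (dt > 0.05)
    warning("dt > 0.05 ms exceeds the full-accuracy integration regime")
  out <- ttp06_step_cpp(as.numeric(state), stimulus, dt,
                        .variant_code(variant))
  names(out) <- names(state)
  out
}

#' Run a paced single-cell protocol
#'
#' Simulates S1 pacing at a fixed cycle length from the resting state,
#' preceded by a quiescent interval, and reports last-beat metrics. Steady
#' state is declared once APD90 changes by less than 1 ms between consecutive
#' beats (or after `n_beats`, whichever comes first).
#'
#' @param variant cell variant, see [step_membrane()].
#' @param pacing_cl_ms S1 cycle length (ms).
#' @param n_beats maximal number of paced beats (>= 1).
#' @param dt integration step (ms).
#' @param quiescent_ms unpaced equilibration before S1 (ms).
#' @param stim_amp_pApF,stim_dur_ms stimulus strength and duration (about
#'   twice diastolic threshold by default).
#' @param record_dt_ms sampling interval of the returned voltage trace.
#' @return list with `time`, `vm` (last-beat trace), `apd90_ms` (per beat),
#'   `resting_mV`, `peak_mV`, `captured`, `steady`, `state` (final).
#' @export
run_single_cell <- function(variant = "epicardial", pacing_cl_ms = 600,
                            n_beats = 5, dt = 0.02, quiescent_ms = 1000,
                            stim_amp_pApF = 40, stim_dur_ms = 2,
                            record_dt_ms = 0.5) {
  stopifnot(n_beats >= 1)
  vc <- .variant_code(variant)
  onsets <- quiescent_ms + (seq_len(n_beats) - 1) * pacing_cl_ms
  t_end <- quiescent_ms + n_beats * pacing_cl_ms
  run <- ttp06_cell_run_cpp(myocyte_state(), t_end, dt, onsets, stim_dur_ms,
                            stim_amp_pApF, record_dt_ms, vc)
  apd <- vapply(seq_len(n_beats), function(b) {
    sel <- run$time >= onsets[b] & run$time < onsets[b] + pacing_cl_ms
    .apd90(run$time[sel], run$vm[sel])
  }, numeric(1))
  last <- run$time >= onsets[n_beats]
  resting <- run$vm[which(run$time >= onsets[1])[1] - 1L]
  captured <- any(run$vm[last] > 0)
  if (!captured) warning("no depolarization detected in the last beat (non-capture)")
  steady <- n_beats >= 2 &&
    is.finite(apd[n_beats]) && is.finite(apd[n_beats - 1]) &&
    abs(apd[n_beats] - apd[n_beats - 1]) < 1
  list(time = run$time[last] - onsets[n_beats], vm = run$vm[last],
       apd90_ms = apd, resting_mV = resting,
       peak_mV = max(run$vm[last]), captured = captured, steady = steady,
       state = run$state)
}

# APD90 of one beat: duration above V90 = rest + 0.1 (peak - rest)
.apd90 <- function(time, vm) {
  if (!length(vm) || max(vm) < 0) return(NA_real_)
  rest <- vm[1]; peak <- max(vm)
  v90 <- rest + 0.1 * (peak - rest)
  above <- vm >= v90
  if (!any(above)) return(NA_real_)
  diff(range(time[above]))
}

# cached equilibrated tissue state after a quiescent interval (uniform resting
# tissue has no diffusion current, so a single-cell run is exact)
.equilibrated_state <- function(quiescent_ms = 1000, dt = 0.02,
                                variant = "epicardial") {
  key <- sprintf("eq|%g|%g|%s", quiescent_ms, dt, variant)
  if (!is.null(.ct_env[[key]])) return(.ct_env[[key]])
  s <- if (quiescent_ms > 0) {
    ttp06_cell_run_cpp(myocyte_state(), quiescent_ms, dt, numeric(0), 1, 0,
                       quiescent_ms, .variant_code(variant))$state
  } else myocyte_state()
  .ct_env[[key]] <- s
  s
}
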