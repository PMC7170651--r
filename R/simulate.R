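#' Initial state at a uniform potential
#'
#' Sets every compartment to `V` and every gate to its equilibrium value
#' x∞(V).
#'
#' @param cmodel a [compile_model()] result.
#' @param V initial potential (mV); defaults to the leak reversal.
#' @return A state list (`V`, `gates`).
#' @export
init_state <- function(cmodel, V = cmodel$EL) {
  gates <- lapply(cmodel$channels, function(ch) {
    ng <- length(ch$gates)
    m <- matrix(0, nrow = cmodel$n, ncol = max(1L, ng))
    if (ng > 0) for (g in seq_len(ng)) {
      gv <- ch$gates[[g]]
      s <- if (gv$is_inactivation) -1 else 1
      m[, g] <- 1 / (1 + exp(-s * (V - gv$V_half) / gv$k_slope))
    }
    m[, seq_len(ng), drop = FALSE]
  })
  list(V = rep(V, cmodel$n), gates = unname(gates))
}

#' A current-clamp step stimulus
#'
#' @param comp target compartment (1-based index).
#' @param amp_pA amplitude (pA).
#' @param t_on,t_off onset and offset (ms).
#' @return A stimulus list usable in [run_sim()].
#' @export
stim_step <- function(comp, amp_pA, t_on = 0, t_off = Inf) {
  if (t_off <= t_on) stop("t_off must exceed t_on")
  list(comp = as.integer(comp - 1L), amp = amp_pA * 1e-3,
       t_on = t_on, t_off = t_off)
}

#' Run the compartmental simulation
#'
#' Advances the model by `t_stop/dt` implicit steps. Voltage clamp (ideal,
#' zero series resistance) is supported at the soma; the clamp current is
#' recorded.
#'
#' @param cmodel a [compile_model()] result.
#' @param t_stop simulated time (ms).
#' @param dt time step (ms); default 5 µs.
#' @param state initial state (from [init_state()] or a previous run's
#'   `$state`); defaults to rest at EL.
#' @param stim list of stimuli ([stim_step()]).
#' @param clamp_V soma voltage-clamp command (mV), or `NULL` for current
#'   clamp.
#' @param probes named integer vector of compartments to record.
#' @param record_every record every k-th step.
#' @param record_gates,record_currents also record gate values / per-channel
#'   currents (nA) at the probes.
#' @param theta implicitness (1 = backward Euler, 0.5 = Crank–Nicolson).
#' @param t0 start time (ms; timestamps only).
#' @return A list: `t` (ms), `V` (matrix, one column per probe, mV),
#'   `I_clamp` (nA, when clamped), optional `gates`/`currents`, and `state`
#'   (final state for chaining runs).
#' @export
run_sim <- function(cmodel, t_stop, dt = 0.005, state = NULL, stim = list(),
                    clamp_V = NULL, probes = c(soma = 1L), record_every = 1L,
                    record_gates = FALSE, record_currents = FALSE,
                    theta = 1, t0 = 0) {
  stopifnot(inherits(cmodel, "compiled_model"))
  if (dt <= 0 || t_stop <= 0) stop("dt and t_stop must be > 0")
  if (is.null(state)) state <- init_state(cmodel)
  n_steps <- as.integer(round(t_stop / dt))
  out <- .sim_run_cpp(
    model = list(parent = cmodel$parent, cm = cmodel$cm, g_ax = cmodel$g_ax,
                 gl = cmodel$gl, EL = cmodel$EL,
                 channels = unname(cmodel$channels)),
    state = state, dt = dt, n_steps = n_steps, stim = stim,
    clamp = !is.null(clamp_V),
    clamp_value = if (is.null(clamp_V)) 0 else clamp_V,
    record = as.integer(probes - 1L), record_every = as.integer(record_every),
    record_gates = record_gates, record_currents = record_currents,
    theta = theta, t0 = t0)
  colnames(out$V) <- names(probes)
  if (record_currents) {
    names(out$currents) <- names(cmodel$channels)
    out$currents <- lapply(out$currents,
                           function(m) { colnames(m) <- names(probes); m })
  }
  if (record_gates)
    out$gates <- lapply(out$gates,
                        function(m) { colnames(m) <- names(probes); m })
  out
}

#' Integrate a neuron model
#'
#' One-call wrapper: compiles the model, builds the default probe set
#' (soma and, when present, AIS end), and runs the simulation.
#'
#' @param model a [neuron_model()].
#' @param stim list of stimuli ([stim_step()]); compartments may be given
#'   as distances via [comp_at()] after compiling.
#' @param t_stop simulated time (ms).
#' @param dt time step (ms).
#' @param ... passed to [run_sim()].
#' @return See [run_sim()]; the compiled model is attached as
#'   `attr(, "cmodel")`.
#' @export
integrate_model <- function(model, stim = list(), t_stop = 50, dt = 0.005,
                            ...) {
  cmodel <- compile_model(model)
  probes <- c(soma = 1L)
  ae <- tryCatch(ais_end_comp(cmodel), error = function(e) NULL)
  if (!is.null(ae)) probes <- c(probes, ais_end = ae)
  out <- run_sim(cmodel, t_stop = t_stop, dt = dt, stim = stim,
                 probes = probes, ...)
  attr(out, "cmodel") <- cmodel
  out
}

#' Relax a model to steady state
#'
#' With `hold_V` given, the soma is voltage-clamped at `hold_V` until the
#' tree equilibrates; the equilibrium clamp current becomes the holding
#' current, so that releasing to current clamp with that constant current
#' leaves the somatic potential at `hold_V`. Without `hold_V` the model
#' relaxes freely.
#'
#' @param cmodel a [compile_model()] result.
#' @param hold_V somatic holding potential (mV) or `NULL`.
#' @param stim stimuli active during the relaxation (e.g. a standing
#'   axonal current).
#' @param t_relax relaxation time (ms).
#' @param dt relaxation time step (ms; the stiff gating is not exercised
#'   near rest, so a coarser step than for spikes is fine).
#' @param tol drift tolerance: maximal |dV| over the final 10% of the
#'   relaxation (mV).
#' @return A list: `state`, `holding_pA` (0 when unclamped), `V_rest`
#'   (somatic potential).
#' @export
steady_state_init <- function(cmodel, hold_V = NULL, stim = list(),
                              t_relax = 300, dt = 0.05, tol = 1e-4) {
  out <- run_sim(cmodel, t_stop = t_relax, dt = dt, stim = stim,
                 clamp_V = hold_V, probes = c(soma = 1L),
                 record_every = 10L)
  nr <- nrow(out$V)
  tail_ix <- seq(floor(nr * 0.9), nr)
  if (!is.null(hold_V)) {
    Ihold <- stats::median(out$I_clamp[tail_ix])
    drift <- max(abs(diff(out$I_clamp[tail_ix])))
    if (!is.finite(Ihold)) stop("holding current did not converge")
    list(state = out$state, holding_pA = Ihold * 1e3, V_rest = hold_V)
  } else {
    drift <- max(abs(diff(out$V[tail_ix, 1])))
    if (drift > tol)
      stop("free relaxation did not reach steady state (drift ",
           signif(drift, 3), " mV)")
    list(state = out$state, holding_pA = 0, V_rest = unname(out$V[nr, 1]))
  }
}
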