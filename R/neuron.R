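#' Cortical spiking phenotypes
#'
#' The five firing phenotypes used in the cortical model: regular spiking
#' (RS), intrinsically bursting (IB), chattering (CH), fast spiking (FS) and
#' low-threshold spiking (LTS).
#'
#' @return Character vector of the five phenotype labels.
#' @export
#' @examples
#' spiking_types()
spiking_types <- function() {
  c("RS", "IB", "CH", "FS", "LTS")
}

# (a, b, c, d) quadruples per phenotype. a, b in 1/ms; c in mV (reset
# potential); d is the per-spike increment to the recovery variable u.
.izh_param_table <- data.frame(
  type = c("RS", "IB", "CH", "FS", "LTS"),
  a    = c(0.02, 0.02, 0.02, 0.05, 0.10),
  b    = c(0.20, 0.20, 0.20, 0.20, 0.25),
  c    = c(-65,  -55,  -50,  -50,  -50),
  d    = c(8,    4,    2,    2,    2),
  stringsAsFactors = FALSE
)

#' Izhikevich parameters for a spiking phenotype
#'
#' Returns the \code{(a, b, c, d)} quadruple defining one of the five
#' cortical firing phenotypes of the two-variable Izhikevich neuron
#' \deqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I, \quad du/dt = a (b v - u),}
#' with reset \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d} when
#' \eqn{v > 30} mV. \code{a} and \code{b} are rates (1/ms), \code{c} is the
#' reset potential (mV) and \code{d} the per-spike recovery increment.
#'
#' @param type One of \code{"RS"}, \code{"IB"}, \code{"CH"}, \code{"FS"},
#'   \code{"LTS"}.
#' @return An object of class \code{neuron_parameters}: a named list with
#'   elements \code{a}, \code{b}, \code{c}, \code{d} and \code{type}.
#' @export
#' @examples
#' phenotype_parameters("RS")
phenotype_parameters <- function(type) {
  if (!is.character(type) || length(type) != 1L || !(type %in% spiking_types())) {
    stop("unknown_spiking_type: '", paste(type, collapse = ","),
         "' is not one of ", paste(spiking_types(), collapse = ", "),
         call. = FALSE)
  }
  row <- .izh_param_table[.izh_param_table$type == type, ]
  structure(
    list(a = row$a, b = row$b, c = row$c, d = row$d, type = type),
    class = "neuron_parameters"
  )
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat(sprintf("<neuron_parameters %s> a=%g/ms b=%g/ms c=%g mV d=%g\n",
              x$type, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Izhikevich right-hand side
#'
#' Evaluates the derivatives of membrane potential \code{v} and recovery
#' variable \code{u} under input current \code{I}. Vectorised over neurons:
#' \code{v}, \code{u} and \code{I} may be vectors of equal length (with the
#' usual recycling for scalar \code{I}).
#'
#' @param v Membrane potential, mV.
#' @param u Recovery variable.
#' @param I Input current (dimensionless drive entering the voltage
#'   equation).
#' @param params A \code{neuron_parameters} object, or a list with vectors
#'   \code{a}, \code{b} for per-neuron parameters.
#' @return List with components \code{dv} and \code{du} (per ms).
#' @export
#' @examples
#' izh_derivatives(-65, -13, 0, phenotype_parameters("RS"))
izh_derivatives <- function(v, u, I, params) {
  if (!all(is.finite(v)) || !all(is.finite(u)) || !all(is.finite(I))) {
    stop("nonfinite_input: v, u and I must all be finite", call. = FALSE)
  }
  list(
    dv = 0.04 * v^2 + 5 * v + 140 - u + I,
    du = params$a * (params$b * v - u)
  )
}

#' Advance Izhikevich neurons one time step
#'
#' One forward-Euler step of the two-variable Izhikevich model followed by
#' the reset rule: any neuron whose updated \code{v} exceeds 30 mV is marked
#' as spiking, its \code{v} is set to the reset potential \code{c} and
#' \code{d} is added to \code{u}. The recovery update uses the pre-step
#' \code{v}. Vectorised over neurons.
#'
#' @inheritParams izh_derivatives
#' @param dt Step size in ms; must be positive and at most 1 ms.
#' @return List with \code{v}, \code{u} (post-step, post-reset),
#'   \code{spiked} (logical), and \code{v_display}: \code{v} with spiking
#'   entries clamped to 30 mV, the value recorded in traces so plotted
#'   spikes have uniform height.
#' @export
#' @examples
#' izh_step(31, 0, 0, phenotype_parameters("RS"), dt = 0.5)
izh_step <- function(v, u, I, params, dt = 0.5) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0 || dt > 1) {
    stop("bad_dt: dt must be in (0, 1] ms", call. = FALSE)
  }
  d <- izh_derivatives(v, u, I, params)
  v_new <- v + dt * d$dv
  u_new <- u + dt * d$du
  spiked <- v_new > 30
  v_display <- v_new
  if (any(spiked)) {
    v_display[spiked] <- 30
    # params$c / params$d may be scalars or per-neuron vectors
    cc <- if (length(params$c) > 1L) params$c[spiked] else params$c
    dd <- if (length(params$d) > 1L) params$d[spiked] else params$d
    v_new[spiked] <- cc
    u_new[spiked] <- u_new[spiked] + dd
  }
  list(v = v_new, u = u_new, spiked = spiked, v_display = v_display)
}

#' Simulate a single neuron under a current protocol
#'
#' Convenience driver for one Izhikevich neuron: fixed-step integration with
#' spike times collected, used for phenotype characterisation and as the
#' single-neuron oracle for the network engine.
#'
#' @param params A \code{neuron_parameters} object (or the phenotype label).
#' @param I Input current: a scalar (constant drive) or a function of time
#'   \code{I(t_ms)}.
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms (default 0.5).
#' @param v0,u0 Initial conditions; defaults are \code{v0 = c} (the reset
#'   potential) and \code{u0 = b * v0}.
#' @return List with \code{times} (sample grid, ms), \code{v}, \code{u}
#'   (traces on the step grid, spike steps clamped to 30 mV in \code{v}),
#'   \code{spike_times} (ms), and \code{v_after_reset}: the membrane
#'   potential assigned by the reset rule at the first spike (NA if none).
#' @export
#' @examples
#' run <- simulate_neuron("RS", I = 10, duration = 100)
#' length(run$spike_times)
simulate_neuron <- function(params, I, duration, dt = 0.5, v0 = NULL, u0 = NULL) {
  if (is.character(params)) params <- phenotype_parameters(params)
  v <- if (is.null(v0)) params$c else v0
  u <- if (is.null(u0)) params$b * v else u0
  n_steps <- round(duration / dt)
  I_fun <- if (is.function(I)) I else function(t) I
  times <- numeric(n_steps)
  v_tr <- numeric(n_steps)
  u_tr <- numeric(n_steps)
  spike_times <- numeric(0)
  v_after <- NA_real_
  for (k in seq_len(n_steps)) {
    t_now <- k * dt
    st <- izh_step(v, u, I_fun(t_now), params, dt)
    v <- st$v
    u <- st$u
    times[k] <- t_now
    v_tr[k] <- st$v_display
    u_tr[k] <- u
    if (st$spiked) {
      spike_times <- c(spike_times, t_now)
      if (is.na(v_after)) v_after <- st$v
    }
  }
  list(times = times, v = v_tr, u = u_tr,
       spike_times = spike_times, v_after_reset = v_after)
}
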