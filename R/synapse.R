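#' Receptor kinetics and coupling parameters
#'
#' Each neuron carries one conductance variable \code{g} per receptor class
#' (AMPA, NMDA, GABA). Between spikes each \code{g} decays exponentially,
#' \eqn{dg/dt = -g/\tau}; every presynaptic spike adds the synapse weight
#' to the target's \code{g} for the source group's receptor. Default decay
#' constants are the standard literature values for the three receptor
#' classes: fast AMPA (5 ms), slow NMDA (150 ms), GABA-A-like (10 ms).
#'
#' @param tau_ampa,tau_nmda,tau_gaba Decay time constants, ms (> 0).
#' @param coupling How \code{g} enters the neuron's input current:
#'   \code{"current"} (default) for additive current-based coupling
#'   \eqn{I_{syn} = g_{AMPA} + g_{NMDA} - g_{GABA}}, or
#'   \code{"conductance"} for \eqn{I_{syn} = \sum_r g_r (E_r - v)} with
#'   reversal potentials \code{e_exc} / \code{e_inh}.
#' @param e_exc,e_inh Reversal potentials (mV) used only under
#'   conductance coupling.
#' @param g_init_max Initial conductances are drawn uniformly on
#'   \[0, \code{g_init_max}) per neuron per receptor (default 1).
#' @param scale Scaling of the recurrent drive inside the engine:
#'   \code{"indegree"} (default) divides each neuron's synaptic current by
#'   its number of incoming synapses, making the mean drive per neuron
#'   depend on the mean presynaptic rate and weight but not on network
#'   size, so the same weight range probes the same dynamical regime in a
#'   1000-neuron reduction and the full 10,000-neuron circuit;
#'   \code{"none"} uses the raw conductance sums.
#' @param gain Dimensionless multiplier on the scaled recurrent drive
#'   (default 1.5). Calibrated once so that the default cortical circuit
#'   crosses its asynchronous-to-synchronous transition inside the 1-100 mV
#'   weight interval probed by \code{\link{weight_sweep}}; see the package
#'   vignette.
#' @return An object of class \code{synapse_params}.
#' @export
synapse_params <- function(tau_ampa = 5, tau_nmda = 150, tau_gaba = 10,
                           coupling = c("current", "conductance"),
                           e_exc = 0, e_inh = -70, g_init_max = 1,
                           scale = c("indegree", "none"), gain = 1.5) {
  stopifnot(tau_ampa > 0, tau_nmda > 0, tau_gaba > 0, g_init_max >= 0,
            is.numeric(gain), gain >= 0)
  coupling <- match.arg(coupling)
  scale <- match.arg(scale)
  structure(
    list(tau = c(AMPA = as.numeric(tau_ampa), NMDA = as.numeric(tau_nmda),
                 GABA = as.numeric(tau_gaba)),
         coupling = coupling, e_exc = as.numeric(e_exc),
         e_inh = as.numeric(e_inh), g_init_max = as.numeric(g_init_max),
         scale = scale, gain = as.numeric(gain)),
    class = "synapse_params"
  )
}

#' Decay conductances over one step
#'
#' Applies the exact solution of \eqn{dg/dt = -g/\tau} over \code{dt}:
#' \eqn{g \leftarrow g\,e^{-dt/\tau}}. Exactness makes the decay
#' unconditionally stable for any step size and gives the semigroup
#' property (two dt-steps equal one 2dt-step).
#'
#' @param g Numeric vector (or list of vectors, one per receptor) of
#'   conductance values.
#' @param tau Decay constant(s), ms; recycled against \code{g}. When
#'   \code{g} is a list, \code{tau} must be a named vector matching its
#'   names.
#' @param dt Step, ms (> 0).
#' @return Decayed \code{g} of the same shape.
#' @export
#' @examples
#' decay_step(10, tau = 5, dt = 5)  # 10 * exp(-1)
decay_step <- function(g, tau, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("bad_dt: dt must be > 0", call. = FALSE)
  if (is.list(g)) {
    return(mapply(function(gi, ti) gi * exp(-dt / ti),
                  g, tau[names(g)], SIMPLIFY = FALSE))
  }
  g * exp(-dt / tau)
}

#' Deliver spikes to target conductances
#'
#' For every synapse whose source neuron spiked, adds the synapse weight to
#' the target neuron's conductance for that synapse's receptor; convergent
#' spikes sum. Propagation uses the adjacency's per-receptor sparse weight
#' matrices.
#'
#' @param g Named list of per-neuron conductance vectors
#'   (\code{AMPA}, \code{NMDA}, \code{GABA}).
#' @param adj An \code{\link{build_adjacency}} result.
#' @param spiked Integer vector of spiking source neurons (1-based global
#'   indices) or a logical vector of length \code{adj$n}.
#' @return The updated conductance list.
#' @export
apply_spikes <- function(g, adj, spiked) {
  if (is.logical(spiked)) {
    stopifnot(length(spiked) == adj$n)
    s <- as.numeric(spiked)
  } else {
    if (length(spiked) == 0) return(g)
    spiked <- as.integer(spiked)
    if (any(spiked < 1L | spiked > adj$n)) {
      stop("unknown_neuron: spike index outside 1..", adj$n, call. = FALSE)
    }
    s <- numeric(adj$n)
    s[spiked] <- s[spiked] + 1
  }
  if (all(s == 0)) return(g)
  for (r in names(g)) {
    if (length(adj$W[[r]]@x) > 0) {
      g[[r]] <- g[[r]] + as.numeric(Matrix::crossprod(adj$W[[r]], s))
    }
  }
  g
}

#' Synaptic input current from conductances
#'
#' Under the default current-based coupling the net synaptic drive per
#' neuron is \eqn{I_{syn} = g_{AMPA} + g_{NMDA} - g_{GABA}}: excitatory
#' conductances depolarise, the GABA conductance hyperpolarises. Under
#' conductance coupling each receptor contributes
#' \eqn{g_r (E_r - v)}.
#'
#' @inheritParams apply_spikes
#' @param params A \code{\link{synapse_params}}.
#' @param v Membrane potentials, required only for conductance coupling.
#' @return Numeric vector of per-neuron synaptic current.
#' @export
#' @examples
#' synaptic_current(list(AMPA = 5, NMDA = 0, GABA = 2))
synaptic_current <- function(g, params = synapse_params(), v = NULL) {
  if (params$coupling == "current") {
    return(g$AMPA + g$NMDA - g$GABA)
  }
  if (is.null(v)) stop("conductance coupling requires v", call. = FALSE)
  (g$AMPA + g$NMDA) * (params$e_exc - v) + g$GABA * (params$e_inh - v)
}

# Seeded initial conductances: uniform on [0, g_init_max) per neuron per
# receptor.
init_synaptic_state <- function(n, params, seed) {
  set.seed(seed)
  g <- lapply(.receptors, function(r) stats::runif(n, 0, params$g_init_max))
  names(g) <- .receptors
  g
}
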