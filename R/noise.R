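#' Thalamic noise specification
#'
#' The thalamus is not simulated as explicit populations; its corticothalamic
#' drive is abstracted as an independent zero-mean Gaussian current injected
#' each integration step into every neuron of the targeted cortical layers
#' (L2/3, L4 and L6 by default), with separate amplitudes for excitatory and
#' inhibitory targets. Because the cortical tables mix merged and single
#' layer labels, targeting \code{"L2/3"} also covers groups tagged
#' \code{"L2"} or \code{"L3"}, and \code{"L6"} also covers \code{"L5/6"}.
#'
#' @param target_layers Character vector of targeted layers.
#' @param sigma_exc Noise current standard deviation for excitatory
#'   targets (default 5).
#' @param sigma_inh Standard deviation for inhibitory targets (default 2).
#' @param bias Constant background current added to every neuron regardless
#'   of layer (default 0); useful for driving characterisation runs with a
#'   deterministic current.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(target_layers = c("L2/3", "L4", "L6"),
                       sigma_exc = 5, sigma_inh = 2, bias = 0) {
  stopifnot(sigma_exc >= 0, sigma_inh >= 0, is.finite(bias))
  structure(
    list(target_layers = as.character(target_layers),
         sigma_exc = as.numeric(sigma_exc), sigma_inh = as.numeric(sigma_inh),
         bias = as.numeric(bias)),
    class = "noise_spec"
  )
}

# Layer label equivalences: which group labels fall under each target label.
layer_matches <- function(group_layers, target_layers) {
  expand <- function(t) {
    switch(t,
           "L2/3" = c("L2/3", "L2", "L3"),
           "L6"   = c("L6", "L5/6"),
           t)
  }
  covered <- unique(unlist(lapply(target_layers, expand)))
  group_layers %in% covered
}

# Per-neuron noise standard deviations for a configured network: sigma_exc
# or sigma_inh for neurons in targeted layers, 0 elsewhere.
noise_sigma_vector <- function(spec, idx) {
  targeted <- layer_matches(idx$layer, spec$target_layers)
  sigma_g <- ifelse(targeted,
                    ifelse(idx$polarity == "excitatory",
                           spec$sigma_exc, spec$sigma_inh),
                    0)
  sigma_g[idx$group_of]
}

#' Draw the thalamic noise current for one step
#'
#' Returns one i.i.d. zero-mean Gaussian current per neuron, with standard
#' deviation \code{sigma_exc} or \code{sigma_inh} according to the target's
#' polarity and exactly 0 for neurons outside the targeted layers. The
#' stream is deterministic given \code{(seed, step)} and independent of any
#' recording configuration.
#'
#' @param spec A \code{\link{noise_spec}}.
#' @param idx Group index of the network (internal; from a config via the
#'   engine) — or directly a numeric vector of per-neuron sigmas.
#' @param step Integer step counter (>= 1).
#' @param seed Integer base seed of the noise substream.
#' @return Numeric vector of per-neuron currents.
#' @export
noise_current <- function(spec, idx, step, seed) {
  sigma <- if (is.numeric(idx)) idx else noise_sigma_vector(spec, idx)
  n <- length(sigma)
  bias <- spec$bias %||% 0
  if (all(sigma == 0)) return(rep.int(bias, n))
  set.seed(substream_seed(seed, "noise", step))
  bias + stats::rnorm(n) * sigma
}
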