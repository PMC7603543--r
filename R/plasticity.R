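#' Rate-based Hebbian plasticity settings
#'
#' An optional, epoch-wise Hebbian modifier of the synaptic weights:
#' every \code{epoch_ms} of simulated time each synapse grows by
#' \eqn{\Delta w_i = \eta\, x_i\, y}, the product of its presynaptic and
#' postsynaptic firing rates over the last epoch scaled by the learning
#' rate. Off by default — the weight-sweep experiment runs with fixed
#' weights.
#'
#' @param enabled Logical; default \code{FALSE}.
#' @param eta Learning rate, >= 0 (default 0.01).
#' @param epoch_ms Interval between updates, ms (> 0, default 50).
#' @return An object of class \code{plasticity_spec}.
#' @export
plasticity_spec <- function(enabled = FALSE, eta = 0.01, epoch_ms = 50) {
  if (eta < 0) stop("negative_eta: learning rate must be >= 0", call. = FALSE)
  if (epoch_ms <= 0) stop("epoch_ms must be > 0", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), eta = as.numeric(eta),
                 epoch_ms = as.numeric(epoch_ms)),
            class = "plasticity_spec")
}

#' Hebbian weight update
#'
#' \eqn{w_i \leftarrow w_i + \eta\, x_i\, y} per synapse, where \eqn{x_i}
#' is the presynaptic firing rate and \eqn{y} the postsynaptic rate over
#' the last epoch; updated weights are floored at 0 (they cannot become
#' negative — the sign of a synapse's effect is carried by its receptor).
#'
#' @param weights Numeric vector of per-synapse weights.
#' @param pre_rate Presynaptic rate per synapse (>= 0; spikes per epoch).
#' @param post_rate Postsynaptic rate per synapse (>= 0).
#' @param eta Learning rate (>= 0).
#' @return Updated weight vector.
#' @export
#' @examples
#' hebbian_update(1, pre_rate = 1, post_rate = 1, eta = 0.1)  # 1.1
hebbian_update <- function(weights, pre_rate, post_rate, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0) {
    stop("negative_eta: learning rate must be a single value >= 0", call. = FALSE)
  }
  if (any(pre_rate < 0) || any(post_rate < 0)) {
    stop("negative_rate: firing rates must be >= 0", call. = FALSE)
  }
  pmax(0, weights + eta * pre_rate * post_rate)
}

# Apply one Hebbian epoch to an adjacency in place: per-edge rates are the
# epoch spike counts of the edge's source and target neurons. Rebuilds the
# per-receptor sparse matrices.
apply_plasticity <- function(adj, epoch_counts, eta) {
  e <- adj$edges
  pre <- epoch_counts[e$source + 1L]
  post <- epoch_counts[e$target + 1L]
  e$weight <- hebbian_update(e$weight, pre, post, eta)
  adj$edges <- e
  for (r in names(adj$W)) {
    sel <- e$receptor == r
    adj$W[[r]] <- Matrix::sparseMatrix(i = e$source[sel] + 1L,
                                       j = e$target[sel] + 1L,
                                       x = e$weight[sel],
                                       dims = c(adj$n, adj$n))
  }
  adj
}
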