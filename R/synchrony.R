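#' Population mean membrane trace
#'
#' \eqn{V(t) = \frac{1}{N}\sum_{i=1}^N v_i(t)} for a matrix of membrane
#' potentials with one neuron per row and one 1 ms sample per column.
#'
#' @param traces Numeric matrix, N neurons x T samples.
#' @return Numeric vector of length T.
#' @export
#' @examples
#' population_mean_trace(rbind(c(1, 2), c(3, 4)))
population_mean_trace <- function(traces) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 1L || ncol(traces) < 1L) {
    stop("empty_traces: need at least one neuron and one sample", call. = FALSE)
  }
  colMeans(traces)
}

#' Temporal (population-style) variance of a series
#'
#' The time-average of the squared signal minus the squared time-average,
#' \eqn{\sigma^2 = \langle x(t)^2 \rangle_t - \langle x(t) \rangle_t^2},
#' i.e. variance normalised by T rather than T-1. Computed in centred form
#' for numerical stability (identical value, guaranteed non-negative).
#'
#' @param series Numeric vector with at least 2 samples.
#' @return Scalar variance.
#' @export
#' @examples
#' temporal_variance(c(0, 2))  # 1
temporal_variance <- function(series) {
  if (length(series) < 2L) {
    stop("too_few_samples: temporal variance needs >= 2 samples", call. = FALSE)
  }
  m <- mean(series)
  mean((series - m)^2)
}

#' Variance-ratio synchrony of a neuronal population
#'
#' The chi-squared synchrony measure: the temporal variance of the
#' population-mean membrane trace divided by the mean of the individual
#' trace variances,
#' \deqn{\chi^2(N) = \frac{\sigma_V^2}{\frac{1}{N}\sum_i \sigma_{V_i}^2}.}
#' It equals 1 for a fully synchronised population (identical traces),
#' tends to \eqn{1/N} for independent neurons, and lies in \[0, 1\] for any
#' trace matrix. If every trace is constant the ratio is undefined; the
#' result is then reported as 0 with \code{degenerate = TRUE} so parameter
#' sweeps over quiescent networks complete.
#'
#' @param traces Numeric matrix, N >= 2 neurons x T >= 2 samples.
#' @param group Optional group label carried into the result.
#' @param weight Optional connection weight (mV) carried into the result.
#' @return An object of class \code{synchrony_result}: list with
#'   \code{chi_squared}, \code{chi} (its square root), \code{n_neurons},
#'   \code{degenerate}, \code{group}, \code{weight}.
#' @export
#' @examples
#' tr <- matrix(rep(sin(1:100), each = 5), nrow = 5)
#' chi_squared(tr)$chi_squared  # 1: identical traces
chi_squared <- function(traces, group = NA_character_, weight = NA_real_) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L) {
    stop("too_few_neurons: the synchrony measure needs N >= 2", call. = FALSE)
  }
  if (!all(is.finite(traces))) {
    stop("nonfinite_traces: trace matrix must be finite", call. = FALSE)
  }
  num <- temporal_variance(population_mean_trace(traces))
  denom <- mean(apply(traces, 1L, temporal_variance))
  degenerate <- denom == 0
  x2 <- if (degenerate) 0 else num / denom
  structure(
    list(chi_squared = x2, chi = sqrt(x2), n_neurons = nrow(traces),
         degenerate = degenerate, group = group, weight = weight),
    class = "synchrony_result"
  )
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony> chi^2 = %.4f (chi = %.4f), N = %d%s%s\n",
              x$chi_squared, x$chi, x$n_neurons,
              if (!is.na(x$group)) paste0(", group ", x$group) else "",
              if (x$degenerate) " [degenerate: all traces constant]" else ""))
  invisible(x)
}

#' Synchrony of every recorded group of a run
#'
#' @param rec A \code{recording_set} with the membrane matrix.
#' @param groups Group names (default: all).
#' @param discard_ms Initial transient to drop before computing variances,
#'   ms (default 50).
#' @param weight Weight label carried into the results.
#' @return Data frame \code{group, weight_mV, chi_squared, chi,
#'   degenerate_flag}.
#' @export
run_synchrony <- function(rec, groups = rec$groups, discard_ms = 50,
                          weight = NA_real_) {
  keep <- seq_len(rec$duration) > discard_ms
  if (sum(keep) < 2L) stop("discard_ms leaves fewer than 2 samples", call. = FALSE)
  rows <- lapply(groups, function(gname) {
    tr <- group_traces(rec, gname)[, keep, drop = FALSE]
    r <- chi_squared(tr, group = gname, weight = weight)
    data.frame(group = gname, weight_mV = weight,
               chi_squared = r$chi_squared, chi = r$chi,
               degenerate_flag = r$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synchrony versus connection weight
#'
#' The headline experiment: for each weight in the sweep grid, every
#' connection weight in the configuration is overridden with that value,
#' the network is simulated afresh, and the chi-squared synchrony of each
#' requested group is computed from its membrane traces (after discarding
#' the initial transient). Each weight's run derives its seed from the base
#' seed plus the weight's index, so the sweep is reproducible while runs
#' stay independent.
#'
#' @param config A valid \code{network_config}.
#' @param weights Numeric vector of weights, mV; default \code{seq(1, 91,
#'   by = 10)} (the 1-to-100 range stepped by 10).
#' @param groups Groups to measure (default: all).
#' @param seed Base seed (default: the config's run seed).
#' @param discard_ms Transient to discard, ms (default 50).
#' @param verbose Log each weight's run.
#' @return Data frame \code{group, weight_mV, chi_squared, chi,
#'   degenerate_flag}, one row per (group, weight).
#' @export
#' @examples
#' cfg <- make_fixture(2, 15, seed = 5)
#' weight_sweep(cfg, weights = c(1, 21), seed = 5)
weight_sweep <- function(config, weights = seq(1, 91, by = 10),
                         groups = config$groups$name, seed = NULL,
                         discard_ms = 50, verbose = FALSE) {
  if (length(weights) == 0) stop("empty_weights: need at least one weight",
                                 call. = FALSE)
  if (!all(groups %in% config$groups$name)) {
    stop("unknown group(s): ",
         paste(setdiff(groups, config$groups$name), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(seed)) seed <- config$run$seed
  out <- vector("list", length(weights))
  for (k in seq_along(weights)) {
    w <- weights[k]
    cfg_w <- config
    cfg_w$connections$weight <- w
    if (verbose) message(sprintf("[izhnet] sweep: weight %g mV (%d/%d)",
                                 w, k, length(weights)))
    rec <- run_network(cfg_w, seed = substream_seed(seed, "sweep", k),
                       record_v = TRUE)
    out[[k]] <- run_synchrony(rec, groups = groups, discard_ms = discard_ms,
                              weight = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write sweep results to CSV
#'
#' @param sweep Data frame from \code{\link{weight_sweep}}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  df <- sweep
  for (j in c("chi_squared", "chi")) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
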