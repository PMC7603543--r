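# Independent oracles used across tests.

# Naive double-loop synchrony measure, written directly from the defining
# variance-ratio formulas (uncentred moments), independent of the package's
# centred implementation.
brute_force_chi2 <- function(m) {
  n <- nrow(m)
  tt <- ncol(m)
  V <- numeric(tt)
  for (t in seq_len(tt)) {
    s <- 0
    for (i in seq_len(n)) s <- s + m[i, t]
    V[t] <- s / n
  }
  sigma_v2 <- sum(V^2) / tt - (sum(V) / tt)^2
  acc <- 0
  for (i in seq_len(n)) {
    vi <- m[i, ]
    acc <- acc + (sum(vi^2) / tt - (sum(vi) / tt)^2)
  }
  sigma_v2 / (acc / n)
}

# Adaptive high-accuracy reference integration of the Izhikevich equations
# (no reset handling; for subthreshold segments only).
reference_trajectory <- function(params, v0, u0, I, times) {
  rhs <- function(t, y, p) {
    list(c(0.04 * y[1]^2 + 5 * y[1] + 140 - y[2] + I,
           p$a * (p$b * y[1] - y[2])))
  }
  out <- deSolve::ode(y = c(v = v0, u = u0), times = times, func = rhs,
                      parms = params, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  as.data.frame(out)
}

# Fixed-step forward-Euler trajectory via the package stepper, failing if a
# reset occurs (the comparison is only meaningful subthreshold).
euler_trajectory <- function(params, v0, u0, I, duration, dt) {
  n <- round(duration / dt)
  v <- v0
  u <- u0
  vs <- numeric(n + 1)
  vs[1] <- v0
  ts <- (0:n) * dt
  for (k in seq_len(n)) {
    st <- izh_step(v, u, I, params, dt)
    stopifnot(!st$spiked)
    v <- st$v
    u <- st$u
    vs[k + 1] <- v
  }
  data.frame(time = ts, v = vs)
}

# Stable fixed point of the subthreshold dynamics (u on the nullcline),
# solving 0.04 v^2 + (5 - b) v + 140 + I = 0 for the lower root.
izh_rest <- function(params, I = 0) {
  bq <- 5 - params$b
  disc <- bq^2 - 4 * 0.04 * (140 + I)
  stopifnot(disc > 0)
  (-bq - sqrt(disc)) / (2 * 0.04)
}

# Tiny two-group configuration used by several engine tests. Regular-spiking
# groups only: their reset potential sits in the basin of the stable rest
# state, so with zero noise and zero drive the network is genuinely silent.
quiet_config <- function(n_per_group = 5, weight = 0, sigma = 0,
                         g_init_max = 0, duration = 50, seed = 1L) {
  groups <- rbind(
    group_spec("RS_a", "pyramidal", "L2/3", n_per_group, "RS", "AMPA"),
    group_spec("RS_b", "pyramidal", "L4", n_per_group, "RS", "AMPA")
  )
  pairs <- expand.grid(source = groups$name, target = groups$name,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  conns <- data.frame(source = pairs$source, target = pairs$target,
                      sparseness = 0.5, weight = as.numeric(weight),
                      stringsAsFactors = FALSE)
  network_config(groups, conns,
                 noise = noise_spec(sigma_exc = sigma, sigma_inh = sigma),
                 synapse = synapse_params(g_init_max = g_init_max),
                 duration = duration, seed = seed)
}
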