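#' Parameters of the theta-neuron network model
#'
#' The dynamics of each node follow the theta-neuron (Ermentrout-Kopell)
#' phase model, driven by an intrinsic current `I0`, Gaussian noise of
#' intensity `I_noise`, and excitatory input from coupled nodes scaled by a
#' global factor `omega`. With `I0 < 0` the isolated noiseless node has a
#' stable steady state `theta* = -2 * atan(sqrt(-I0))`; noise kicks it over
#' the neighboring saddle, producing a spike (a full phase rotation).
#'
#' @param I0 Intrinsic drive (default -1.2, excitable regime).
#' @param I_noise Noise intensity (default 6).
#' @param omega Global coupling scale (>= 0).
#' @param dt Integration step in model time units (default 0.01).
#' @param n_steps Number of integration steps (default 4e6; analyses at
#'   desk scale typically pass 4e5).
#' @param active_window A node counts as active at time t if it spiked
#'   within the trailing window of this length (model time units; default
#'   0.5, chosen so an uncoupled node at the default drive and noise is
#'   active well under 20% of the time).
#' @param n_runs Independent noise realizations averaged by [bni()] and
#'   [node_ictogenicity()] (default 10).
#' @param classic_form Use the degenerate literal multiplier `(1 - cos)` on
#'   the input current instead of the standard `(1 + cos)` (default FALSE).
#' @param noise_per_step Add `I_noise * N(0,1)` to the current per step
#'   without `sqrt(dt)` scaling, instead of the Euler-Maruyama convention
#'   (default FALSE).
#' @return Object of class `theta_params`.
#' @export
theta_params <- function(I0 = -1.2, I_noise = 6, omega = 0, dt = 0.01,
                         n_steps = 4e6, active_window = 0.5, n_runs = 10,
                         classic_form = FALSE, noise_per_step = FALSE) {
  stopifnot(dt > 0, n_steps >= 1, omega >= 0, active_window > 0,
            n_runs >= 1, I_noise >= 0)
  structure(list(I0 = I0, I_noise = I_noise, omega = omega, dt = dt,
                 n_steps = n_steps, active_window = active_window,
                 n_runs = n_runs, classic_form = classic_form,
                 noise_per_step = noise_per_step),
            class = "theta_params")
}

#' Stable fixed point of the uncoupled noiseless theta neuron
#'
#' For `I0 < 0` the equation `1 - cos(theta) + (1 + cos(theta)) * I0 = 0`
#' has solutions `theta = +/- 2 * atan(sqrt(-I0))`; the negative root is the
#' stable one.
#'
#' @param I0 Intrinsic drive, must be negative.
#' @return The stable phase in (-pi, 0).
#' @export
theta_fixed_point <- function(I0) {
  if (I0 >= 0) stop("a stable steady state requires I0 < 0")
  -2 * atan(sqrt(-I0))
}

#' Simulate the coupled theta-neuron network
#'
#' Euler-Maruyama integration from `theta_i(0) = theta*`. Node i receives
#' `I0 + omega/N * sum_j c_ji * (1 - cos(theta_j - theta*)) + noise`; spikes
#' are upward crossings of `theta = pi`. Optionally a single node is removed
#' (virtual resection): it is silenced and excluded from the BNI average,
#' but the coupling sum stays normalized by the full `N` so the remaining
#' weights are unchanged.
#'
#' @param C Square nonnegative weight matrix (`c_ij` = connection i -> j) or
#'   `connectivity_matrix`.
#' @param params A [theta_params()].
#' @param removed_node Optional node index to resect.
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @param return_spikes Also return per-node spike times.
#' @return Object of class `simulation_result`: `active` (per-node fraction
#'   of time in the active state; `NA` for a removed node), `bni` (mean
#'   active fraction over simulated nodes), `n_spikes`, and optionally
#'   `spike_times`.
#' @export
simulate_theta <- function(C, params = theta_params(), removed_node = NULL,
                           seed, return_spikes = FALSE) {
  W <- as_weights(C)
  if (any(W < 0)) stop("coupling assumes nonnegative weights")
  n <- nrow(W)
  rm_idx <- -1L
  if (!is.null(removed_node)) {
    if (removed_node < 1 || removed_node > n)
      stop("removed_node out of range")
    rm_idx <- as.integer(removed_node) - 1L
  }
  res <- with_seed(seed,
    theta_simulate_cpp(W, params$I0, params$I_noise, params$omega,
                       params$dt, params$n_steps, params$active_window,
                       rm_idx, params$classic_form, params$noise_per_step,
                       return_spikes))
  res$bni <- mean(res$active, na.rm = TRUE)
  res$removed_node <- removed_node
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$active), " node(s), BNI = ",
      round(x$bni, 4),
      if (!is.null(x$removed_node))
        paste0(" (node ", x$removed_node, " removed)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Brain network ictogenicity (BNI)
#'
#' Average over `params$n_runs` independent noise realizations of the mean
#' fraction of time the network's nodes spend in the active state.
#'
#' @inheritParams simulate_theta
#' @param omega Optional override of `params$omega`.
#' @return Scalar in [0, 1].
#' @export
bni <- function(C, params = theta_params(), seed, omega = NULL,
                removed_node = NULL) {
  if (!is.null(omega)) params$omega <- omega
  seeds <- derive_seeds(seed, params$n_runs, salt = 41)
  mean(vapply(seeds, function(s)
    simulate_theta(C, params, removed_node, seed = s)$bni, numeric(1)))
}

#' Calibrate the coupling scale to 50% network activity
#'
#' Finds `omega_50`, the global coupling scale at which the network spends
#' (on average over `n_runs` noise realizations) the target fraction of
#' time in the active state. The same seed is reused for every evaluation
#' (common random numbers), making BNI a deterministic, near-monotone
#' function of omega: the search brackets the target by doubling the upper
#' bound from 1, then bisects until `|BNI - target| <= tol` or the bracket
#' width falls below 1e-2 of its scale.
#'
#' @inheritParams bni
#' @param target Target BNI (default 0.5).
#' @param tol Acceptance tolerance on BNI (default 0.05).
#' @param omega_max Cap on the doubling search (default 2^15).
#' @return List with `omega_50`, `bni_achieved`, `n_evaluations`, `trace`
#'   (data.frame of evaluated omega/BNI pairs).
#' @export
calibrate_omega <- function(C, params = theta_params(), target = 0.5,
                            tol = 0.05, seed, omega_max = 2^15) {
  stopifnot(target >= 0, target < 1)
  trace <- data.frame(omega = numeric(), bni = numeric())
  f <- function(om) {
    b <- bni(C, params, seed = seed, omega = om)
    trace[nrow(trace) + 1L, ] <<- c(om, b)
    b
  }
  b0 <- f(0)
  if (abs(b0 - target) <= tol || target == 0)
    return(list(omega_50 = 0, bni_achieved = b0,
                n_evaluations = nrow(trace), trace = trace))
  if (b0 > target)
    stop("BNI at omega = 0 (", round(b0, 3), ") already exceeds the ",
         "target (", target, "): not reachable from below")
  lo <- 0; blo <- b0
  hi <- 1
  repeat {
    bhi <- f(hi)
    if (bhi >= target) break
    lo <- hi; blo <- bhi
    hi <- hi * 2
    if (hi > omega_max)
      stop("target BNI not reached by omega = ", omega_max,
           " (BNI = ", round(bhi, 3), " at omega = ", hi / 2, ")")
  }
  best <- if (abs(bhi - target) < abs(blo - target)) c(hi, bhi) else c(lo, blo)
  while (abs(best[2] - target) > tol && (hi - lo) > 1e-2 * max(1, hi)) {
    mid <- (lo + hi) / 2
    bm <- f(mid)
    if (abs(bm - target) < abs(best[2] - target)) best <- c(mid, bm)
    if (bm < target) lo <- mid else hi <- mid
  }
  list(omega_50 = best[1], bni_achieved = best[2],
       n_evaluations = nrow(trace), trace = trace)
}

#' Node ictogenicity via virtual resection
#'
#' For each node i, runs `n_runs` simulations with node i removed (keeping
#' the coupling normalization by the full N) at the calibrated coupling
#' `omega_50`, and summarizes the resulting drop in network activity as
#' `NI_i = (0.5 - BNI_post) / 0.5`, averaged over runs. `NI = 1` means
#' removal silences the network; `NI = 0` means no change from the 50%
#' operating point; negative values mean removal increases activity.
#'
#' @inheritParams bni
#' @param omega_50 Calibrated coupling scale (see [calibrate_omega()]).
#' @return Object of class `ni_profile`: data.frame `ni` with per-node mean
#'   NI, `replicates` (nodes x n_runs matrix of per-run NI values),
#'   `omega_50`.
#' @export
node_ictogenicity <- function(C, omega_50, params = theta_params(), seed) {
  W <- as_weights(C)
  n <- nrow(W)
  params$omega <- omega_50
  reps <- matrix(NA_real_, n, params$n_runs)
  for (i in seq_len(n)) {
    seeds <- derive_seeds(seed, params$n_runs, salt = 1000 + i)
    bni_post <- vapply(seeds, function(s)
      simulate_theta(W, params, removed_node = i, seed = s)$bni, numeric(1))
    reps[i, ] <- (0.5 - bni_post) / 0.5
  }
  structure(list(ni = data.frame(node = seq_len(n), ni = rowMeans(reps)),
                 replicates = reps, omega_50 = omega_50),
            class = "ni_profile")
}

#' @export
print.ni_profile <- function(x, ...) {
  top <- x$ni[order(-x$ni$ni), ][1, ]
  cat("<ni_profile> ", nrow(x$ni), " node(s), omega_50 = ",
      signif(x$omega_50, 4), "; top node ", top$node, " (NI = ",
      round(top$ni, 3), ")\n", sep = "")
  invisible(x)
}
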