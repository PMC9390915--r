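#' Build a sparse rank-one network for the Go-Nogo integration task
#'
#' Constructs the geometric connectivity solution for evidence integration:
#' input and readout patterns are generated randomly, then tied to the
#' rank-one structure by setting \code{I = n} (so the input is picked up by
#' the recurrent dynamics) and \code{w = m} (so the recurrent dynamics drive
#' the readout), while a common component gives \code{m} and \code{n} an
#' overlap \code{sigma_mn} in a shared dimension. The coupling matrix is the
#' rescaled outer product \eqn{m_i n_j} with exactly \code{C} non-zero inputs
#' kept per neuron, so the spectral outlier sits at
#' \eqn{\lambda_1 = C\,\sigma_{mn}} regardless of \code{N}. With
#' \eqn{\lambda_1 > 1} the network is bistable along \code{m}; the lower fixed
#' point is located at construction time and used as the trial initial state.
#'
#' @param N network size.
#' @param C non-zero inputs kept per neuron.
#' @param sigma2 variance of the connectivity-vector entries.
#' @param sigma_mn covariance of \code{m} and \code{n}.
#' @param tau unit time constant (ms).
#' @return A \code{"task_network"} (which is also a \code{"network_model"})
#'   with readout weights \code{w}, spectral \code{theory}, and cached
#'   \code{x_lower}/\code{kappa_lower} when bistable.
#' @examples
#' set.seed(8)
#' net <- task_network(400, C = 100, sigma2 = 0.1, sigma_mn = 0.08)
#' net$theory$outlier  # C * sigma_mn = 8
#' @export
task_network <- function(N, C, sigma2 = 0.1, sigma_mn = 0.04, tau = 100) {
  N <- check_count(N, 2L)
  C <- check_count(C)
  if (C > N) stop("`C` must not exceed `N`", call. = FALSE)
  vectors <- connectivity_vectors(N, sigma2, sigma_mn)
  P <- rank_one_matrix(vectors, rescaled = TRUE)
  mask <- sparsity_mask(N, "fixed_in_degree", C = C)
  W <- sparsify(P, mask)
  theory <- spectral_theory("rank_one_rescaled", sigma2 = sigma2,
                            sigma_mn = sigma_mn, C = C, N = N)
  net <- network_model(W, I = vectors$n, tau = tau)
  net$w <- vectors$m
  net$C <- C
  net$g <- NULL
  net$theory <- theory
  class(net) <- c("task_network", class(net))
  if (theory$outlier > 1) {
    fp <- find_fixed_point(net, sign = -1)
    net$x_lower <- fp$state
    net$kappa_lower <- fp$kappa_r
  } else {
    net$x_lower <- numeric(N)
    net$kappa_lower <- 0
  }
  net
}

#' Dense low-rank-plus-Gaussian control network for the task
#'
#' The same task geometry (\code{I = n}, \code{w = m}) implemented with dense
#' connectivity \eqn{W = P + g\,\mathrm{Gaussian}}, \eqn{P_{ij} = m_i n_j/N}:
#' the spectral outlier sits at \eqn{\sigma_{mn}} and the bulk disk has radius
#' \eqn{g}. Used to compare sparsity against an explicit random component with
#' a matched eigenspectrum shape. See [dense_control_preset] for a published
#' parameter set; note that the mapping between the sparse network's
#' parameters and an "equivalent" dense control is not certified by this
#' package.
#'
#' @inheritParams task_network
#' @param g strength of the Gaussian component.
#' @return A \code{"task_network"}.
#' @export
control_network <- function(N, sigma2, sigma_mn, g, tau = 100) {
  N <- check_count(N, 2L)
  vectors <- connectivity_vectors(N, sigma2, sigma_mn)
  W <- composite_matrix(vectors, g)
  theory <- structure(
    list(outlier = sigma_mn, bulk_radius = check_scalar(g, min = 0),
         branch = "composite", sigma2 = sigma2, sigma_mn = sigma_mn,
         g = g, N = N, s = NULL, C = NULL),
    class = "spectral_theory")
  net <- network_model(W, I = vectors$n, tau = tau)
  net$w <- vectors$m
  net$C <- NULL
  net$g <- g
  net$theory <- theory
  class(net) <- c("task_network", class(net))
  if (theory$outlier > 1) {
    fp <- find_fixed_point(net, sign = -1)
    net$x_lower <- fp$state
    net$kappa_lower <- fp$kappa_r
  } else {
    net$x_lower <- numeric(N)
    net$kappa_lower <- 0
  }
  net
}

#' Dense control parameter preset
#'
#' A published parameterisation of the dense low-rank-plus-Gaussian control
#' network (\code{sigma2 = 9}, \code{sigma_mn = 2.3}, \code{g = 1.3}),
#' provided for convenience. Its claimed spectral equivalence to a particular
#' sparse task network depends on a scaling convention that cannot be
#' reconstructed unambiguously, so this package exposes the numbers without
#' asserting that equivalence.
#'
#' @format A named list with elements \code{sigma2}, \code{sigma_mn},
#'   \code{g}.
#' @export
dense_control_preset <- list(sigma2 = 9, sigma_mn = 2.3, g = 1.3)

#' @export
print.task_network <- function(x, ...) {
  cat(sprintf("Task network: N = %d%s, sigma2 = %g, sigma_mn = %g\n",
              x$N,
              if (!is.null(x$C)) sprintf(", C = %d", x$C)
              else sprintf(", dense + Gaussian g = %g", x$g),
              x$vectors$sigma2, x$vectors$sigma_mn))
  cat(sprintf("  theory: outlier = %.4g, bulk radius = %.4g (%s)\n",
              x$theory$outlier, x$theory$bulk_radius,
              classify_regime(x$theory)))
  if (x$theory$outlier > 1)
    cat(sprintf("  bistable; lower fixed point kappa_r = %.4g\n",
                x$kappa_lower))
  invisible(x)
}

#' Simulate one evidence-integration trial
#'
#' Starts the network in the lower fixed point (negative readout) and
#' presents a fluctuating stimulus \eqn{c(t) I + \eta(t)} for
#' \code{duration} ms, where \eqn{c(t) = \bar c + \xi(t)} is the stimulus
#' magnitude with white-noise fluctuations of intensity \code{stim_sd}
#' (units: strength per \eqn{\sqrt{ms}}) and \eqn{\eta(t)} is independent
#' per-unit white noise of amplitude \code{unit_noise_sd}. The readout is
#' \eqn{z(t) = \frac{1}{N} \sum_i w_i \tanh(x_i(t))} by default; the
#' \eqn{1/N} normalisation and the nonlinearity are switchable.
#'
#' @param net a \code{"task_network"}.
#' @param c_bar mean stimulus strength.
#' @param duration stimulus duration (ms).
#' @param stim_sd white-noise intensity of the stimulus fluctuations.
#' @param unit_noise_sd per-unit noise amplitude.
#' @param dt integration step (ms).
#' @param seed optional seed.
#' @param x0 initial state; defaults to the cached lower fixed point.
#' @param apply_phi,normalise readout switches: use \code{tanh(x)} (vs raw
#'   \code{x}) and divide by \code{N}.
#' @param return_trajectory keep the full state record.
#' @return A \code{"task_trial"}: list with \code{times}, readout \code{z},
#'   \code{c_bar}, the realised stimulus record \code{c}, and optionally
#'   \code{trajectory}.
#' @export
run_trial <- function(net, c_bar, duration = 500, stim_sd = 0.3,
                      unit_noise_sd = 0.05, dt = net$tau / 20, seed = NULL,
                      x0 = NULL, apply_phi = TRUE, normalise = TRUE,
                      return_trajectory = FALSE) {
  stopifnot(inherits(net, "task_network"))
  if (!is.null(seed)) set.seed(seed)
  c_bar <- check_scalar(c_bar)
  stim_sd <- check_scalar(stim_sd, min = 0)
  nt <- max(1L, round(duration / dt))
  cvec <- rep(c_bar, nt)
  if (stim_sd > 0) cvec <- cvec + stim_sd * stats::rnorm(nt) / sqrt(dt)
  x0 <- x0 %||% net$x_lower
  traj <- stats::simulate(net, duration = duration, dt = dt, x0 = x0,
                          input = cvec, noise_std = unit_noise_sd)
  r <- if (apply_phi) tanh(traj$x) else traj$x
  z <- as.numeric(r %*% net$w)
  if (normalise) z <- z / net$N
  structure(
    list(times = traj$times, z = z, c_bar = c_bar, c = cvec, dt = dt,
         trajectory = if (return_trajectory) traj),
    class = "task_trial")
}

#' Go-Nogo decision from a readout time series
#'
#' The decision is the sign of the time-averaged readout over the terminal
#' \code{decision_window} ms of the trial; an exact zero ties to
#' \code{"negative"} (conservative Nogo default).
#'
#' @param z a \code{"task_trial"}, or a numeric readout series (then
#'   \code{times} must be given).
#' @param decision_window terminal averaging window (ms).
#' @param times sample times when \code{z} is a bare numeric vector.
#' @return \code{"positive"} or \code{"negative"}.
#' @export
decision <- function(z, decision_window = 50, times = NULL) {
  if (inherits(z, "task_trial")) {
    times <- z$times
    z <- z$z
  }
  if (is.null(times) || length(times) != length(z))
    stop("`times` must accompany a bare readout series", call. = FALSE)
  t_end <- max(times)
  if (decision_window > t_end)
    stop("decision window longer than the readout series", call. = FALSE)
  sel <- times >= t_end - decision_window
  if (mean(z[sel]) > 0) "positive" else "negative"
}

#' Locate the noise-free decision threshold by bisection
#'
#' With all noise switched off the bistable switch is deterministic and the
#' decision is a step function of \eqn{\bar c}; this routine brackets and
#' bisects the switching value. Serves as the reference point around which
#' psychometric curves are sampled.
#'
#' @param net a \code{"task_network"}.
#' @param lower lower bracket (must give a negative decision).
#' @param upper optional upper bracket; found by doubling when omitted.
#' @param tol absolute tolerance on the threshold.
#' @param ... further arguments passed to [run_trial()] (e.g.
#'   \code{duration}).
#' @return The threshold stimulus strength.
#' @export
locate_threshold <- function(net, lower = 0, upper = NULL, tol = 1e-3, ...) {
  dec <- function(cb)
    decision(run_trial(net, cb, stim_sd = 0, unit_noise_sd = 0, ...))
  if (dec(lower) == "positive")
    stop("`lower` already produces a positive decision", call. = FALSE)
  if (is.null(upper)) {
    upper <- max(abs(lower), 0.05)
    for (i in 1:25) {
      if (dec(upper) == "positive") break
      upper <- upper * 2
    }
    if (dec(upper) != "positive")
      stop("could not bracket the threshold from above", call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (dec(mid) == "positive") upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Psychometric curve of a task network
#'
#' Fraction of positive decisions over repeated noisy trials as the mean
#' stimulus strength is varied.
#'
#' @param net a \code{"task_network"}.
#' @param c_bar_grid stimulus strengths to probe.
#' @param repeats trials per strength.
#' @param seed base seed; trial \code{k} of strength \code{i} uses a seed
#'   derived deterministically from it.
#' @param ... further arguments passed to [run_trial()] (noise amplitudes,
#'   duration, ...).
#' @param decision_window terminal averaging window (ms).
#' @return A \code{"psychometric_curve"}: data frame with columns
#'   \code{c_bar} and \code{proportion_positive}, plus attributes
#'   \code{repeats} and network parameters.
#' @export
psychometric_curve <- function(net, c_bar_grid, repeats = 50, seed = NULL,
                               decision_window = 50, ...) {
  stopifnot(inherits(net, "task_network"))
  repeats <- check_count(repeats)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  prop <- vapply(seq_along(c_bar_grid), function(i) {
    pos <- vapply(seq_len(repeats), function(k) {
      tr <- run_trial(net, c_bar_grid[i],
                      seed = derive_seed(seed, (i - 1L) * repeats + k), ...)
      decision(tr, decision_window) == "positive"
    }, logical(1))
    mean(pos)
  }, numeric(1))
  structure(
    data.frame(c_bar = c_bar_grid, proportion_positive = prop),
    repeats = repeats, seed = seed,
    params = list(N = net$N, C = net$C, g = net$g,
                  sigma2 = net$vectors$sigma2,
                  sigma_mn = net$vectors$sigma_mn),
    class = c("psychometric_curve", "data.frame"))
}

#' @export
plot.psychometric_curve <- function(x, ...) {
  graphics::plot(x$c_bar, x$proportion_positive, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "mean stimulus strength",
                 ylab = "proportion positive", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Stimulus strength at which a psychometric curve crosses 0.5
#'
#' Linear interpolation between the two grid points bracketing 0.5; returns
#' \code{NA} when the curve never crosses.
#'
#' @param curve a \code{"psychometric_curve"}.
#' @return A single number or \code{NA}.
#' @export
threshold_estimate <- function(curve) {
  p <- curve$proportion_positive
  cb <- curve$c_bar
  i <- which(p[-1] >= 0.5 & p[-length(p)] < 0.5)
  if (!length(i)) {
    if (all(p >= 0.5) || all(p < 0.5)) return(NA_real_)
    i <- which.min(abs(p - 0.5))
    return(cb[i])
  }
  i <- i[1]
  cb[i] + (0.5 - p[i]) * (cb[i + 1] - cb[i]) / (p[i + 1] - p[i])
}
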