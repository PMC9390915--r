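#' Firing-rate network model
#'
#' A recurrent network of \eqn{N} rate units with hyperbolic-tangent transfer,
#' evolving as
#' \deqn{\tau \dot x_i = -x_i + \sum_j W_{ij}\,\tanh(x_j) + I_i u(t),}
#' where \code{W[i, j]} couples unit \code{j} onto unit \code{i}, \code{I} is a
#' feedforward input pattern and \code{u(t)} a scalar input signal. Sparse
#' coupling matrices are stored in compressed form internally so that
#' simulation cost scales with the number of non-zero connections.
#'
#' @param W coupling matrix: a \code{"weight_matrix"} or plain square matrix.
#' @param I optional feedforward input pattern (length-\code{N} vector).
#' @param tau time constant of the single-unit dynamics, in ms.
#' @return A \code{"network_model"} object.
#' @seealso [simulate.network_model()], [find_fixed_point()]
#' @export
network_model <- function(W, I = NULL, tau = 100) {
  vectors <- if (inherits(W, "weight_matrix")) W$vectors
  provenance <- if (inherits(W, "weight_matrix")) W$provenance else "custom"
  Wm <- as_matrix(W)
  if (nrow(Wm) != ncol(Wm)) stop("`W` must be square", call. = FALSE)
  N <- nrow(Wm)
  tau <- check_scalar(tau)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (!is.null(I)) {
    if (!is.numeric(I) || length(I) != N)
      stop("`I` must be a numeric vector of length N", call. = FALSE)
  }
  # compressed storage pays off when most entries are structural zeros
  density <- mean(Wm != 0)
  W_op <- if (density < 0.3)
    methods::as(Matrix::Matrix(Wm, sparse = TRUE), "generalMatrix")
  else Wm
  structure(
    list(W = Wm, W_op = W_op, I = I, tau = tau, N = N,
         vectors = vectors, provenance = provenance),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("Rate network: N = %d, tau = %g ms, coupling = %s\n",
              x$N, x$tau, x$provenance))
  if (!is.null(x$vectors))
    cat(sprintf("  rank-one structure: sigma2 = %g, sigma_mn = %g\n",
                x$vectors$sigma2, x$vectors$sigma_mn))
  if (!is.null(x$I)) cat("  feedforward input pattern present\n")
  invisible(x)
}

#' @export
summary.network_model <- function(object, ...) {
  print(object)
  cat(sprintf("  coupling density = %.3f\n", mean(object$W != 0)))
  invisible(object)
}

# One forward-Euler pass. u is a vector of per-step input magnitudes
# (length nt) or NULL; returns the (nt/thin + 1) x N state record.
euler_run <- function(model, x0, nt, dt, u = NULL, noise_std = 0, thin = 1L) {
  N <- model$N
  tau <- model$tau
  W <- model$W_op
  Ivec <- model$I %||% numeric(N)
  x <- x0
  n_rec <- nt %/% thin + 1L
  out <- matrix(NA_real_, n_rec, N)
  out[1L, ] <- x
  rec <- 1L
  a <- dt / tau
  b <- noise_std * sqrt(dt / tau)
  for (k in seq_len(nt)) {
    drive <- as.numeric(W %*% tanh(x))
    if (!is.null(u) && u[k] != 0) drive <- drive + Ivec * u[k]
    x <- x + a * (drive - x)
    if (b > 0) x <- x + b * stats::rnorm(N)
    if (k %% thin == 0L) {
      if (any(!is.finite(x)))
        stop(sprintf("state diverged at step %d (t = %g ms)", k, k * dt),
             call. = FALSE)
      rec <- rec + 1L
      out[rec, ] <- x
    }
  }
  out
}

resolve_x0 <- function(model, x0) {
  N <- model$N
  if (is.character(x0)) {
    switch(x0,
      zero = numeric(N),
      random = stats::rnorm(N),
      lower_fixed_point =
        find_fixed_point(model, sign = -1)$state,
      stop(sprintf("unknown initial-state preset '%s'", x0), call. = FALSE))
  } else {
    if (!is.numeric(x0) || length(x0) != N)
      stop("`x0` must be a preset name or length-N vector", call. = FALSE)
    as.numeric(x0)
  }
}

resolve_input <- function(input, nt, dt) {
  if (is.null(input)) return(NULL)
  if (is.function(input)) return(vapply(seq_len(nt) * dt - dt, input, 0))
  if (is.numeric(input) && length(input) == 1L) return(rep(input, nt))
  if (is.numeric(input) && length(input) == nt) return(as.numeric(input))
  stop("`input` must be NULL, a scalar, a function of t, or a length-nt vector",
       call. = FALSE)
}

#' Simulate a firing-rate network
#'
#' Integrates the network dynamics with the forward-Euler scheme. With noise
#' the update uses Euler--Maruyama scaling: per-unit white noise of standard
#' deviation \code{noise_std * sqrt(dt/tau)} is added each step.
#'
#' @param object a \code{"network_model"}.
#' @param nsim number of trajectories; when larger than 1 a list of
#'   trajectories is returned.
#' @param seed optional seed passed to \code{set.seed()}.
#' @param duration total simulated time (ms).
#' @param dt integration step (ms); must not exceed \code{tau/10}.
#' @param x0 initial state: a length-N vector or one of the presets
#'   \code{"zero"}, \code{"random"} (iid standard normal),
#'   \code{"lower_fixed_point"}.
#' @param input scalar input signal \code{u(t)}: \code{NULL} (autonomous), a
#'   constant, a function of time, or a vector with one value per step.
#' @param noise_std per-unit white-noise amplitude (0 = deterministic).
#' @param thin record every \code{thin}-th step (the initial state is always
#'   recorded).
#' @param ... unused.
#' @return An \code{"lr_trajectory"}: list with \code{times} (ms), the
#'   time-by-unit activation matrix \code{x}, the input record \code{u}, and
#'   the model.
#' @examples
#' set.seed(3)
#' net <- network_model(gaussian_matrix(100, g = 0.5), tau = 100)
#' tr  <- simulate(net, duration = 1000, x0 = "random")
#' max(abs(tr$x[nrow(tr$x), ]))  # decays: whole spectrum inside unit disk
#' @export
simulate.network_model <- function(object, nsim = 1, seed = NULL,
                                   duration = 10 * object$tau,
                                   dt = object$tau / 20,
                                   x0 = "zero", input = NULL, noise_std = 0,
                                   thin = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  dt <- check_scalar(dt)
  if (dt <= 0 || dt > object$tau / 10)
    stop("`dt` must be positive and at most tau/10", call. = FALSE)
  duration <- check_scalar(duration)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  noise_std <- check_scalar(noise_std, min = 0)
  thin <- check_count(thin)
  nt <- max(1L, round(duration / dt))
  u <- resolve_input(input, nt, dt)
  if (!is.null(u) && is.null(object$I))
    stop("model has no input pattern `I` but an input signal was given",
         call. = FALSE)
  one <- function() {
    xinit <- resolve_x0(object, x0)
    xrec <- euler_run(object, xinit, nt, dt, u, noise_std, thin)
    structure(
      list(times = seq(0L, nt %/% thin) * (dt * thin),
           x = xrec, u = u, dt = dt, model = object),
      class = "lr_trajectory")
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
print.lr_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: N = %d units, %d samples over %g ms\n",
              ncol(x$x), nrow(x$x), max(x$times)))
  invisible(x)
}

#' @export
plot.lr_trajectory <- function(x, units = seq_len(min(8, ncol(x$x))), ...) {
  graphics::matplot(x$times, x$x[, units, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "activation x_i", ...)
  invisible(x)
}

traj_matrix <- function(traj) {
  if (inherits(traj, "lr_trajectory")) traj$x
  else if (is.matrix(traj)) traj
  else stop("expected an `lr_trajectory` or a time-by-unit matrix",
            call. = FALSE)
}

#' Latent-variable projections of a trajectory
#'
#' Projects the population activity onto the axes that organise rank-one
#' dynamics:
#' \deqn{\kappa_r(t) = m^T x(t) / \lVert m \rVert^2, \quad
#'       \kappa_I(t) = I^T x(t) / \lVert I \rVert^2, \quad
#'       \kappa_{rec}(t) = \frac{1}{N} \sum_j n_j \tanh(x_j(t)).}
#' \eqn{\kappa_r} measures structure along the right connectivity vector,
#' \eqn{\kappa_I} the component along the input pattern, and
#' \eqn{\kappa_{rec}} the recurrent drive (which equals \eqn{\kappa_r} at any
#' equilibrium of the dense rank-one network).
#'
#' @param traj an \code{"lr_trajectory"} or time-by-unit matrix.
#' @param m,I,n the projection vectors; default to the model's connectivity
#'   vectors and input pattern when available. \code{I} may be omitted
#'   (\code{kappa_I} is then absent); \code{m} and \code{I}, when given, must
#'   have non-zero norm.
#' @return A \code{"latent_trajectory"}: list with \code{times},
#'   \code{kappa_r}, \code{kappa_I} (possibly \code{NULL}), \code{kappa_rec}.
#' @export
latent_projections <- function(traj, m = NULL, I = NULL, n = NULL) {
  x <- traj_matrix(traj)
  if (inherits(traj, "lr_trajectory")) {
    m <- m %||% traj$model$vectors$m
    n <- n %||% traj$model$vectors$n
    I <- I %||% traj$model$I
  }
  if (is.null(m) || sum(m^2) == 0)
    stop("`m` is missing or has zero norm", call. = FALSE)
  if (!is.null(I) && sum(I^2) == 0)
    stop("`I` has zero norm", call. = FALSE)
  N <- ncol(x)
  kr <- as.numeric(x %*% m) / sum(m^2)
  ki <- if (!is.null(I)) as.numeric(x %*% I) / sum(I^2)
  krec <- if (!is.null(n)) as.numeric(tanh(x) %*% n) / N
  structure(
    list(times = if (inherits(traj, "lr_trajectory")) traj$times,
         kappa_r = kr, kappa_I = ki, kappa_rec = krec),
    class = "latent_trajectory")
}

#' Participation ratio of a trajectory
#'
#' Effective dimensionality \eqn{(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2}
#' of the eigenvalues \eqn{\lambda_i} of the covariance matrix of activations
#' over time. Equals 1 for activity along a single fixed direction and \eqn{d}
#' for isotropic activity in \eqn{d} dimensions.
#'
#' @param traj an \code{"lr_trajectory"} or time-by-unit matrix with at least
#'   two time samples and non-zero total variance.
#' @return A single number in \code{[1, N]}.
#' @export
participation_ratio <- function(traj) {
  x <- traj_matrix(traj)
  if (nrow(x) < 2) stop("need at least two time samples", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  # covariance eigenvalues via singular values of the centred data
  sv <- svd(xc, nu = 0, nv = 0)$d
  lam <- sv^2 / (nrow(x) - 1)
  if (sum(lam) == 0) stop("trajectory has zero variance", call. = FALSE)
  sum(lam)^2 / sum(lam^2)
}

#' Principal-component structure and alignment of a trajectory
#'
#' PCA of the activations over time: variance fractions of the leading
#' components and the absolute cosine similarity of each component with the
#' (unit-normalised) right connectivity vector \code{m} and input pattern
#' \code{I}.
#'
#' @param traj an \code{"lr_trajectory"} or time-by-unit matrix.
#' @param m,I reference directions; default to the model's vectors.
#' @param k number of leading components to report.
#' @return A \code{"dimensionality_report"}: list with
#'   \code{participation_ratio}, \code{variance_fractions} (length \code{k},
#'   non-increasing), and \code{alignment}, a \code{k x 2} matrix of absolute
#'   cosines with columns \code{m} and \code{I}.
#' @export
pca_alignment <- function(traj, m = NULL, I = NULL, k = 3) {
  x <- traj_matrix(traj)
  if (inherits(traj, "lr_trajectory")) {
    m <- m %||% traj$model$vectors$m
    I <- I %||% traj$model$I
  }
  k <- check_count(k)
  if (k > ncol(x)) stop("`k` must not exceed N", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 0, nv = min(k, nrow(x)))
  lam <- sv$d^2
  fractions <- numeric(k)
  nz <- min(k, length(lam))
  if (sum(lam) > 0) fractions[seq_len(nz)] <- lam[seq_len(nz)] / sum(lam)
  pcs <- sv$v  # N x nv, orthonormal columns
  cosine <- function(v) {
    if (is.null(v)) return(rep(NA_real_, k))
    v <- v / sqrt(sum(v^2))
    out <- rep(NA_real_, k)
    out[seq_len(ncol(pcs))] <- abs(as.numeric(crossprod(pcs, v)))
    out
  }
  structure(
    list(participation_ratio = participation_ratio(x),
         variance_fractions = fractions,
         alignment = cbind(m = cosine(m), I = cosine(I))),
    class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat(sprintf("Dimensionality: participation ratio = %.3f\n",
              x$participation_ratio))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions), collapse = " "), "\n")
  invisible(x)
}

#' Locate an autonomous fixed point by relaxation
#'
#' Integrates the autonomous dynamics from a small perturbation
#' \code{sign * eps * direction} off the origin until the state velocity drops
#' below tolerance, returning the equilibrium and its projection
#' \eqn{\kappa_r} on \code{direction}. For a bistable rank-one network the two
#' signs converge to the two non-trivial fixed points; when the whole spectrum
#' lies inside the unit disk the result is the origin.
#'
#' @param model a \code{"network_model"} (the input signal is held at zero).
#' @param direction perturbation direction; defaults to the model's \code{m}.
#' @param sign +1 or -1, selecting the branch.
#' @param eps perturbation amplitude relative to \code{direction}.
#' @param dt integration step (ms).
#' @param tol convergence tolerance on \code{max |dx/dt|} (per ms).
#' @param t_max maximum integration time before a non-convergence error.
#' @return List with \code{state} (length-N vector), \code{kappa_r}, and the
#'   relaxation time \code{t}.
#' @export
find_fixed_point <- function(model, direction = NULL, sign = 1, eps = 1e-2,
                             dt = model$tau / 20, tol = 1e-6,
                             t_max = 500 * model$tau) {
  stopifnot(inherits(model, "network_model"))
  direction <- direction %||% model$vectors$m
  if (is.null(direction))
    stop("no `direction` given and the model carries no vectors",
         call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  W <- model$W_op
  tau <- model$tau
  x <- sign * eps * direction
  t <- 0
  a <- dt / tau
  repeat {
    deriv <- (as.numeric(W %*% tanh(x)) - x) / tau
    if (max(abs(deriv)) < tol) break
    x <- x + a * (as.numeric(W %*% tanh(x)) - x)
    t <- t + dt
    if (any(!is.finite(x)))
      stop(sprintf("state diverged at t = %g ms", t), call. = FALSE)
    if (t > t_max)
      stop(sprintf("fixed point not reached within t_max = %g ms", t_max),
           call. = FALSE)
  }
  m <- model$vectors$m %||% direction
  list(state = x, kappa_r = sum(m * x) / sum(m^2), t = t)
}

#' Draw an input pattern with prescribed overlap with n
#'
#' Generates a feedforward pattern \code{I} with unit entry variance and
#' population covariance \code{sigma_nI} with the left connectivity vector
#' \code{n}, via \eqn{I = (\sigma_{nI}/\sigma^2)\, n + b\, w} with \code{w}
#' standard normal and \eqn{b} chosen so that \eqn{Var(I_i) = 1}. Requires
#' \eqn{\sigma_{nI}^2 \le \sigma^2}.
#'
#' @param vectors a \code{"connectivity_vectors"} object supplying \code{n}.
#' @param sigma_nI target covariance between entries of \code{I} and \code{n}.
#' @return A length-N numeric vector.
#' @export
draw_input_pattern <- function(vectors, sigma_nI) {
  stopifnot(inherits(vectors, "connectivity_vectors"))
  sigma_nI <- check_scalar(sigma_nI)
  s2 <- vectors$sigma2
  if (s2 <= 0 || sigma_nI^2 > s2)
    stop("need sigma_nI^2 <= sigma2 and sigma2 > 0", call. = FALSE)
  a <- sigma_nI / s2
  b <- sqrt(1 - sigma_nI^2 / s2)
  a * vectors$n + b * stats::rnorm(vectors$N)
}

#' Step input signal
#'
#' Convenience constructor for a rectangular input pulse \code{u(t)}.
#'
#' @param onset,offset window limits in ms.
#' @param amplitude pulse height.
#' @return A function of time suitable for the \code{input} argument of
#'   [simulate.network_model()].
#' @export
step_input <- function(onset, offset, amplitude = 1) {
  force(onset); force(offset); force(amplitude)
  function(t) if (t >= onset && t < offset) amplitude else 0
}
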