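#' Classify the autonomous dynamical regime from spectral theory
#'
#' The fate of the autonomous dynamics is set by which spectral component, if
#' any, crosses the instability of the zero fixed point at unity:
#' \describe{
#'   \item{\code{"decaying"}}{both outlier \eqn{\lambda_1} and bulk radius
#'     \eqn{R} are at most 1; all activity relaxes to zero.}
#'   \item{\code{"structured_stationary"}}{\eqn{\lambda_1 > 1} and
#'     \eqn{\lambda_1 \ge R}; the outlier leads the instability, producing
#'     bistable stationary activity aligned with \code{m}. Ties
#'     \eqn{\lambda_1 = R > 1} are labelled structured, since chaos requires
#'     the bulk to surpass the outlier.}
#'   \item{\code{"chaotic"}}{\eqn{R > 1} and \eqn{R > \lambda_1}; the bulk
#'     leads, producing high-dimensional irregular fluctuations.}
#' }
#'
#' @param theory a \code{"spectral_theory"} object, or a single numeric
#'   outlier value (with \code{bulk_radius} supplied).
#' @param bulk_radius bulk radius when \code{theory} is numeric.
#' @return One of \code{"decaying"}, \code{"structured_stationary"},
#'   \code{"chaotic"}.
#' @export
classify_regime <- function(theory, bulk_radius = NULL) {
  if (inherits(theory, "spectral_theory")) {
    lambda1 <- theory$outlier
    R <- theory$bulk_radius
  } else {
    lambda1 <- check_scalar(theory)
    R <- check_scalar(bulk_radius, min = 0)
  }
  if (max(lambda1, R) <= 1) "decaying"
  else if (lambda1 >= R) "structured_stationary"
  else "chaotic"
}

#' Phase diagram of dynamical regimes over the variance-covariance plane
#'
#' Labels every cell of a \eqn{(\sigma^2, \sigma_{mn})} grid using the
#' rescaled-branch spectral theory (outlier \eqn{\lambda_1 = C \sigma_{mn}},
#' bulk radius \eqn{R = \sigma^2 \sqrt{C (N - C)/N}}) and records the three
#' analytic boundary curves:
#' outlier instability \eqn{\sigma_{mn} = 1/C}; bulk instability
#' \eqn{\sigma^2 = 1 / \sqrt{C(N-C)/N}}; structured-to-chaotic transition
#' \eqn{C\sigma_{mn} = \sigma^2\sqrt{C(N-C)/N}}.
#'
#' @param sigma2_grid,sigma_mn_grid positive numeric grids.
#' @param C connections kept per unit.
#' @param N network size (\code{C <= N}).
#' @return A \code{"phase_diagram"}: list with a data frame \code{cells}
#'   (columns \code{sigma2}, \code{sigma_mn}, \code{outlier}, \code{radius},
#'   \code{label}), a \code{boundaries} list, and \code{C}, \code{N}.
#' @examples
#' pd <- phase_diagram(seq(0.01, 0.15, length = 30),
#'                     seq(0.0005, 0.01, length = 30), C = 200, N = 1000)
#' table(pd$cells$label)
#' @export
phase_diagram <- function(sigma2_grid, sigma_mn_grid, C, N) {
  C <- check_count(C)
  N <- check_count(N, 2L)
  if (C > N) stop("`C` must not exceed `N`", call. = FALSE)
  if (any(sigma2_grid < 0) || any(sigma_mn_grid < 0))
    stop("grids must be non-negative", call. = FALSE)
  cells <- expand.grid(sigma2 = sigma2_grid, sigma_mn = sigma_mn_grid,
                       KEEP.OUT.ATTRS = FALSE)
  geom <- sqrt(C * (N - C) / N)
  cells$outlier <- C * cells$sigma_mn
  cells$radius <- cells$sigma2 * geom
  cells$label <- mapply(classify_regime, cells$outlier, cells$radius)
  boundaries <- list(
    outlier_instability = list(sigma_mn = 1 / C),
    bulk_instability = list(sigma2 = if (geom > 0) 1 / geom else Inf),
    structured_chaotic = list(slope_sigma_mn_per_sigma2 = geom / C))
  structure(list(cells = cells, boundaries = boundaries, C = C, N = N),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: C = %d, N = %d, %d cells\n",
              x$C, x$N, nrow(x$cells)))
  print(table(x$cells$label))
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  s2 <- sort(unique(x$cells$sigma2))
  smn <- sort(unique(x$cells$sigma_mn))
  lv <- c("decaying", "structured_stationary", "chaotic")
  z <- matrix(match(x$cells$label, lv), length(s2), length(smn))
  graphics::image(s2, smn, z, col = c("grey85", "steelblue", "firebrick"),
                  xlab = expression(sigma^2), ylab = expression(sigma[mn]),
                  ...)
  graphics::abline(h = x$boundaries$outlier_instability$sigma_mn, lty = 2)
  graphics::abline(v = x$boundaries$bulk_instability$sigma2, lty = 2)
  graphics::abline(0, x$boundaries$structured_chaotic$slope_sigma_mn_per_sigma2,
                   lty = 3)
  invisible(x)
}

#' Diagnose the dynamical regime from a simulated trajectory
#'
#' Operational classification of a sufficiently long autonomous simulation:
#' \code{"decaying"} when the terminal activity has dropped below an
#' amplitude floor; \code{"structured_stationary"} when \eqn{\kappa_r}
#' settles to a non-zero constant (temporal coefficient of variation below
#' \code{cv_tol} over the analysis window); \code{"chaotic"} otherwise
#' (sustained irregular activity). The analysis window is the final
#' \code{window_frac} of the trajectory, so the leading transient is ignored.
#'
#' @param traj an autonomous \code{"lr_trajectory"} covering at least
#'   \code{min_duration} time constants.
#' @param latents optional \code{"latent_trajectory"}; computed from the
#'   model's vectors when omitted.
#' @param activity_floor RMS activation below which activity counts as
#'   decayed.
#' @param cv_tol stationarity threshold on \code{sd/|mean|} of
#'   \eqn{\kappa_r}.
#' @param window_frac fraction of the trajectory (from the end) analysed.
#' @param min_duration minimum trajectory length in units of \code{tau}.
#' @return A regime label, as in [classify_regime()].
#' @export
empirical_regime <- function(traj, latents = NULL, activity_floor = 1e-3,
                             cv_tol = 0.05, window_frac = 0.5,
                             min_duration = 50) {
  stopifnot(inherits(traj, "lr_trajectory"))
  tau <- traj$model$tau
  if (max(traj$times) < min_duration * tau)
    stop(sprintf("trajectory must cover at least %g tau", min_duration),
         call. = FALSE)
  nt <- nrow(traj$x)
  idx <- seq.int(ceiling(nt * (1 - window_frac)) + 1L, nt)
  # decay check on the terminal tenth, after any slow relaxation
  tail_idx <- seq.int(max(1L, nt - max(2L, nt %/% 10)), nt)
  rms_tail <- sqrt(mean(traj$x[tail_idx, ]^2))
  if (rms_tail < activity_floor) return("decaying")
  latents <- latents %||% latent_projections(traj)
  kr <- latents$kappa_r[idx]
  mu <- mean(kr)
  if (abs(mu) > activity_floor && stats::sd(kr) / abs(mu) < cv_tol)
    "structured_stationary"
  else
    "chaotic"
}
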