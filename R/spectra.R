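#' Circular-law spectral radius of a sparsified Gaussian matrix
#'
#' For a Gaussian coupling matrix with entry variance \eqn{g^2/N}, removing a
#' fraction \code{s} of connections at random leaves iid entries of variance
#' \eqn{(1-s) g^2 / N}, so by the circular law the spectral radius is
#' \deqn{R = g \sqrt{1 - s}.}
#' The fixed-degree form \eqn{g\sqrt{C/N}} is obtained by passing
#' \code{s = 1 - C/N}.
#'
#' @param g coupling strength (non-negative).
#' @param s degree of sparsity in \code{[0, 1]}.
#' @return The predicted radius, a single number.
#' @export
theory_gaussian_radius <- function(g, s) {
  g <- check_scalar(g, min = 0)
  s <- check_scalar(s, min = 0, max = 1)
  g * sqrt(1 - s)
}

#' Eigenvalue outlier of a sparsified rank-one matrix
#'
#' The rank-one structure survives random sparsification as a spectral
#' "backbone": \code{m} remains (asymptotically) a right eigenvector, with the
#' associated real eigenvalue reduced by the fraction of surviving
#' connections.
#' \describe{
#'   \item{scaled branch (\code{rescaled = FALSE})}{\eqn{\lambda_1 =
#'     (1-s)\,\sigma_{mn}}, equivalently \eqn{C \sigma_{mn} / N} when sparsity
#'     is imposed by keeping \code{C} connections per unit.}
#'   \item{rescaled branch (\code{rescaled = TRUE})}{for the matrix without
#'     the \eqn{1/N} scaling, \eqn{\lambda_1 = C\,\sigma_{mn}}, independent of
#'     both \eqn{s} and \eqn{N}.}
#' }
#'
#' @param sigma_mn covariance of the connectivity vectors.
#' @param s degree of sparsity (scaled branch; ignored when \code{C} and
#'   \code{N} are supplied).
#' @param C connections kept per unit (required for the rescaled branch).
#' @param N network size (with \code{C}, implies \code{s = 1 - C/N} on the
#'   scaled branch).
#' @param rescaled logical; use the rescaled (no \eqn{1/N}) convention.
#' @return Predicted outlier location on the real axis.
#' @examples
#' theory_rank_one_outlier(0.04, C = 200, rescaled = TRUE)  # 8
#' theory_rank_one_outlier(4, s = 0.5)                      # 2
#' @export
theory_rank_one_outlier <- function(sigma_mn, s = NULL, C = NULL, N = NULL,
                                    rescaled = FALSE) {
  sigma_mn <- check_scalar(sigma_mn)
  rescaled <- check_flag(rescaled)
  if (rescaled) {
    if (is.null(C))
      stop("the rescaled branch requires `C`", call. = FALSE)
    C <- check_count(C)
    return(C * sigma_mn)
  }
  if (!is.null(C) && !is.null(N)) {
    C <- check_count(C); N <- check_count(N, 2L)
    if (C > N) stop("`C` must not exceed `N`", call. = FALSE)
    s <- 1 - C / N
  }
  if (is.null(s)) stop("supply `s`, or `C` and `N`", call. = FALSE)
  s <- check_scalar(s, min = 0, max = 1)
  (1 - s) * sigma_mn
}

#' Bulk spectral radius of a sparsified rank-one matrix
#'
#' Sparsification of a rank-one matrix induces, besides the outlier, a
#' continuous bulk of eigenvalues around the origin. Its radius follows the
#' circular law applied to the deflated matrix (the sparse matrix minus its
#' rank-one mean, which carries the bulk but not the outlier):
#' \describe{
#'   \item{scaled branch}{\eqn{R = \sigma^2 \sqrt{s(1-s)/N}}; non-monotonic in
#'     \code{s}, maximal at \code{s = 0.5}, vanishing at \code{s = 0} and
#'     \code{s = 1}.}
#'   \item{rescaled branch}{\eqn{R = \sigma^2 \sqrt{C (N - C) / N}} with
#'     \code{C = (1-s) N}; approaches \eqn{\sigma^2 \sqrt{C}} as
#'     \eqn{N \to \infty} at fixed \code{C}.}
#' }
#'
#' @param sigma2 variance of the connectivity-vector entries.
#' @param s degree of sparsity (scaled branch; alternative to \code{C}).
#' @param N network size.
#' @param C connections kept per unit (implies \code{s = 1 - C/N}).
#' @param rescaled logical; use the rescaled convention.
#' @return Predicted bulk radius (non-negative).
#' @examples
#' theory_rank_one_bulk_radius(0.1, N = 2000, C = 60, rescaled = TRUE)  # 0.763
#' @export
theory_rank_one_bulk_radius <- function(sigma2, s = NULL, N = NULL, C = NULL,
                                        rescaled = FALSE) {
  sigma2 <- check_scalar(sigma2, min = 0)
  rescaled <- check_flag(rescaled)
  if (is.null(N)) stop("`N` is required", call. = FALSE)
  N <- check_count(N, 2L)
  if (!is.null(C)) {
    C <- check_count(C)
    if (C > N) stop("`C` must not exceed `N`", call. = FALSE)
    s <- 1 - C / N
  }
  if (is.null(s)) stop("supply `s` or `C`", call. = FALSE)
  s <- check_scalar(s, min = 0, max = 1)
  if (rescaled) {
    C <- (1 - s) * N
    sigma2 * sqrt(C * (N - C) / N)
  } else {
    sigma2 * sqrt(s * (1 - s) / N)
  }
}

#' Analytic spectral summary of a connectivity ensemble
#'
#' Bundles the predicted outlier and bulk radius for a parameter point, in any
#' of the three branches (\code{"gaussian"}, \code{"rank_one_scaled"},
#' \code{"rank_one_rescaled"}). Gaussian matrices have no structural outlier
#' (\code{outlier = 0}).
#'
#' @param branch connectivity branch.
#' @param g,sigma2,sigma_mn,s,C,N ensemble parameters; see
#'   [theory_gaussian_radius()], [theory_rank_one_outlier()],
#'   [theory_rank_one_bulk_radius()].
#' @return A \code{"spectral_theory"} object: list with \code{outlier},
#'   \code{bulk_radius} and the inputs used.
#' @export
spectral_theory <- function(branch = c("rank_one_rescaled", "rank_one_scaled",
                                       "gaussian"),
                            g = NULL, sigma2 = NULL, sigma_mn = NULL,
                            s = NULL, C = NULL, N = NULL) {
  branch <- match.arg(branch)
  if (branch == "gaussian") {
    out <- list(outlier = 0,
                bulk_radius = theory_gaussian_radius(g, s %||%
                                                       (1 - C / N)))
  } else {
    rescaled <- branch == "rank_one_rescaled"
    out <- list(
      outlier = theory_rank_one_outlier(sigma_mn, s = s, C = C, N = N,
                                        rescaled = rescaled),
      bulk_radius = theory_rank_one_bulk_radius(sigma2, s = s, N = N, C = C,
                                                rescaled = rescaled))
  }
  structure(c(out, list(branch = branch, g = g, sigma2 = sigma2,
                        sigma_mn = sigma_mn, s = s, C = C, N = N)),
            class = "spectral_theory")
}

#' @export
print.spectral_theory <- function(x, ...) {
  cat(sprintf(
    "Spectral theory (%s): outlier = %.4g, bulk radius = %.4g\n",
    x$branch, x$outlier, x$bulk_radius))
  invisible(x)
}

#' Eigenvalue spectrum of a coupling matrix
#'
#' Dense (LAPACK) eigendecomposition; returns all \code{N} complex
#' eigenvalues. For real matrices non-real eigenvalues come in conjugate
#' pairs.
#'
#' @param W a \code{"weight_matrix"} or plain square numeric matrix.
#' @return Complex vector of length \code{N}.
#' @export
compute_spectrum <- function(W) {
  W <- as_matrix(W)
  if (nrow(W) != ncol(W)) stop("matrix must be square", call. = FALSE)
  if (any(!is.finite(W))) stop("matrix has non-finite entries", call. = FALSE)
  ev <- eigen(W, only.values = TRUE)$values
  as.complex(ev)
}

#' Separate the spectral outlier from the bulk
#'
#' Identifies the eigenvalue with largest real part as a candidate outlier and
#' declares it measurable only when it is separable from the rest of the
#' spectrum: its real part must exceed the largest modulus among the remaining
#' eigenvalues (by a configurable relative margin, default strictly greater).
#' When no separable outlier exists -- for instance when theory places the
#' outlier inside the bulk, where its location cannot be measured -- the bulk
#' radius is taken over the full spectrum.
#'
#' @param spectrum complex vector of eigenvalues.
#' @param theory optional \code{"spectral_theory"} to attach for comparison.
#' @param margin relative separation margin: the candidate is accepted when
#'   \code{Re(outlier) > (1 + margin) * max(Mod(rest))}. Default 0.
#' @return A \code{"spectral_report"}: list with \code{eigenvalues},
#'   \code{outlier_hat} (or \code{NA} when not measurable),
#'   \code{bulk_radius_hat}, \code{outlier_measurable}, \code{theory}.
#' @examples
#' est <- estimate_outlier_and_bulk(c(2 + 0i, 0.1i, -0.1i, 0.05 + 0i))
#' est$outlier_hat      # 2
#' est$bulk_radius_hat  # 0.1
#' @export
estimate_outlier_and_bulk <- function(spectrum, theory = NULL, margin = 0) {
  if (length(spectrum) == 0) stop("empty spectrum", call. = FALSE)
  spectrum <- as.complex(spectrum)
  margin <- check_scalar(margin, min = 0)
  i <- which.max(Re(spectrum))
  cand <- Re(spectrum[i])
  rest <- Mod(spectrum[-i])
  rest_max <- if (length(rest)) max(rest) else 0
  measurable <- length(rest) > 0 && cand > (1 + margin) * rest_max && cand > 0
  structure(
    list(eigenvalues = spectrum,
         outlier_hat = if (measurable) cand else NA_real_,
         bulk_radius_hat = if (measurable) rest_max else
           max(Mod(spectrum)),
         outlier_measurable = measurable,
         theory = theory),
    class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat(sprintf("Spectral report on %d eigenvalues:\n", length(x$eigenvalues)))
  if (x$outlier_measurable)
    cat(sprintf("  outlier  = %.4g\n", x$outlier_hat))
  else
    cat("  outlier  : not separable from bulk\n")
  cat(sprintf("  bulk radius = %.4g\n", x$bulk_radius_hat))
  if (!is.null(x$theory))
    cat(sprintf("  theory: outlier = %.4g, bulk radius = %.4g\n",
                x$theory$outlier, x$theory$bulk_radius))
  invisible(x)
}

#' Remove the rank-one outlier from a sparsified matrix
#'
#' Constructs the deflated matrix \eqn{\tilde P^* = \tilde P - (1-s) P},
#' where \eqn{P} is the dense rank-one matrix and \eqn{\tilde P} its
#' sparsified version. \code{m} remains an eigenvector but now with eigenvalue
#' (asymptotically) zero, while the remaining eigenvalue distribution -- the
#' bulk -- is unchanged. Entrywise,
#' \eqn{\tilde P^*_{ij} = P_{ij}(s - B_{ij})} with \eqn{B = 1 - X}, so the
#' entry variance is \eqn{\sigma^4 s (1-s) / N^2}; the circular law applied to
#' this variance yields the bulk-radius prediction.
#'
#' @param P_sparse the sparsified \code{"weight_matrix"}.
#' @param P_dense the dense matrix it was derived from.
#' @param s the degree of sparsity of the mask used.
#' @return A \code{"weight_matrix"} with provenance \code{"deflated"}.
#' @export
deflate_outlier <- function(P_sparse, P_dense, s) {
  Ws <- as_matrix(P_sparse)
  Wd <- as_matrix(P_dense)
  s <- check_scalar(s, min = 0, max = 1)
  if (!all(dim(Ws) == dim(Wd)))
    stop("matrix dimensions differ", call. = FALSE)
  vectors <- if (inherits(P_sparse, "weight_matrix")) P_sparse$vectors
  new_weight_matrix(Ws - (1 - s) * Wd, "deflated", vectors = vectors)
}
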