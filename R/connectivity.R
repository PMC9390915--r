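#' Draw a pair of correlated connectivity vectors
#'
#' Generates the right and left connectivity vectors \code{m} and \code{n} of a
#' rank-one recurrent network. Entries of each vector are marginally
#' \eqn{N(0, \sigma^2)} and pairs \eqn{(m_i, n_i)} have covariance
#' \eqn{\sigma_{mn}}, realised through the three-vector construction
#' \deqn{m = \sqrt{\sigma^2 - \sigma_{mn}}\, x + \sqrt{\sigma_{mn}}\, z, \qquad
#'       n = \sqrt{\sigma^2 - \sigma_{mn}}\, y + \sqrt{\sigma_{mn}}\, z,}
#' with \code{x}, \code{y}, \code{z} independent standard-normal vectors. The
#' shared component \code{z} gives \code{m} and \code{n} their overlap
#' \eqn{m^T n / N \to \sigma_{mn}} as \eqn{N} grows; this overlap sets the
#' location of the structural eigenvalue of the rank-one coupling matrix.
#'
#' Randomness comes from the R session RNG, so call \code{set.seed()} first for
#' reproducible draws.
#'
#' @param N number of units (integer, at least 2).
#' @param sigma2 variance \eqn{\sigma^2} of the entries of both vectors
#'   (non-negative).
#' @param sigma_mn covariance \eqn{\sigma_{mn}} between paired entries;
#'   must lie in \code{[0, sigma2]}. The degenerate value
#'   \code{sigma_mn == sigma2} gives \code{m == n}.
#' @return An object of class \code{"connectivity_vectors"}: a list with
#'   elements \code{m}, \code{n}, \code{N}, \code{sigma2}, \code{sigma_mn}.
#' @seealso [rank_one_matrix()], [overlap()]
#' @examples
#' set.seed(1)
#' cv <- connectivity_vectors(1000, sigma2 = 16, sigma_mn = 1.44)
#' overlap(cv)  # close to 1.44
#' @export
connectivity_vectors <- function(N, sigma2, sigma_mn) {
  N <- check_count(N, min = 2L)
  sigma2 <- check_scalar(sigma2, min = 0)
  sigma_mn <- check_scalar(sigma_mn)
  if (sigma_mn < 0 || sigma_mn > sigma2)
    stop("`sigma_mn` must lie in [0, sigma2]", call. = FALSE)
  x <- stats::rnorm(N)
  y <- stats::rnorm(N)
  z <- stats::rnorm(N)
  a <- sqrt(sigma2 - sigma_mn)
  b <- sqrt(sigma_mn)
  structure(
    list(m = a * x + b * z, n = a * y + b * z,
         N = N, sigma2 = sigma2, sigma_mn = sigma_mn),
    class = "connectivity_vectors")
}

#' Sample overlap of a connectivity-vector pair
#'
#' The normalised scalar product \eqn{m^T n / N}, the finite-size realisation
#' of the covariance \eqn{\sigma_{mn}}.
#'
#' @param vectors a \code{"connectivity_vectors"} object.
#' @return A single number.
#' @export
overlap <- function(vectors) {
  stopifnot(inherits(vectors, "connectivity_vectors"))
  sum(vectors$m * vectors$n) / vectors$N
}

#' @export
print.connectivity_vectors <- function(x, ...) {
  cat(sprintf(
    "Connectivity vectors (m, n): N = %d, sigma2 = %g, sigma_mn = %g\n",
    x$N, x$sigma2, x$sigma_mn))
  cat(sprintf("  sample overlap m'n/N = %.4f\n", overlap(x)))
  invisible(x)
}

new_weight_matrix <- function(W, provenance, vectors = NULL, mask = NULL,
                              g = NULL) {
  structure(
    list(W = W, provenance = provenance, vectors = vectors, mask = mask,
         g = g, N = nrow(W)),
    class = "weight_matrix")
}

#' Full-rank Gaussian coupling matrix
#'
#' An \eqn{N \times N} matrix with entries drawn iid from
#' \eqn{N(0, g^2/N)}; its eigenvalues fill (asymptotically uniformly) a disk
#' of radius \eqn{g} by the circular law. Convention: \code{W[i, j]} is the
#' weight from unit \code{j} onto unit \code{i}.
#'
#' @param N matrix dimension.
#' @param g coupling strength; entry variance is \code{g^2/N}.
#' @return A \code{"weight_matrix"} with provenance \code{"gaussian"}.
#' @examples
#' set.seed(1)
#' J <- gaussian_matrix(300, g = 1)
#' max(Mod(compute_spectrum(J)))  # close to 1
#' @export
gaussian_matrix <- function(N, g) {
  N <- check_count(N, min = 2L)
  g <- check_scalar(g, min = 0)
  W <- matrix(stats::rnorm(N * N, sd = g / sqrt(N)), N, N)
  new_weight_matrix(W, "gaussian", g = g)
}

#' Rank-one coupling matrix from connectivity vectors
#'
#' Builds the outer-product matrix in one of two scaling conventions:
#' \describe{
#'   \item{scaled (\code{rescaled = FALSE})}{\eqn{P_{ij} = m_i n_j / N}; the
#'     unique non-zero eigenvalue is \eqn{m^T n / N \approx \sigma_{mn}}.}
#'   \item{rescaled (\code{rescaled = TRUE})}{\eqn{P_{ij} = m_i n_j}; used in
#'     the high-sparsity limit where a fixed number \eqn{C} of connections per
#'     unit is kept while \eqn{N} grows, so that outlier and bulk stay finite.}
#' }
#'
#' @param vectors a \code{"connectivity_vectors"} object.
#' @param rescaled logical; drop the \eqn{1/N} weight scaling.
#' @return A \code{"weight_matrix"} with provenance \code{"rank_one_scaled"} or
#'   \code{"rank_one_rescaled"}.
#' @export
rank_one_matrix <- function(vectors, rescaled = FALSE) {
  stopifnot(inherits(vectors, "connectivity_vectors"))
  rescaled <- check_flag(rescaled)
  W <- outer(vectors$m, vectors$n)
  if (!rescaled) W <- W / vectors$N
  new_weight_matrix(
    W, if (rescaled) "rank_one_rescaled" else "rank_one_scaled",
    vectors = vectors)
}

#' Random sparsity mask
#'
#' A binary \eqn{N \times N} matrix used to zero a random subset of
#' connections. Three schemes:
#' \describe{
#'   \item{\code{"bernoulli"}}{each entry is 1 independently with probability
#'     \code{1 - s}, where \code{s} is the expected fraction of removed
#'     connections.}
#'   \item{\code{"fixed_in_degree"}}{exactly \code{C} ones per row: each unit
#'     keeps \code{C} incoming connections, chosen uniformly without
#'     replacement. This is the default convention for dynamics and task
#'     experiments, since in-degree governs the recurrent drive a unit
#'     receives.}
#'   \item{\code{"fixed_out_degree"}}{exactly \code{C} ones per column
#'     (outgoing connections per unit).}
#' }
#' For the fixed-degree schemes the implied sparsity is \code{s = 1 - C/N}.
#'
#' @param N mask dimension.
#' @param scheme one of \code{"bernoulli"}, \code{"fixed_in_degree"},
#'   \code{"fixed_out_degree"}.
#' @param s fraction of zeroed connections (Bernoulli scheme only), in
#'   \code{[0, 1]}.
#' @param C number of retained connections per unit (fixed-degree schemes),
#'   \code{1 <= C <= N}.
#' @return A \code{"sparsity_mask"}: list with the binary matrix \code{X},
#'   \code{scheme}, \code{s}, \code{C}, \code{N}.
#' @export
sparsity_mask <- function(N, scheme = c("bernoulli", "fixed_in_degree",
                                        "fixed_out_degree"),
                          s = NULL, C = NULL) {
  N <- check_count(N, min = 1L)
  scheme <- match.arg(scheme)
  if (scheme == "bernoulli") {
    if (is.null(s)) stop("bernoulli scheme requires `s`", call. = FALSE)
    s <- check_scalar(s, min = 0, max = 1)
    X <- matrix(as.numeric(stats::runif(N * N) >= s), N, N)
    C <- NULL
  } else {
    if (is.null(C)) stop("fixed-degree schemes require `C`", call. = FALSE)
    C <- check_count(C, min = 1L)
    if (C > N) stop("`C` must not exceed `N`", call. = FALSE)
    X <- matrix(0, N, N)
    if (scheme == "fixed_in_degree") {
      for (i in seq_len(N)) X[i, sample.int(N, C)] <- 1
    } else {
      for (j in seq_len(N)) X[sample.int(N, C), j] <- 1
    }
    s <- 1 - C / N
  }
  structure(list(X = X, scheme = scheme, s = s, C = C, N = N),
            class = "sparsity_mask")
}

#' @export
print.sparsity_mask <- function(x, ...) {
  cat(sprintf("Sparsity mask: N = %d, scheme = %s, s = %.4g%s\n",
              x$N, x$scheme, x$s,
              if (!is.null(x$C)) sprintf(", C = %d", x$C) else ""))
  invisible(x)
}

#' Sparsify a coupling matrix with a binary mask
#'
#' Elementwise (Hadamard) product of a weight matrix with a sparsity mask,
#' removing the masked fraction of connections. The mask and the original
#' provenance are recorded on the result.
#'
#' @param W a \code{"weight_matrix"}.
#' @param mask a \code{"sparsity_mask"} of matching dimension.
#' @return A \code{"weight_matrix"} whose entries are zero wherever the mask
#'   is zero.
#' @examples
#' set.seed(1)
#' cv <- connectivity_vectors(200, 16, 4)
#' P  <- rank_one_matrix(cv)
#' Ps <- sparsify(P, sparsity_mask(200, "bernoulli", s = 0.5))
#' @export
sparsify <- function(W, mask) {
  stopifnot(inherits(W, "weight_matrix"), inherits(mask, "sparsity_mask"))
  if (nrow(W$W) != mask$N)
    stop("matrix and mask dimensions differ", call. = FALSE)
  out <- new_weight_matrix(W$W * mask$X, W$provenance,
                           vectors = W$vectors, mask = mask, g = W$g)
  out
}

#' Dense rank-one plus Gaussian coupling matrix
#'
#' The composite connectivity \eqn{W = g\,\mathrm{Gaussian} + P} with
#' \eqn{P_{ij} = m_i n_j / N}: the classical dense control against which
#' sparsified rank-one networks are compared. Its spectrum has an outlier near
#' \eqn{\sigma_{mn}} and a circular bulk of radius \eqn{g}.
#'
#' @inheritParams rank_one_matrix
#' @param g strength of the Gaussian component (entry variance
#'   \code{g^2/N}).
#' @return A \code{"weight_matrix"} with provenance \code{"composite"}.
#' @export
composite_matrix <- function(vectors, g) {
  stopifnot(inherits(vectors, "connectivity_vectors"))
  g <- check_scalar(g, min = 0)
  N <- vectors$N
  W <- outer(vectors$m, vectors$n) / N
  if (g > 0) W <- W + matrix(stats::rnorm(N * N, sd = g / sqrt(N)), N, N)
  new_weight_matrix(W, "composite", vectors = vectors, g = g)
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Weight matrix: N = %d, provenance = %s\n", x$N, x$provenance))
  if (!is.null(x$mask))
    cat(sprintf("  sparsified: scheme = %s, s = %.4g\n",
                x$mask$scheme, x$mask$s))
  if (!is.null(x$vectors))
    cat(sprintf("  vectors: sigma2 = %g, sigma_mn = %g\n",
                x$vectors$sigma2, x$vectors$sigma_mn))
  invisible(x)
}
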