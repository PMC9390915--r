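# Plain-text array bundles: each object is a set of CSV arrays plus a JSON
# sidecar of parameters, so results remain portable and diffable.

write_array_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

read_array_csv <- function(path, vector = FALSE) {
  x <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(x) <- NULL
  if (vector) as.numeric(x) else x
}

#' Persist a weight matrix as a plain-text bundle
#'
#' Writes \code{<name>_W.csv} (and \code{<name>_m.csv}, \code{<name>_n.csv},
#' \code{<name>_X.csv} when present) plus a JSON sidecar
#' \code{<name>.json} with the generative parameters.
#'
#' @param wm a \code{"weight_matrix"}.
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @return Invisibly, the sidecar path.
#' @seealso [read_weight_bundle()]
#' @export
write_weight_bundle <- function(wm, dir, name) {
  stopifnot(inherits(wm, "weight_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_array_csv(wm$W, file.path(dir, paste0(name, "_W.csv")))
  meta <- list(name = name, N = wm$N, provenance = wm$provenance)
  if (!is.null(wm$vectors)) {
    write_array_csv(wm$vectors$m, file.path(dir, paste0(name, "_m.csv")))
    write_array_csv(wm$vectors$n, file.path(dir, paste0(name, "_n.csv")))
    meta$sigma2 <- wm$vectors$sigma2
    meta$sigma_mn <- wm$vectors$sigma_mn
  }
  if (!is.null(wm$mask)) {
    write_array_csv(wm$mask$X, file.path(dir, paste0(name, "_X.csv")))
    meta$scheme <- wm$mask$scheme
    meta$s <- wm$mask$s
    meta$C <- wm$mask$C
  }
  if (!is.null(wm$g)) meta$g <- wm$g
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read back a weight-matrix bundle
#'
#' @param dir directory holding the bundle.
#' @param name file-name stem used at write time.
#' @return A \code{"weight_matrix"} equivalent to the one written.
#' @export
read_weight_bundle <- function(dir, name) {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  W <- read_array_csv(file.path(dir, paste0(name, "_W.csv")))
  vectors <- NULL
  mpath <- file.path(dir, paste0(name, "_m.csv"))
  if (file.exists(mpath)) {
    vectors <- structure(
      list(m = read_array_csv(mpath, vector = TRUE),
           n = read_array_csv(file.path(dir, paste0(name, "_n.csv")),
                              vector = TRUE),
           N = meta$N, sigma2 = meta$sigma2, sigma_mn = meta$sigma_mn),
      class = "connectivity_vectors")
  }
  mask <- NULL
  xpath <- file.path(dir, paste0(name, "_X.csv"))
  if (file.exists(xpath)) {
    mask <- structure(
      list(X = read_array_csv(xpath), scheme = meta$scheme, s = meta$s,
           C = meta$C, N = meta$N),
      class = "sparsity_mask")
  }
  new_weight_matrix(W, meta$provenance, vectors = vectors, mask = mask,
                    g = meta$g)
}

#' Persist a trajectory as a plain-text bundle
#'
#' Writes the sample times, the activation record and (when the model carries
#' connectivity vectors) the latent time series as CSV files with a JSON
#' sidecar.
#'
#' @param traj an \code{"lr_trajectory"}.
#' @param dir output directory.
#' @param name file-name stem.
#' @return Invisibly, the sidecar path.
#' @export
write_trajectory_bundle <- function(traj, dir, name) {
  stopifnot(inherits(traj, "lr_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_array_csv(traj$times, file.path(dir, paste0(name, "_times.csv")))
  write_array_csv(traj$x, file.path(dir, paste0(name, "_x.csv")))
  if (!is.null(traj$model$vectors)) {
    lat <- latent_projections(traj)
    k <- cbind(kappa_r = lat$kappa_r,
               kappa_I = lat$kappa_I %||% rep(NA_real_, length(lat$kappa_r)),
               kappa_rec = lat$kappa_rec)
    utils::write.table(k, file.path(dir, paste0(name, "_latents.csv")),
                       sep = ",", row.names = FALSE, col.names = TRUE)
  }
  meta <- list(name = name, N = ncol(traj$x), samples = nrow(traj$x),
               dt = traj$dt, tau = traj$model$tau)
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
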