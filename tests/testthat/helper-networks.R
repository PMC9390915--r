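# Shared builders for small networks used across test files.

make_sparse_rescaled_net <- function(N, C, sigma2, sigma_mn, tau = 100) {
  cv <- connectivity_vectors(N, sigma2, sigma_mn)
  W <- sparsify(rank_one_matrix(cv, rescaled = TRUE),
                sparsity_mask(N, "fixed_in_degree", C = C))
  network_model(W, tau = tau)
}

make_dense_rank_one_net <- function(N, sigma2, sigma_mn, I = NULL,
                                    tau = 100) {
  cv <- connectivity_vectors(N, sigma2, sigma_mn)
  network_model(rank_one_matrix(cv), I = I, tau = tau)
}

# independent 1-D mean-field oracle for the autonomous fixed point of a dense
# scaled rank-one network: root of kappa = (1/N) sum_j n_j tanh(kappa m_j)
mean_field_kappa <- function(m, n, interval = c(1e-6, 100)) {
  f <- function(k) mean(n * tanh(k * m)) - k
  stats::uniroot(f, interval, tol = 1e-10)$root
}
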