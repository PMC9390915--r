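# internal validation helpers -------------------------------------------------

check_count <- function(x, min = 1L, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

check_scalar <- function(x, min = -Inf, max = Inf,
                         name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  as.numeric(x)
}

check_flag <- function(x, name = deparse(substitute(x))) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  x
}

# Coerce a weight_matrix | base matrix to a plain numeric matrix.
as_matrix <- function(W) {
  if (inherits(W, "weight_matrix")) W <- W$W
  if (inherits(W, "Matrix")) W <- as.matrix(W)
  if (!is.matrix(W) || !is.numeric(W))
    stop("expected a numeric matrix or a `weight_matrix`", call. = FALSE)
  W
}

# Deterministic per-instance seed stream derived from a base seed; stays well
# below 2^31 so it is always a valid `set.seed()` input.
derive_seed <- function(base_seed, index) {
  (as.integer(base_seed) %% 1000000L) * 1000L + (as.integer(index) %% 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
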