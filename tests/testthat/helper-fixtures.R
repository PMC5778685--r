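# small programmatic fixtures shared across test files

rand_vol <- function(d = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  vol3d(array(runif(prod(d)), d), spacing = spacing)
}

# mask with `n` foreground voxels at the start of the raster
mask_n <- function(n, d = c(4, 4, 4), spacing = c(1, 1, 1)) {
  a <- array(0, d)
  if (n > 0) a[seq_len(n)] <- 1
  vol3d(a, spacing = spacing)
}

# a clean (noise/bias/jitter-free) phantom reused by several tests
clean_phantom <- function(seed = 1, ...) {
  make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0,
                            max_translation = 0, max_rotation_deg = 0,
                            seed = seed, ...))
}

# small training set for classifier tests: two z-scored Gaussian blobs
blob_data <- function(n_per = 1000, sep = 3, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, sep), ncol = p),
             matrix(rnorm(n_per * p, 0), ncol = p))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = rep(c(1, 0), each = n_per))
}
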