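# Shared fixtures: small geometries/grids and independent oracles.

tiny_geometry <- function(n_elements = 16) {
  array_geometry(n_elements, pitch = 0.3, kerf = 0.06, center_frequency = 4)
}

tiny_grid <- function(geometry = tiny_geometry(), depth = c(15, 25),
                      spacing = geometry$wavelength / 2) {
  xmax <- max(abs(geometry$element_positions[, "x"]))
  image_grid(seq(-xmax, xmax, by = spacing), seq(depth[1], depth[2], by = spacing))
}

# make a bimage directly from a matrix of amplitudes
image_from_matrix <- function(m, dx = 0.1, dz = 0.1) {
  g <- image_grid(seq(0, by = dx, length.out = ncol(m)),
                  seq(1, by = dz, length.out = nrow(m)))
  bimage(pmax(m, 0), g, tag = "DAS")
}

# brute-force oracle: minimize w' H w over the probability simplex by
# exhaustive grid enumeration with the given step (3-lag instances only)
simplex_grid_min <- function(H, step = 0.01) {
  stopifnot(nrow(H) == 3)
  w1 <- seq(0, 1, by = step)
  grid <- expand.grid(w1 = w1, w2 = w1)
  grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
  W <- cbind(grid$w1, grid$w2, pmax(1 - grid$w1 - grid$w2, 0))
  obj <- rowSums((W %*% H) * W)
  list(value = min(obj), w = W[which.min(obj), ])
}

# a coherence-stack object built directly from an array (for unit tests that
# bypass channel simulation)
stack_from_array <- function(values, kernel_length = 8, grid = NULL) {
  if (is.null(grid)) {
    grid <- image_grid(seq(0, by = 0.1, length.out = dim(values)[2]),
                       seq(1, by = 0.1, length.out = dim(values)[1]))
  }
  structure(list(values = values, n_lags = dim(values)[3],
                 kernel_length = as.integer(kernel_length), grid = grid),
            class = "coherence_stack")
}
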