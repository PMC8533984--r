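# shared fixtures: coordinate grids, analytic fields, small cached datasets

grid_xy <- function(n) {
  list(X = matrix(seq_len(n), n, n, byrow = TRUE),
       Y = matrix(seq_len(n), n, n))
}

# smooth residue-free random phase: sum of a few broad gaussian bumps
random_smooth_phase <- function(n = 64, k = 4, peak = 6, seed = 1) {
  set.seed(seed)
  g <- grid_xy(n)
  ph <- matrix(0, n, n)
  for (i in seq_len(k)) {
    cx <- runif(1, 0.25 * n, 0.75 * n); cy <- runif(1, 0.25 * n, 0.75 * n)
    s <- runif(1, n / 6, n / 3); a <- runif(1, -peak, peak)
    ph <- ph + a * exp(-((g$X - cx)^2 + (g$Y - cy)^2) / (2 * s^2))
  }
  ph
}

vortex_phase <- function(n = 128, cx = 60.5, cy = 40.5) {
  g <- grid_xy(n)
  wrap_phase(atan2(g$Y - cy, g$X - cx))
}

disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- grid_xy(n)
  (g$X - cx)^2 + (g$Y - cy)^2 <= r^2
}

# memoised small labelled dataset shared across tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_labeled_dataset(
        synthetic_dataset_spec(n_cells_per_class = 6, seed = 42))
    }
    cache
  }
})

# well-separated gaussian blobs as a tabular stand-in for feature vectors
make_blobs <- function(n_per_class = 40, d = 10, sep = 10, seed = 1,
                       states = c("live", "apoptotic", "necrotic")) {
  set.seed(seed)
  stopifnot(d >= length(states))
  centers <- matrix(0, length(states), d)
  centers[cbind(seq_along(states), seq_along(states))] <- sep
  rows <- lapply(seq_along(states), function(k) {
    X <- matrix(rnorm(n_per_class * d), n_per_class, d) +
      matrix(centers[k, ], n_per_class, d, byrow = TRUE)
    colnames(X) <- paste0("f", seq_len(d))
    dplyr::bind_cols(tibble::tibble(line = "HeLa", state = states[k]),
                     tibble::as_tibble(X))
  })
  dplyr::bind_rows(rows)
}
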