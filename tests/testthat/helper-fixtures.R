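# shared fixtures: built once per test run, coarse resolutions keep the
# suite fast while staying well above the generators' validity limits

default_spec <- bifurcation_spec()

coarse_resolution <- 0.3

fixture_env <- new.env()

get_phantom <- function() {
  if (is.null(fixture_env$phantom)) {
    prof <- build_radius_profile(default_spec, ds = coarse_resolution / 2)
    fixture_env$phantom <- list(
      profile = prof,
      regions = detect_regions(prof),
      geometry = generate_bifurcation_mesh(default_spec, coarse_resolution,
                                           profile = prof))
  }
  fixture_env$phantom
}

# single-direction WSS series on a tiny tube mesh from a magnitude signal
make_series <- function(mags, direction = c(0, 0, 1), T = 0.8) {
  g <- get_tiny_tube()
  nf <- nrow(g$mesh$faces)
  n <- length(mags)
  wss <- array(0, dim = c(nf, 3, n))
  for (k in seq_len(n)) {
    wss[, , k] <- matrix(direction, nf, 3, byrow = TRUE) * mags[k]
  }
  fl <- flow_series(T = T, t = T * (seq_len(n) - 1) / n, q = rep(1, n))
  wss_series(g$mesh, wss, fl)
}

# per-face vector series from an n x 3 matrix of time samples (all faces equal)
make_vector_series <- function(vecs, T = 0.8) {
  g <- get_tiny_tube()
  nf <- nrow(g$mesh$faces)
  n <- nrow(vecs)
  wss <- array(0, dim = c(nf, 3, n))
  for (k in seq_len(n)) wss[, , k] <- matrix(vecs[k, ], nf, 3, byrow = TRUE)
  fl <- flow_series(T = T, t = T * (seq_len(n) - 1) / n, q = rep(1, n))
  wss_series(g$mesh, wss, fl)
}

get_tiny_tube <- function() {
  if (is.null(fixture_env$tiny_tube))
    fixture_env$tiny_tube <- generate_tube_mesh(4, radius = 1, resolution = 0.5)
  fixture_env$tiny_tube
}
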