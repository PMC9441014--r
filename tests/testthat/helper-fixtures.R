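# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A known stable 10-region model and its exact covariances.
small_truth <- function() {
  fixture("small_truth", function() {
    model <- random_mou_model(10, density = 0.2, tau_seconds = 2, seed = 7)
    list(model = model,
         emp = model_covariances(model, lag_trs = 1, tr_seconds = 2))
  })
}

# A deterministic phase_series with two internally synchronised blocks
# (5 and 3 regions), mutually desynchronised.
block_phases <- function(n_time = 8) {
  phases <- matrix(rep(c(rep(0, 5), rep(pi, 3)), each = n_time), n_time, 8)
  structure(list(phases = phases, band_hz = c(0.04, 0.07), tr_seconds = 2),
            class = "phase_series")
}

# Brute-force largest connected component size of a binary adjacency matrix
# (independent oracle for the igraph-based implementation).
brute_largest_component <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    comp <- 0L
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      comp <- comp + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, comp)
  }
  best
}

# circular distance in [0, pi], reimplemented independently of the package
wrap_phase_distance_for_test <- function(d) {
  pmin(abs(d) %% (2 * pi), 2 * pi - abs(d) %% (2 * pi))
}

# simple phase unwrapping for slope checks
unwrap_for_test <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
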