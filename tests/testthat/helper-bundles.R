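# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# idealized noise-free study: every estimator should recover truth exactly
noise_free_bundle <- function() {
  cached("noise_free", function() {
    generate_study(truth_config(seed = 11, n_genes = 1000,
                                noise_cv = 0, nb_dispersion = 0))
  })
}

noise_free_result <- function() {
  cached("noise_free_result", function() {
    suppressWarnings(run_pipeline(noise_free_bundle()))
  })
}

# study at the default (realistic) noise level
noisy_bundle <- function() {
  cached("noisy", function() {
    generate_study(truth_config(seed = 11, n_genes = 1000))
  })
}

# independent brute-force hypergeometric upper-tail oracle:
# P(overlap >= x) for a set of size K and a list of size n drawn from a
# background of size N, by explicit enumeration of choose() terms
hyper_tail_oracle <- function(x, K, n, N) {
  js <- seq(max(x, 0, K + n - N), min(K, n))
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# independent step-up false-discovery-rate oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}
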