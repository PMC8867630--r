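# Shared fixtures, built in code.

# 2-D separable geometry: controls at the origin, two patient clouds at
# (+gap, 0) and (-gap, 0).
toy_polytope_data <- function(n = 30, gap = 5, sd = 0.5, seed = 7) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(2 * n, 0, sd), n, 2),
      cbind(rnorm(n, gap, sd), rnorm(n, 0, sd)),
      cbind(rnorm(n, -gap, sd), rnorm(n, 0, sd))
    )
    list(x = X,
         y = c(rep(1, n), rep(-1, 2 * n)),
         truth = c(rep(1, n), rep(2, n)))
  })
}

# small planted cohort for fast module tests
small_cohort <- function(seed = 5, n_hc = 60, n_asd = 60, n_sites = 3,
                         n_features = 30, d = 1.2, ...) {
  simulate_cohort(n_hc = n_hc, n_asd = n_asd, n_sites = n_sites,
                  n_features = n_features, effect_size_d = d, seed = seed,
                  ...)
}

# brute-force ARI from the contingency-table definition, written
# independently of the package implementation
ari_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  n11 <- sum(same_a[up] & same_b[up])
  n00 <- sum(!same_a[up] & !same_b[up])
  n10 <- sum(same_a[up] & !same_b[up])
  n01 <- sum(!same_a[up] & same_b[up])
  # Rand index pair counts -> adjusted form
  total <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# mean pairwise Spearman identity oracle for Kendall's W on untied data
w_from_spearman <- function(scores) {
  m <- nrow(scores)
  rho <- cor(t(scores), method = "spearman")
  rbar <- mean(rho[upper.tri(rho)])
  ((m - 1) * rbar + 1) / m
}

# tiny deterministic series object for dynamics tests
toy_series <- function(mat, pairs = NULL, id = "sub-0001", fd = 0.1) {
  structure(list(subject_id = id, mat = mat, tr = 2,
                 homotopic_pairs = pairs, mean_fd = fd),
            class = "polysub_series")
}
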