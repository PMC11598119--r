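# small shared fixtures, built in code

sphere_problem <- function(dim, lower = -5, upper = 5) {
  slo_problem(function(x) sum(x^2), dim = dim, lower = lower, upper = upper)
}

# two well-separated Gaussian blobs; KNN separates them perfectly
separated_blobs <- function(n_per_class = 20, n_features = 5, gap = 10,
                            seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * n_features), n_per_class),
    matrix(rnorm(n_per_class * n_features, mean = gap), n_per_class)
  )
  labeled_dataset(X, rep(1:2, each = n_per_class))
}
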