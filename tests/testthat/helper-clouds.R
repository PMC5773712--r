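# two well-separated Gaussian feature clouds for classifier/protocol tests
make_clouds <- function(n_per_class = 20, dim = 220, sep = 3, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * dim, mean = sep), n_per_class, dim),
             matrix(rnorm(n_per_class * dim, mean = -sep), n_per_class, dim))
  list(x = x, labels = rep(c("secretory", "non_secretory"), each = n_per_class))
}
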