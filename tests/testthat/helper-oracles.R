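# independent oracles used to cross-check the implementation

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# mean silhouette width computed from first principles (no cluster pkg)
silhouette_oracle <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force K selection: run kmeans for each k, score with the oracle
choose_k_oracle <- function(x, k_range = 2:10, seed = 42) {
  x <- as.matrix(x)
  sil <- withr::with_seed(seed, vapply(k_range, function(k) {
    km <- kmeans(x, centers = k, nstart = 10, iter.max = 100)
    silhouette_oracle(x, km$cluster)
  }, numeric(1)))
  k_range[which.max(sil)]
}

# independent percentile bootstrap of a mean (plain loop)
boot_ci_oracle <- function(v, n_boot = 10000, seed = 1, conf = 0.95) {
  set.seed(seed)
  means <- numeric(n_boot)
  for (b in seq_len(n_boot)) means[b] <- mean(sample(v, replace = TRUE))
  alpha <- (1 - conf) / 2
  unname(quantile(means, c(alpha, 1 - alpha)))
}

# minimal NeuroML-subset document for parser tests
write_test_nml <- function(body, path = tempfile(fileext = ".nml")) {
  writeLines(c(
    '<neuroml xmlns="http://www.neuroml.org/schema/neuroml2" id="doc">',
    '  <cell id="c1"><biophysicalProperties id="b"><membraneProperties>',
    body,
    '  </membraneProperties></biophysicalProperties></cell>',
    '</neuroml>'), path)
  path
}
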