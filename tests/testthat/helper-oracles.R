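# Independent oracles used across the suite. These are deliberately naive
# quadratic/loop implementations, kept separate from the package code paths
# they check.

# Brute-force pairwise Pearson correlation between matrix rows.
oracle_pairwise_cor <- function(mat) {
  n <- nrow(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(mat),
                                                rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- cor(mat[i, ], mat[j, ])
    }
  }
  out
}

# Textbook UPGMA (average linkage) on a distance matrix; returns the sorted
# merge heights. Clusters are merged greedily at the smallest average
# inter-cluster distance, with the average recomputed from the original
# distances each time.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Explicit r -> t -> p -> z chain through the distribution functions,
# scalar, no log-scale tricks (adequate away from saturation).
oracle_cor_chain <- function(x, y, zmax = 40) {
  n <- length(x)
  r <- cor(x, y)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df = n - 2)
  # upper-tail form of qnorm(1 - p/2): same quantity without the
  # catastrophic cancellation in 1 - p/2 at small p
  z <- sign(r) * qnorm(p / 2, lower.tail = FALSE)
  list(r = r, t = t, p = p, z = min(abs(z), zmax) * sign(r))
}

# Small reusable panels -----------------------------------------------------

cat_only_config <- function(n = 40, n_probes = 300, noise_sd = 0.03,
                            seed = 1, ...) {
  generator_config(
    species = list(species_spec("cat", n_samples = n,
                                age_range = c(0.2, 21), max_lifespan = 30)),
    n_probes = n_probes,
    n_age_probes = as.integer(min(60, n_probes %/% 5)),
    n_sex_probes = as.integer(min(10, n_probes %/% 10)),
    n_species_marker_probes = 0L, noise_sd = noise_sd, seed = seed, ...)
}

dual_config <- function(n_cat = 40, n_human = 50, n_probes = 500,
                        seed = 1, ...) {
  generator_config(
    species = list(
      species_spec("cat", n_samples = n_cat, age_range = c(0.2, 21),
                   max_lifespan = 30, maturity = 1),
      species_spec("human", n_samples = n_human, age_range = c(0, 93),
                   max_lifespan = 122, maturity = 15)),
    n_probes = n_probes, n_age_probes = 100L, n_sex_probes = 16L,
    n_species_marker_probes = 30L, seed = seed, ...)
}
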