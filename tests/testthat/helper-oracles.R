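# Brute-force genotype-space oracles for probability of identity.
# These enumerate genotypes directly and are implemented independently of
# the closed forms in R/identity.R.

# P(two independent HWE genotypes match) = sum_g P(g)^2 over unordered
# genotypes g = {i, j}.
oracle_pi_hwe <- function(p) {
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      total <- total + pg^2
    }
  }
  total
}

# P(two full siblings share a genotype): enumerate ordered parental
# genotypes (HWE) and, per parent pair, the offspring genotype distribution
# (one allele uniformly from each parent); two sibs are iid given parents.
oracle_pi_sibs <- function(p) {
  k <- length(p)
  total <- 0
  for (m1 in seq_len(k)) for (m2 in seq_len(k)) {
    for (f1 in seq_len(k)) for (f2 in seq_len(k)) {
      p_parents <- p[m1] * p[m2] * p[f1] * p[f2]
      # offspring unordered genotype distribution for this parent pair
      off <- matrix(0, k, k)
      for (a in c(m1, m2)) for (b in c(f1, f2)) {
        i <- min(a, b); j <- max(a, b)
        off[i, j] <- off[i, j] + 0.25
      }
      total <- total + p_parents * sum(off^2)
    }
  }
  total
}

random_freq_vector <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
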