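# Independent brute-force oracles and fixture builders used across tests.

# NODF by direct enumeration of every ordered row and column pair.
nodf_oracle <- function(m) {
  pair_terms <- function(m) {
    n <- nrow(m)
    total <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      fi <- sum(m[i, ]); fj <- sum(m[j, ])
      if (fi > fj && fj > 0)
        total <- total + sum(m[i, ] == 1 & m[j, ] == 1) / fj
    }
    total
  }
  (pair_terms(m) + pair_terms(t(m))) /
    (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# Barber modularity by the direct double sum over all cells.
barber_q_oracle <- function(m, row_labels, col_labels) {
  mtot <- sum(m)
  q <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (row_labels[i] == col_labels[j])
      q <- q + m[i, j] - sum(m[i, ]) * sum(m[, j]) / mtot
  }
  q / mtot
}

# perfectly nested staircase: row i has ones in columns 1..(n - i + 1)
staircase_matrix <- function(n) {
  outer(seq_len(n), seq_len(n), function(i, j) as.integer(j <= n - i + 1))
}

# two disconnected all-ones blocks
two_block_matrix <- function(n1, n2 = n1) {
  m <- matrix(0L, n1 + n2, n1 + n2)
  m[seq_len(n1), seq_len(n1)] <- 1L
  m[n1 + seq_len(n2), n1 + seq_len(n2)] <- 1L
  m
}

random_binary <- function(nr, nc, p = 0.5) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# pool soil samples to one community row per site
aggregate_sites <- function(sim) {
  rowsum(sim$counts, sim$sample_meta$site)
}

# small 4-site metadata for a toy matrix
toy_metadata <- function(mat, strain_sites, phage_sites,
                         site_region = c(T = "Mexico", Y = "Mexico",
                                         S = "Argentina", C = "Argentina")) {
  rbind(
    data.frame(id = rownames(mat), entity_class = "strain",
               site = strain_sites, region = unname(site_region[strain_sites]),
               taxon = NA, genotype = NA, collection = "LC"),
    data.frame(id = colnames(mat), entity_class = "phage",
               site = phage_sites, region = unname(site_region[phage_sites]),
               taxon = NA, genotype = NA, collection = "LC"))
}
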