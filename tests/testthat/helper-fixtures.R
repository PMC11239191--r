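# Shared fixtures, all built in code.

# Zero potential on a uniform grid (h = 0.5 nm unless stated).
zero_potential <- function(L, h = 0.5) {
  grid <- seq(0, L, by = h)
  total_potential(list(), grid = grid)
}

# Arbitrary potential from explicit values (grid spacing h).
make_potential <- function(grid, U) porefpt:::new_potential_profile(grid, U)

# Random smooth potential: sum of up to `k_max` Gaussian/barrier terms,
# rescaled so max |U| <= u_max kBT.
random_potential <- function(L, h = 0.5, k_max = 3, u_max = 5) {
  grid <- seq(0, L, by = h)
  k <- sample.int(k_max, 1)
  terms <- lapply(seq_len(k), function(i) {
    if (stats::runif(1) < 0.5)
      gaussian_term(grid, EG = stats::runif(1, -u_max, u_max),
                    xG = stats::runif(1, 0.2 * L, 0.8 * L),
                    sG = stats::runif(1, 0.05 * L, 0.3 * L))
    else
      barrier_term(grid, EB = stats::runif(1, -u_max, u_max),
                   xB = stats::runif(1, 0.2 * L, 0.8 * L),
                   sB = stats::runif(1, 0.05 * L, 0.3 * L))
  })
  U <- total_potential(terms)
  m <- max(abs(U$U))
  if (m > u_max) U$U <- U$U * (u_max / m)
  U
}

# Random residue string over the 20 standard codes.
random_sequence_text <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# The dsDNA-surrogate polymer: one neutral residue, 98 glutamates, one X,
# at 34 nm per residue (100 charged units over 3400 nm).
dsdna_sequence <- function() {
  parse_sequence(paste0("A", strrep("E", 98), "X"), laa = 34)
}
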