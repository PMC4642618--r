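# Shared in-code fixtures and independent oracles.

toy_matrix <- function(n = 4, p = 3, seed = 1, prefix = "f") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         paste0(prefix, seq_len(p))))
}

toy_dataset <- function(n = 4, p = 3, seed = 1, name = "toy", prefix = "f") {
  omics_dataset(toy_matrix(n, p, seed, prefix), name = name)
}

# Independent pair-counting ARI: loops over all sample pairs and counts
# agreements/disagreements directly (no contingency table).
ari_bruteforce <- function(l1, l2) {
  n <- length(l1)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- l1[i] == l1[j]
    s2 <- l2[i] == l2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  exp_a <- (a + b) * (a + c_) / tot
  max_a <- ((a + b) + (a + c_)) / 2
  if (abs(max_a - exp_a) < 1e-12) return(as.numeric(b + c_ == 0))
  (a - exp_a) / (max_a - exp_a)
}

# Exhaustive-enumeration PAM objective: minimum over all medoid sets of the
# total dissimilarity of each point to its nearest medoid.
pam_bruteforce_objective <- function(d, k) {
  combs <- utils::combn(nrow(d), k)
  min(apply(combs, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min))))
}

# Small standardized single-source simulation run through the fusion front
# end, returning profiles plus the truth.
tiny_fused_sim <- function(n = 45, p = 40, k_true = 3, effect_size = 3,
                           noise_fraction = 0.3, seed = 1, grid_n = 8,
                           basis_k = 20) {
  spec <- sim_spec(n, k_true, list(list(name = "om", n_features = p)),
                   effect_size = effect_size, within_sd = 1,
                   noise_fraction = noise_fraction, seed = seed)
  sim <- simulate_multiomics(spec)
  ds <- standardize_features(sim$datasets[[1]])
  concat <- concatenate_omics(list(ds))
  emb <- embed_concat(concat)
  prof <- smooth_profiles(emb, concat, grid_n = grid_n, basis_k = basis_k)
  list(sim = sim, concat = concat, embedding = emb, profiles = prof)
}
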