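# Shared fixtures and oracles for the test suite. All fixtures are built in
# code; the brute-force functions here are independent oracles for the exact
# tests and must stay free of package internals.

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# exact signed-rank tail probabilities by enumerating all 2^n sign vectors
brute_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- signs %*% r
  list(V = v_obs,
       p_greater = mean(v_all >= v_obs - 1e-9),
       p_less = mean(v_all <= v_obs + 1e-9))
}

# exact rank-sum tails by enumerating all subsets assigned to group 1
brute_rank_sum <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  subsets <- combn(length(r), n1)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  list(W = w_obs,
       p_greater = mean(w_all >= w_obs - 1e-9),
       p_less = mean(w_all <= w_obs + 1e-9))
}

# exact hypergeometric tails by enumerating all size-n draws from the
# background
brute_hypergeom <- function(N, K, n, k) {
  annotated <- seq_len(K)
  draws <- combn(N, n)
  overlap <- apply(draws, 2, function(idx) sum(idx %in% annotated))
  list(p_enrich = mean(overlap >= k), p_deplete = mean(overlap <= k))
}

# hand-built mating records for one male: female-1 values then one female-2
# value (NA entries mean no ejaculate -> zeros)
male_records <- function(male_id, f1_values, f2_value, status = "dominant") {
  vals <- c(f1_values, f2_value)
  ej <- as.integer(!is.na(vals))
  vals[is.na(vals)] <- 0
  k <- length(vals)
  data.frame(
    trial_id = male_id, male_id = male_id, status = status,
    female_order = c(rep(1L, k - 1L), 2L),
    cumulative_exposure = seq_len(k),
    ejaculated = ej,
    sperm_number = vals, sf_volume_ul = vals, sf_protein_ug_per_ul = vals,
    stringsAsFactors = FALSE
  )
}

# standardized log-composition matrix of a proteome simulation
prep_standardized <- function(sim) {
  ab <- apex_compositional(sim$counts)
  keep <- filter_consistent(sim$counts)
  log_standardize(ab[keep, , drop = FALSE], standardize = TRUE)
}

# high-signal planted-cluster simulation used by the recovery tests
high_signal_sim <- function(seed, fractions = c(0.43, 0.19, 0.21, 0.17),
                            n_proteins = 400) {
  simulate_proteome(proteome_sim_config(
    n_proteins = n_proteins, cluster_fractions = fractions,
    profile_amplitude = 1.2, count_depth = 300, dispersion = 0,
    annotation_plan = list(), seed = seed))
}
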