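# Small fixture builders shared across test files.

# A tiny complete expression matrix with two groups of n samples each.
tiny_matrix <- function(n_features = 10, n_per_group = 3, sd = 0.3,
                        seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(n_features * 2 * n_per_group, mean = 20, sd = sd),
                 n_features, 2 * n_per_group)
  rownames(vals) <- sprintf("F%02d", seq_len(n_features))
  colnames(vals) <- sprintf("s%d", seq_len(2 * n_per_group))
  expression_matrix(vals, rep(c("control", "treated"), each = n_per_group))
}

# A null study config with no planted effects and no missingness.
null_config <- function(n_proteins = 2000, n_reps = 4, seed = 1) {
  sim_config(n_proteins = n_proteins,
             n_replicates_per_arm = n_reps,
             planted_effects = list(planted_pathway = 0),
             missing_rate_mcar = 0,
             mnar_intensity_quantile = 0,
             seed = seed)
}

# Brute-force two-sided Mann-Whitney p over all group labelings, computing
# the U statistic from scratch for each labeling (independent of the
# rank-sum-enumeration path in the implementation).
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U_obs <- u_stat(a, b)
  idx <- utils::combn(n, na)
  Us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9)))
}
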