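# Independent oracles used across the suite. Each is a deliberately
# naive implementation (enumeration / brute force) kept separate from the
# package's code paths.

# BH step-up, written out longhand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# One-sided (greater) Wilcoxon rank-sum p by enumerating every group
# assignment of the pooled values.
wilcox_oracle_greater <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(w_all >= w_obs - 1e-9)
}

# Two-sided exact Spearman p by enumerating all permutations of y's ranks.
spearman_oracle_two_sided <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(rank(x), rank(y))
  perms <- all_perms(n)
  rhos <- apply(perms, 2, function(pm) cor(seq_len(n), pm))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(rep(k, ncol(sub)), sub + (sub >= k))
  }))
}

# Average local clustering coefficient by explicit neighbor-pair counting.
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    d <- length(nb)
    if (d < 2) next
    links <- sum(adj[nb, nb]) / 2
    cc[v] <- 2 * links / (d * (d - 1))
  }
  mean(cc)
}

# MCC by exhaustive subset checking: a subset is a maximal clique iff it
# is complete and no vertex can extend it.
mcc_oracle <- function(adj) {
  n <- nrow(adj)
  score <- numeric(n)
  for (size in 2:n) {
    for (sub in utils::combn(n, size, simplify = FALSE)) {
      a <- adj[sub, sub]
      if (any(a[upper.tri(a)] == 0)) next
      extendable <- any(vapply(setdiff(seq_len(n), sub), function(v) {
        all(adj[v, sub] > 0)
      }, logical(1)))
      if (!extendable) score[sub] <- score[sub] + factorial(size - 1)
    }
  }
  score
}

random_em <- function(n_genes, n_cols, layer = "normalized", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expression_matrix(matrix(abs(rnorm(n_genes * n_cols, 3)), n_genes),
                    sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(n_cols)), layer = layer)
}

# Small per-sample dataset with one strongly planted channel, shared by
# the scoring tests.
planted_channel_fixture <- function(seed = 11, n_samples = 12,
                                    cells_per_type = 200, fold = 10) {
  pp <- data.frame(ligand = "gene0005", receptor = "gene0006",
                   sender = "type01", receiver = "type02",
                   fold_elevation = fold, stringsAsFactors = FALSE)
  cfg <- simulation_config(n_samples = n_samples, n_cell_types = 4,
                           cells_per_type = cells_per_type, n_genes = 60,
                           nb_mean = 2, nb_dispersion = 1,
                           dropout_rate = 0.3, planted_pairs = pp,
                           seed = seed)
  sim <- simulate_single_cell_dataset(cfg)
  pairs <- data.frame(ligand = sprintf("gene%04d", seq(1, 59, 2)),
                      receptor = sprintf("gene%04d", seq(2, 60, 2)),
                      stringsAsFactors = FALSE)
  list(sim = sim, pairs = pairs, planted = pp,
       normalized = lapply(sim$matrices, normalize_cells))
}
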