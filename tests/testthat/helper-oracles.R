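# Independent oracles kept deliberately naive: enumeration and brute force,
# never the code paths they check.

# Latent-state enumeration of the single-site occupancy likelihood:
# sum over z in {0, 1} of Pr(z) * Pr(history | z).
enum_site_likelihood <- function(history, psi, p) {
  if (length(p) == 1) p <- rep(p, length(history))
  obs <- !is.na(history)
  y <- history[obs]
  pj <- p[obs]
  pr_given_occupied <- prod(pj^y * (1 - pj)^(1 - y))
  pr_given_empty <- prod((1 - y)^y * 1) * as.numeric(all(y == 0))
  (1 - psi) * pr_given_empty + psi * pr_given_occupied
}

# All binary histories of length J as a matrix (rows = histories).
all_histories <- function(J) {
  as.matrix(expand.grid(rep(list(0:1), J)))
}

# Brute-force collinearity pruning: the largest subset of columns with all
# pairwise |r| <= threshold, preferring higher-priority columns on ties
# (priority = column order).
brute_force_prune <- function(x, threshold) {
  nms <- colnames(x)
  q <- length(nms)
  cc <- abs(stats::cor(x))
  best <- character(0)
  best_rank <- NULL
  for (k in q:0) {
    if (length(best) > 0) break
    if (k == 0) { best <- character(0); break }
    for (idx in utils::combn(q, k, simplify = FALSE)) {
      sub <- cc[idx, idx, drop = FALSE]
      if (all(sub[upper.tri(sub)] <= threshold)) {
        rank_vec <- idx
        if (is.null(best_rank) ||
            paste(rank_vec, collapse = ",") < paste(best_rank, collapse = ",")) {
          best <- nms[idx]
          best_rank <- rank_vec
        }
      }
    }
    if (length(best) > 0) break
  }
  best
}

# Intercept-only occupancy MLE by grid search on the probability scale.
grid_search_mle <- function(d, m, step = 1e-3) {
  grid <- seq(step, 1 - step, by = step)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (psi in grid) {
    # profile p on the grid for each psi
    ll_p <- vapply(grid, function(p) {
      lik <- psi * p^d * (1 - p)^(m - d) + (1 - psi) * (d == 0)
      sum(log(lik))
    }, numeric(1))
    j <- which.max(ll_p)
    if (ll_p[j] > best_ll) {
      best_ll <- ll_p[j]
      best <- c(psi, grid[j])
    }
  }
  list(psi = best[1], p = best[2], loglik = best_ll)
}

# Small simulated dataset shared across tests (fixed seed, modest size).
make_test_sim <- function(n_sites = 150, seed = 421) {
  design <- sim_design(
    n_sites = n_sites, J = 8, occasion_length = 4,
    beta_psi = c(forest_d = 0.7, past = -0.5),
    beta_p = c(forest_d = 0.4),
    psi_intercept = 0.2, p_intercept = -0.3
  )
  simulate_camtrap(design, seed = seed)
}
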