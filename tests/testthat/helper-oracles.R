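# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately share no code with the implementation:
# statistics are computed from first-principles formulas and p-values by
# exhaustive enumeration.

# Kruskal-Wallis H from the rank-sum formula with tie correction
oracle_kw_h <- function(values, group) {
  group <- as.factor(group)
  n_tot <- length(values)
  r <- rank(values)
  rs <- tapply(r, group, sum)
  ns <- tapply(r, group, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / ns) - 3 * (n_tot + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n_tot^3 - n_tot))
}

# exact permutation p for KW over all distinct assignments of the values to
# groups of the observed sizes (2 or 3 groups)
oracle_kw_perm_p <- function(values, group) {
  group <- as.factor(group)
  sizes <- as.integer(table(group))
  h_obs <- oracle_kw_h(values, group)
  n <- length(values)
  cnt <- 0L; tot <- 0L
  for (g1 in asplit(utils::combn(n, sizes[1L]), 2L)) {
    rest <- setdiff(seq_len(n), g1)
    if (length(sizes) == 2L) {
      lab <- integer(n); lab[g1] <- 1L; lab[rest] <- 2L
      tot <- tot + 1L
      if (oracle_kw_h(values, lab) >= h_obs - 1e-10) cnt <- cnt + 1L
    } else {
      for (g2 in asplit(utils::combn(rest, sizes[2L]), 2L)) {
        lab <- integer(n)
        lab[g1] <- 1L; lab[g2] <- 2L; lab[setdiff(rest, g2)] <- 3L
        tot <- tot + 1L
        if (oracle_kw_h(values, lab) >= h_obs - 1e-10) cnt <- cnt + 1L
      }
    }
  }
  cnt / tot
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns on the
# tie-averaged ranks of |x|
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# exact two-sided rank-sum p by enumerating all subsets of the combined
# sample assigned to the first group (Mann-Whitney U convention)
oracle_rank_sum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(length(r), m)
  u_all <- apply(subsets, 2L, function(i) sum(r[i])) - m * (m + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# exact two-sided Spearman permutation p over all n! orderings of y
# (n <= 7; permutations generated by filtering the n^n grid)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1L, function(p) length(unique(p)) == n), ,
                drop = FALSE]
  rho_obs <- abs(cor(rank(x), rank(y)))
  rho_all <- apply(perms, 1L, function(p) abs(cor(rank(x), rank(y)[p])))
  mean(rho_all >= rho_obs - 1e-12)
}

# conservative >= level order-statistic CI for the median: widest-in symmetric
# rank pair (k, n+1-k) whose binomial coverage reaches the level
oracle_median_orderstat_ci <- function(x, level = 0.95) {
  n <- length(x)
  xs <- sort(x)
  for (k in seq_len(floor(n / 2))) {
    cover <- 1 - 2 * pbinom(k - 1, n, 0.5)
    if (cover >= level) ci <- c(xs[k], xs[n + 1 - k]) else break
  }
  ci
}

# shared heavy fixture: a multi-seed run of the full simulate-fit-window
# pipeline at the study's group sizes (memoised across test files)
pipeline_seed_runs <- local({
  cache <- NULL
  function(seeds = 1:10) {
    if (is.null(cache)) {
      cache <<- lapply(seeds, function(s)
        full_pipeline(run_config(seed = s, fit_curves = TRUE)))
    }
    cache
  }
})
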