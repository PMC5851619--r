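# Cohort statistics battery: omnibus group comparisons with pairwise
# Bonferroni follow-up, within-group recovery tests, rank correlation,
# forward-stepwise linear modelling and bootstrap medians. Standard tests
# delegate to base R; the stepwise selection, the bootstrap CI, and the
# small-sample exact Wilcoxon paths (which, unlike base R, enumerate the
# null distribution even in the presence of ties) are implemented here.

# Exact Wilcoxon convention: enumeration for n <= 25, normal approximation
# with tie correction beyond. Ranks are tie-averaged, so scaled ranks
# (2 * rank) are integers and the null distribution can be built by dynamic
# programming over the rank multiset.

# two-sided p from a discrete null distribution: 2 * min(lower, upper) tail
two_sided_from_dist <- function(probs, vals, obs) {
  lo <- sum(probs[vals <= obs + 1e-9])
  hi <- sum(probs[vals >= obs - 1e-9])
  min(1, 2 * min(lo, hi))
}

# exact signed-rank test: W = sum of positive ranks of |x| (zeros dropped);
# null = independent random signs on the tie-averaged ranks
exact_signed_rank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  s <- as.integer(round(2 * r))
  maxs <- sum(s)
  f <- numeric(maxs + 1L); f[1L] <- 1
  for (si in s) {
    g <- f
    g[(si + 1L):(maxs + 1L)] <- g[(si + 1L):(maxs + 1L)] + f[seq_len(maxs + 1L - si)]
    f <- g
  }
  probs <- f / 2^n
  vals <- (0:maxs) / 2
  list(statistic = w_obs, p_value = two_sided_from_dist(probs, vals, w_obs))
}

# exact rank-sum test: statistic in the Mann-Whitney convention of base R,
# W = sum(ranks of x) - m(m+1)/2; null = random m-subsets of the combined
# tie-averaged rank multiset
exact_rank_sum <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  s <- as.integer(round(2 * r))
  maxs <- sum(s)
  # f[j+1, k+1] = number of j-subsets with scaled rank sum k
  f <- matrix(0, nrow = m + 1L, ncol = maxs + 1L)
  f[1L, 1L] <- 1
  for (si in s) {
    for (j in seq(m, 1L)) {
      cols <- (si + 1L):(maxs + 1L)
      f[j + 1L, cols] <- f[j + 1L, cols] + f[j, seq_len(maxs + 1L - si)]
    }
  }
  counts <- f[m + 1L, ]
  probs <- counts / sum(counts)
  vals <- (0:maxs) / 2 - m * (m + 1) / 2
  list(statistic = w_obs, p_value = two_sided_from_dist(probs, vals, w_obs))
}

# dispatcher: exact for n <= 25, else base R's normal approximation with
# tie correction
signed_rank_test <- function(x) {
  nz <- x[x != 0]
  if (length(nz) <= 25L) exact_signed_rank(x)
  else {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
}

rank_sum_test <- function(x, y) {
  if (length(x) + length(y) <= 25L) exact_rank_sum(x, y)
  else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
}

#' Compare a variable across severity groups
#'
#' Quantitative variables: Kruskal-Wallis omnibus test (tie-corrected) with
#' pairwise Wilcoxon rank-sum follow-up; categorical variables: Chi-squared
#' test on the contingency table with pairwise 2xk Chi-squared follow-up.
#' Pairwise p-values are Bonferroni-adjusted by the number of pairs (3 for
#' three groups).
#'
#' @param values Vector of observations (numeric, or factor/binary for
#'   `kind = "categorical"`).
#' @param group Group labels, same length as `values`.
#' @param kind `"quantitative"` or `"categorical"`.
#' @param exact If `TRUE` (quantitative only, total n <= 12), the omnibus
#'   p-value is computed by exhaustive permutation of the group labels
#'   instead of the chi-squared approximation of the Kruskal-Wallis H.
#' @return A list of class `group_comparison`: `statistic`, `p_value`,
#'   `pairwise` (data.frame with raw and Bonferroni-adjusted p per pair),
#'   and per-group `medians` and `iqrs` (quantitative only).
#' @export
group_compare <- function(values, group,
                          kind = c("quantitative", "categorical"),
                          exact = FALSE) {
  kind <- match.arg(kind)
  group <- as.factor(group)
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  lev <- levels(group)
  if (length(lev) < 2L) stop("need at least two non-empty groups", call. = FALSE)

  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)

  if (kind == "quantitative") {
    if (length(unique(values)) == 1L) {
      # all observations identical: no evidence against the null
      stat <- 0; p <- 1
    } else {
      kw <- stats::kruskal.test(values, group)
      stat <- unname(kw$statistic); p <- kw$p.value
      if (exact) {
        if (length(values) > 12L)
          stop("exact permutation only supported for n <= 12", call. = FALSE)
        p <- kw_permutation_p(values, group, stat)
      }
    }
    pw_raw <- vapply(seq_len(n_pairs), function(j) {
      a <- values[group == pairs[1L, j]]
      b <- values[group == pairs[2L, j]]
      if (length(unique(c(a, b))) == 1L) return(1)
      rank_sum_test(a, b)$p_value
    }, numeric(1))
    med <- tapply(values, group, stats::median)
    iqr <- tapply(values, group, function(v)
      unname(diff(stats::quantile(v, c(0.25, 0.75)))))
  } else {
    tab <- table(group, values)
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
    pw_raw <- vapply(seq_len(n_pairs), function(j) {
      sub <- group %in% pairs[, j]
      t2 <- table(droplevels(group[sub]), values[sub])
      if (any(dim(t2) < 2L)) return(1)
      suppressWarnings(stats::chisq.test(t2, correct = FALSE)$p.value)
    }, numeric(1))
    med <- iqr <- NULL
  }

  pairwise <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    p_raw = pw_raw,
    p_adj = pmin(pw_raw * n_pairs, 1),
    stringsAsFactors = FALSE
  )
  structure(list(kind = kind, statistic = stat, p_value = p,
                 pairwise = pairwise, medians = med, iqrs = iqr),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  test <- if (x$kind == "quantitative") "Kruskal-Wallis" else "Chi-squared"
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", test, x$statistic, x$p_value))
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

# exact permutation p for the Kruskal-Wallis H: enumerate every distinct
# assignment of the observations to groups of the observed sizes and count
# assignments with H >= observed
kw_permutation_p <- function(values, group, h_obs) {
  group <- as.factor(group)
  sizes <- table(group)
  n <- length(values)
  idx_all <- seq_len(n)
  h_of <- function(assign) unname(
    stats::kruskal.test(values, factor(assign))$statistic)
  cnt <- 0L; tot <- 0L
  first <- utils::combn(idx_all, sizes[[1L]])
  for (a in seq_len(ncol(first))) {
    g1 <- first[, a]
    rest <- setdiff(idx_all, g1)
    if (length(sizes) == 2L) {
      assign <- integer(n); assign[g1] <- 1L; assign[rest] <- 2L
      tot <- tot + 1L
      if (h_of(assign) >= h_obs - 1e-10) cnt <- cnt + 1L
    } else if (length(sizes) == 3L) {
      second <- utils::combn(rest, sizes[[2L]])
      for (b in seq_len(ncol(second))) {
        g2 <- second[, b]
        assign <- integer(n)
        assign[g1] <- 1L; assign[g2] <- 2L
        assign[setdiff(rest, g2)] <- 3L
        tot <- tot + 1L
        if (h_of(assign) >= h_obs - 1e-10) cnt <- cnt + 1L
      }
    } else stop("exact permutation supports 2 or 3 groups", call. = FALSE)
  }
  cnt / tot
}

#' Test whether a group recovered to baseline
#'
#' Wilcoxon signed-rank test of the back-to-supine endpoint against a zero
#' median: a significant result means the group's flow did not return to the
#' initial supine baseline.
#'
#' @param x Endpoint values in percent.
#' @return List with `statistic`, `p_value`, `n_nonzero`, `median`, and
#'   `degenerate` (TRUE when all values are zero, in which case no p-value
#'   is defined).
#' @export
baseline_recovery_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("no data", call. = FALSE)
  nz <- sum(x != 0)
  if (nz == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                median = 0, degenerate = TRUE))
  }
  wt <- signed_rank_test(x)
  list(statistic = wt$statistic, p_value = wt$p_value,
       n_nonzero = nz, median = stats::median(x),
       degenerate = length(x) < 2L)
}

#' Spearman rank correlation
#'
#' Tie-handled Spearman correlation. The p-value uses the t approximation
#' by default; for small samples (`n <= 9`, no ties) an exact permutation
#' p-value over all `n!` orderings is available.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact If `TRUE` and `n <= 9` with no ties, compute the exact
#'   permutation p-value.
#' @return List with `rho`, `p_value`, `n`, `method`, and `degenerate`
#'   (TRUE when either input is constant, leaving rho undefined).
#' @export
correlate <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  if (exact && n <= 9L && !has_ties) {
    p <- spearman_exact_p(x, y)
    method <- "exact permutation"
  } else {
    # t approximation on rho with n - 2 df
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method,
       degenerate = FALSE)
}

# exact two-sided permutation p for Spearman's rho, |rho_perm| >= |rho_obs|
# over all n! orderings of y (n <= 9)
spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  rho_obs <- abs(stats::cor(rx, ry))
  perms <- permutations_of(n)
  cnt <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(stats::cor(rx, ry[perms[i, ]])) >= rho_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  k <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[i, ]
      out[k, ] <- row
      k <- k + 1L
    }
  }
  out
}

#' Forward-stepwise linear model
#'
#' Pure forward selection: at each step the candidate whose partial t-test
#' p-value (equivalently the single-term partial F) is smallest and below
#' `alpha_in` enters the model; selection stops when no remaining candidate
#' qualifies. There is no removal step. Categorical candidates should be
#' supplied as 0/1 indicator columns. Candidates perfectly collinear with
#' the entered set are skipped with a warning.
#'
#' @param response Numeric response vector.
#' @param candidates data.frame of candidate predictors (numeric columns).
#' @param alpha_in Entry threshold on the partial p-value (default 0.05);
#'   `alpha_in = 1` enters every non-collinear candidate, reproducing the
#'   ordinary least-squares fit on all candidates.
#' @return An object of class `stepwise_model`: `selected` (entry order),
#'   `coefficients` (final-model slopes incl. intercept), `entry_p`
#'   (p-value at entry), `adj_r_squared`, `r_squared`, `n`, and `fit`
#'   (the final `lm`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); z <- rnorm(50)
#' y <- 2 * x + rnorm(50, 0, 0.5)
#' stepwise_lm(y, data.frame(x = x, z = z))
stepwise_lm <- function(response, candidates, alpha_in = 0.05) {
  stopifnot(is.data.frame(candidates), nrow(candidates) == length(response))
  keep <- stats::complete.cases(candidates) & is.finite(response)
  response <- response[keep]
  candidates <- candidates[keep, , drop = FALSE]
  n <- length(response)
  dat <- cbind(.y = response, candidates)

  selected <- character(0)
  entry_p <- numeric(0)
  remaining <- names(candidates)
  repeat {
    if (length(remaining) == 0L || n <= length(selected) + 2L) break
    base_terms <- if (length(selected)) paste(selected, collapse = " + ") else "1"
    fit0 <- stats::lm(stats::as.formula(paste(".y ~", base_terms)), data = dat)
    best_p <- Inf; best_var <- NULL
    drop_vars <- character(0)
    for (v in remaining) {
      fit1 <- stats::lm(stats::as.formula(
        paste(".y ~", base_terms, "+", v)), data = dat)
      cf <- stats::summary.lm(fit1)$coefficients
      if (!(v %in% rownames(cf)) || is.na(stats::coef(fit1)[v])) {
        drop_vars <- c(drop_vars, v)  # collinear with entered set
        next
      }
      pv <- cf[v, "Pr(>|t|)"]
      if (is.finite(pv) && pv < best_p) { best_p <- pv; best_var <- v }
    }
    if (length(drop_vars)) {
      warning("skipping collinear candidate(s): ",
              paste(drop_vars, collapse = ", "), call. = FALSE)
      remaining <- setdiff(remaining, drop_vars)
    }
    if (is.null(best_var) || best_p >= alpha_in) break
    selected <- c(selected, best_var)
    entry_p <- c(entry_p, best_p)
    remaining <- setdiff(remaining, best_var)
  }

  final_terms <- if (length(selected)) paste(selected, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste(".y ~", final_terms)), data = dat)
  sm <- stats::summary.lm(fit)
  names(entry_p) <- selected
  structure(list(selected = selected,
                 coefficients = stats::coef(fit),
                 entry_p = entry_p,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 n = n, fit = fit),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Forward-stepwise model: intercept only (no candidate entered)\n")
  } else {
    cat("Forward-stepwise model, entry order:",
        paste(x$selected, collapse = ", "), "\n")
    print(round(x$coefficients, 4))
    cat(sprintf("adjusted R^2 = %.3f (n = %d)\n", x$adj_r_squared, x$n))
  }
  invisible(x)
}

#' Median with percentile-bootstrap confidence interval
#'
#' @param x Numeric vector, `n >= 2`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed RNG seed; the interval is deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @return List with `median`, `ci_lower`, `ci_upper`, `level`, `n_boot`.
#' @export
median_ci <- function(x, n_boot = 10000L, seed = NULL, level = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  boots <- with_local_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  nrow = n_boot)
    apply(idx, 1L, function(i) stats::median(x[i]))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(median = stats::median(x), ci_lower = ci[1L], ci_upper = ci[2L],
       level = level, n_boot = n_boot)
}

#' Paired pre/post comparison
#'
#' Wilcoxon signed-rank test on paired differences (e.g. recovery offset
#' before versus after long-term CPAP treatment).
#'
#' @param pre,post Equal-length paired numeric vectors.
#' @return List with `statistic`, `p_value`, `median_diff` (post - pre),
#'   `n`, `degenerate` (all differences zero).
#' @export
paired_pre_post <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  keep <- is.finite(pre) & is.finite(post)
  d <- post[keep] - pre[keep]
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_diff = 0, n = length(d), degenerate = TRUE))
  }
  wt <- signed_rank_test(d)
  list(statistic = wt$statistic, p_value = wt$p_value,
       median_diff = stats::median(d), n = length(d), degenerate = FALSE)
}
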