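# Independent brute-force oracles. These deliberately share no code with the
# package: matchings are found by exhaustive enumeration, rank statistics by
# direct arithmetic on ranks.

# Best gated partial matching between two point sets by exhaustive
# enumeration: maximal cardinality first, minimal total squared displacement
# second. Returns list(cardinality, cost).
oracle_best_matching <- function(xy_a, xy_b, gate) {
  n1 <- nrow(xy_a); n2 <- nrow(xy_b)
  d2 <- outer(xy_a[, 1], xy_b[, 1], `-`)^2 +
        outer(xy_a[, 2], xy_b[, 2], `-`)^2
  feas <- d2 <= gate^2
  best <- list(cardinality = 0L, cost = 0)
  recurse <- function(i, used_b, card, cost) {
    if (i > n1) {
      if (card > best$cardinality ||
          (card == best$cardinality && cost < best$cost - 1e-12))
        best <<- list(cardinality = card, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used_b, card, cost)       # leave row i unmatched
    for (j in seq_len(n2)) {
      if (feas[i, j] && !used_b[j]) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, card + 1L, cost + d2[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, max(n2, 1L)), 0L, 0)
  best
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n, na) group
# assignments of the pooled sample (matches the convention p = min(1,
# 2 * min(P(U <= u), P(U >= u)))).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  splits <- utils::combn(length(pooled), na)
  u_of <- function(av, bv) {
    sum(outer(av, bv, `>`)) + 0.5 * sum(outer(av, bv, `==`))
  }
  u_obs <- u_of(a, b)
  us <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12)))
}

oracle_mw_u <- function(a, b) {
  sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
}

# Tie-corrected Kruskal-Wallis H straight from the rank-sum formula.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  tie <- table(x)
  denom <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (denom == 0) 0 else h / denom
}

# Dunn pairwise z from mean ranks with tie-corrected pooled variance.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  nm <- if (is.null(names(groups))) as.character(seq_along(groups))
        else names(groups)
  g <- rep(nm, lengths(groups))
  N <- length(x)
  r <- rank(x)
  tie <- table(x)
  s2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  rb <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  (rb[[i]] - rb[[j]]) / sqrt(s2 * (1 / n[[i]] + 1 / n[[j]]))
}

# Spearman r with midranks as the Pearson correlation of the rank vectors,
# computed from the covariance definition.
oracle_spearman_r <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Monte-Carlo permutation p for Kruskal-Wallis (reference for the exact
# enumeration inside the package).
oracle_kw_mc_p <- function(groups, B = 20000) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  h_obs <- oracle_kw_h(groups)
  hs <- replicate(B, {
    xp <- sample(x)
    oracle_kw_h(split(xp, g))
  })
  mean(hs >= h_obs - 1e-9)
}
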