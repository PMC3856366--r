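# Independent oracles used to cross-check the package's statistics. These
# deliberately avoid the code paths (and the stats:: routines) the package
# calls, so agreement is evidence rather than tautology.

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(nx + ny, nx) label assignments of the combined sample.
mwEnumP <- function(x, y) {
  nx <- length(x)
  combined <- c(x, y)
  n <- length(combined)
  uStat <- function(idx) {
    xs <- combined[idx]
    ys <- combined[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- uStat(seq_len(nx))
  all.u <- apply(utils::combn(n, nx), 2, uStat)
  min(1, 2 * min(mean(all.u <= obs), mean(all.u >= obs)))
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
hyperEnumP <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up: sort, scale by m/i, cumulative minimum from
# the largest p, restore input order, cap at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Simple-regression coefficients from the normal equations.
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Spearman rho as Pearson correlation of average ranks.
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
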