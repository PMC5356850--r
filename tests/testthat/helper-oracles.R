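# Independent brute-force / closed-form oracles used to check the statistics
# kernel. These deliberately avoid stats::p.adjust / t.test / wilcox.test.

# Benjamini-Hochberg step-up by its definition: sort ascending, compute
# m * p_(i) / i, take running minima from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  scaled <- m * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# One-sample t on differences, closed form.
paired_t_oracle <- function(d) {
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}

# Exact Mann-Whitney by enumeration of all assignments of the pooled sample.
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Exact Wilcoxon signed-rank by enumeration of all 2^n sign flips.
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  list(v = v_obs, p = min(p, 1))
}

pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
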