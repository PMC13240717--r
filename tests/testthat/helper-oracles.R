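# Independent brute-force oracles used to validate the package's
# statistics. These deliberately avoid the code paths they check: Fisher
# via choose()-ratio enumeration, Mann-Whitney via full rank-arrangement
# enumeration, BH via the step-up formula written out directly.

# hypergeometric probability of a 2x2 table with fixed margins, from
# binomial coefficients only
oracle_table_prob <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# two-sided Fisher p by probability-ordering enumeration
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; k <- a + c; n2 <- c + d
  xs <- max(0, k - n2):min(k, m)
  probs <- vapply(xs, function(x) oracle_table_prob(x, m - x, k - x, n2 - (k - x)), numeric(1))
  p_obs <- oracle_table_prob(a, b, c, d)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# exact two-sided Mann-Whitney p by enumerating every assignment of ranks
# to the first sample (tie-free data only)
oracle_mw_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_obs <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# BH step-up written out directly: m*p(i)/i with a cumulative minimum from
# the largest p downward, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# every 2x2 table with all four margins at most `max_margin`
all_tables_with_margins <- function(max_margin) {
  g <- expand.grid(a = 0:max_margin, b = 0:max_margin,
                   c = 0:max_margin, d = 0:max_margin)
  g <- g[g$a + g$b <= max_margin & g$c + g$d <= max_margin &
           g$a + g$c <= max_margin & g$b + g$d <= max_margin &
           g$a + g$b + g$c + g$d >= 1, ]
  g
}

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "amylatlas", mustWork = TRUE)
}

# tip partition of a clade_partition as a canonical list of sorted label sets
partition_sets <- function(part) {
  s <- split(names(part$assignments), part$assignments)
  unname(lapply(s, sort))
}
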