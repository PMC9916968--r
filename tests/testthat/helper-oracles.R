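# Independent oracles used across test files. Each re-derives its
# quantity by a different route than the package implementation:
# explicit choose() enumeration, brute-force assignment enumeration,
# or hand-written closed forms.

# Two-sided Fisher p by full enumeration of the tables admissible under
# the observed margins, with point probabilities from binomial
# coefficients (no dhyper).
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pk[ks == tab[1, 1]]
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

# Kruskal-Wallis H via the between/within-variance identity on ranks,
# a formula algebraically distinct from the rank-sum form used in the
# package (equal including tie correction).
kw_h_oracle <- function(groups) {
  r <- rank(unlist(groups))
  n <- lengths(groups)
  idx <- split(seq_along(r), rep(seq_along(groups), n))
  N <- length(r)
  rbar <- mean(r)
  between <- sum(vapply(idx, function(i) length(i) * (mean(r[i]) - rbar)^2,
                        numeric(1)))
  total <- sum((r - rbar)^2)
  (N - 1) * between / total
}

# Exact Kruskal-Wallis p by brute-force enumeration of all assignments
# of the pooled observations to groups of the observed sizes.
kw_exact_oracle <- function(groups) {
  h_obs <- kw_h_oracle(groups)
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  assignments <- enumerate_partitions(seq_along(pooled), sizes)
  h_all <- vapply(assignments, function(idx) {
    kw_h_oracle(lapply(idx, function(i) pooled[i]))
  }, numeric(1))
  mean(h_all >= h_obs - 1e-12)
}

enumerate_partitions <- function(indices, sizes) {
  if (length(sizes) == 1L) return(list(list(indices)))
  out <- list()
  for (f in combn(indices, sizes[1L], simplify = FALSE)) {
    for (r in enumerate_partitions(setdiff(indices, f), sizes[-1L])) {
      out[[length(out) + 1L]] <- c(list(f), r)
    }
  }
  out
}

# Spearman rho via explicit Pearson sums on midranks.
spearman_oracle_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Exact two-sided Spearman p by enumerating all n! orderings of y.
spearman_exact_oracle <- function(x, y) {
  rho_obs <- abs(spearman_oracle_rho(x, y))
  n <- length(x)
  perm_idx <- all_orderings(n)
  hits <- vapply(perm_idx, function(p) {
    abs(spearman_oracle_rho(x, y[p])) >= rho_obs - 1e-12
  }, logical(1))
  mean(hits)
}

# all n! orderings: insert n at every position of each (n-1)-ordering
all_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_orderings(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Kaplan-Meier survival at each distinct event time by the hand
# product-limit formula.
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events)[ord]
  ev_times <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ev_times, surv = surv)
}

# Two-group log-rank statistic from the hand O-E table.
logrank_oracle <- function(t1, e1, t2, e2) {
  all_t <- sort(unique(c(t1[as.logical(e1)], t2[as.logical(e2)])))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in all_t) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & as.logical(e1)); d2 <- sum(t2 == t & as.logical(e2))
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
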