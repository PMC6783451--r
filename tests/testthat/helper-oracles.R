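# Independent brute-force oracles. These deliberately avoid the package's
# log-factorial enumeration: probabilities are computed with plain
# factorial() arithmetic (exact in double precision for the table totals
# used here) and tables are enumerated cell by cell.

# two-sided exact p for a 2x3 table by exhaustive enumeration
oracle_fisher_2x3 <- function(f, m, rel_tol = 1e-7) {
  tab <- rbind(f, m)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  tab_prob <- function(t) {
    prod(factorial(rs)) * prod(factorial(cs)) /
      (factorial(n) * prod(factorial(t)))
  }
  p_obs <- tab_prob(tab)
  total <- 0
  for (a11 in 0:min(rs[1], cs[1])) {
    for (a12 in 0:min(rs[1] - a11, cs[2])) {
      a13 <- rs[1] - a11 - a12
      if (a13 > cs[3]) next
      t2 <- cs - c(a11, a12, a13)
      if (any(t2 < 0)) next
      p <- tab_prob(rbind(c(a11, a12, a13), t2))
      if (p <= p_obs * (1 + rel_tol)) total <- total + p
    }
  }
  min(1, total)
}

# exact HWE p by direct enumeration with factorial arithmetic
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1; na <- 2 * n2 + n1
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob_h <- function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }
  probs <- vapply(hs, prob_h, numeric(1))
  p_obs <- probs[match(n1, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# random 2x3 tables with both row sums >= 1 and total <= max_total
random_tables <- function(n_tables, max_total = 40) {
  lapply(seq_len(n_tables), function(i) {
    repeat {
      t <- matrix(rpois(6, sample(0:4, 6, replace = TRUE)), 2, 3)
      if (sum(t) >= 2 && sum(t) <= max_total &&
          all(rowSums(t) >= 1)) return(t)
    }
  })
}
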