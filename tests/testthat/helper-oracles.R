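# Independent brute-force oracles over the ordered-tuple state space
# (9^5 = 59,049 worlds), against which the package's multiset-collapsed
# enumeration is checked. Built lazily and cached for the test session.

.oracle_env <- new.env(parent = emptyenv())

ordered_worlds <- function(lengths = 1:9) {
  key <- paste(lengths, collapse = ",")
  if (is.null(.oracle_env[[key]])) {
    w <- as.matrix(expand.grid(rep(list(lengths), 5), KEEP.OUT.ATTRS = FALSE))
    dimnames(w) <- NULL
    .oracle_env[[key]] <- w
  }
  .oracle_env[[key]]
}

# literal listener by enumerating the 9^4 completions of the revealed stick
oracle_literal <- function(u, lengths = 1:9) {
  rest <- as.matrix(expand.grid(rep(list(lengths), 4), KEEP.OUT.ATTRS = FALSE))
  mid <- (min(lengths) + max(lengths)) / 2
  m <- (u + rowSums(rest)) / 5
  sum(m > mid) / sum(m != mid)
}

# pragmatic listener by direct summation over all ordered worlds containing u:
# each of the five slots is a candidate revelation, chosen with soft-max
# probability exp(beta * log L0(agenda | length)) over slots
oracle_pragmatic <- function(u, agenda, beta, lengths = 1:9) {
  w <- ordered_worlds(lengths)
  mid <- (min(lengths) + max(lengths)) / 2
  l0 <- vapply(lengths, oracle_literal, numeric(1), lengths = lengths)
  lam <- if (agenda == "longer") log(l0) else log(1 - l0)
  util <- matrix(lam[match(w, lengths)], nrow(w), 5L)
  t_w <- exp(beta * util)
  s_u <- rowSums((w == u) * t_w) / rowSums(t_w)   # P(reveal length u | world)
  m <- rowMeans(w)
  num_l <- sum(s_u[m > mid])
  num_s <- sum(s_u[m < mid])
  num_l / (num_l + num_s)
}
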