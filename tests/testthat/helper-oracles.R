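# Independent reference implementations written as plain nested loops,
# transcribed directly from the estimator definitions. They deliberately
# share no code with the package internals and are used to cross-check
# the vectorized implementations.

oracle_fuzzyen <- function(x, m, r, n_exp) {
  N <- length(x)
  phi_of_order <- function(ord) {
    nv <- N - m                       # matched support for both orders
    X <- matrix(0, nv, ord)
    for (i in seq_len(nv)) {
      seg <- x[i:(i + ord - 1)]
      X[i, ] <- seg - sum(seg) / ord  # remove the local baseline
    }
    total <- 0
    for (i in seq_len(nv)) {
      inner <- 0
      for (j in seq_len(nv)) {
        if (j == i) next
        d <- 0
        for (k in seq_len(ord)) d <- max(d, abs(X[i, k] - X[j, k]))
        inner <- inner + exp(-(d^n_exp) / r)
      }
      total <- total + inner / (nv - 1)
    }
    total / nv
  }
  log(phi_of_order(m)) - log(phi_of_order(m + 1))
}

# counting histogram: B equal-width bins on [0, max], last bin closed
oracle_epdf <- function(d, B) {
  mx <- max(d)
  if (mx == 0) return(c(1, rep(0, B - 1)))
  edges <- (0:B) * (mx / B)
  counts <- integer(B)
  for (v in d) {
    for (t in seq_len(B)) {
      hit <- if (t == 1) v >= edges[1] && v <= edges[2]
             else v > edges[t] && v <= edges[t + 1]
      if (hit) {
        counts[t] <- counts[t] + 1L
        break
      }
    }
  }
  counts / length(d)
}

oracle_shannon <- function(p, B) {
  s <- 0
  for (pt in p) if (pt > 0) s <- s - pt * log2(pt)
  s / log2(B)
}

oracle_disten <- function(x, m, tau, B) {
  N <- length(x)
  nv <- N - (m - 1) * tau
  d <- c()
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      dij <- 0
      for (k in 0:(m - 1))
        dij <- max(dij, abs(x[i + k * tau] - x[j + k * tau]))
      d <- c(d, dij)
    }
  }
  oracle_shannon(oracle_epdf(d, B), B)
}

oracle_mdisten <- function(x, m, tau, B, r_factor, n_exp) {
  N <- length(x)
  mu <- sum(x) / N
  r <- r_factor * sqrt(sum((x - mu)^2) / N)
  nv <- N - (m - 1) * tau
  d <- c()
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      ss <- 0
      for (k in 0:(m - 1))
        ss <- ss + (x[i + k * tau] - x[j + k * tau])^2
      d <- c(d, (sqrt(ss) / r)^n_exp)
    }
  }
  oracle_shannon(oracle_epdf(d, B), B)
}

# exhaustive pair counting, ties worth one half
oracle_auc <- function(neg, pos) {
  wins <- 0
  for (a in neg) for (b in pos)
    wins <- wins + (b > a) + 0.5 * (b == a)
  wins / (length(neg) * length(pos))
}

# brute-force best achievable training objective over all midpoint cuts
# and both orientations
oracle_best_threshold_value <- function(scores, labels, objective) {
  y <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  best <- -Inf
  for (thr in cand) {
    for (high in c(TRUE, FALSE)) {
      pred <- if (high) scores > thr else scores < thr
      v <- if (objective == "accuracy") mean(pred == y)
           else (mean(pred[y]) + mean(!pred[!y])) / 2
      best <- max(best, v)
    }
  }
  best
}

random_signal <- function(n, seed) {
  set.seed(seed)
  ts_signal(rnorm(n), fs = 100)
}
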