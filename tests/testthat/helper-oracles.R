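# Brute-force reference implementations of the printed index formulas,
# written as literal loop transcriptions, independent of the package code.

oracle_shannon <- function(x, base = exp(1)) {
  p <- x[x > 0] / sum(x)
  h <- 0
  for (pi in p) h <- h - pi * (log(pi) / log(base))
  h
}

oracle_pielou <- function(x, base = exp(1)) {
  S <- sum(x > 0)
  if (S == 1) return(NA_real_)
  oracle_shannon(x, base) / (log(S) / log(base))
}

oracle_simpson <- function(x) {
  p <- x[x > 0] / sum(x)
  s <- 0
  for (pi in p) s <- s + pi * pi
  1 - s
}

oracle_gini_brown <- function(x) {
  y <- sort(x[x > 0])               # ranked in increasing value
  n <- length(y)
  num <- 0
  for (i in seq_len(n)) num <- num + i * y[i]
  2 * num / (n * sum(y)) - (n + 1) / n
}

oracle_chao1 <- function(x) {
  x <- x[x > 0]
  S <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) S + f1 * (f1 - 1) / (2 * f2) else S + f1 * (f1 - 1) / 2
}

oracle_uc50 <- function(x) {
  p <- sort(x[x > 0] / sum(x), decreasing = TRUE)
  acc <- 0
  for (k in seq_along(p)) {
    acc <- acc + p[k]
    if (acc >= 0.5 - 1e-12) return(k)
  }
  length(p)
}

oracle_shannon_corrected <- function(x, dialect = "printed") {
  x <- x[x > 0]
  p <- x / sum(x)
  S <- length(x)
  f1 <- sum(x == 1)
  if (dialect == "printed") {
    cc <- 1 - f1 / S
    k <- S
  } else {
    cc <- 1 - f1 / sum(x)
    k <- sum(x)
  }
  if (cc <= 0) return(NA_real_)
  h <- 0
  for (pi in p) {
    cp <- cc * pi
    h <- h - cp * log(cp) / (1 - (1 - cp)^k)
  }
  h
}

# All integer count multisets with given maximum total and number of clones,
# enumerated exhaustively (parts in decreasing order).
enumerate_count_vectors <- function(max_total, max_clones) {
  parts <- function(n, k, max_val) {
    if (n == 0) return(list(integer(0)))
    if (k == 0) return(list())
    out <- list()
    for (v in seq_len(min(n, max_val)))
      for (rest in parts(n - v, k - 1, v))
        out <- c(out, list(c(v, rest)))
    out
  }
  do.call(c, lapply(seq_len(max_total),
                    function(n) parts(n, max_clones, n)))
}

# Monte-Carlo oracle for the expected Simpson index of a gradient population:
# direct expectation of 1 - d^2 - sum(background^2) under uniform rescaling.
oracle_simpson_expectation <- function(S, d, n_draws = 4000) {
  vals <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    u <- stats::runif(S - 1)
    bg <- u * (1 - d) / sum(u)
    vals[b] <- 1 - d^2 - sum(bg^2)
  }
  mean(vals)
}
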