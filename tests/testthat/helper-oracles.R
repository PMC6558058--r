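# Independent brute-force oracles used to cross-check the implementation.

# simple-regression slope/intercept/SE via explicit normal equations
ols_brute <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - 2)
  se <- sqrt(sigma2 * diag(xtx_inv))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se = unname(se[2]))
}

# textbook Benjamini-Hochberg step-up
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# four-parameter ANCOVA design-matrix solve; returns interaction estimate,
# SE and two-sided p for the fluorescence-by-group term
ancova_brute <- function(x, y, g) {
  gi <- as.numeric(factor(g)) - 1
  X <- cbind(1, x, gi, x * gi)
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- length(y) - 4
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta[4] / se[4]
  list(estimate = unname(beta[4]), se = unname(se[4]),
       p = unname(2 * pt(-abs(tval), df)),
       slope_A = unname(beta[2]), slope_B = unname(beta[2] + beta[4]))
}

# brute-force Hamming-scan off-target counter (counts sequences, both strands)
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
hamming_hits <- function(probe, db, max_mm) {
  pats <- c(probe, revcomp_chr(probe))
  pl <- nchar(probe)
  pv <- lapply(pats, function(p) strsplit(p, "")[[1]])
  sum(vapply(db, function(s) {
    if (nchar(s) < pl) return(FALSE)
    sv <- strsplit(s, "")[[1]]
    for (off in 0:(nchar(s) - pl)) {
      win <- sv[(off + 1):(off + pl)]
      for (p in pv) if (sum(win != p) <= max_mm) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# compact design used across tests
tiny_design <- function(...) {
  experiment_design(n_otus = 6, probes_per_otu = 10,
                    control_spots_per_array = 5, seed = 42, ...)
}
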