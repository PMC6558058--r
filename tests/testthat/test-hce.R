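test_that("fit_hce reproduces exact and hand-computed regressions", {
  x <- 1:10
  exact <- fit_hce(x, 2 * x + 5, min_spots = 5)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 5)
  expect_equal(exact$se, 0)
  expect_true(exact$passes_2se)
  expect_equal(exact$p, 0)

  # hand OLS: Sxy = 15, Sxx = 10, SSE = 4.3, df = 3
  h <- fit_hce(1:5, c(3, 5, 4, 8, 9), min_spots = 5)
  expect_equal(h$slope, 1.5)
  expect_equal(h$se, sqrt(4.3 / 3 / 10))
  expect_equal(h$se, 0.379, tolerance = 2e-3)
  expect_equal(h$df, 3)
  expect_true(h$passes_2se)

  null <- fit_hce(1:6, rep(0, 6), min_spots = 5)
  expect_equal(null$slope, 0)
  expect_false(null$passes_2se)
  expect_equal(null$p, 1)

  expect_error(fit_hce(1:4, 1:4, min_spots = 5), "too few")
  expect_error(fit_hce(rep(2, 6), rnorm(6), min_spots = 5), "degenerate")
})

test_that("fit_hce matches brute-force normal equations on random instances", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rlnorm(n, 1, 0.6)
    y <- runif(1, -3, 3) * x + rnorm(n, sd = runif(1, 0.1, 5))
    mine <- fit_hce(x, y, min_spots = 5)
    ref <- ols_brute(x, y)
    expect_lt(abs(mine$slope - ref$slope) / max(abs(ref$slope), 1e-12), 1e-10)
    expect_lt(abs(mine$se - ref$se) / ref$se, 1e-10)
    expect_lt(abs(mine$intercept - ref$intercept) /
                max(abs(ref$intercept), 1e-12), 1e-8)
  }
})

test_that("rescaling fluorescence rescales the slope but not the inference", {
  set.seed(21)
  x <- rlnorm(20, 1.5, 0.5)
  y <- 2 * x + rnorm(20, sd = 3)
  a <- fit_hce(x, y)
  k <- 7.3
  b <- fit_hce(k * x, y)
  expect_equal(b$slope, a$slope / k)
  expect_equal(b$se, a$se / k)
  expect_equal(b$t, a$t)
  expect_equal(b$p, a$p)
  expect_equal(b$passes_2se, a$passes_2se)
})

test_that("bh_adjust equals the textbook step-up on permutations of <= 6 p-values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "missing")

  base_sets <- list(c(0.01, 0.02, 0.3, 0.31, 0.9, 1.0),
                    c(0.001, 0.049, 0.05, 0.05, 0.2, 0.6),
                    c(0.5, 0.5, 0.5, 0.04, 0.013, 0.0004))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (ps in base_sets)
    for (perm in perms(ps))
      expect_equal(bh_adjust(perm), bh_brute(perm))
})

test_that("the dual criterion requires both the 2-SE margin and the adjusted t-test", {
  fits <- data.frame(
    otu_id = paste0("o", 1:3), array_id = "a1",
    slope = c(10, 10, 1), se = c(4, 6, 0.1),
    p = c(0.001, 0.001, 0.9))
  fits$passes_2se <- fits$slope - 2 * fits$se > 0
  called <- call_enrichment(fits, alpha = 0.05)
  expect_true(called$enriched[1])          # 10 - 8 > 0 and significant
  expect_false(called$enriched[2])         # fails the 2-SE margin
  expect_false(called$enriched[3])         # fails the t-test
  expect_true(all(called$p_adj >= called$p))
  expect_true(all(called$enriched <= called$passes_2se))
})

test_that("BH family scope is per array by default, global on request", {
  fits <- data.frame(
    otu_id = rep(paste0("o", 1:4), 2),
    array_id = rep(c("a1", "a2"), each = 4),
    slope = 10, se = 1,
    p = c(0.001, 0.02, 0.03, 0.04, 0.8, 0.9, 0.95, 1))
  fits$passes_2se <- TRUE
  per_array <- call_enrichment(fits, family = "array")
  expect_equal(per_array$p_adj[1:4], bh_brute(fits$p[1:4]))
  expect_equal(per_array$p_adj[5:8], bh_brute(fits$p[5:8]))
  global <- call_enrichment(fits, family = "global")
  expect_equal(global$p_adj, bh_brute(fits$p))
})

test_that("consensus applies the two-out-of-three rule on every flag combination", {
  combos <- expand.grid(r1 = c(TRUE, FALSE), r2 = c(TRUE, FALSE),
                        r3 = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    flags <- unlist(combos[i, ])
    cc <- consensus_call(flags)
    expect_equal(cc$enriched, sum(flags) >= 2)
    expect_equal(cc$n_significant, sum(flags))
    expect_equal(cc$n_replicates, 3)
  }
  # missing replicates reduce the denominator; monotone in added TRUE flags
  expect_true(consensus_call(c(TRUE, NA, NA))$enriched)
  expect_false(consensus_call(c(TRUE, FALSE, NA))$enriched)
  for (i in seq_len(nrow(combos))) {
    flags <- unlist(combos[i, ])
    before <- consensus_call(flags)$enriched
    flags[which(!flags)[1]] <- TRUE
    if (anyNA(flags)) next
    expect_true(consensus_call(flags)$enriched >= before)
  }
  expect_error(consensus_call(c(NA, NA)), "at least one")
})

test_that("consensus_table aggregates per-array calls by OTU and condition", {
  fits <- data.frame(
    otu_id = rep(c("o1", "o2"), each = 3),
    treatment = "light", fraction = "attached",
    replicate = rep(1:3, 2),
    enriched = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  tab <- consensus_table(fits)
  expect_equal(tab$enriched[tab$otu_id == "o1"], TRUE)
  expect_equal(tab$enriched[tab$otu_id == "o2"], FALSE)
  expect_equal(tab$n_replicates, c(3L, 3L))
})

test_that("regression CIs on generated data cover the true slope", {
  # single-array experiments at high ion counts: nominal 95% coverage
  d <- experiment_design(treatments = "light", fractions = "attached",
                         replicates_per_condition = 1, n_otus = 1,
                         probes_per_otu = 25, mean_total_cn_counts = 1e7,
                         seed = 1)
  es <- data.frame(otu_id = "OTU0001", treatment = "light",
                   fraction = "attached", true_slope = 5)
  covered <- vapply(1:60, function(s) {
    ex <- generate_experiment(d, es, seed = s)
    sp <- annotate_spots(ex$spots)
    f <- fit_hce_table(sp)
    half <- qt(0.975, f$df) * f$se
    abs(f$slope - 5) <= half
  }, logical(1))
  expect_gte(mean(covered), 0.85)  # 60 seeds: loose bound, full check in acceptance
})
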