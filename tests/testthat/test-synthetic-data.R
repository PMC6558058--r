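test_that("identical design, effects and seed give identical output", {
  d <- tiny_design()
  es <- data.frame(otu_id = "OTU0001", treatment = "light",
                   fraction = "attached", true_slope = 4)
  e1 <- generate_experiment(d, es, seed = 11)
  e2 <- generate_experiment(d, es, seed = 11)
  expect_identical(e1$spots, e2$spots)
  expect_identical(e1$reads, e2$reads)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_experiment(d, es, seed = 12)
  expect_false(identical(e1$spots$n15_counts, e3$spots$n15_counts))
})

test_that("null experiments carry no enrichment signal", {
  d <- tiny_design()
  ex <- generate_null_experiment(d, seed = 3)
  expect_true(all(!ex$truth$slopes$enriched_flag))
  sp <- suppressMessages(annotate_spots(ex$spots))
  # mean permil across all spots is 0 within Monte-Carlo error
  mc_se <- sd(sp$permil) / sqrt(nrow(sp))
  expect_lt(abs(mean(sp$permil)), 4 * mc_se)
  # control spots individually read ~0 permil
  ctrl <- sp$permil[sp$is_control]
  expect_lt(abs(mean(ctrl)), 4 * sd(ctrl) / sqrt(length(ctrl)))
})

test_that("realized mean ratio matches the generative moment", {
  d <- experiment_design(treatments = "light", fractions = "attached",
                         replicates_per_condition = 1, n_otus = 40,
                         probes_per_otu = 25, seed = 5)
  slope <- 2
  es <- data.frame(otu_id = d$taxonomy$otu_id, treatment = "light",
                   fraction = "attached", true_slope = slope)
  ex <- generate_experiment(d, es, seed = 5)
  tgt <- !ex$spots$is_control
  r <- ex$spots$n15_counts[tgt] / ex$spots$n14_counts[tgt]
  expected <- d$background_ratio *
    (1 + slope * mean(ex$spots$fluorescence[tgt]) / 1000)
  mc_se <- sd(r) / sqrt(sum(tgt))
  expect_lt(abs(mean(r) - expected), 3 * mc_se)
})

test_that("true slopes are exactly recoverable from noiseless tables", {
  d <- tiny_design()
  es <- expand.grid(otu_id = d$taxonomy$otu_id,
                    treatment = d$treatments, fraction = d$fractions,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(1)
  es$true_slope <- runif(nrow(es), -2, 8)
  ex <- generate_experiment(d, es, seed = 9, poisson_noise = FALSE)
  sp <- suppressMessages(annotate_spots(ex$spots))
  fits <- suppressMessages(fit_hce_table(sp, min_spots = 5))
  key_f <- paste(fits$otu_id, fits$treatment, fits$fraction)
  key_t <- paste(es$otu_id, es$treatment, es$fraction)
  truth <- es$true_slope[match(key_f, key_t)]
  expect_lt(max(abs(fits$slope - truth) / pmax(abs(truth), 1e-12)), 1e-9)
})

test_that("invalid designs and effect specs are rejected", {
  expect_error(experiment_design(n_otus = 0), "n_otus")
  expect_error(experiment_design(n_otus = 5, probes_per_otu = 1),
               "probes_per_otu")
  expect_warning(experiment_design(n_otus = 5, probes_per_otu = 3),
                 "degrees of freedom")
  expect_error(experiment_design(n_otus = 5, background_ratio = 0),
               "background_ratio")
  expect_error(experiment_design(n_otus = 5, mean_total_cn_counts = -1),
               "mean_total_cn_counts")
  d <- tiny_design()
  expect_error(generate_experiment(
    d, data.frame(otu_id = "nope", treatment = "light",
                  fraction = "attached", true_slope = 1)), "unknown OTUs")
  expect_error(generate_experiment(
    d, data.frame(otu_id = "OTU0001", treatment = "light",
                  fraction = "attached", true_slope = Inf)), "finite")
})

test_that("read-count tables honor depth and expected family fractions", {
  d <- tiny_design()
  ex <- generate_experiment(d, seed = 2)
  depth <- tapply(ex$reads$reads,
                  paste(ex$reads$treatment, ex$reads$fraction,
                        ex$reads$replicate), sum)
  expect_true(all(depth == d$read_depth))
  frac <- ex$truth$family_read_fraction
  sums <- tapply(frac$read_fraction, paste(frac$treatment, frac$fraction), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("bulk presets embed the configured treatment effects", {
  d <- experiment_design(n_otus = 2, replicates_per_condition = 3, seed = 1)
  noiseless <- generate_bulk_measurements(d, cv = 0, seed = 1)
  m <- aggregate(noiseless[c("cell_count", "doc")],
                 list(treatment = noiseless$treatment), mean)
  expect_equal(m$cell_count[m$treatment == "dark"], 1.15)
  expect_equal(m$cell_count[m$treatment == "light"], 1.00)
  expect_equal(m$doc[m$treatment == "dark"] / m$doc[m$treatment == "light"],
               1.65)
  zero <- generate_bulk_measurements(
    d, effects = list(cell_count = 0, doc = 0), cv = 0, seed = 1)
  expect_equal(zero$cell_count[zero$treatment == "dark"],
               zero$cell_count[zero$treatment == "light"])
  noisy <- generate_bulk_measurements(d, cv = 0.1, seed = 4)
  expect_true(all(noisy$cell_count > 0) && all(noisy$doc > 0))
  expect_error(generate_bulk_measurements(
    d, effects = list(cell_count = -1, doc = 0)), "greater than -1")
})
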