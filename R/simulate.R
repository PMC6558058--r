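#' Simulate a complete Chip-SIP experiment
#'
#' Generates per-array probe-spot tables, a companion 16S read-count table and
#' a ground-truth record for a Chip-SIP experiment described by a
#' [experiment_design()]. The generative model inverts the analysis model:
#' each probe carries a fixed hybridization affinity (lognormal, emulating the
#' designed spread of probe melting temperatures), a spot's fluorescence `f`
#' is lognormal around the probe's affinity-scaled mean, its expected permil
#' enrichment is `delta = slope * f + intercept` for the OTU's true slope in
#' that condition, the expected 15N/14N ratio is
#' `r = background_ratio * (1 + delta / 1000)`, and the 14N and 15N ion counts
#' are independent Poisson draws partitioning the spot's total CN count budget
#' as `N14 ~ Pois(total / (1 + r))`, `N15 ~ Pois(total * r / (1 + r))`.
#' Control-oligonucleotide spots have expected enrichment 0 by construction.
#'
#' @param design a `chipsip_design`.
#' @param effect_spec data frame with columns `otu_id`, `treatment`,
#'   `fraction`, `true_slope` (permil per kflu) and optionally
#'   `true_intercept` (permil, default 0). Combinations not listed get slope
#'   0. `NULL` means all slopes 0 (a null experiment).
#' @param seed integer seed; defaults to `design$seed`. Identical
#'   (design, effect_spec, seed) triples produce identical output.
#' @param poisson_noise if `FALSE`, ion counts are set to their expected
#'   values (non-integer), giving noiseless tables from which the true slopes
#'   are exactly recoverable.
#' @param family_profiles optional data frame (`family`, `treatment`,
#'   `fraction`, `weight`) of relative family read abundances per condition;
#'   defaults to a geometric rank-abundance profile shared by all conditions.
#'
#' @return list of class `chipsip_experiment` with elements
#'   \describe{
#'     \item{spots}{spot table, one row per probe spot across all arrays:
#'       `array_id, treatment, fraction, replicate, probe_id, otu_id,
#'        is_control, fluorescence, n14_counts, n15_counts`
#'       (+ `c13n14_counts` when `design$include_c13`).}
#'     \item{reads}{long read-count table: `otu_id, family, treatment,
#'       fraction, replicate, reads` (multinomial, `design$read_depth` reads
#'       per sample).}
#'     \item{truth}{list with `slopes` (per OTU x condition: `true_slope`,
#'       `true_intercept`, `enriched_flag = true_slope > 0`) and
#'       `family_read_fraction` (expected family fractions per condition).}
#'   }
#' @export
generate_experiment <- function(design, effect_spec = NULL,
                                seed = design$seed,
                                poisson_noise = TRUE,
                                family_profiles = NULL) {
  stopifnot(inherits(design, "chipsip_design"))
  slopes <- expand_effect_spec(design, effect_spec)
  set.seed(as.integer(seed))

  otus <- otu_ids(design)
  ppo <- design$probes_per_otu
  probe_df <- data.frame(
    otu_id = rep(otus, each = ppo),
    probe_id = paste0(rep(otus, each = ppo), "_p",
                      formatC(rep(seq_len(ppo), design$n_otus),
                              width = 2, flag = "0")),
    affinity = stats::rlnorm(design$n_otus * ppo, 0, design$sdlog_affinity),
    stringsAsFactors = FALSE
  )

  conditions <- expand.grid(treatment = design$treatments,
                            fraction = design$fractions,
                            replicate = seq_len(design$replicates_per_condition),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions <- conditions[order(conditions$treatment, conditions$fraction,
                                 conditions$replicate), , drop = FALSE]

  spot_list <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cnd <- conditions[i, ]
    array_id <- sprintf("%s_%s_rep%d", cnd$treatment, cnd$fraction,
                        cnd$replicate)
    key <- paste(slopes$treatment, slopes$fraction)
    sl <- slopes[key == paste(cnd$treatment, cnd$fraction), , drop = FALSE]
    sl <- sl[match(probe_df$otu_id, sl$otu_id), , drop = FALSE]

    n_t <- nrow(probe_df)
    n_c <- design$control_spots_per_array
    flu_noise <- stats::rlnorm(n_t + n_c,
                               -design$sdlog_fluorescence^2 / 2,
                               design$sdlog_fluorescence)
    fluorescence <- design$mean_fluorescence *
      c(probe_df$affinity, rep(1, n_c)) * flu_noise
    delta <- c(sl$true_slope * fluorescence[seq_len(n_t)] + sl$true_intercept,
               rep(0, n_c))
    spot_list[[i]] <- data.frame(
      array_id = array_id,
      treatment = cnd$treatment,
      fraction = cnd$fraction,
      replicate = cnd$replicate,
      probe_id = c(probe_df$probe_id,
                   sprintf("CTRL%02d", seq_len(n_c))),
      otu_id = c(probe_df$otu_id, rep(NA_character_, n_c)),
      is_control = c(rep(FALSE, n_t), rep(TRUE, n_c)),
      fluorescence = fluorescence,
      stringsAsFactors = FALSE
    )
    spot_list[[i]]$.delta <- delta
  }
  spots <- do.call(rbind, spot_list)
  rownames(spots) <- NULL

  r <- design$background_ratio * (1 + spots$.delta / 1000)
  if (any(r <= 0)) stop("effect_spec implies non-positive expected isotope ",
                        "ratios (permil enrichment below -1000)")
  lam14 <- design$mean_total_cn_counts / (1 + r)
  lam15 <- design$mean_total_cn_counts * r / (1 + r)
  if (poisson_noise) {
    spots$n14_counts <- stats::rpois(length(lam14), lam14)
    spots$n15_counts <- stats::rpois(length(lam15), lam15)
  } else {
    spots$n14_counts <- lam14
    spots$n15_counts <- lam15
  }
  if (design$include_c13) {
    # 13C channel: higher background ratio and inflated multiplicative noise;
    # carried through but never used in enrichment calls.
    lam13 <- lam14 * 0.0112 * stats::rlnorm(length(lam14), 0, 0.1)
    spots$c13n14_counts <- if (poisson_noise)
      stats::rpois(length(lam13), lam13) else lam13
  }
  spots$.delta <- NULL

  reads <- simulate_reads(design, family_profiles)

  truth <- list(
    slopes = data.frame(slopes,
                        enriched_flag = slopes$true_slope > 0,
                        stringsAsFactors = FALSE),
    family_read_fraction = reads$expected
  )
  out <- list(spots = spots, reads = reads$counts, truth = truth,
              design = design, seed = as.integer(seed))
  class(out) <- "chipsip_experiment"
  out
}

#' @export
print.chipsip_experiment <- function(x, ...) {
  cat(sprintf("Chip-SIP synthetic experiment: %d spots on %d arrays, %d OTUs (seed %d)\n",
              nrow(x$spots), length(unique(x$spots$array_id)),
              x$design$n_otus, x$seed))
  invisible(x)
}

#' Simulate a null Chip-SIP experiment (no isotope incorporation)
#'
#' Convenience wrapper around [generate_experiment()] with every true slope
#' set to zero, used for false-discovery-rate calibration.
#'
#' @inheritParams generate_experiment
#' @return see [generate_experiment()]; all `truth$slopes$enriched_flag` are
#'   `FALSE`.
#' @export
generate_null_experiment <- function(design, seed = design$seed,
                                     poisson_noise = TRUE) {
  generate_experiment(design, effect_spec = NULL, seed = seed,
                      poisson_noise = poisson_noise)
}

expand_effect_spec <- function(design, effect_spec) {
  grid <- expand.grid(otu_id = otu_ids(design),
                      treatment = design$treatments,
                      fraction = design$fractions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$true_slope <- 0
  grid$true_intercept <- 0
  if (is.null(effect_spec)) return(grid)
  req <- c("otu_id", "treatment", "fraction", "true_slope")
  if (!all(req %in% names(effect_spec)))
    stop("effect_spec needs columns: ", paste(req, collapse = ", "))
  if (!all(is.finite(effect_spec$true_slope)))
    stop("all true slopes must be finite")
  bad <- setdiff(effect_spec$otu_id, otu_ids(design))
  if (length(bad))
    stop("effect_spec refers to unknown OTUs: ", paste(bad, collapse = ", "))
  key_g <- paste(grid$otu_id, grid$treatment, grid$fraction)
  key_e <- paste(effect_spec$otu_id, effect_spec$treatment,
                 effect_spec$fraction)
  if (anyDuplicated(key_e)) stop("duplicate rows in effect_spec")
  if (!all(key_e %in% key_g))
    stop("effect_spec refers to conditions not in the design")
  m <- match(key_g, key_e)
  hit <- !is.na(m)
  grid$true_slope[hit] <- effect_spec$true_slope[m[hit]]
  if ("true_intercept" %in% names(effect_spec))
    grid$true_intercept[hit] <- effect_spec$true_intercept[m[hit]]
  grid
}

simulate_reads <- function(design, family_profiles = NULL) {
  tax <- design$taxonomy
  fams <- unique(tax$family)
  conds <- expand.grid(treatment = design$treatments,
                       fraction = design$fractions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(family_profiles)) {
    # geometric rank-abundance profile, identical across conditions
    w <- 0.6^(seq_along(fams) - 1)
    family_profiles <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
      data.frame(family = fams, treatment = conds$treatment[i],
                 fraction = conds$fraction[i], weight = w,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("family", "treatment", "fraction", "weight") %in%
                  names(family_profiles)),
            all(family_profiles$weight >= 0))

  counts_list <- list()
  expected_list <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- family_profiles$treatment == conds$treatment[i] &
      family_profiles$fraction == conds$fraction[i]
    prof <- family_profiles[sel, , drop = FALSE]
    prof <- prof[match(fams, prof$family), , drop = FALSE]
    if (anyNA(prof$weight))
      stop("family_profiles missing a family for condition ",
           conds$treatment[i], "/", conds$fraction[i])
    fam_p <- prof$weight / sum(prof$weight)
    expected_list[[i]] <- data.frame(
      family = fams, treatment = conds$treatment[i],
      fraction = conds$fraction[i], read_fraction = fam_p,
      stringsAsFactors = FALSE)
    n_per_fam <- table(factor(tax$family, levels = fams))
    otu_p <- fam_p[match(tax$family, fams)] /
      as.numeric(n_per_fam[tax$family])
    for (r in seq_len(design$replicates_per_condition)) {
      cnt <- as.integer(stats::rmultinom(1, design$read_depth, otu_p))
      counts_list[[length(counts_list) + 1L]] <- data.frame(
        otu_id = tax$otu_id, family = tax$family,
        treatment = conds$treatment[i], fraction = conds$fraction[i],
        replicate = r, reads = cnt, stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts_list),
       expected = do.call(rbind, expected_list))
}

#' Simulate bulk bottle measurements (cell counts and DOC)
#'
#' Generates per-bottle cell abundances and dissolved organic carbon (DOC)
#' concentrations for the incubation treatments. The default presets embed a
#' 15% higher cell abundance and 65% higher DOC in the dark treatment
#' relative to the light baseline, the bulk community response pattern the
#' downstream summary ([summarize_bulk()]) is designed to quantify.
#'
#' @param design a `chipsip_design`; its treatments and replicate count set
#'   the bottles. The first treatment is the baseline.
#' @param effects named list/vector of proportional effects of each
#'   non-baseline treatment, per variable: `list(cell_count = 0.15,
#'   doc = 0.65)` means +15% cells and +65% DOC relative to baseline.
#'   Effects must be > -1 (a -100% effect would zero the variable).
#' @param baselines named list/vector of baseline means
#'   (default `cell_count = 1, doc = 1`, arbitrary units).
#' @param cv coefficient of variation of multiplicative lognormal
#'   bottle-to-bottle noise (0 gives exact means).
#' @param seed integer seed.
#' @return data frame: `bottle_id, treatment, replicate, cell_count, doc`.
#' @export
generate_bulk_measurements <- function(design,
                                       effects = list(cell_count = 0.15,
                                                      doc = 0.65),
                                       baselines = list(cell_count = 1,
                                                        doc = 1),
                                       cv = 0.05,
                                       seed = design$seed) {
  stopifnot(inherits(design, "chipsip_design"))
  vars <- names(baselines)
  stopifnot(length(vars) >= 1, all(vars %in% names(effects)) ||
              length(design$treatments) == 1)
  if (any(unlist(effects) <= -1))
    stop("effects must be greater than -1 (-100%)")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(as.integer(seed))
  out <- expand.grid(treatment = design$treatments,
                     replicate = seq_len(design$replicates_per_condition),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$treatment, out$replicate), , drop = FALSE]
  out <- data.frame(bottle_id = sprintf("%s_b%d", out$treatment,
                                        out$replicate), out,
                    stringsAsFactors = FALSE)
  baselinetrt <- design$treatments[1]
  sdlog <- sqrt(log(1 + cv^2))
  for (v in vars) {
    mult <- ifelse(out$treatment == baselinetrt, 1,
                   1 + as.numeric(effects[[v]]))
    mu <- as.numeric(baselines[[v]]) * mult
    noise <- if (cv > 0)
      stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog) else rep(1, nrow(out))
    out[[v]] <- mu * noise
  }
  rownames(out) <- NULL
  out
}
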