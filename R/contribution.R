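#' Mean HCE per family and condition
#'
#' Averages hybridization-corrected enrichment over all (OTU, replicate) HCE
#' values within a family, separately for each (treatment, fraction)
#' condition. The default averages at the value level -- every replicate fit
#' of every member OTU counts once -- rather than averaging per-OTU means
#' first; `averaging = "otu_means"` selects the latter.
#'
#' @param fits HCE fit table ([fit_hce_table()]) with `otu_id`, `treatment`,
#'   `fraction`, `slope`.
#' @param taxonomy data frame mapping `otu_id` to `family` (or to `lineage`,
#'   from which the family is extracted with [taxonomy_family()]). OTUs
#'   without a family are pooled into `"unclassified"` (logged).
#' @param averaging `"values"` (default) or `"otu_means"`.
#' @return data frame: `family, treatment, fraction, mean_hce, n_values`.
#' @export
family_mean_hce <- function(fits, taxonomy,
                            averaging = c("values", "otu_means")) {
  averaging <- match.arg(averaging)
  req <- c("otu_id", "treatment", "fraction", "slope")
  miss <- setdiff(req, names(fits))
  if (length(miss)) stop("fit table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"family" %in% names(taxonomy)) {
    if (!"lineage" %in% names(taxonomy))
      stop("taxonomy needs a 'family' or 'lineage' column")
    taxonomy$family <- taxonomy_family(taxonomy$lineage)
  }
  fam <- taxonomy$family[match(fits$otu_id, taxonomy$otu_id)]
  unknown <- is.na(fam)
  if (any(unknown)) {
    message("family_mean_hce: ", length(unique(fits$otu_id[unknown])),
            " OTU(s) without a family assigned to 'unclassified'")
    fam[unknown] <- "unclassified"
  }
  fits$family <- fam
  if (averaging == "otu_means") {
    fits <- stats::aggregate(slope ~ otu_id + family + treatment + fraction,
                             data = fits, FUN = mean)
  }
  agg <- stats::aggregate(slope ~ family + treatment + fraction, data = fits,
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(family = agg$family, treatment = agg$treatment,
                    fraction = agg$fraction,
                    mean_hce = agg$slope[, 1],
                    n_values = as.integer(agg$slope[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$treatment, out$fraction, out$family), , drop = FALSE]
}

#' Family read fractions from an OTU read-count table
#'
#' Pools reads across the replicates of each (treatment, fraction) condition
#' and returns each family's fraction of the condition's reads.
#'
#' @param reads long read-count table (`otu_id`, `treatment`, `fraction`,
#'   `replicate`, `reads`) as produced by [generate_experiment()], with either
#'   a `family` column or a `taxonomy` map.
#' @param taxonomy optional data frame (`otu_id`, `family`/`lineage`) used
#'   when `reads` lacks a `family` column.
#' @return data frame: `family, treatment, fraction, read_fraction`
#'   (fractions sum to 1 within each condition).
#' @export
family_read_fractions <- function(reads, taxonomy = NULL) {
  if (!"family" %in% names(reads)) {
    if (is.null(taxonomy)) stop("reads lack a family column; pass taxonomy")
    if (!"family" %in% names(taxonomy))
      taxonomy$family <- taxonomy_family(taxonomy$lineage)
    reads$family <- taxonomy$family[match(reads$otu_id, taxonomy$otu_id)]
    reads$family[is.na(reads$family)] <- "unclassified"
  }
  agg <- stats::aggregate(reads ~ family + treatment + fraction, data = reads,
                          FUN = sum)
  tot <- stats::aggregate(reads ~ treatment + fraction, data = agg, FUN = sum)
  m <- match(paste(agg$treatment, agg$fraction),
             paste(tot$treatment, tot$fraction))
  data.frame(family = agg$family, treatment = agg$treatment,
             fraction = agg$fraction,
             read_fraction = agg$reads / tot$reads[m],
             stringsAsFactors = FALSE)
}

#' Abundance-weighted family contributions to isotope incorporation
#'
#' Combines each family's mean HCE with its 16S read fraction to estimate the
#' family's share of the community's total isotope incorporation in each
#' condition: `weighted = max(mean_hce, 0) * read_fraction`, normalized to
#' percent within the condition. Negative family mean HCE (no net
#' incorporation) is clipped to zero before weighting.
#'
#' @param mean_hce data frame from [family_mean_hce()].
#' @param read_fractions data frame from [family_read_fractions()] (or the
#'   generator's expected fractions). Families present in only one input get
#'   a zero for the missing quantity.
#' @return data frame: `family, treatment, fraction, mean_hce, read_fraction,
#'   weighted, percent_of_total`. Conditions whose families all have zero
#'   weighted incorporation get `NA` percentages with a warning.
#' @export
weighted_contribution <- function(mean_hce, read_fractions) {
  key_h <- paste(mean_hce$family, mean_hce$treatment, mean_hce$fraction)
  key_r <- paste(read_fractions$family, read_fractions$treatment,
                 read_fractions$fraction)
  all_key <- union(key_h, key_r)
  take <- function(df, key, col, default = 0) {
    v <- df[[col]][match(all_key, key)]
    v[is.na(v)] <- default
    v
  }
  parts <- do.call(rbind, strsplit(all_key, " ", fixed = TRUE))
  out <- data.frame(family = parts[, 1], treatment = parts[, 2],
                    fraction = parts[, 3],
                    mean_hce = take(mean_hce, key_h, "mean_hce"),
                    read_fraction = take(read_fractions, key_r,
                                         "read_fraction"),
                    stringsAsFactors = FALSE)
  cond <- paste(out$treatment, out$fraction)
  for (cd in unique(cond)) {
    s <- sum(out$read_fraction[cond == cd])
    if (s > 1 + 1e-8)
      stop("read fractions sum to ", signif(s, 4), " > 1 in condition ", cd)
  }
  out$weighted <- pmax(out$mean_hce, 0) * out$read_fraction
  out$percent_of_total <- NA_real_
  for (cd in unique(cond)) {
    idx <- which(cond == cd)
    tot <- sum(out$weighted[idx])
    if (tot > 0) {
      out$percent_of_total[idx] <- 100 * out$weighted[idx] / tot
    } else {
      warning("condition ", cd, ": all weighted contributions are zero; ",
              "percent_of_total undefined")
    }
  }
  out <- out[order(out$treatment, out$fraction, -out$weighted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize bulk bottle measurements
#'
#' Computes per-treatment means and the percent difference of each bulk
#' variable between two treatments, plus the Pearson correlation between the
#' first two variables across bottles (e.g. cell counts vs DOC).
#'
#' @param bulk data frame from [generate_bulk_measurements()] (or measured
#'   equivalents) with a `treatment` column and numeric variables.
#' @param variables names of the bulk variables
#'   (default `c("cell_count", "doc")`).
#' @param reference treatment used as the percent-difference baseline
#'   (default `"light"`); the comparison treatment is the other one.
#' @return list with `means` (treatment x variable means), `percent_diff`
#'   (named vector, `(other - reference) / reference * 100`), and
#'   `correlation` (`r`, `p`, `n` for the first two variables; `NA` when
#'   fewer than 3 paired observations).
#' @export
summarize_bulk <- function(bulk, variables = c("cell_count", "doc"),
                           reference = "light") {
  stopifnot(all(variables %in% names(bulk)), "treatment" %in% names(bulk))
  trts <- unique(bulk$treatment)
  if (!reference %in% trts) stop("reference treatment not present")
  means <- stats::aggregate(bulk[variables], list(treatment = bulk$treatment),
                            mean)
  other <- setdiff(trts, reference)
  pdiff <- NULL
  if (length(other) == 1) {
    mref <- means[means$treatment == reference, variables, drop = FALSE]
    moth <- means[means$treatment == other, variables, drop = FALSE]
    pdiff <- unlist((moth - mref) / mref * 100)
    names(pdiff) <- variables
  }
  corr <- list(r = NA_real_, p = NA_real_, n = nrow(bulk))
  if (length(variables) >= 2 && nrow(bulk) >= 3) {
    x <- bulk[[variables[1]]]; y <- bulk[[variables[2]]]
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      ct <- stats::cor.test(x, y)
      corr <- list(r = unname(ct$estimate), p = ct$p.value, n = nrow(bulk))
    }
  }
  list(means = means, percent_diff = pdiff, correlation = corr)
}

#' Stacked-bar plot of family contributions
#'
#' @param contrib data frame from [weighted_contribution()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix plotted (families x conditions, percent).
#' @export
plot_contributions <- function(contrib, ...) {
  cond <- paste(contrib$treatment, contrib$fraction, sep = "\n")
  fams <- sort(unique(contrib$family))
  m <- matrix(0, length(fams), length(unique(cond)),
              dimnames = list(fams, unique(cond)))
  m[cbind(contrib$family, cond)] <- contrib$percent_of_total
  m[is.na(m)] <- 0
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "% of 15N incorporation", ...)
  invisible(m)
}
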