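#' Hybridization-corrected enrichment (HCE): per-OTU regression fit
#'
#' Fits the ordinary least-squares regression of a probe set's permil
#' enrichment on its fluorescence hybridization signal. The slope is the
#' hybridization-corrected enrichment (HCE), the per-OTU isotope-incorporation
#' statistic: probes that hybridized more target rRNA (higher fluorescence)
#' carry more of the labeled RNA, so for an incorporating taxon enrichment
#' rises with fluorescence and the slope is positive, while nonspecific
#' background affects weak and strong spots alike. An intercept is included
#' so residual background offsets do not bias the slope.
#'
#' @param fluorescence spot fluorescence values (kflu).
#' @param permil background-corrected permil enrichment values.
#' @param min_spots minimum usable spots required (default 5, giving at least
#'   3 residual degrees of freedom).
#' @return one-row data frame: `n_spots`, `slope` (the HCE, permil/kflu),
#'   `intercept`, `se` (slope standard error), `df` (`n_spots - 2`),
#'   `t` (`slope / se`), `p` (two-sided, t distribution), and `passes_2se`
#'   (`slope - 2 * se > 0`, the directional part of the enrichment criterion).
#' @details Spots with missing fluorescence or permil are dropped before
#'   fitting. Fewer than `min_spots` usable spots, or zero fluorescence
#'   variance, is an error; the table-level driver [fit_hce_table()] skips
#'   such OTUs and logs the reason instead. An exact linear relation gives
#'   `se = 0` and, for a nonzero slope, `t = +/-Inf`, `p = 0`.
#' @export
fit_hce <- function(fluorescence, permil, min_spots = 5L) {
  ok <- is.finite(fluorescence) & is.finite(permil)
  x <- fluorescence[ok]
  y <- permil[ok]
  n <- length(x)
  if (n < min_spots)
    stop("too few usable spots (", n, " < min_spots = ", min_spots, ")")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: zero fluorescence variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  sse <- max(sum((y - intercept - slope * x)^2), 0)
  dfree <- n - 2L
  se <- sqrt(sse / dfree / sxx)
  t <- if (se > 0) slope / se else if (slope == 0) 0 else sign(slope) * Inf
  p <- if (se > 0) 2 * stats::pt(-abs(t), dfree) else if (slope == 0) 1 else 0
  data.frame(n_spots = n, slope = slope, intercept = intercept, se = se,
             df = dfree, t = t, p = p, passes_2se = slope - 2 * se > 0)
}

#' Fit HCE for every (OTU, array) probe set in a spot table
#'
#' Groups an annotated spot table (see [annotate_spots()]) by array and OTU,
#' fits [fit_hce()] in each group, and returns one row per fit. Control spots
#' are ignored. OTUs with too few usable spots or degenerate fluorescence on
#' an array are skipped and recorded in the `"skipped"` attribute.
#'
#' @param spots annotated spot table with columns `array_id`, `otu_id`,
#'   `is_control`, `fluorescence`, `permil` (plus `treatment`, `fraction`,
#'   `replicate` if present, carried through).
#' @param min_spots passed to [fit_hce()].
#' @return data frame of HCE fits; attribute `"skipped"` lists
#'   (array_id, otu_id, reason) for groups without a fit.
#' @export
fit_hce_table <- function(spots, min_spots = 5L) {
  req <- c("array_id", "otu_id", "is_control", "fluorescence", "permil")
  miss <- setdiff(req, names(spots))
  if (length(miss)) stop("spot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  spots <- spots[!spots$is_control & !is.na(spots$otu_id), , drop = FALSE]
  if (!nrow(spots)) stop("no target (non-control) spots to fit")
  keep_meta <- intersect(c("treatment", "fraction", "replicate"),
                         names(spots))
  groups <- split(seq_len(nrow(spots)),
                  list(array_id = spots$array_id, otu_id = spots$otu_id),
                  drop = TRUE, sep = "\r")
  fits <- vector("list", length(groups))
  skipped <- list()
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    fit <- tryCatch(
      fit_hce(spots$fluorescence[idx], spots$permil[idx], min_spots),
      error = function(e) conditionMessage(e))
    first <- idx[1]
    if (is.character(fit)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        array_id = spots$array_id[first], otu_id = spots$otu_id[first],
        reason = fit, stringsAsFactors = FALSE)
      fits[[i]] <- NULL
    } else {
      meta <- spots[first, c("otu_id", "array_id", keep_meta), drop = FALSE]
      rownames(meta) <- NULL
      fits[[i]] <- cbind(meta, fit)
    }
  }
  out <- do.call(rbind, fits)
  if (is.null(out)) stop("no OTU produced a usable HCE fit")
  out <- out[order(out$array_id, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(array_id = character(), otu_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(skipped))
    message("fit_hce_table: skipped ", nrow(skipped), " (array, OTU) group(s)")
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values with the Benjamini-Hochberg false discovery
#' rate procedure (a validating wrapper around `stats::p.adjust`).
#'
#' @param p numeric p-values, all in \[0, 1\], no missing values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must all lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call isotopically enriched OTUs with the dual criterion
#'
#' Applies the enrichment criterion to a table of HCE fits: an OTU is called
#' enriched on an array when its slope minus two standard errors is positive
#' AND its slope t-test (`t = slope / se`) is significant after
#' Benjamini-Hochberg adjustment (`p_adj < alpha`). The BH family is, by
#' default, all OTUs fitted on the same array (each array is an independent
#' hybridization); `family = "global"` adjusts across the whole table.
#'
#' @param fits data frame from [fit_hce_table()] (needs `array_id`, `p`,
#'   `passes_2se`).
#' @param alpha FDR level (default 0.05).
#' @param family `"array"` (default) or `"global"` BH family scope.
#' @return `fits` with columns `p_adj` and `enriched` added.
#' @export
call_enrichment <- function(fits, alpha = 0.05,
                            family = c("array", "global")) {
  family <- match.arg(family)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!nrow(fits)) stop("empty fit table")
  fits$p_adj <- NA_real_
  if (family == "global") {
    fits$p_adj <- bh_adjust(fits$p)
  } else {
    for (idx in split(seq_len(nrow(fits)), fits$array_id))
      fits$p_adj[idx] <- bh_adjust(fits$p[idx])
  }
  fits$enriched <- fits$passes_2se & fits$p_adj < alpha
  fits
}

#' Replicate consensus call for one OTU in one condition
#'
#' An OTU is called enriched in a condition when at least `threshold` of its
#' replicate arrays were individually called enriched; the default threshold
#' is `ceiling(2 * n / 3)`, the two-out-of-three rule at triplicate designs.
#'
#' @param flags logical vector of per-replicate enrichment calls (`NA` =
#'   replicate missing; it reduces the replicate count).
#' @param threshold required number of significant replicates; `NULL` uses
#'   `ceiling(2 * n / 3)`.
#' @return list with `n_replicates`, `n_significant`, `threshold`, `enriched`.
#' @export
consensus_call <- function(flags, threshold = NULL) {
  flags <- flags[!is.na(flags)]
  n <- length(flags)
  if (n < 1) stop("at least one non-missing replicate flag is required")
  if (is.null(threshold)) threshold <- ceiling(2 * n / 3)
  list(n_replicates = n, n_significant = sum(flags), threshold = threshold,
       enriched = sum(flags) >= threshold)
}

#' Consensus enrichment calls across replicates
#'
#' Aggregates per-array enrichment calls (from [call_enrichment()]) into one
#' consensus call per OTU and condition via [consensus_call()].
#'
#' @param fits called fit table with columns `otu_id`, `treatment`,
#'   `fraction`, `enriched`.
#' @param threshold passed to [consensus_call()].
#' @return data frame: `otu_id, treatment, fraction, n_replicates,
#'   n_significant, enriched`.
#' @export
consensus_table <- function(fits, threshold = NULL) {
  req <- c("otu_id", "treatment", "fraction", "enriched")
  miss <- setdiff(req, names(fits))
  if (length(miss)) stop("fit table lacks column(s): ",
                         paste(miss, collapse = ", "))
  groups <- split(seq_len(nrow(fits)),
                  list(fits$otu_id, fits$treatment, fits$fraction),
                  drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(idx) {
    cc <- consensus_call(fits$enriched[idx], threshold)
    data.frame(otu_id = fits$otu_id[idx[1]],
               treatment = fits$treatment[idx[1]],
               fraction = fits$fraction[idx[1]],
               n_replicates = cc$n_replicates,
               n_significant = cc$n_significant,
               enriched = cc$enriched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$treatment, out$fraction, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
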