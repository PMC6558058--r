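#' Isotope ratio from ion counts, with counting-statistics error
#'
#' Computes the 15N/14N ratio `n15 / n14` of a probe spot from the two
#' secondary-ion channel counts, and its standard error under Poisson counting
#' statistics, `ratio * sqrt(1/n15 + 1/n14)`.
#'
#' @param n14 nonnegative integer counts of 12C14N- ions (vectorized).
#' @param n15 nonnegative integer counts of 12C15N- ions.
#' @return data frame with columns `ratio` and `ratio_se`. A zero `n15` gives
#'   ratio 0 with `ratio_se = NA` (flagged unreliable with a warning).
#' @details A zero `n14` leaves the ratio undefined and is an error; in the
#'   table-level pipeline ([annotate_spots()]) such spots are excluded and the
#'   exclusion is logged instead.
#' @export
compute_ratio <- function(n14, n15) {
  check_counts(n14, "n14")
  check_counts(n15, "n15")
  stopifnot(length(n14) == length(n15))
  if (any(n14 == 0))
    stop("undefined isotope ratio: n14 counts of zero at position(s) ",
         paste(utils::head(which(n14 == 0), 5), collapse = ", "))
  ratio <- n15 / n14
  se <- rep(NA_real_, length(ratio))
  ok <- n15 > 0
  se[ok] <- ratio[ok] * sqrt(1 / n15[ok] + 1 / n14[ok])
  if (any(!ok))
    warning(sum(!ok), " spot(s) with zero n15 counts: ratio 0 with ",
            "unreliable (NA) standard error")
  data.frame(ratio = ratio, ratio_se = se)
}

# Counts are nonnegative and finite; non-integer values are allowed so that
# expected-value (noiseless) tables flow through the same code path.
check_counts <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(what, " must be nonnegative finite counts")
  invisible(TRUE)
}

#' Background isotope ratio from control-oligonucleotide spots
#'
#' Aggregates the ratios of an array's control spots into the array's
#' background 15N/14N ratio. The default is the n14-count-weighted mean,
#' which is the counting-statistics-efficient pooled estimate under Poisson
#' noise; a robust median alternative is available.
#'
#' @param ratio numeric vector of control-spot ratios.
#' @param weight optional weights (use the spots' `n14` counts); ignored by
#'   the median method. `NULL` means equal weights.
#' @param method `"weighted_mean"` (default) or `"median"`.
#' @return a single background ratio.
#' @export
estimate_background <- function(ratio, weight = NULL,
                                method = c("weighted_mean", "median")) {
  method <- match.arg(method)
  ok <- is.finite(ratio)
  if (!any(ok)) stop("no usable control-spot ratios")
  ratio <- ratio[ok]
  if (method == "median") return(stats::median(ratio))
  if (is.null(weight)) weight <- rep(1, length(ratio))
  else weight <- weight[ok]
  if (any(!is.finite(weight)) || any(weight < 0) || sum(weight) == 0)
    stop("weights must be nonnegative with positive sum")
  sum(ratio * weight) / sum(weight)
}

#' Permil enrichment relative to a background ratio
#'
#' The standard delta definition,
#' `permil = (ratio / background_ratio - 1) * 1000`, with the reference taken
#' from the same array's control spots rather than canonical natural
#' abundance, so that unlabeled material reads 0 permil by construction.
#'
#' @param ratio measured isotope ratio(s).
#' @param background_ratio the array's background ratio (> 0).
#' @return permil enrichment value(s), bounded below by -1000.
#' @export
permil_enrichment <- function(ratio, background_ratio) {
  if (!all(is.finite(background_ratio)) || any(background_ratio <= 0))
    stop("background_ratio must be > 0")
  if (any(ratio < 0, na.rm = TRUE)) stop("ratio must be >= 0")
  (ratio / background_ratio - 1) * 1000
}

#' Augment a spot table with ratios and background-corrected permil enrichment
#'
#' Per-array pipeline step: computes each spot's 15N/14N ratio and Poisson
#' standard error, estimates the array's background ratio from its
#' control-oligonucleotide spots, and expresses every spot as permil
#' enrichment relative to that background. Spots with zero n14 counts (ratio
#' undefined) are excluded, and the exclusions are recorded in the
#' `"excluded"` attribute of the result rather than silently dropped.
#'
#' @param spots spot table with at least columns `array_id`, `is_control`,
#'   `n14_counts`, `n15_counts` (see [generate_experiment()] /
#'   [read_spot_table()]).
#' @param background_method passed to [estimate_background()].
#' @return the spot table augmented with `ratio`, `ratio_se`, `permil`,
#'   `background_ratio_used`, minus excluded rows; attribute `"excluded"`
#'   holds a data frame of dropped spots with a `reason` column.
#' @export
annotate_spots <- function(spots,
                           background_method = c("weighted_mean", "median")) {
  background_method <- match.arg(background_method)
  req <- c("array_id", "is_control", "n14_counts", "n15_counts")
  miss <- setdiff(req, names(spots))
  if (length(miss)) stop("spot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- spots$n14_counts == 0
  excluded <- spots[bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- "zero n14 counts (undefined ratio)"
    message("annotate_spots: excluding ", nrow(excluded),
            " spot(s) with zero n14 counts")
  }
  spots <- spots[!bad, , drop = FALSE]

  rs <- suppressWarnings(compute_ratio(spots$n14_counts, spots$n15_counts))
  spots$ratio <- rs$ratio
  spots$ratio_se <- rs$ratio_se

  bg <- vapply(split(seq_len(nrow(spots)), spots$array_id), function(idx) {
    ctrl <- idx[spots$is_control[idx]]
    if (!length(ctrl))
      stop("array ", spots$array_id[idx[1]],
           ": no usable control spots to estimate the background ratio")
    estimate_background(spots$ratio[ctrl], spots$n14_counts[ctrl],
                        method = background_method)
  }, numeric(1))
  spots$background_ratio_used <- bg[spots$array_id]
  spots$permil <- permil_enrichment(spots$ratio, spots$background_ratio_used)
  rownames(spots) <- NULL
  attr(spots, "excluded") <- if (nrow(excluded)) excluded else
    excluded[0, , drop = FALSE]
  spots
}
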