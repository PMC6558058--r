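#' ANCOVA test of a treatment effect on isotope incorporation (one OTU)
#'
#' Tests whether a treatment changes an OTU's hybridization-corrected
#' enrichment by fitting the least-squares model
#' `permil ~ fluorescence + group + fluorescence:group` to the OTU's spots
#' pooled across replicates of the two groups. The coefficient of the
#' `fluorescence:group` interaction -- the crossed effect -- is the difference
#' between the two groups' HCE slopes, and its two-sided t-test p-value is the
#' evidence that the treatment affected incorporation. Main effects are fitted
#' (so group-specific intercepts are absorbed) but calls use only the
#' interaction.
#'
#' @param fluorescence,permil spot-level values for one OTU.
#' @param group two-level factor/character identifying the contrasted
#'   conditions (e.g. light vs dark). The first level (or `levels[1]` after
#'   `factor()`) is group A, the second group B.
#' @param min_spots minimum usable spots required in each group (default 5).
#' @return one-row data frame: `group_A`, `group_B`, `n_A`, `n_B`, `slope_A`,
#'   `slope_B`, `interaction_estimate` (`slope_B - slope_A`),
#'   `interaction_se`, `interaction_p`.
#' @export
fit_ancova <- function(fluorescence, permil, group, min_spots = 5L) {
  ok <- is.finite(fluorescence) & is.finite(permil) & !is.na(group)
  x <- fluorescence[ok]; y <- permil[ok]
  g <- factor(group[ok])
  if (nlevels(g) != 2)
    stop("group must have exactly two observed levels")
  n_ab <- table(g)
  if (any(n_ab < min_spots))
    stop("group below min_spots: ",
         paste(names(n_ab)[n_ab < min_spots], collapse = ", "))
  if (any(tapply(x, g, stats::var) == 0))
    stop("degenerate design: zero fluorescence variance within a group")
  fit <- stats::lm(y ~ x * g)
  cf <- summary(fit)$coefficients
  int_row <- grep("^x:g", rownames(cf))
  slope_a <- cf["x", "Estimate"]
  est <- cf[int_row, "Estimate"]
  data.frame(group_A = levels(g)[1], group_B = levels(g)[2],
             n_A = as.integer(n_ab[1]), n_B = as.integer(n_ab[2]),
             slope_A = slope_a, slope_B = slope_a + est,
             interaction_estimate = est,
             interaction_se = cf[int_row, "Std. Error"],
             interaction_p = cf[int_row, "Pr(>|t|)"],
             stringsAsFactors = FALSE)
}

contrast_specs <- function() {
  list(
    light_vs_dark_attached   = list(fix = c(fraction = "attached"),
                                    var = "treatment",
                                    A = "light", B = "dark"),
    light_vs_dark_free       = list(fix = c(fraction = "free_living"),
                                    var = "treatment",
                                    A = "light", B = "dark"),
    attached_vs_free_light   = list(fix = c(treatment = "light"),
                                    var = "fraction",
                                    A = "attached", B = "free_living"),
    attached_vs_free_dark    = list(fix = c(treatment = "dark"),
                                    var = "fraction",
                                    A = "attached", B = "free_living")
  )
}

#' Per-OTU ANCOVA over the standard treatment and lifestyle contrasts
#'
#' Runs [fit_ancova()] for every OTU over the requested contrasts (light vs
#' dark within each size fraction; attached vs free-living within each
#' light regime), pooling each condition's replicates, then BH-adjusts the
#' interaction p-values within each contrast and assigns a direction:
#' `"none"` unless `interaction_p_adj < alpha`, otherwise the group with the
#' larger HCE slope.
#'
#' @param spots annotated spot table ([annotate_spots()]) with `otu_id`,
#'   `treatment`, `fraction`, `fluorescence`, `permil`, `is_control`.
#' @param contrasts subset of
#'   `c("light_vs_dark_attached", "light_vs_dark_free",
#'      "attached_vs_free_light", "attached_vs_free_dark")`.
#' @param alpha significance level for the adjusted interaction p (0.05).
#' @param min_spots per-group minimum passed to [fit_ancova()].
#' @return data frame with one row per (OTU, contrast):
#'   `otu_id, contrast, group_A, group_B, slope_A, slope_B,
#'    interaction_estimate, interaction_se, interaction_p,
#'    interaction_p_adj, direction`. Attribute `"skipped"` records
#'   (otu_id, contrast, reason) for groups that could not be tested.
#' @export
ancova_contrasts <- function(spots,
                             contrasts = names(contrast_specs()),
                             alpha = 0.05, min_spots = 5L) {
  specs <- contrast_specs()
  contrasts <- match.arg(contrasts, names(specs), several.ok = TRUE)
  spots <- spots[!spots$is_control & !is.na(spots$otu_id), , drop = FALSE]
  out <- list(); skipped <- list()
  for (cn in contrasts) {
    sp <- specs[[cn]]
    sub <- spots
    for (col in names(sp$fix)) sub <- sub[sub[[col]] == sp$fix[[col]], ,
                                          drop = FALSE]
    sub <- sub[sub[[sp$var]] %in% c(sp$A, sp$B), , drop = FALSE]
    if (!nrow(sub)) next
    grp <- factor(sub[[sp$var]], levels = c(sp$A, sp$B))
    rows <- list()
    for (idx in split(seq_len(nrow(sub)), sub$otu_id)) {
      res <- tryCatch(
        fit_ancova(sub$fluorescence[idx], sub$permil[idx], grp[idx],
                   min_spots),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          otu_id = sub$otu_id[idx[1]], contrast = cn, reason = res,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(otu_id = sub$otu_id[idx[1]], contrast = cn,
                           stringsAsFactors = FALSE), res)
      }
    }
    if (!length(rows)) next
    tab <- do.call(rbind, rows)
    tab$interaction_p_adj <- bh_adjust(tab$interaction_p)
    tab$direction <- ifelse(tab$interaction_p_adj >= alpha, "none",
                            ifelse(tab$interaction_estimate > 0,
                                   tab$group_B, tab$group_A))
    out[[cn]] <- tab
  }
  if (!length(out)) stop("no contrast could be tested on this spot table")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(otu_id = character(), contrast = character(),
               reason = character(), stringsAsFactors = FALSE)
  res
}

#' Tabulate significant ANCOVA contrasts per OTU
#'
#' Reshapes [ancova_contrasts()] results into a wide per-OTU summary whose
#' five indicator columns mirror the standard reporting layout: higher
#' incorporation in the light or in the dark among particle-attached taxa,
#' higher in the light among free-living taxa, and higher in the free-living
#' fraction within the light and within the dark incubations. OTUs with no
#' significant contrast are omitted.
#'
#' @param results data frame from [ancova_contrasts()].
#' @param taxonomy optional data frame (`otu_id`, `lineage` or `family`) to
#'   prepend a taxonomy column.
#' @return data frame with `otu_id` (+ taxonomy) and indicator columns
#'   `higher_in_light_attached, higher_in_dark_attached,
#'    higher_in_light_free_living, higher_in_free_living_light,
#'    higher_in_free_living_dark` containing `"X"` or `""`.
#' @export
tabulate_contrasts <- function(results, taxonomy = NULL) {
  cols <- c(higher_in_light_attached    = "light_vs_dark_attached:light",
            higher_in_dark_attached     = "light_vs_dark_attached:dark",
            higher_in_light_free_living = "light_vs_dark_free:light",
            higher_in_free_living_light = "attached_vs_free_light:free_living",
            higher_in_free_living_dark  = "attached_vs_free_dark:free_living")
  sig <- results[results$direction != "none", , drop = FALSE]
  key <- paste(sig$contrast, sig$direction, sep = ":")
  keep <- key %in% cols
  sig <- sig[keep, , drop = FALSE]; key <- key[keep]
  otus <- sort(unique(sig$otu_id))
  out <- data.frame(otu_id = otus, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    hit <- unique(sig$otu_id[key == cols[[nm]]])
    out[[nm]] <- ifelse(otus %in% hit, "X", "")
  }
  if (!is.null(taxonomy)) {
    taxcol <- if ("lineage" %in% names(taxonomy)) "lineage" else "family"
    out <- data.frame(otu_id = out$otu_id,
                      taxonomy = taxonomy[[taxcol]][
                        match(out$otu_id, taxonomy$otu_id)],
                      out[-1], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
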