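spot_required_cols <- c("array_id", "treatment", "fraction", "replicate",
                        "probe_id", "otu_id", "is_control", "fluorescence",
                        "n14_counts", "n15_counts")

#' Read a probe-spot measurement table
#'
#' Reads a tab-delimited (or comma-delimited) spot table with one row per
#' probe spot and validates its schema. Rows with unparseable numeric fields
#' are rejected with row-numbered warnings rather than silently dropped.
#'
#' @param path TSV (default) or CSV file with the columns
#'   `array_id, treatment, fraction, replicate, probe_id, otu_id, is_control,
#'    fluorescence, n14_counts, n15_counts` (+ optional `c13n14_counts`).
#' @return validated spot data frame; rejected rows (if any) are in the
#'   `"rejected"` attribute.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          comment.char = "")
  miss <- setdiff(spot_required_cols, names(df))
  if (length(miss))
    stop("spot table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  num_cols <- intersect(c("fluorescence", "n14_counts", "n15_counts",
                          "c13n14_counts", "replicate"), names(df))
  bad <- rep(FALSE, nrow(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | (is.na(v) & !is.na(df[[cc]]))
    df[[cc]] <- v
  }
  bad <- bad | is.na(df$fluorescence) | is.na(df$n14_counts) |
    is.na(df$n15_counts)
  df$is_control <- as.logical(df$is_control)
  bad <- bad | is.na(df$is_control)
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected))
    warning("rejected ", nrow(rejected), " unparseable row(s): ",
            paste(utils::head(which(bad), 10), collapse = ", "))
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

#' Write a table as TSV
#'
#' Canonical table writer: tab-delimited, UTF-8, header row, `.` decimal
#' mark, no quoting. [read_spot_table()] and [read_tsv()] round-trip its
#' output exactly.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Parse a semicolon-delimited taxonomy lineage
#'
#' Splits a lineage such as
#' `"Bacteria;Bacteroidetes;Flavobacteria_Flavobacteriales;Flavobacteriaceae_1; Maribacter"`
#' into its ordered ranks and extracts the family. Because lineages in probe
#' manifests often have irregular depth, the family is located by the
#' `-aceae` suffix pattern anywhere in a rank first, falling back to the
#' fifth (family) rank position, and finally to `"unclassified"`.
#' Whitespace around ranks is trimmed; empty ranks are preserved as
#' placeholders so that re-serialization is lossless modulo whitespace.
#'
#' @param lineage a single lineage string.
#' @return list with `ranks` (character vector), `family`, and `lineage`
#'   (the trimmed, re-serialized string).
#' @seealso [taxonomy_family()] for the vectorized family extractor.
#' @export
parse_taxonomy <- function(lineage) {
  stopifnot(is.character(lineage), length(lineage) == 1, nzchar(lineage))
  ranks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  fam_idx <- grep("aceae", ranks)
  family <- if (length(fam_idx)) ranks[fam_idx[1]]
  else if (length(ranks) >= 5 && nzchar(ranks[5])) ranks[5]
  else "unclassified"
  list(ranks = ranks, family = family,
       lineage = paste(ranks, collapse = ";"))
}

#' Extract the family rank from lineage strings (vectorized)
#' @param lineage character vector of lineage strings.
#' @return character vector of family names (`"unclassified"` when absent).
#' @export
taxonomy_family <- function(lineage) {
  vapply(lineage, function(l) parse_taxonomy(l)$family, character(1),
         USE.NAMES = FALSE)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; recognized fields are the [experiment_design()]
#'   arguments plus `alpha`, `min_spots`, `consensus_threshold`, `bh_family`,
#'   `seed` and `out_dir`. Missing fields take the package defaults.
#' @return a list suitable for `do.call(run_pipeline, ...)` after extracting
#'   design fields.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    stop("alpha must be in (0, 1)")
  cfg
}

#' Run the full Chip-SIP analysis pipeline on a synthetic experiment
#'
#' End-to-end orchestration: simulate an experiment, convert ion counts to
#' background-corrected permil enrichment, fit per-(OTU, array) HCE, call
#' enrichment with the dual criterion, form replicate consensus calls, test
#' treatment contrasts by ANCOVA (when the design has both levels), and
#' compute abundance-weighted family contributions. All stage outputs are
#' returned and, when `out_dir` is given, written as TSV plus a YAML run
#' report. Outputs are a deterministic function of (design, effect_spec,
#' seed): rerunning writes byte-identical files.
#'
#' @param design a `chipsip_design`.
#' @param effect_spec passed to [generate_experiment()].
#' @param seed integer seed (default `design$seed`).
#' @param alpha significance level for enrichment calls and ANCOVA (0.05).
#' @param min_spots minimum spots per fit (5).
#' @param consensus_threshold passed to [consensus_table()] (`NULL` =
#'   two-thirds rule).
#' @param bh_family BH family scope for [call_enrichment()].
#' @param out_dir optional output directory (created if needed).
#' @return list of class `chipsip_run`: `experiment`, `spots` (annotated),
#'   `fits`, `consensus`, `ancova` (or `NULL`), `table1` (or `NULL`),
#'   `contributions`, `report`.
#' @export
run_pipeline <- function(design, effect_spec = NULL, seed = design$seed,
                         alpha = 0.05, min_spots = 5L,
                         consensus_threshold = NULL,
                         bh_family = c("array", "global"),
                         out_dir = NULL) {
  bh_family <- match.arg(bh_family)
  exper <- generate_experiment(design, effect_spec, seed = seed)
  spots <- annotate_spots(exper$spots)
  fits <- fit_hce_table(spots, min_spots = min_spots)
  fits <- call_enrichment(fits, alpha = alpha, family = bh_family)
  consensus <- consensus_table(fits, threshold = consensus_threshold)

  anc <- NULL; tab1 <- NULL
  can_contrast <- any(vapply(contrast_specs(), function(sp) {
    lv <- unique(spots[[sp$var]][spots[[names(sp$fix)]] == sp$fix[[1]]])
    all(c(sp$A, sp$B) %in% lv)
  }, logical(1)))
  if (can_contrast) {
    anc <- ancova_contrasts(spots, alpha = alpha, min_spots = min_spots)
    tab1 <- tabulate_contrasts(anc, taxonomy = design$taxonomy)
  }

  fam_hce <- family_mean_hce(fits, design$taxonomy)
  fam_frac <- family_read_fractions(exper$reads)
  contrib <- weighted_contribution(fam_hce, fam_frac)

  report <- list(
    package_version = as.character(utils::packageVersion("chipsip")),
    seed = as.integer(seed),
    alpha = alpha, min_spots = as.integer(min_spots),
    bh_family = bh_family,
    n_arrays = length(unique(spots$array_id)),
    n_otus = design$n_otus,
    n_spots = nrow(exper$spots),
    n_spots_excluded = nrow(attr(spots, "excluded")),
    n_fits = nrow(fits),
    n_fits_skipped = nrow(attr(fits, "skipped")),
    n_enriched_calls = sum(fits$enriched),
    n_otus_enriched_by_condition = {
      enr <- consensus[consensus$enriched, , drop = FALSE]
      cnt <- table(paste(enr$treatment, enr$fraction, sep = "/"))
      as.list(stats::setNames(as.integer(cnt), names(cnt)))
    },
    n_significant_contrasts = if (is.null(anc)) 0L else
      sum(anc$direction != "none")
  )

  out <- list(experiment = exper, spots = spots, fits = fits,
              consensus = consensus, ancova = anc, table1 = tab1,
              contributions = contrib, report = report)
  class(out) <- "chipsip_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spot <- exper$spots
    write_tsv(write_spot, file.path(out_dir, "spots.tsv"))
    write_tsv(spots, file.path(out_dir, "spots_annotated.tsv"))
    write_tsv(fits, file.path(out_dir, "hce.tsv"))
    write_tsv(consensus, file.path(out_dir, "consensus.tsv"))
    if (!is.null(anc)) {
      write_tsv(anc, file.path(out_dir, "ancova.tsv"))
      write_tsv(tab1, file.path(out_dir, "contrast_table.tsv"))
    }
    write_tsv(contrib, file.path(out_dir, "contributions.tsv"))
    write_tsv(exper$reads, file.path(out_dir, "reads.tsv"))
    write_tsv(exper$truth$slopes, file.path(out_dir, "truth_slopes.tsv"))
    yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  }
  out
}

#' @export
print.chipsip_run <- function(x, ...) {
  r <- x$report
  cat("Chip-SIP pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  %d arrays, %d OTUs, %d spots (%d excluded)\n",
              r$n_arrays, r$n_otus, r$n_spots, r$n_spots_excluded))
  cat(sprintf("  HCE fits: %d (%d skipped); enriched calls: %d\n",
              r$n_fits, r$n_fits_skipped, r$n_enriched_calls))
  if (length(r$n_otus_enriched_by_condition)) {
    cat("  consensus-enriched OTUs by condition:\n")
    for (nm in names(r$n_otus_enriched_by_condition))
      cat(sprintf("    %s: %d\n", nm, r$n_otus_enriched_by_condition[[nm]]))
  }
  cat(sprintf("  significant ANCOVA contrasts: %d\n",
              r$n_significant_contrasts))
  invisible(x)
}
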