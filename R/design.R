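#' Describe a Chip-SIP experiment layout
#'
#' Collects the design parameters of a Chip-SIP experiment: which treatments
#' and size fractions were incubated, how many replicate arrays were run per
#' condition, how many OTUs are targeted with how many probes each, and the
#' physical parameters of the NanoSIMS measurement (background isotope ratio,
#' mean total CN ion counts per probe spot).
#'
#' Fluorescence is expressed throughout in kilo-units of scanner signal
#' ("kflu"); HCE slopes are therefore in permil per kflu.
#'
#' @param treatments character vector of treatment labels
#'   (default `c("light", "dark")`).
#' @param fractions character vector of size-fraction labels
#'   (default `c("attached", "free_living")`).
#' @param replicates_per_condition number of replicate arrays per
#'   (treatment, fraction) condition (default 3).
#' @param n_otus number of target OTUs on the array.
#' @param probes_per_otu number of probes per OTU (default 25). Must be at
#'   least 2 for a regression to be defined; a warning is issued below 5.
#' @param control_spots_per_array number of control-oligonucleotide spots
#'   per array (default 10); these define the array's background ratio.
#' @param background_ratio true 15N/14N background ratio of unlabeled rRNA
#'   (default 0.003676, natural abundance).
#' @param mean_total_cn_counts expected total CN- secondary ion counts
#'   (14N + 15N channels) collected per probe spot (default 2e6).
#' @param mean_fluorescence geometric-mean spot fluorescence in kflu
#'   (default 5).
#' @param sdlog_affinity log-scale SD of the fixed per-probe hybridization
#'   affinity multiplier, emulating the designed spread of probe melting
#'   temperatures (default 0.5).
#' @param sdlog_fluorescence log-scale SD of residual spot-to-spot
#'   fluorescence noise (default 0.2).
#' @param include_c13 also simulate a 13C14N- ion channel (never used in
#'   enrichment calls; it carries a higher, noisier background).
#' @param read_depth 16S reads per sequenced sample for the companion
#'   read-count table (default 20000).
#' @param taxonomy data frame mapping `otu_id` to `family` (and optionally a
#'   full `lineage`); defaults to [default_taxonomy()] over `n_otus`.
#' @param seed default random seed used by the generators.
#'
#' @return An object of class `chipsip_design` (a validated list).
#' @seealso [generate_experiment()], [generate_null_experiment()]
#' @export
experiment_design <- function(treatments = c("light", "dark"),
                              fractions = c("attached", "free_living"),
                              replicates_per_condition = 3L,
                              n_otus,
                              probes_per_otu = 25L,
                              control_spots_per_array = 10L,
                              background_ratio = 0.003676,
                              mean_total_cn_counts = 2e6,
                              mean_fluorescence = 5,
                              sdlog_affinity = 0.5,
                              sdlog_fluorescence = 0.2,
                              include_c13 = FALSE,
                              read_depth = 20000L,
                              taxonomy = NULL,
                              seed = 1L) {
  stopifnot(length(treatments) >= 1, length(fractions) >= 1)
  if (anyDuplicated(treatments) || anyDuplicated(fractions))
    stop("treatment and fraction labels must be unique")
  replicates_per_condition <- as.integer(replicates_per_condition)
  if (is.na(replicates_per_condition) || replicates_per_condition < 1L)
    stop("replicates_per_condition must be >= 1")
  n_otus <- as.integer(n_otus)
  if (is.na(n_otus) || n_otus < 1L) stop("n_otus must be a positive integer")
  probes_per_otu <- as.integer(probes_per_otu)
  if (is.na(probes_per_otu) || probes_per_otu < 2L)
    stop("probes_per_otu must be >= 2 (a slope needs at least 2 spots)")
  if (probes_per_otu < 5L)
    warning("probes_per_otu < 5: per-array HCE fits will have very few ",
            "degrees of freedom")
  control_spots_per_array <- as.integer(control_spots_per_array)
  if (is.na(control_spots_per_array) || control_spots_per_array < 1L)
    stop("control_spots_per_array must be >= 1")
  if (!is.finite(background_ratio) || background_ratio <= 0)
    stop("background_ratio must be > 0")
  if (!is.finite(mean_total_cn_counts) || mean_total_cn_counts <= 0)
    stop("mean_total_cn_counts must be > 0")
  if (!is.finite(mean_fluorescence) || mean_fluorescence <= 0)
    stop("mean_fluorescence must be > 0")
  if (sdlog_affinity < 0 || sdlog_fluorescence < 0)
    stop("log-scale standard deviations must be >= 0")
  read_depth <- as.integer(read_depth)
  if (is.na(read_depth) || read_depth < 1L) stop("read_depth must be >= 1")

  if (is.null(taxonomy)) taxonomy <- default_taxonomy(n_otus)
  if (!all(c("otu_id", "family") %in% names(taxonomy)))
    stop("taxonomy must have columns 'otu_id' and 'family'")
  if (nrow(taxonomy) != n_otus || anyDuplicated(taxonomy$otu_id))
    stop("taxonomy must have exactly one row per OTU")

  design <- list(
    treatments = as.character(treatments),
    fractions = as.character(fractions),
    replicates_per_condition = replicates_per_condition,
    n_otus = n_otus,
    probes_per_otu = probes_per_otu,
    control_spots_per_array = control_spots_per_array,
    background_ratio = background_ratio,
    mean_total_cn_counts = mean_total_cn_counts,
    mean_fluorescence = mean_fluorescence,
    sdlog_affinity = sdlog_affinity,
    sdlog_fluorescence = sdlog_fluorescence,
    include_c13 = isTRUE(include_c13),
    read_depth = read_depth,
    taxonomy = taxonomy,
    seed = as.integer(seed)
  )
  class(design) <- "chipsip_design"
  design
}

#' @export
print.chipsip_design <- function(x, ...) {
  cat("Chip-SIP experiment design\n")
  cat(sprintf("  conditions: %d treatment(s) x %d fraction(s) x %d replicate(s) = %d arrays\n",
              length(x$treatments), length(x$fractions),
              x$replicates_per_condition, n_arrays(x)))
  cat(sprintf("  targets: %d OTUs x %d probes + %d control spots per array\n",
              x$n_otus, x$probes_per_otu, x$control_spots_per_array))
  cat(sprintf("  background 15N/14N ratio: %g; mean CN counts per spot: %g\n",
              x$background_ratio, x$mean_total_cn_counts))
  invisible(x)
}

n_arrays <- function(design) {
  length(design$treatments) * length(design$fractions) *
    design$replicates_per_condition
}

otu_ids <- function(design) design$taxonomy$otu_id

#' Default OTU-to-family assignment for simulated experiments
#'
#' Assigns OTUs round-robin to a panel of bacterial families typical of
#' phytodetritus-amended coastal seawater incubations, with full
#' semicolon-delimited lineages so taxonomy parsing can be exercised on
#' realistic strings.
#'
#' @param n_otus number of OTUs.
#' @return data frame with columns `otu_id`, `family`, `lineage`.
#' @export
default_taxonomy <- function(n_otus) {
  panel <- data.frame(
    family = c("Flavobacteriaceae", "Alteromonadaceae", "Colwelliaceae",
               "Rhodobacteraceae", "Pseudoalteromonadaceae",
               "Oceanospirillaceae", "Cryomorphaceae", "Rhodospirillaceae"),
    lineage = c(
      "Bacteria;Bacteroidetes;Flavobacteria;Flavobacteriales;Flavobacteriaceae",
      "Bacteria;Gammaproteobacteria;Gammaproteobacteria;Alteromonadales;Alteromonadaceae",
      "Bacteria;Gammaproteobacteria;Gammaproteobacteria;Alteromonadales;Colwelliaceae",
      "Bacteria;Alphaproteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae",
      "Bacteria;Gammaproteobacteria;Gammaproteobacteria;Alteromonadales;Pseudoalteromonadaceae",
      "Bacteria;Gammaproteobacteria;Gammaproteobacteria;Oceanospirillales;Oceanospirillaceae",
      "Bacteria;Bacteroidetes;Flavobacteria;Flavobacteriales;Cryomorphaceae",
      "Bacteria;Alphaproteobacteria;Alphaproteobacteria;Rhodospirillales;Rhodospirillaceae"),
    stringsAsFactors = FALSE
  )
  idx <- ((seq_len(n_otus) - 1L) %% nrow(panel)) + 1L
  data.frame(
    otu_id = sprintf("OTU%04d", seq_len(n_otus)),
    family = panel$family[idx],
    lineage = paste0(panel$lineage[idx], ";",
                     sub("aceae.*$", "", panel$family[idx]), "_genus"),
    stringsAsFactors = FALSE
  )
}
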