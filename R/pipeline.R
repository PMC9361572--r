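#  End-to-end pipeline: Ka/Ks estimation on a pair list, optional
#  divergence dating, and event binning, with run metadata so every output
#  is reproducible from its inputs and configuration.

#' Read a polyploidization anchor configuration file
#'
#' Flat `key=value` file: a `genome=` line plus one `event_name=ks` line per
#' anchor.
#'
#' @param path Path to the config file.
#' @return An [event_anchor_set()].
#' @export
read_anchor_config <- function(path) {
  cfg <- read_config(path)
  if (!"genome" %in% names(cfg)) stop("anchor config needs a 'genome' key")
  ev <- cfg[names(cfg) != "genome"]
  if (length(ev) == 0L) stop("anchor config has no events")
  vals <- suppressWarnings(as.numeric(ev))
  if (any(is.na(vals)))
    stop("non-numeric anchor Ks for event(s): ",
         paste(names(ev)[is.na(vals)], collapse = ", "))
  event_anchor_set(cfg[["genome"]], setNames(vals, names(ev)))
}

#' Read a lineage-rate configuration file
#'
#' Flat `key=value` file with keys `within_clade_rate`, `cross_clade_rate`
#' (substitutions/site/year) and one `clade.<species>=<clade>` line per
#' species.
#'
#' @param path Path to the config file.
#' @return A `rate_config` (see [default_rate_config()]).
#' @export
read_rate_config <- function(path) {
  cfg <- read_config(path,
                     allowed = c("^within_clade_rate$", "^cross_clade_rate$",
                                 "^clade\\.[^=]+$"),
                     allow_regex = TRUE)
  need <- c("within_clade_rate", "cross_clade_rate")
  if (!all(need %in% names(cfg)))
    stop("rate config needs keys: ", paste(need, collapse = ", "))
  sp <- grepl("^clade\\.", names(cfg))
  if (!any(sp)) stop("rate config has no clade.<species> entries")
  default_rate_config(
    clades = setNames(unname(cfg[sp]), sub("^clade\\.", "", names(cfg)[sp])),
    within_rate = rate_model("within_clade", as.numeric(cfg[["within_clade_rate"]])),
    cross_rate = rate_model("cross_clade", as.numeric(cfg[["cross_clade_rate"]])))
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the Ka/Ks, dating and event-binning pipeline
#'
#' Wires the stages together on file inputs: reads aligned coding sequences
#' and a pair list, computes NG86 Ka/Ks for every pair, optionally converts
#' Ks to divergence times under a rate model, bins Ks against
#' polyploidization anchors, and writes `kaks.tsv`, `times.tsv` (when a
#' rate is given), `bins.tsv`, `bin_counts.tsv` and `run_metadata.txt` into
#' the output directory.  Identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param cds_fasta Path to aligned coding sequences (FASTA; each listed
#'   pair mutually aligned, in frame).
#' @param pair_tsv Path to the two-column pair list.
#' @param anchors An `anchor_set`, or a path to an anchor config file, or
#'   `NULL` to skip binning.
#' @param rate A `rate_model`, or `NULL` to skip dating.
#' @param relation Relation tag for the pair list.
#' @param min_codons Passed to [compute_kaks()].
#' @param time_digits Decimals for reported divergence times.
#' @return Invisibly, a list with the stage tables (`kaks`, `times`,
#'   `binning`) and the output paths.
#' @export
run_pipeline <- function(out_dir, cds_fasta, pair_tsv, anchors = NULL,
                         rate = NULL, relation = "paralog",
                         min_codons = 30L, time_digits = 2L) {
  if (is.character(anchors))
    anchors <- .run_stage("config", read_anchor_config(anchors))
  if (!is.null(anchors) && !inherits(anchors, "anchor_set"))
    stop("stage 'config' failed: anchors must be an anchor_set or a config path")
  if (!is.null(rate) && !inherits(rate, "rate_model"))
    stop("stage 'config' failed: rate must be a rate_model")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cds <- .run_stage("read_cds", read_fasta(cds_fasta))
  pairs <- .run_stage("read_pairs", read_pair_list(pair_tsv, relation))
  if (nrow(pairs) == 0L) stop("stage 'read_pairs' failed: no pairs to analyze")

  kaks <- .run_stage("kaks", kaks_table(pairs, cds, min_codons = min_codons))
  paths <- c(kaks = file.path(out_dir, "kaks.tsv"))
  write_results_tsv(kaks, paths[["kaks"]])

  times <- NULL
  if (!is.null(rate)) {
    times <- .run_stage("date",
                        divergence_time(kaks$Ks, rate, kaks$pair_id))
    times$T_mya <- round(times$T_mya, time_digits)
    paths[["times"]] <- file.path(out_dir, "times.tsv")
    write_results_tsv(times, paths[["times"]])
  }

  binning <- NULL
  if (!is.null(anchors)) {
    binning <- .run_stage("assign", bin_pairs(kaks, anchors))
    paths[["bins"]] <- file.path(out_dir, "bins.tsv")
    paths[["bin_counts"]] <- file.path(out_dir, "bin_counts.tsv")
    write_results_tsv(rbind(binning$assignments, binning$unassigned),
                      paths[["bins"]])
    write_results_tsv(binning$counts, paths[["bin_counts"]])
  }

  meta <- c(
    sprintf("ksdater_version=%s", as.character(packageVersion("ksdater"))),
    sprintf("cds_fasta=%s", cds_fasta),
    sprintf("pair_tsv=%s", pair_tsv),
    sprintf("relation=%s", relation),
    sprintf("n_pairs=%d", nrow(pairs)),
    sprintf("min_codons=%d", as.integer(min_codons)),
    "genetic_code=standard",
    "ng86_site_stops=nonsynonymous",
    "ng86_pathway_stops=excluded_then_nonsynonymous_fallback",
    "gap_handling=complete_deletion_by_codon",
    if (!is.null(rate)) sprintf("rate=%s:%.4g", rate$name, rate$r),
    if (!is.null(anchors)) sprintf("anchors=%s:%s", anchors$genome,
                                   paste(sprintf("%s=%.4f",
                                                 names(anchors$anchors),
                                                 anchors$anchors),
                                         collapse = ",")))
  paths[["metadata"]] <- file.path(out_dir, "run_metadata.txt")
  writeLines(meta, paths[["metadata"]])

  invisible(list(kaks = kaks, times = times, binning = binning,
                 paths = paths))
}
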