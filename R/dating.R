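#  Divergence-time estimation from Ks (T = Ks / 2r) and assignment of
#  paralogous pairs to polyploidization events by binning Ks against the
#  events' modal Ks anchors.

#' Neutral substitution rate model
#'
#' @param name Rate label (e.g. `"apiaceae_within"`).
#' @param r Neutral substitution rate in substitutions per site per year
#'   (must be positive).
#' @return Object of class `rate_model`.
#' @examples
#' rate_model("apiaceae_within", 5.2e-9)
#' @export
rate_model <- function(name, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("rate r must be a single positive number")
  structure(list(name = as.character(name), r = r), class = "rate_model")
}

#' Default lineage-rate configuration
#'
#' Two-tier clock: a within-clade rate applied when both species belong to
#' the same configured clade, and a cross-clade rate otherwise.  The
#' defaults are the Apiaceae rate 5.2e-9 substitutions/site/year (celery,
#' coriander, carrot) and the dicotyledon average 1.5e-8 for comparisons
#' against outgroups such as Arabidopsis.
#'
#' @param clades Named character vector mapping species to clade labels.
#' @param within_rate,cross_rate `rate_model` objects.
#' @return A list of class `rate_config`.
#' @export
default_rate_config <- function(
    clades = c(celery = "apiaceae", coriander = "apiaceae",
               carrot = "apiaceae", arabidopsis = "rosid", grape = "rosid",
               lettuce = "asterid", ginseng = "asterid"),
    within_rate = rate_model("apiaceae_within", 5.2e-9),
    cross_rate = rate_model("dicot_average", 1.5e-8)) {
  structure(list(clades = clades, within_rate = within_rate,
                 cross_rate = cross_rate), class = "rate_config")
}

#' Select the neutral rate for a species pair
#'
#' Returns the within-clade rate when both species share a clade in the
#' configuration's lineage map, the cross-clade rate otherwise.  Unknown
#' species are an error.
#'
#' @param species_a,species_b Species names present in `config$clades`.
#' @param config A `rate_config`, see [default_rate_config()].
#' @return A `rate_model`.
#' @examples
#' select_rate("celery", "coriander")   # 5.2e-9
#' select_rate("celery", "arabidopsis") # 1.5e-8
#' @export
select_rate <- function(species_a, species_b, config = default_rate_config()) {
  unknown <- setdiff(c(species_a, species_b), names(config$clades))
  if (length(unknown) > 0L)
    stop("species not in lineage map: ", paste(unknown, collapse = ", "))
  if (config$clades[[species_a]] == config$clades[[species_b]])
    config$within_rate else config$cross_rate
}

#' Divergence time from Ks under a neutral molecular clock
#'
#' Applies `T = Ks / (2 r)` and reports T in millions of years (Mya).
#' `NaN` Ks values (saturated pairs) propagate to `NaN` times.
#'
#' @param ks Numeric vector of Ks values (`>= 0` or `NaN`).
#' @param rate A `rate_model`.
#' @param pair_id Optional identifiers (recycled).
#' @return Data frame with columns `pair_id`, `ks`, `rate_name`, `T_mya`
#'   (full precision; round on output).
#' @examples
#' divergence_time(0.1103, rate_model("apiaceae_within", 5.2e-9))
#' @export
divergence_time <- function(ks, rate, pair_id = NULL) {
  if (!inherits(rate, "rate_model")) stop("rate must be a rate_model")
  if (!is.numeric(ks)) stop("ks must be numeric")
  neg <- !is.nan(ks) & !is.na(ks) & ks < 0
  if (any(neg)) stop("negative ks value(s)")
  if (is.null(pair_id)) pair_id <- paste0("pair", seq_along(ks))
  data.frame(pair_id = rep_len(as.character(pair_id), length(ks)),
             ks = ks, rate_name = rate$name,
             T_mya = ks / (2 * rate$r) / 1e6,
             stringsAsFactors = FALSE)
}

#' Polyploidization event anchor set
#'
#' An anchor is the modal Ks of the paralog pairs a polyploidization event
#' created; a pair's own Ks is bracketed between anchors to date its birth
#' relative to the events.
#'
#' @param genome Genome/species label.
#' @param anchors Named numeric vector of anchor Ks values; values must be
#'   positive and distinct, names unique.  Stored sorted ascending.
#' @return Object of class `anchor_set`.
#' @examples
#' event_anchor_set("celery",
#'   c(alpha = 0.3659, celery_omega = 0.7154, gamma = 1.2560))
#' @export
event_anchor_set <- function(genome, anchors) {
  if (!is.numeric(anchors) || is.null(names(anchors)) ||
      any(names(anchors) == ""))
    stop("anchors must be a named numeric vector")
  if (any(!is.finite(anchors)) || any(anchors <= 0))
    stop("anchor Ks values must be positive and finite")
  if (anyDuplicated(names(anchors))) stop("duplicate event names")
  anchors <- sort(anchors)
  if (any(diff(anchors) <= 0)) stop("anchor Ks values must be distinct")
  structure(list(genome = as.character(genome), anchors = anchors),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Polyploidization anchors for %s:\n", x$genome))
  for (i in seq_along(x$anchors))
    cat(sprintf("  %-15s Ks = %.4f\n", names(x$anchors)[i], x$anchors[i]))
  invisible(x)
}

#' Built-in polyploidization anchors
#'
#' Modal Ks anchors of the polyploidization events in the supported
#' genomes: the eudicot gamma triplication (Ks 1.2560) and the Apiaceae
#' alpha duplication (0.3659) shared by celery, coriander and carrot; the
#' genome-specific omega duplications (celery 0.7154, coriander 0.7194,
#' carrot 0.7470); the lettuce-specific L1 event (0.6415); and the two
#' ginseng-specific events G1 (0.2884) and G2 (0.0297).
#'
#' @param genome One of `"celery"`, `"coriander"`, `"carrot"`, `"lettuce"`,
#'   `"ginseng"`.
#' @return An `anchor_set`.
#' @examples
#' polyploidy_anchors("celery")
#' @export
polyploidy_anchors <- function(genome = c("celery", "coriander", "carrot",
                                          "lettuce", "ginseng")) {
  genome <- match.arg(genome)
  sets <- list(
    celery    = c(alpha = 0.3659, celery_omega = 0.7154, gamma = 1.2560),
    coriander = c(alpha = 0.3659, coriander_omega = 0.7194, gamma = 1.2560),
    carrot    = c(alpha = 0.3659, carrot_omega = 0.7470, gamma = 1.2560),
    lettuce   = c(L1 = 0.6415, gamma = 1.2560),
    ginseng   = c(G2 = 0.0297, G1 = 0.2884, gamma = 1.2560))
  event_anchor_set(genome, sets[[genome]])
}

# Interval index (1..m+1) for each finite ks given ascending anchor values;
# intervals are (lower, upper], so ks == anchor falls in the anchor's own
# interval.
.interval_index <- function(ks, anchor_values) {
  findInterval(ks, anchor_values, left.open = TRUE) + 1L
}

.interval_labels <- function(anchors) {
  ev <- names(anchors$anchors)
  m <- length(ev)
  if (m == 1L) return(c(paste0("after_", ev[1L]), paste0("before_", ev[1L])))
  c(paste0("after_", ev[1L]),
    paste0("between_", ev[-m], "_", ev[-1L]),
    paste0("before_", ev[m]))
}

# Four-colour scheme used when a three-anchor set (most recent, middle,
# oldest -- e.g. alpha, omega, gamma) is active: red = younger than the
# most recent event, green/orange = between anchors, blue = older than the
# oldest event.
.interval_colors <- function(n_anchors) {
  if (n_anchors == 3L) c("red", "green", "orange", "blue")
  else rep(NA_character_, n_anchors + 1L)
}

#' Assign Ks values to polyploidization-event intervals
#'
#' Each finite Ks is placed in one of the half-open intervals
#' `(lower, upper]` delimited by the anchor Ks values; a Ks exactly equal to
#' an anchor belongs to that anchor's interval.  The attributed event is the
#' upper bounding anchor's event (a pair inside `(alpha, omega]` is read as
#' born with the omega event); Ks above the largest anchor predates all
#' events and gets no attribution.  `NaN` Ks values are labelled
#' `"unassigned"` with a warning.
#'
#' @param ks Numeric vector of Ks values (finite values must be `>= 0`).
#' @param anchors An `anchor_set`.
#' @param pair_id Optional identifiers (recycled).
#' @return Data frame with columns `pair_id`, `ks`, `interval_label`,
#'   `attributed_event`, `color_class` (four-colour scheme when the anchor
#'   set has exactly three events, else `NA`).
#' @examples
#' assign_event(c(0.6081, 0.9464, 1.5), polyploidy_anchors("celery"))
#' @export
assign_event <- function(ks, anchors, pair_id = NULL) {
  if (!inherits(anchors, "anchor_set")) stop("anchors must be an anchor_set")
  if (!is.numeric(ks)) stop("ks must be numeric")
  fin <- is.finite(ks)
  if (any(fin & ks < 0)) stop("negative ks value(s)")
  if (any(!fin)) warning(sprintf("%d Ks value(s) not finite; left unassigned",
                                 sum(!fin)))
  if (is.null(pair_id)) pair_id <- paste0("pair", seq_along(ks))
  av <- anchors$anchors
  labels <- .interval_labels(anchors)
  colors <- .interval_colors(length(av))
  events <- c(names(av), NA_character_)  # attributed = upper bounding anchor

  idx <- rep(NA_integer_, length(ks))
  idx[fin] <- .interval_index(ks[fin], av)
  data.frame(pair_id = rep_len(as.character(pair_id), length(ks)),
             ks = ks,
             interval_label = ifelse(is.na(idx), "unassigned", labels[idx]),
             attributed_event = events[ifelse(is.na(idx), length(events), idx)],
             color_class = colors[ifelse(is.na(idx), NA_integer_, idx)],
             stringsAsFactors = FALSE)
}

#' Bin Ka/Ks results against polyploidization anchors
#'
#' Runs [assign_event()] on the Ks column of a results table and tallies
#' pairs per interval.
#'
#' @param kaks Data frame with columns `pair_id` and `Ks` (as produced by
#'   [kaks_table()]), or `ks`.
#' @param anchors An `anchor_set`.
#' @return List of class `ks_binning` with elements `assignments` (one row
#'   per finite-Ks pair), `unassigned` (NaN-Ks pairs) and `counts` (one row
#'   per interval, zero counts included).
#' @examples
#' k <- data.frame(pair_id = c("p1", "p2"), Ks = c(0.6081, 0.9464))
#' bin_pairs(k, polyploidy_anchors("celery"))$counts
#' @export
bin_pairs <- function(kaks, anchors) {
  ks_col <- if ("Ks" %in% names(kaks)) "Ks" else "ks"
  if (!ks_col %in% names(kaks)) stop("kaks needs a 'Ks' (or 'ks') column")
  ids <- if ("pair_id" %in% names(kaks)) kaks$pair_id
         else paste0("pair", seq_len(nrow(kaks)))
  asg <- if (nrow(kaks) > 0L)
    suppressWarnings(assign_event(kaks[[ks_col]], anchors, ids))
  else
    assign_event(numeric(0), anchors)
  labels <- .interval_labels(anchors)
  events <- c(names(anchors$anchors), NA_character_)
  fin <- asg$interval_label != "unassigned"
  counts <- data.frame(
    interval_label = labels,
    attributed_event = events,
    n = as.integer(table(factor(asg$interval_label[fin], levels = labels))),
    stringsAsFactors = FALSE)
  structure(list(genome = anchors$genome,
                 assignments = asg[fin, , drop = FALSE],
                 unassigned = asg[!fin, , drop = FALSE],
                 counts = counts),
            class = "ks_binning")
}

#' @export
print.ks_binning <- function(x, ...) {
  cat(sprintf("Ks binning against %s anchors: %d pair(s), %d unassigned\n",
              x$genome, nrow(x$assignments), nrow(x$unassigned)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
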