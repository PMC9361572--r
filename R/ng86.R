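#  Nei-Gojobori (1986) counting method for pairwise Ka/Ks.
#
#  Conventions implemented (recorded in run metadata by the pipeline):
#  * standard genetic code only;
#  * single-nucleotide mutations that create a stop codon count as
#    nonsynonymous in site counting;
#  * mutational pathways passing through a stop codon are excluded from
#    difference counting; if every pathway is excluded, all pathways are
#    used with stop-entering steps counted as nonsynonymous;
#  * codon columns containing gaps or ambiguity codes are dropped whole
#    (complete deletion at codon granularity).

.BASES <- c("A", "C", "G", "T")

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
}

.is_stop <- function(codon) unname(.genetic_code()[codon] == "*")

# All 9 single-nucleotide neighbours of a codon.
.codon_neighbors <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(.BASES, nt[pos])) {
      mut <- nt
      mut[pos] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

# Fractional synonymous/nonsynonymous site count for one sense codon.
.sites_one <- function(codon, code) {
  aa <- code[[codon]]
  nb <- .codon_neighbors(codon)
  syn <- sum(code[nb] == aa)  # stop neighbours translate to "*" != aa
  c(s = syn / 3, n = 3 - syn / 3)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged (Sd, Nd) between two sense codons.
.diffs_one <- function(codon_a, codon_b, code) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  paths <- .permutations(pos)
  step_counts <- function(order, allow_stop) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && !allow_stop) return(NULL)
      if (aa_cur == aa_nxt && aa_nxt != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- Filter(Negate(is.null), lapply(paths, step_counts, allow_stop = FALSE))
  if (length(counted) == 0L) {
    counted <- lapply(paths, step_counts, allow_stop = TRUE)
  }
  m <- do.call(rbind, counted)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# Precompute per-codon site counts and the 61 x 61 pathway-averaged
# difference tables once per session; all pair computations are lookups.
.build_ng86_tables <- function() {
  code <- as.list(.genetic_code())
  sense <- names(.genetic_code())[.genetic_code() != "*"]
  sites <- t(vapply(sense, .sites_one, c(s = 0, n = 0), code = .genetic_code()))
  nsen <- length(sense)
  Sd <- Nd <- matrix(0, nsen, nsen, dimnames = list(sense, sense))
  for (i in seq_len(nsen)) {
    for (j in seq_len(nsen)) {
      if (j < i) {
        Sd[i, j] <- Sd[j, i]
        Nd[i, j] <- Nd[j, i]
      } else if (j > i) {
        d <- .diffs_one(sense[i], sense[j], code)
        Sd[i, j] <- d[["Sd"]]
        Nd[i, j] <- d[["Nd"]]
      }
    }
  }
  assign("sense_codons", sense, envir = .ksdater_env)
  assign("site_table", sites, envir = .ksdater_env)
  assign("Sd_table", Sd, envir = .ksdater_env)
  assign("Nd_table", Nd, envir = .ksdater_env)
  invisible(NULL)
}

.ng86_tables <- function() {
  if (!exists("site_table", envir = .ksdater_env)) .build_ng86_tables()
  .ksdater_env
}

.check_sense_codon <- function(codon, arg = "codon") {
  if (length(codon) != 1L || !grepl("^[ACGT]{3}$", codon))
    stop(sprintf("%s must be a single codon over {A,C,G,T}, got '%s'",
                 arg, paste(codon, collapse = ",")))
  if (.is_stop(codon))
    stop(sprintf("%s is a stop codon ('%s'); sense codon required", arg, codon))
  invisible(codon)
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the nine single-nucleotide mutations of a sense codon, a
#' mutation that preserves the encoded amino acid contributes 1/3 to the
#' synonymous site count `s`; all other mutations, including those creating a
#' stop codon, contribute 1/3 to the nonsynonymous count `n`.  By
#' construction `s + n == 3` for every sense codon.
#'
#' @param codon A single sense codon (string over A/C/G/T, standard code).
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' count_codon_sites("TTT")  # 1/3 synonymous, 8/3 nonsynonymous
#' count_codon_sites("TGG")  # tryptophan: no synonymous sites
#' @export
count_codon_sites <- function(codon) {
  codon <- toupper(codon)
  .check_sense_codon(codon)
  tab <- .ng86_tables()$site_table
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

#' Pathway-averaged synonymous and nonsynonymous differences between codons
#'
#' Codons differing at `k` positions are connected by `k!` single-step
#' mutational pathways.  Each step is classified as synonymous or
#' nonsynonymous and the counts are averaged over pathways.  Pathways whose
#' intermediate codons are stops are excluded; if every pathway is excluded,
#' all pathways are used with stop-entering steps counted as nonsynonymous.
#' `Sd + Nd` equals the number of differing nucleotide positions.
#'
#' @param codon_a,codon_b Sense codons (strings over A/C/G/T).
#' @return Named numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' count_codon_differences("TTT", "TTC")  # one synonymous difference
#' count_codon_differences("TTT", "GTA")  # two pathways averaged
#' @export
count_codon_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  .check_sense_codon(codon_a, "codon_a")
  .check_sense_codon(codon_b, "codon_b")
  env <- .ng86_tables()
  c(Sd = env$Sd_table[codon_a, codon_b], Nd = env$Nd_table[codon_a, codon_b])
}

#' Jukes--Cantor multiple-hit correction
#'
#' Converts an observed proportion of differences per site `p` into an
#' estimated number of substitutions per site, `d = -3/4 * log(1 - 4p/3)`.
#' The formula diverges at `p = 0.75`; at or beyond that boundary the
#' estimate is saturated and `NaN` is returned.
#'
#' @param p Numeric vector of difference proportions, each `>= 0`.
#' @return Numeric vector of corrected distances; `NaN` where `p >= 0.75`.
#' @examples
#' jukes_cantor(c(0, 0.1, 0.75))
#' @export
jukes_cantor <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- !is.nan(p) & !is.na(p) & p < 0
  if (any(bad)) stop("p must be non-negative")
  ifelse(is.nan(p) | p >= 0.75, NaN, -0.75 * log(1 - 4 * p / 3))
}

#' Prepare an aligned coding-sequence pair for Ka/Ks estimation
#'
#' Takes two pre-aligned, in-frame coding sequences of equal length and
#' produces the cleaned codon pair on which NG86 counting operates:
#' a terminal stop codon column is stripped, codon columns containing a gap
#' (`-`), `N`, or any non-ACGT symbol in either sequence are dropped whole
#' (complete deletion) and counted in `excluded_codons`, and any stop codon
#' remaining in a retained column raises an error naming the codon index.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length divisible
#'   by 3.
#' @param pair_id Identifier carried through to results.
#' @return An object of class `codon_pair` with elements `pair_id`,
#'   `codons_a`, `codons_b` (retained codon vectors), `seq_a`, `seq_b`
#'   (retained sequences) and `excluded_codons`.
#' @examples
#' preprocess_pair("ATGAAATAA", "ATGAAGTAA", "toy")
#' @export
preprocess_pair <- function(seq_a, seq_b, pair_id = "pair") {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop(sprintf("aligned sequences must have equal length (%d vs %d)",
                 nchar(seq_a), nchar(seq_b)))
  if (nchar(seq_a) %% 3L != 0L)
    stop(sprintf("aligned length %d is not divisible by 3", nchar(seq_a)))
  if (nchar(seq_a) == 0L) stop("empty alignment")
  n <- nchar(seq_a) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  ca <- substring(seq_a, starts, starts + 2L)
  cb <- substring(seq_b, starts, starts + 2L)

  valid <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  # terminal stop column: stripped, not counted as excluded
  if (n > 0L && valid[n] && (.is_stop(ca[n]) || .is_stop(cb[n]))) {
    ca <- ca[-n]
    cb <- cb[-n]
    valid <- valid[-n]
    n <- n - 1L
  }
  keep <- which(valid)
  excluded <- n - length(keep)
  ca_keep <- ca[keep]
  cb_keep <- cb[keep]
  if (length(keep) == 0L) stop("no codon columns retained after filtering")

  stop_a <- .is_stop(ca_keep)
  stop_b <- .is_stop(cb_keep)
  if (any(stop_a | stop_b)) {
    idx <- keep[which(stop_a | stop_b)[1L]]
    seqname <- if (stop_a[which(stop_a | stop_b)[1L]]) "seq_a" else "seq_b"
    stop(sprintf("internal stop codon in %s at codon %d", seqname, idx))
  }
  structure(
    list(pair_id = pair_id,
         codons_a = ca_keep, codons_b = cb_keep,
         seq_a = paste(ca_keep, collapse = ""),
         seq_b = paste(cb_keep, collapse = ""),
         excluded_codons = excluded),
    class = "codon_pair")
}

#' Pairwise Ka/Ks by the Nei--Gojobori (1986) method
#'
#' Counts fractional synonymous (`S`) and nonsynonymous (`N`) sites averaged
#' over the two sequences, sums pathway-averaged synonymous (`Sd`) and
#' nonsynonymous (`Nd`) differences over codon columns, forms the
#' proportions `pS = Sd/S` and `pN = Nd/N`, and applies the Jukes--Cantor
#' correction to obtain `Ks` and `Ka`.  `omega = Ka/Ks` is `NaN` when `Ks`
#' is `NaN` or zero.  Saturation (`pS` or `pN >= 0.75`) yields `NaN` with
#' the corresponding flag set; pairs shorter than `min_codons` retained
#' codons are flagged `too_short` with a warning.
#'
#' @param pair A `codon_pair` from [preprocess_pair()], or an aligned
#'   sequence string (then `seq_b` must be supplied).
#' @param seq_b Optional second sequence when `pair` is a raw string.
#' @param pair_id Identifier used when building the pair from raw strings.
#' @param min_codons Minimum retained codons below which `too_short` is
#'   flagged (warning, not error).
#' @return An object of class `kaks_result`: a list with `pair_id`,
#'   `n_codons`, `excluded_codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `omega` and logical flags `saturated_s`, `saturated_n`,
#'   `too_short`.
#' @examples
#' p <- preprocess_pair("ATGAAACCC", "ATGAAGCCA", "toy")
#' compute_kaks(p)
#' @export
compute_kaks <- function(pair, seq_b = NULL, pair_id = "pair",
                         min_codons = 30L) {
  if (!inherits(pair, "codon_pair")) {
    if (is.null(seq_b)) stop("supply a codon_pair or two aligned sequences")
    pair <- preprocess_pair(pair, seq_b, pair_id)
  }
  env <- .ng86_tables()
  ca <- pair$codons_a
  cb <- pair$codons_b
  L <- length(ca)
  if (L == 0L) stop("zero retained codons")

  sa <- env$site_table[ca, , drop = FALSE]
  sb <- env$site_table[cb, , drop = FALSE]
  S <- (sum(sa[, "s"]) + sum(sb[, "s"])) / 2
  N <- (sum(sa[, "n"]) + sum(sb[, "n"])) / 2
  idx <- cbind(match(ca, rownames(env$Sd_table)),
               match(cb, colnames(env$Sd_table)))
  Sd <- sum(env$Sd_table[idx])
  Nd <- sum(env$Nd_table[idx])

  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  omega <- if (is.nan(Ks) || Ks == 0) NaN else Ka / Ks

  too_short <- L < min_codons
  if (too_short)
    warning(sprintf("pair '%s': only %d retained codons (< %d); estimates unstable",
                    pair$pair_id, L, min_codons))
  structure(
    list(pair_id = pair$pair_id, n_codons = L,
         excluded_codons = pair$excluded_codons,
         S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         Ks = Ks, Ka = Ka, omega = omega,
         saturated_s = !is.nan(pS) && pS >= 0.75,
         saturated_n = !is.nan(pN) && pN >= 0.75,
         too_short = too_short),
    class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks for pair '%s' (%d codons, %d excluded)\n",
              x$pair_id, x$n_codons, x$excluded_codons))
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks = %.4f  Ka = %.4f  Ka/Ks = %.4f\n", x$Ks, x$Ka, x$omega))
  invisible(x)
}

#' @export
as.data.frame.kaks_result <- function(x, ...) {
  data.frame(pair_id = x$pair_id, n_codons = x$n_codons,
             excluded_codons = x$excluded_codons,
             S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd,
             pS = x$pS, pN = x$pN, Ks = x$Ks, Ka = x$Ka, omega = x$omega,
             saturated_s = x$saturated_s, saturated_n = x$saturated_n,
             too_short = x$too_short, stringsAsFactors = FALSE)
}

#' Ka/Ks table for a list of gene pairs
#'
#' Looks up each pair's sequences in a named set of aligned coding
#' sequences, runs [compute_kaks()] and stacks the results.
#'
#' @param pairs A pair data frame from [read_pair_list()] (columns `gene_a`,
#'   `gene_b`).
#' @param cds Named character vector of aligned coding sequences, e.g. from
#'   [read_fasta()].  Each pair's two sequences must be mutually aligned.
#' @param min_codons Passed to [compute_kaks()].
#' @return Data frame with one row per pair (schema of
#'   `as.data.frame.kaks_result`).
#' @export
kaks_table <- function(pairs, cds, min_codons = 30L) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing) > 0L)
    stop("sequences missing from the CDS set: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    id <- paste(pairs$gene_a[i], pairs$gene_b[i], sep = "|")
    cp <- preprocess_pair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]], id)
    as.data.frame(compute_kaks(cp, min_codons = min_codons))
  })
  do.call(rbind, rows)
}
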