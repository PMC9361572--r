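#  MCScanX-style classification of family genes into five duplication
#  types.  Precedence: wgd_segmental > tandem > proximal > dispersed >
#  singleton.  Gene order ("rank") is genome-wide order within each
#  chromosome, so tandem means adjacent among ALL genes, not just family
#  members.

DUP_CLASSES <- c("wgd_segmental", "tandem", "proximal", "dispersed",
                 "singleton")

#' Classify family genes by duplication type
#'
#' Each gene receives exactly one of five labels, in precedence order:
#'
#' 1. `wgd_segmental` -- the gene appears in any collinear pair;
#' 2. `tandem` -- it has a homolog at adjacent gene rank
#'    (`|delta rank| == 1`) on the same chromosome;
#' 3. `proximal` -- it has a homolog within `1 < |delta rank| <=
#'    proximal_window` on the same chromosome;
#' 4. `dispersed` -- it has any other homolog;
#' 5. `singleton` -- no homology evidence at all.
#'
#' @param family_genes Character vector of gene ids to classify.
#' @param homolog_pairs Pair data frame (see [gene_pair_list()]) of homology
#'   evidence.
#' @param collinear_pairs Pair data frame of collinear (syntenic-block)
#'   pairs.
#' @param loci Locus data frame with `gene_id`, `chrom` and a `rank` column
#'   (see [read_locus_table()] / [assign_gene_ranks()]); must cover every
#'   gene referenced.
#' @param proximal_window Maximum gene-rank distance for the proximal rule
#'   (`>= 2`).
#' @return Object of class `dup_classification`: a data frame with columns
#'   `gene_id`, `class`, `partner`, `rule`, plus attribute
#'   `proximal_window`.
#' @export
classify_genes <- function(family_genes, homolog_pairs, collinear_pairs,
                           loci, proximal_window = 10L) {
  family_genes <- as.character(family_genes)
  if (length(family_genes) == 0L) stop("empty family gene set")
  if (proximal_window < 2L) stop("proximal_window must be >= 2")
  if (!"rank" %in% names(loci)) loci <- assign_gene_ranks(loci)

  referenced <- unique(c(family_genes, homolog_pairs$gene_a,
                         homolog_pairs$gene_b, collinear_pairs$gene_a,
                         collinear_pairs$gene_b))
  missing <- setdiff(referenced, loci$gene_id)
  if (length(missing) > 0L)
    stop("gene(s) without a locus: ", paste(missing, collapse = ", "))

  chrom_of <- setNames(loci$chrom, loci$gene_id)
  rank_of <- setNames(loci$rank, loci$gene_id)
  collinear_genes <- unique(c(collinear_pairs$gene_a, collinear_pairs$gene_b))

  # homolog partner lists, both directions
  partners <- split(c(homolog_pairs$gene_b, homolog_pairs$gene_a),
                    c(homolog_pairs$gene_a, homolog_pairs$gene_b))

  classify_one <- function(g) {
    if (g %in% collinear_genes) {
      prt <- c(collinear_pairs$gene_b[collinear_pairs$gene_a == g],
               collinear_pairs$gene_a[collinear_pairs$gene_b == g])
      return(c("wgd_segmental", sort(prt)[1L], "collinear_pair"))
    }
    prt <- sort(unique(partners[[g]]))
    if (length(prt) == 0L) return(c("singleton", NA, "no_homolog"))
    same <- prt[chrom_of[prt] == chrom_of[[g]]]
    dr <- abs(rank_of[same] - rank_of[[g]])
    if (any(dr == 1L))
      return(c("tandem", same[dr == 1L][1L], "adjacent_rank"))
    prox <- dr > 1L & dr <= proximal_window
    if (any(prox))
      return(c("proximal", same[prox][1L], "within_proximal_window"))
    c("dispersed", prt[1L], "distant_homolog")
  }

  m <- t(vapply(family_genes, classify_one, character(3)))
  res <- data.frame(gene_id = family_genes,
                    class = factor(m[, 1L], levels = DUP_CLASSES),
                    partner = m[, 2L], rule = m[, 3L],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "proximal_window") <- as.integer(proximal_window)
  class(res) <- c("dup_classification", "data.frame")
  res
}

#' Summarize duplication-type contributions
#'
#' Counts genes per duplication type and reports the percentage contribution
#' of each type, rounded to two decimals (so a 5-of-9 WGD/segmental share
#' prints as 55.56).
#'
#' @param result A `dup_classification` from [classify_genes()], or any data
#'   frame with a `class` column over the five labels.
#' @return Data frame with columns `class`, `count`, `percentage`; all five
#'   classes present (zero counts included).
#' @export
summarize_contribution <- function(result) {
  if (!is.data.frame(result) || !"class" %in% names(result))
    stop("result must have a 'class' column")
  if (nrow(result) == 0L) stop("empty classification result")
  counts <- table(factor(result$class, levels = DUP_CLASSES))
  data.frame(class = DUP_CLASSES,
             count = as.integer(counts),
             percentage = round(100 * as.integer(counts) / nrow(result), 2),
             stringsAsFactors = FALSE)
}
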