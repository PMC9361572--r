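#  Readers and writers for the external formats the pipeline touches:
#  FASTA (coding sequences), TSV (pair lists, locus tables, results),
#  newick (trees), and flat key=value configuration files.
#
#  Coordinate convention: locus tables on disk are 1-based inclusive (GFF
#  convention); in memory loci are 0-based half-open.

#' Read coding sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`.  Only the alphabet
#' `{A,C,G,T,N,-}` is accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not valid FASTA: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  setNames(unname(seqs), ids)
}

#' Read a gene locus table
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `start`, `end`,
#' `strand` with 1-based inclusive coordinates on disk (GFF convention).
#' Lines starting with `#` are ignored.  Coordinates are converted to
#' 0-based half-open, and a gene-order `rank` (0-based, consecutive within
#' each chromosome) is assigned by sorting on `(chrom, start)`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "chrom", "start", "end", "strand"))
  if (nrow(df) == 0L) stop("empty locus table: ", path)
  df$chrom <- as.character(df$chrom)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s) in locus table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- df$start >= df$end
  if (any(bad))
    stop("start >= end for gene(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ", "))
  df$start <- as.integer(df$start) - 1L  # to 0-based half-open
  df$end <- as.integer(df$end)
  assign_gene_ranks(df)
}

#' Assign gene-order ranks to a locus table
#'
#' Ranks are 0-based, consecutive within each chromosome, ordered by start
#' coordinate (strand is ignored: gene order, not transcription order).
#'
#' @param loci Data frame with at least `gene_id`, `chrom`, `start`.
#' @return The same data frame, sorted by `(chrom, start)`, with a `rank`
#'   column.
#' @export
assign_gene_ranks <- function(loci) {
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  loci$rank <- unlist(lapply(split(seq_len(nrow(loci)), loci$chrom)[unique(loci$chrom)],
                             function(ix) seq_along(ix) - 1L),
                      use.names = FALSE)
  rownames(loci) <- NULL
  loci
}

#' Read a two-column gene-pair list
#'
#' Pairs are canonicalized (lexicographically smaller id first) and
#' duplicates collapsed with a warning.  Self-pairs are an error.  Lines
#' starting with `#` are ignored; an empty file yields an empty pair list.
#'
#' @param path Path to a two-column TSV of gene ids.
#' @param relation Relation tag attached to every pair: one of `"ortholog"`,
#'   `"paralog"`, `"collinear"`, `"homolog"`.
#' @return Data frame with columns `gene_a`, `gene_b`, `relation`.
#' @export
read_pair_list <- function(path,
                           relation = c("homolog", "ortholog", "paralog",
                                        "collinear")) {
  relation <- match.arg(relation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(gene_pair_list(character(0), character(0), relation))
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) stop("pair list rows need two tab-separated ids")
  gene_pair_list(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                 relation)
}

#' Build a canonical gene-pair list from two id vectors
#'
#' @param gene_a,gene_b Character vectors of gene ids (recycled pairwise).
#' @param relation Relation tag (see [read_pair_list()]).
#' @return Data frame with columns `gene_a`, `gene_b`, `relation`;
#'   canonically ordered, duplicates collapsed (with a warning), self-pairs
#'   rejected.
#' @export
gene_pair_list <- function(gene_a, gene_b, relation = "homolog") {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b)) stop("gene_a and gene_b lengths differ")
  self <- gene_a == gene_b
  if (any(self))
    stop("self-pair(s) not allowed: ", paste(unique(gene_a[self]), collapse = ", "))
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  df <- data.frame(gene_a = a, gene_b = b,
                   relation = rep_len(relation, length(a)),
                   stringsAsFactors = FALSE)
  dup <- duplicated(paste(df$gene_a, df$gene_b, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate pair(s)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a rooted tree in newick format
#'
#' @param path Path to a newick file (one tree).
#' @return An `ape::phylo` tree.  Non-binary trees are accepted and flagged
#'   with attribute `binary = FALSE`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick file: ", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  attr(tree, "binary") <- ape::is.rooted(tree) && ape::is.binary(tree)
  tree
}

#' Read a gene-to-species leaf map
#'
#' Two-column TSV: gene-tree leaf name, species-tree leaf name.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `map[gene_leaf] == species`.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty species map: ", path)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) stop("species map rows need two tab-separated names")
  genes <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene leaf in species map: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  setNames(vapply(parts, `[`, "", 2L), genes)
}

#' Write a results table as TSV
#'
#' Header row; numeric columns printed with 4 decimals; `NA`/`NaN` printed
#' as `NA`; tab delimiter.
#'
#' @param records Data frame of results sharing one schema.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @return The path, invisibly.
#' @export
write_results_tsv <- function(records, path, digits = 4L) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v) | is.nan(v), "NA", formatC(v, format = "f",
                                                      digits = digits))
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write: ", path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key=value` entry per line; `#` comments and blank lines ignored;
#' whitespace around keys and values trimmed.
#'
#' @param path Path to the config file.
#' @param allowed Optional character vector (or regexes when
#'   `allow_regex = TRUE`) of permitted keys; unknown keys are an error.
#' @param allow_regex Treat `allowed` entries as regular expressions.
#' @return Named character vector of values.
#' @export
read_config <- function(path, allowed = NULL, allow_regex = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!all(grepl("=", lines)))
    stop("malformed config line(s) in ", path, " (expected key=value)")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (!is.null(allowed)) {
    ok <- if (allow_regex) {
      vapply(keys, function(k) any(vapply(allowed, grepl, TRUE, x = k)), TRUE)
    } else keys %in% allowed
    if (!all(ok))
      stop("unknown config key(s) in ", path, ": ",
           paste(keys[!ok], collapse = ", "))
  }
  setNames(vals, keys)
}
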