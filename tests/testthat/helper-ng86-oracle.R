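# Independent brute-force NG86 oracle.
#
# Written separately from the package implementation: translation goes
# through seqinr, neighbour enumeration and pathway averaging are done by
# direct recursion per call, with no lookup tables.  Used to cross-check
# the package's optimized (table-driven) estimator.

oracle_code <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons,
               function(cd) seqinr::translate(strsplit(cd, "")[[1]]), "")
  setNames(aa, codons)
})

oracle_sites <- function(codon) {
  aa <- oracle_code[[codon]]
  nt <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == nt[pos]) next
      mut <- nt
      mut[pos] <- b
      if (oracle_code[[paste(mut, collapse = "")]] == aa) syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# all orderings of the differing positions, by recursion
oracle_orders <- function(pos) {
  if (length(pos) <= 1L) return(list(pos))
  out <- list()
  for (i in seq_along(pos))
    for (rest in oracle_orders(pos[-i]))
      out[[length(out) + 1L]] <- c(pos[i], rest)
  out
}

oracle_diffs <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(Sd = 0, Nd = 0))
  walk <- function(order, strict) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- oracle_code[[paste(cur, collapse = "")]]
      aa2 <- oracle_code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && strict) return(NULL)
      if (aa1 == aa2 && aa2 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  orders <- oracle_orders(pos)
  kept <- Filter(Negate(is.null), lapply(orders, walk, strict = TRUE))
  if (length(kept) == 0L) kept <- lapply(orders, walk, strict = FALSE)
  m <- do.call(rbind, kept)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

oracle_kaks <- function(seq_a, seq_b) {
  n <- nchar(seq_a) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  ca <- substring(seq_a, starts, starts + 2L)
  cb <- substring(seq_b, starts, starts + 2L)
  S <- N <- Sd <- Nd <- 0
  for (i in seq_len(n)) {
    sa <- oracle_sites(ca[i])
    sb <- oracle_sites(cb[i])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

oracle_sense_codons <- names(oracle_code)[oracle_code != "*"]

# random pair of aligned sense-codon sequences for oracle comparisons
random_codon_pair <- function(n_codons, mut_prob = 0.5) {
  ca <- sample(oracle_sense_codons, n_codons, replace = TRUE)
  cb <- ifelse(runif(n_codons) < mut_prob,
               sample(oracle_sense_codons, n_codons, replace = TRUE), ca)
  list(seq_a = paste(ca, collapse = ""), seq_b = paste(cb, collapse = ""))
}
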