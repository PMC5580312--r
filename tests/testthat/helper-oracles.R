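# Independent oracles used to validate the optimised implementations.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# CDS consistent with a protein (arbitrary codon per residue, plus stop)
cds_for_protein <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  pick <- function(aa) {
    cands <- names(gc)[gc == aa]
    cands[1]
  }
  paste(c(vapply(strsplit(prot, "")[[1]], pick, ""), "TAA"), collapse = "")
}

# Exhaustive local-alignment oracle: enumerates every chain of aligned
# residue pairs (an optimal local alignment under negative gap costs starts
# and ends with an aligned column); the gap between consecutive aligned
# pairs costs open + k * ext per inserted run. Structurally different from
# the three-state affine DP it validates.
sw_oracle <- function(protein_a, protein_b, matrix = "BLOSUM50",
                      gap_open = 10, gap_ext = 1) {
  mat <- synorth:::blosum_matrix(matrix)
  A <- strsplit(protein_a, "")[[1]]; B <- strsplit(protein_b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- mat[A, B, drop = FALSE]
  gapc <- function(k) ifelse(k > 0, gap_open + k * gap_ext, 0)
  f <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ext_best <- 0
    if (i > 1 && j > 1) {
      pred <- f[seq_len(i - 1), seq_len(j - 1), drop = FALSE] -
        outer(gapc(i - seq_len(i - 1) - 1), gapc(j - seq_len(j - 1) - 1), "+")
      ext_best <- max(0, pred)
    }
    f[i, j] <- M[i, j] + ext_best
  }
  max(0, f)
}

# Brute-force maximum-weight bipartite matching by recursion over rows.
matching_oracle <- function(w) {
  na <- nrow(w); nb <- ncol(w)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > na) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)
    for (j in seq_len(nb)) {
      if (!(j %in% used) && w[i, j] > 0) rec(i + 1, c(used, j), acc + w[i, j])
    }
  }
  rec(1, integer(0), 0)
  best
}

# Random additive distance matrix from a random tree with known topology.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
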