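#' Protein-guided codon alignment of a gene cluster
#'
#' Progressive multiple alignment of the cluster's proteins (guide tree:
#' neighbour joining on k-mer distances; profile-profile steps use the same
#' affine-gap dynamic programme as the similarity stage, with BLOSUM50),
#' optionally refined by one leave-one-out realignment round, then
#' back-translated: every aligned residue is replaced by its source codon and
#' every gap by \code{"---"}. De-gapping a row therefore recovers the
#' original CDS truncated to its translated codons (a terminal stop codon or
#' trailing partial codon is not part of the alignment).
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param cds named character vector of the matching coding sequences (same
#'   names). A gene whose CDS is shorter than 3x its protein is dropped with
#'   a warning.
#' @param params a [scoring_params()] object (gap penalties).
#' @param refine apply one leave-one-out refinement round (default TRUE).
#' @return object of class \code{codon_alignment}: list with \code{aa}
#'   (aligned proteins) and \code{codon} (aligned coding sequences, width a
#'   multiple of 3), both named character vectors of equal width.
#' @examples
#' aln <- align_codons(c(g1 = "MKV", g2 = "MV"),
#'                     c(g1 = "ATGAAAGTT", g2 = "ATGGTT"))
#' aln$codon
#' @export
align_codons <- function(proteins, cds, params = scoring_params(),
                         refine = TRUE) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)),
            setequal(names(proteins), names(cds)))
  cds <- cds[names(proteins)]
  ok <- nchar(cds) >= 3 * nchar(proteins) & nchar(proteins) > 0
  if (any(!ok)) {
    warning("dropping gene(s) with protein/CDS length mismatch: ",
            paste(names(proteins)[!ok], collapse = ", "))
    proteins <- proteins[ok]; cds <- cds[ok]
  }
  stopifnot(length(proteins) >= 1)
  mat <- blosum_matrix("BLOSUM50")
  enc <- lapply(proteins, function(p) encode_protein(p, warn = FALSE) - 1L)
  profiles <- lapply(enc, function(e) matrix(e, nrow = 1))
  names(profiles) <- names(proteins)

  prof <- if (length(profiles) == 1) {
    p <- profiles[[1]]; rownames(p) <- names(profiles); p
  } else {
    merge_order <- guide_merge_order(proteins)
    prof <- NULL
    build <- function(node) {
      if (is.character(node)) {
        p <- profiles[[node]]; rownames(p) <- node; return(p)
      }
      Reduce(function(a, b) merge_profiles(a, b, mat, params), lapply(node, build))
    }
    build(merge_order)
  }
  if (refine && nrow(prof) > 2)
    prof <- refine_profile(prof, mat, params)
  prof <- prof[names(proteins), , drop = FALSE]
  alpha <- aa_alphabet()
  aa <- apply(prof, 1, function(r) {
    ch <- rep("-", length(r))
    ch[r >= 0] <- alpha[r[r >= 0] + 1]
    paste(ch, collapse = "")
  })
  codon <- vapply(names(proteins), function(g) {
    r <- prof[g, ]
    cd <- substring(cds[[g]], 3 * seq_len(nchar(proteins[[g]])) - 2,
                    3 * seq_len(nchar(proteins[[g]])))
    out <- rep("---", length(r))
    out[r >= 0] <- cd
    paste(out, collapse = "")
  }, "")
  out <- list(aa = aa, codon = codon)
  class(out) <- "codon_alignment"
  out
}

# Guide topology as nested lists of leaf names: NJ on k-mer distances,
# midpoint-rooted for a deterministic progressive order.
guide_merge_order <- function(proteins, k = 3L) {
  n <- length(proteins)
  nm <- names(proteins)
  if (n == 2) return(list(nm[1], nm[2]))
  km <- lapply(proteins, function(p) {
    L <- nchar(p)
    if (L < k) return(p)
    unique(substring(p, seq_len(L - k + 1), seq(k, L)))
  })
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- length(intersect(km[[i]], km[[j]]))
    D[i, j] <- D[j, i] <- 1 - sh / max(1, min(length(km[[i]]), length(km[[j]])))
  }
  tr <- neighbor_joining(D)
  tr <- phangorn::midpoint(tr)
  tree_to_nested(tr)
}

tree_to_nested <- function(tr) {
  n_tip <- length(tr$tip.label)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  rec <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    lapply(sort(kids), rec)
  }
  rec(root)
}

merge_profiles <- function(pa, pb, mat, params) {
  r <- .cpp_profile_align(pa, pb, mat, params$gap_open, params$gap_ext)
  w <- length(r$a)
  out <- matrix(-1L, nrow(pa) + nrow(pb), w,
                dimnames = list(c(rownames(pa), rownames(pb)), NULL))
  out[seq_len(nrow(pa)), which(r$a > 0)] <- pa[, r$a[r$a > 0], drop = FALSE]
  out[nrow(pa) + seq_len(nrow(pb)), which(r$b > 0)] <- pb[, r$b[r$b > 0], drop = FALSE]
  out
}

# Simple sum-of-pairs column score used only to accept/reject refinement:
# substitution score for residue pairs, -1 per residue-gap pair, 0 for
# gap-gap.
sp_score <- function(prof, mat) {
  n <- nrow(prof)
  if (n < 2) return(0)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- prof[i, ]; b <- prof[j, ]
    both <- a >= 0 & b >= 0
    s <- s + sum(mat[cbind(a[both] + 1, b[both] + 1)]) - sum(xor(a >= 0, b >= 0))
  }
  s
}

refine_profile <- function(prof, mat, params) {
  best <- sp_score(prof, mat)
  for (g in rownames(prof)) {
    rest <- prof[setdiff(rownames(prof), g), , drop = FALSE]
    keep_cols <- colSums(rest >= 0) > 0
    rest <- rest[, keep_cols, drop = FALSE]
    row <- prof[g, ]
    row <- matrix(row[row >= 0], nrow = 1, dimnames = list(g, NULL))
    cand <- merge_profiles(rest, row, mat, params)[rownames(prof), , drop = FALSE]
    sc <- sp_score(cand, mat)
    if (sc > best) { prof <- cand; best <- sc }
  }
  prof
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$aa), "sequences,",
      nchar(x$aa[1]), "aa columns\n")
  invisible(x)
}

#' Jukes-Cantor distances from a codon alignment
#'
#' Pairwise p-distance over columns where both sequences have a non-gap
#' nucleotide, corrected as \code{d = -(3/4) ln(1 - (4/3) p)}. Saturated
#' pairs (p >= 0.749) and pairs with no shared columns are set to \code{cap}
#' (the latter with a warning).
#'
#' @param aln a \code{codon_alignment} or named character vector of aligned
#'   nucleotide sequences of equal width.
#' @param cap maximum distance (default 10).
#' @return a symmetric matrix of distances with zero diagonal.
#' @export
jc_distance <- function(aln, cap = 10) {
  seqs <- if (inherits(aln, "codon_alignment")) aln$codon else aln
  n <- length(seqs)
  stopifnot(n >= 2, length(unique(nchar(seqs))) == 1)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- valid[i, ] & valid[j, ]
    ns <- sum(sh)
    if (ns == 0) {
      warning("no shared ungapped columns between ", names(seqs)[i], " and ",
              names(seqs)[j], "; distance set to cap")
      d <- cap
    } else {
      p <- sum(m[i, sh] != m[j, sh]) / ns
      d <- if (p >= 0.749) cap else min(cap, -0.75 * log(1 - 4 * p / 3))
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}) with two determinism /
#' robustness guarantees layered on top: taxa are ordered lexicographically
#' before tree construction so equal-distance ties resolve identically on
#' every run, and negative branch lengths are clamped to zero. Additive
#' distance matrices are recovered exactly. Fewer than three taxa yield the
#' trivial tree.
#'
#' @param D symmetric distance matrix with dimnames, or a \code{dist}.
#' @return an unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  n <- nrow(D)
  if (n == 1) stop("need at least 2 taxa")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rownames(D)[1],
                                        D[1, 2] / 2, rownames(D)[2], D[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' The number of bipartitions present in exactly one of the two unrooted
#' trees (the symmetric difference of their split sets).
#'
#' @param tree_a,tree_b \code{phylo} objects over the same leaf set.
#' @return integer distance.
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets")
  if (length(tree_a$tip.label) < 4) return(0L)
  as.integer(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b),
                               check.labels = TRUE))
}
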