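#' Detect inparalogues within each species pair
#'
#' For one species pair: genes connected by prefilter-passing hits (bit
#' score and e-value thresholds, weights = bit scores) are Markov-clustered;
#' within each cluster a protein-guided codon alignment, Jukes-Cantor
#' distances and a neighbour-joining tree are built, and every maximal
#' same-species clade with two or more leaves is reduced to a single
#' ancestral representative -- the member with the highest
#' fragment-bias-corrected similarity to any gene of the other species (ties
#' broken by longer CDS, then gene ID). The remaining clade members are
#' flagged inparalogues; a flagged gene is syntenic when it lies within
#' \code{params$window} ordinals of its representative on the same contig.
#' Flagged genes are excluded from that species pair's candidate sets, so
#' only ancestral copies compete for orthology.
#'
#' @param gene_sets list of \code{gene_set} objects (all species).
#' @param hits hit table from [all_vs_all_scores()].
#' @param gene_order gene-order table from [build_gene_order()].
#' @param params a [scoring_params()] object.
#' @param score_col ranking column for representative selection
#'   (\code{"s_prime"} or \code{"raw50"}).
#' @param refine passed to [align_codons()].
#' @return list with \code{calls} (data.frame of inparalogue calls:
#'   \code{gene_id}, \code{representative_id}, \code{syntenic},
#'   \code{species}, \code{species_pair}) and \code{clusters} (per
#'   species-pair key, the similarity-cluster membership used downstream as
#'   phylogeny evidence).
#' @export
detect_inparalogues <- function(gene_sets, hits, gene_order,
                                params = scoring_params(),
                                score_col = "s_prime", refine = TRUE) {
  species <- vapply(gene_sets, function(g) g$species_id, "")
  names(gene_sets) <- species
  calls <- list(); memberships <- list()
  if (length(species) >= 2) {
    pairs <- combn(sort(species), 2)
    for (k in seq_len(ncol(pairs))) {
      r <- detect_inparalogues_pair(gene_sets[[pairs[1, k]]],
                                    gene_sets[[pairs[2, k]]],
                                    hits, gene_order, params,
                                    score_col, refine)
      calls[[k]] <- r$calls
      memberships[[species_pair_key(pairs[1, k], pairs[2, k])]] <- r$membership
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out) || !nrow(out))
    out <- data.frame(gene_id = character(), representative_id = character(),
                      syntenic = logical(), species = character(),
                      species_pair = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(calls = out, clusters = memberships)
}

detect_inparalogues_pair <- function(gs_a, gs_b, hits, gene_order, params,
                                     score_col, refine) {
  sp <- c(gs_a$species_id, gs_b$species_id)
  h <- hits[hits$species_a %in% sp & hits$species_b %in% sp &
            hits$bit >= params$min_bit & hits$evalue <= params$max_evalue, ]
  none <- list(calls = data.frame(gene_id = character(),
                                  representative_id = character(),
                                  syntenic = logical(), species = character(),
                                  species_pair = character(),
                                  stringsAsFactors = FALSE),
               membership = NULL)
  if (!nrow(h)) return(none)
  species_of <- c(setNames(rep(sp[1], nrow(gs_a$genes)), gs_a$genes$gene_id),
                  setNames(rep(sp[2], nrow(gs_b$genes)), gs_b$genes$gene_id))
  proteins <- c(gs_a$protein, gs_b$protein)
  cds <- c(gs_a$cds, gs_b$cds)
  cl <- mcl_cluster(h[, c("gene_a", "gene_b", "bit")],
                    inflation = params$inflation)
  cross <- h[h$species_a != h$species_b, ]
  pos <- gene_order[gene_order$species %in% sp, ]
  pos_idx <- setNames(seq_len(nrow(pos)), pos$gene_id)
  out <- list()
  for (genes in cl$clusters) {
    sp_of <- species_of[genes]
    if (max(table(sp_of)) < 2) next
    groups <- same_species_clades(genes, sp_of, proteins, cds, params, refine)
    for (grp in groups) {
      rep_id <- pick_representative(grp, sp_of[grp][1], cross, cds, score_col)
      flagged <- setdiff(grp, rep_id)
      syn <- vapply(flagged, function(g) {
        i <- pos_idx[g]; j <- pos_idx[rep_id]
        if (is.na(i) || is.na(j)) return(FALSE)
        pos$contig[i] == pos$contig[j] &&
          abs(pos$ordinal[i] - pos$ordinal[j]) <= params$window
      }, TRUE)
      out[[length(out) + 1]] <- data.frame(
        gene_id = flagged, representative_id = rep_id, syntenic = unname(syn),
        species = unname(sp_of[flagged]),
        species_pair = species_pair_key(sp[1], sp[2]),
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) calls <- none$calls
  list(calls = calls, membership = cl$membership)
}

# Maximal same-species clades (>= 2 leaves) of the cluster's NJ tree,
# evaluated on the unrooted tree: every edge splits the leaves in two; each
# single-species side of size >= 2 is a candidate clade and the maximal
# candidates (which form a laminar, hence disjoint, family when both species
# are present) are returned. A cluster containing only one species is a
# single group.
same_species_clades <- function(genes, sp_of, proteins, cds, params, refine) {
  genes <- sort(genes)
  if (length(unique(sp_of[genes])) == 1) return(list(genes))
  if (length(genes) == 3) {
    # any unrooted 3-leaf tree is a star; the same-species pair is the clade
    tab <- split(genes, sp_of[genes])
    dup <- tab[[which(lengths(tab) == 2)]]
    return(list(sort(dup)))
  }
  aln <- align_codons(proteins[genes], cds[genes], params, refine = refine)
  if (length(aln$codon) < length(genes)) genes <- names(aln$codon)
  if (length(genes) < 3 || length(unique(sp_of[genes])) == 1)
    return(if (length(genes) >= 2 && max(table(sp_of[genes])) >= 2)
             list(sort(genes)) else list())
  D <- jc_distance(aln)
  tr <- neighbor_joining(D)
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  desc <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  cand <- list()
  add <- function(side) {
    if (length(side) >= 2 && length(unique(sp_of[side])) == 1)
      cand[[length(cand) + 1]] <<- sort(side)
  }
  for (v in tr$edge[, 2]) {
    s <- desc(v)
    add(s)
    add(setdiff(tr$tip.label, s))
  }
  if (!length(cand)) return(list())
  cand <- unique(cand)
  maximal <- cand[vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      i != j && all(cand[[i]] %in% cand[[j]]) && length(cand[[j]]) > length(cand[[i]])
    }, TRUE))
  }, TRUE)]
  unique(maximal)
}

# Representative = clade member with the best cross-species score; ties by
# longer CDS, then gene id.
pick_representative <- function(grp, species, cross, cds, score_col) {
  best <- vapply(grp, function(g) {
    s <- c(cross[[score_col]][cross$gene_a == g], cross[[score_col]][cross$gene_b == g])
    if (length(s)) max(s) else -Inf
  }, 0)
  lens <- nchar(cds[grp])
  grp[order(-best, -lens, grp)][1]
}
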