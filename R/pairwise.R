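#' Assign 1:1 orthologues per species pair by maximum-weight matching
#'
#' For every species pair, the union of the two directions' top-k candidate
#' edges is taken as a bipartite graph weighted by the fragment-bias-
#' corrected similarity, and a maximum-weight matching is computed (per
#' connected component, via \pkg{igraph}). Matched pairs carry similarity
#' evidence; ties are broken deterministically by higher score then
#' lexicographic pair id (edges are sorted before matching).
#'
#' @param candidates candidate table from [build_candidates()].
#' @param score_col weight column (\code{"s_prime"} or \code{"raw50"}).
#' @return data.frame of orthologue pairs: \code{gene_a}, \code{gene_b}
#'   (species_a < species_b), \code{species_a}, \code{species_b}, score
#'   columns, \code{positional}, \code{rescued}, evidence flags
#'   \code{ev_similarity}, \code{ev_synteny}, \code{ev_phylogeny}.
#' @export
assign_orthologues <- function(candidates, score_col = "s_prime") {
  if (!nrow(candidates)) return(empty_pairs())
  # orient each edge so species_a < species_b, then deduplicate directions
  a_first <- candidates$species < candidates$target_species
  ed <- data.frame(
    gene_a = ifelse(a_first, candidates$gene, candidates$candidate),
    gene_b = ifelse(a_first, candidates$candidate, candidates$gene),
    species_a = pmin(candidates$species, candidates$target_species),
    species_b = pmax(candidates$species, candidates$target_species),
    s_prime = candidates$s_prime, raw50 = candidates$raw50,
    stringsAsFactors = FALSE)
  ed <- ed[!duplicated(ed[, c("gene_a", "gene_b", "species_a", "species_b")]), ]
  out <- lapply(split(ed, species_pair_key(ed$species_a, ed$species_b)),
                match_pair_block, score_col = score_col)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

match_pair_block <- function(ed, score_col) {
  ed <- ed[order(-ed[[score_col]], ed$gene_a, ed$gene_b), ]
  na <- paste0("A|", ed$gene_a); nb <- paste0("B|", ed$gene_b)
  g <- igraph::graph_from_edgelist(cbind(na, nb), directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B|")
  m <- igraph::max_bipartite_match(g, weights = ed[[score_col]])
  matched <- m$matching
  left <- names(matched)[startsWith(names(matched), "A|") & !is.na(matched)]
  key_a <- substring(left, 3)
  key_b <- substring(matched[left], 3)
  sel <- match(paste(key_a, key_b), paste(ed$gene_a, ed$gene_b))
  out <- ed[sel, , drop = FALSE]
  out$positional <- FALSE
  out$rescued <- FALSE
  out$ev_similarity <- TRUE
  out$ev_synteny <- FALSE
  out$ev_phylogeny <- FALSE
  out[order(out$gene_a), ]
}

empty_pairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             species_a = character(), species_b = character(),
             s_prime = numeric(), raw50 = numeric(), positional = logical(),
             rescued = logical(), ev_similarity = logical(),
             ev_synteny = logical(), ev_phylogeny = logical(),
             stringsAsFactors = FALSE)
}

#' Re-calibrate orthologue calls with micro-synteny windows
#'
#' Three passes over each species pair's matching, using windows of
#' \code{params$window} genes either side of a gene's ordinal position:
#' (i) gap filling -- an unmatched gene g is paired with an unmatched gene h
#' of the other species when at least two of g's window neighbours are
#' matched to window neighbours of h and (g,h) itself passes the similarity
#' filters; such pairs are flagged \code{positional} and gain synteny
#' evidence; (ii) inparalogue rescue -- a gene flagged as inparalogue is
#' eligible for (i) like any unmatched gene, and when it is filled in, its
#' inparalogue call is withdrawn (\code{rescued}); rescued genes never
#' displace existing pairs; (iii) every pair supported by at least two
#' matched window anchors gains synteny evidence, and every pair whose genes
#' share a within-pair similarity cluster gains phylogeny evidence.
#' Conflicting fills for one slot keep the higher corrected similarity.
#'
#' @param pairs matching from [assign_orthologues()].
#' @param hits hit table from [all_vs_all_scores()].
#' @param gene_order gene-order table from [build_gene_order()].
#' @param inparalogues inparalogue calls (data.frame, see
#'   [detect_inparalogues()]; pass the \code{$calls} element).
#' @param clusters optional named list (by species-pair key) of cluster
#'   membership vectors from the inparalogue stage, used for phylogeny
#'   evidence.
#' @param params a [scoring_params()] object.
#' @param score_col score column used to resolve conflicting fills.
#' @return list with updated \code{pairs} and \code{inparalogues} (rescued
#'   calls withdrawn).
#' @export
synteny_recalibrate <- function(pairs, hits, gene_order, inparalogues,
                                clusters = NULL, params = scoring_params(),
                                score_col = "s_prime") {
  ph <- passing_hits(hits, params)
  ph <- ph[ph$species_a != ph$species_b, ]
  rescued_all <- character(0)
  out <- list()
  all_sp <- sort(unique(gene_order$species))
  if (length(all_sp) >= 2) {
    sp_pairs <- combn(all_sp, 2)
    for (k in seq_len(ncol(sp_pairs))) {
      sa <- sp_pairs[1, k]; sb <- sp_pairs[2, k]
      key <- species_pair_key(sa, sb)
      p <- pairs[pairs$species_a == sa & pairs$species_b == sb, , drop = FALSE]
      h <- ph[(ph$species_a == sa & ph$species_b == sb) |
              (ph$species_a == sb & ph$species_b == sa), , drop = FALSE]
      ip <- inparalogues[inparalogues$species_pair == key, , drop = FALSE]
      r <- recalibrate_pair_block(p, h, gene_order, ip, sa, sb, params,
                                  score_col,
                                  membership = clusters[[key]])
      rescued_all <- c(rescued_all, paste(r$rescued_genes, key))
      out[[k]] <- r$pairs
    }
  }
  new_pairs <- do.call(rbind, out) %||% empty_pairs()
  rownames(new_pairs) <- NULL
  keep <- !(paste(inparalogues$gene_id, inparalogues$species_pair) %in% rescued_all)
  list(pairs = new_pairs, inparalogues = inparalogues[keep, , drop = FALSE])
}

recalibrate_pair_block <- function(p, h, gene_order, ip, sa, sb, params,
                                   score_col, membership = NULL) {
  w <- params$window
  go <- gene_order[gene_order$species %in% c(sa, sb), ]
  ctg <- setNames(go$contig, go$gene_id)
  ord <- setNames(go$ordinal, go$gene_id)
  near <- function(g1, g2) {
    !is.na(ctg[g1]) & !is.na(ctg[g2]) & ctg[g1] == ctg[g2] &
      abs(ord[g1] - ord[g2]) <= w & g1 != g2
  }
  genes_a <- go$gene_id[go$species == sa]
  genes_b <- go$gene_id[go$species == sb]
  matched_a <- setNames(p$gene_b, p$gene_a)
  matched_b <- setNames(p$gene_a, p$gene_b)
  # orient hits so gene_a is from species sa
  swap <- h$species_a == sb
  h2 <- h
  h2$gene_a[swap] <- h$gene_b[swap]; h2$gene_b[swap] <- h$gene_a[swap]
  hit_key <- paste(h2$gene_a, h2$gene_b)

  anchors <- function(g, hcand) {
    # matched pairs (x, y) with x near g and y near hcand
    x <- p$gene_a[near(p$gene_a, g)]
    if (!length(x)) return(0L)
    sum(near(matched_a[x], hcand))
  }

  # (i) + (ii): candidate fills between unmatched genes (flagged inparalogues
  # are unmatched by construction and eligible -> rescue)
  un_a <- setdiff(genes_a, names(matched_a))
  un_b <- setdiff(genes_b, names(matched_b))
  cand <- h2[h2$gene_a %in% un_a & h2$gene_b %in% un_b, , drop = FALSE]
  fills <- NULL
  if (nrow(cand)) {
    n_anch <- mapply(anchors, cand$gene_a, cand$gene_b)
    cand <- cand[n_anch >= 2, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(-cand[[score_col]], cand$gene_a, cand$gene_b), ]
      cand <- cand[!duplicated(cand$gene_a) & !duplicated(cand$gene_b), , drop = FALSE]
      fills <- data.frame(
        gene_a = cand$gene_a, gene_b = cand$gene_b,
        species_a = sa, species_b = sb,
        s_prime = cand$s_prime, raw50 = cand$raw50,
        positional = TRUE, rescued = FALSE,
        ev_similarity = TRUE, ev_synteny = TRUE, ev_phylogeny = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  rescued_genes <- character(0)
  if (!is.null(fills) && nrow(ip)) {
    hit_ip <- fills$gene_a %in% ip$gene_id | fills$gene_b %in% ip$gene_id
    fills$rescued <- hit_ip
    rescued_genes <- intersect(c(fills$gene_a, fills$gene_b), ip$gene_id)
  }
  p <- rbind(p, fills)
  if (nrow(p)) {
    # (iii) synteny evidence for anchored pairs; phylogeny evidence for pairs
    # sharing a within-pair similarity cluster
    n_anch <- mapply(anchors, p$gene_a, p$gene_b)
    p$ev_synteny <- p$ev_synteny | n_anch >= 2
    if (!is.null(membership)) {
      ma <- membership[p$gene_a]; mb <- membership[p$gene_b]
      p$ev_phylogeny <- !is.na(ma) & !is.na(mb) & ma == mb
    }
    p <- p[order(p$gene_a), ]
  }
  list(pairs = p, rescued_genes = rescued_genes)
}
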