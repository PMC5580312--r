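#' Cluster the pairwise-orthologue graph
#'
#' Markov clustering (default inflation 2) of the graph whose nodes are genes
#' and whose edges are the pairwise orthologue calls (unit weight). Chains of
#' pairwise calls without a direct edge end up in one cluster, giving the
#' transitive families that are then reconciled into orthogroups.
#'
#' @param pairs orthologue pairs (after recalibration).
#' @param inflation MCL inflation.
#' @return a \code{cluster_set}.
#' @export
cluster_orthologue_graph <- function(pairs, inflation = 2) {
  stopifnot(nrow(pairs) > 0)
  mcl_cluster(data.frame(from = pairs$gene_a, to = pairs$gene_b, weight = 1,
                         stringsAsFactors = FALSE), inflation = inflation)
}

#' Consensus species tree from single-copy clusters
#'
#' Samples up to \code{sample_n} clusters containing exactly one gene from
#' every species (seeded), concatenates their protein-guided codon
#' alignments, computes Jukes-Cantor distances between species and returns
#' the neighbour-joining tree. All-zero distances (identical sequences
#' across species) yield a star-like tree with a warning.
#'
#' @param clusters a \code{cluster_set} over genes.
#' @param gene_sets list of \code{gene_set} objects.
#' @param sample_n maximum number of single-copy clusters to concatenate.
#' @param seed RNG seed for the cluster sample.
#' @param params a [scoring_params()] object.
#' @param refine passed to [align_codons()].
#' @return an unrooted \code{phylo} tree over the species.
#' @export
consensus_species_tree <- function(clusters, gene_sets, sample_n = 50L,
                                   seed = 1L, params = scoring_params(),
                                   refine = TRUE) {
  species <- sort(vapply(gene_sets, function(g) g$species_id, ""))
  if (length(species) < 3)
    stop("consensus tree needs at least 3 species")
  species_of <- unlist(lapply(gene_sets, function(g)
    setNames(rep(g$species_id, nrow(g$genes)), g$genes$gene_id)))
  proteins <- unlist(lapply(gene_sets, function(g) g$protein))
  cds <- unlist(lapply(gene_sets, function(g) g$cds))
  single <- Filter(function(cl) {
    sp <- species_of[cl]
    length(cl) == length(species) && setequal(sp, species) && !anyDuplicated(sp)
  }, clusters$clusters)
  if (!length(single))
    stop("no single-copy cluster available for the consensus tree")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  take <- sample(seq_along(single), min(sample_n, length(single)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  cat_aln <- setNames(rep("", length(species)), species)
  for (i in take) {
    genes <- single[[i]]
    aln <- align_codons(proteins[genes], cds[genes], params, refine = refine)
    if (length(aln$codon) < length(genes)) next
    sp <- species_of[names(aln$codon)]
    cat_aln[sp] <- paste0(cat_aln[sp], aln$codon)
  }
  D <- jc_distance(cat_aln)
  if (all(D == 0))
    warning("species sequences are identical; consensus tree is star-like")
  neighbor_joining(D)
}

#' Reconcile clusters into orthogroups
#'
#' Within each cluster of the orthologue graph, orthogroups (at most one
#' gene per species) are extracted greedily: seed with the highest-scoring
#' unused pair, then repeatedly add, over the species not yet represented,
#' the unused gene with the highest summed similarity to the current members
#' among genes with a pairwise orthologue call to at least half of them;
#' repeat until no seed pair remains. Genes left over stay outside any
#' orthogroup.
#'
#' @param clusters a \code{cluster_set} from [cluster_orthologue_graph()].
#' @param pairs recalibrated orthologue pairs.
#' @param n_species total number of species in the run (defines the
#'   all-species class).
#' @param score_col score column.
#' @return list with \code{members} (data.frame \code{og_id},
#'   \code{gene_id}, \code{species}) and \code{table} (data.frame
#'   \code{og_id}, \code{n_species}, \code{class}).
#' @export
reconcile_orthogroups <- function(clusters, pairs, n_species,
                                  score_col = "s_prime") {
  species_of <- c(setNames(pairs$species_a, pairs$gene_a),
                  setNames(pairs$species_b, pairs$gene_b))
  members <- list()
  ogi <- 0L
  for (genes in clusters$clusters) {
    sub <- pairs[pairs$gene_a %in% genes & pairs$gene_b %in% genes, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(-sub[[score_col]], sub$gene_a, sub$gene_b), ]
    used <- character(0)
    repeat {
      avail <- !(sub$gene_a %in% used) & !(sub$gene_b %in% used)
      if (!any(avail)) break
      seedp <- sub[which(avail)[1], ]
      og <- c(seedp$gene_a, seedp$gene_b)
      repeat {
        og_sp <- unname(species_of[og])
        cand <- setdiff(genes[!(genes %in% used) & !(genes %in% og)], og)
        cand <- cand[!(species_of[cand] %in% og_sp)]
        if (!length(cand)) break
        # pairwise calls from each candidate to current members
        calls <- vapply(cand, function(g) {
          sum((sub$gene_a == g & sub$gene_b %in% og) |
              (sub$gene_b == g & sub$gene_a %in% og))
        }, 0L)
        score <- vapply(cand, function(g) {
          sum(sub[[score_col]][(sub$gene_a == g & sub$gene_b %in% og) |
                               (sub$gene_b == g & sub$gene_a %in% og)])
        }, 0)
        ok <- calls * 2L >= length(og)
        if (!any(ok)) break
        cand <- cand[ok]; score <- score[ok]
        best <- cand[order(-score, cand)][1]
        og <- c(og, best)
      }
      ogi <- ogi + 1L
      members[[ogi]] <- data.frame(og_id = sprintf("OG%05d", ogi),
                                   gene_id = sort(og),
                                   species = unname(species_of[sort(og)]),
                                   stringsAsFactors = FALSE)
      used <- c(used, og)
    }
  }
  members <- do.call(rbind, members) %||%
    data.frame(og_id = character(), gene_id = character(),
               species = character(), stringsAsFactors = FALSE)
  rownames(members) <- NULL
  if (nrow(members)) {
    nsp <- tapply(members$species, members$og_id, function(x) length(unique(x)))
    tab <- data.frame(og_id = names(nsp), n_species = as.integer(nsp),
                      class = ifelse(as.integer(nsp) == n_species,
                                     "ONE_TO_ONE_ALL", "ONE_TO_ONE_PARTIAL"),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$og_id), ]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(og_id = character(), n_species = integer(),
                      class = character(), stringsAsFactors = FALSE)
  }
  list(members = members, table = tab)
}

#' Classify every gene into one of four classes
#'
#' Genes in an orthogroup spanning all species are \code{ORTHOLOGUE_ALL};
#' genes in any other orthogroup are \code{ORTHOLOGUE_PARTIAL}; genes
#' flagged as inparalogues (and never rescued) are \code{INPARALOGUE}; genes
#' with no hit passing the similarity filters to any other gene are
#' \code{DE_NOVO}; remaining genes -- homologous singletons that entered no
#' orthogroup -- are \code{INPARALOGUE}. The four classes partition the gene
#' set.
#'
#' @param gene_sets list of \code{gene_set} objects.
#' @param orthogroups output of [reconcile_orthogroups()].
#' @param inparalogues inparalogue calls after rescue.
#' @param hits hit table.
#' @param params a [scoring_params()] object.
#' @return data.frame \code{gene_id}, \code{species}, \code{class}.
#' @export
classify_genes <- function(gene_sets, orthogroups, inparalogues, hits,
                           params = scoring_params()) {
  species_of <- unlist(lapply(gene_sets, function(g)
    setNames(rep(g$species_id, nrow(g$genes)), g$genes$gene_id)))
  gene_ids <- names(species_of)
  cls <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  og_class <- setNames(orthogroups$table$class, orthogroups$table$og_id)
  in_og <- setNames(og_class[orthogroups$members$og_id],
                    orthogroups$members$gene_id)
  cls[names(in_og)] <- ifelse(in_og == "ONE_TO_ONE_ALL",
                              "ORTHOLOGUE_ALL", "ORTHOLOGUE_PARTIAL")
  flagged <- setdiff(unique(inparalogues$gene_id), names(in_og))
  cls[flagged] <- "INPARALOGUE"
  ph <- passing_hits(hits, params)
  has_hit <- unique(c(ph$gene_a, ph$gene_b))
  cls[is.na(cls) & !(gene_ids %in% has_hit)] <- "DE_NOVO"
  cls[is.na(cls)] <- "INPARALOGUE"
  data.frame(gene_id = gene_ids, species = unname(species_of), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Assemble named super-orthogroups
#'
#' Orthogroups plus leftover inparalogues (DUP) and de novo genes (DNV) are
#' clustered by domain-level similarity: nodes are orthogroups (represented
#' by their member genes) and individual DUP/DNV genes; an edge joins two
#' nodes whenever any filter-passing hit links their gene sets, weighted by
#' the maximum corrected similarity between the sets -- except that edges
#' incident to DUP/DNV nodes are down-weighted to \code{epsilon}, so
#' duplications and births attach to families without driving cluster
#' merges. Markov clustering then yields one super-orthogroup (SOG) per
#' cluster. SOGs are coded \code{"AAAA"}, \code{"AAAB"}, ... in decreasing
#' size (ties by smallest member orthogroup id); within a SOG, orthogroups
#' are numbered \code{-0001}, \code{-0002}, ... by decreasing species count
#' (ties by orthogroup id); DUP/DNV members keep their class code.
#'
#' @param orthogroups output of [reconcile_orthogroups()].
#' @param classes gene classification from [classify_genes()].
#' @param hits hit table.
#' @param params a [scoring_params()] object.
#' @param epsilon weight of DUP/DNV edges (default 1e-9); \code{NA} drops
#'   them entirely.
#' @param inflation MCL inflation.
#' @return data.frame with one row per SOG member: \code{sog_id},
#'   \code{member_id} (orthogroup id or gene id), \code{member_type}
#'   (\code{OG}/\code{DUP}/\code{DNV}), \code{sog_member_id} (e.g.
#'   \code{"AAAA-0001"} for orthogroups, \code{NA} otherwise).
#' @export
build_super_orthogroups <- function(orthogroups, classes, hits,
                                    params = scoring_params(),
                                    epsilon = 1e-9, inflation = 2) {
  node_of <- setNames(orthogroups$members$og_id, orthogroups$members$gene_id)
  loose <- classes[classes$class %in% c("INPARALOGUE", "DE_NOVO"), ]
  loose <- loose[!(loose$gene_id %in% names(node_of)), ]
  node_of <- c(node_of, setNames(loose$gene_id, loose$gene_id))
  node_type <- c(setNames(rep("OG", nrow(orthogroups$table)), orthogroups$table$og_id),
                 setNames(ifelse(loose$class == "INPARALOGUE", "DUP", "DNV"),
                          loose$gene_id))
  ph <- passing_hits(hits, params)
  na <- node_of[ph$gene_a]; nb <- node_of[ph$gene_b]
  keep <- !is.na(na) & !is.na(nb) & na != nb
  edges <- NULL
  if (any(keep)) {
    e <- data.frame(from = pmin(na[keep], nb[keep]),
                    to = pmax(na[keep], nb[keep]),
                    weight = ph$s_prime[keep], stringsAsFactors = FALSE)
    e <- e[order(e$from, e$to, -e$weight), ]
    e <- e[!duplicated(e[, c("from", "to")]), ]
    dd <- node_type[e$from] != "OG" | node_type[e$to] != "OG"
    if (is.na(epsilon)) e <- e[!dd, , drop = FALSE] else e$weight[dd] <- epsilon
    edges <- e
  }
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(from = character(), to = character(), weight = numeric())
  cl <- mcl_cluster(edges, nodes = names(node_type), inflation = inflation)
  # order SOGs by decreasing size, ties by smallest member og id
  key <- vapply(cl$clusters, function(x) min(x), "")
  ordc <- order(-lengths(cl$clusters), key)
  nsp <- setNames(orthogroups$table$n_species, orthogroups$table$og_id)
  out <- list()
  for (i in seq_along(ordc)) {
    nodes <- cl$clusters[[ordc[i]]]
    code <- sog_code(i - 1L)
    ogs <- nodes[node_type[nodes] == "OG"]
    ogs <- ogs[order(-nsp[ogs], ogs)]
    rest <- sort(nodes[node_type[nodes] != "OG"])
    out[[i]] <- data.frame(
      sog_id = code,
      member_id = c(ogs, rest),
      member_type = unname(node_type[c(ogs, rest)]),
      sog_member_id = c(if (length(ogs)) sprintf("%s-%04d", code, seq_along(ogs)),
                        rep(NA_character_, length(rest))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Four-letter code: 0 -> "AAAA", 1 -> "AAAB", ...; overflow beyond 26^4 is
# fatal.
sog_code <- function(i) {
  if (any(i >= 26^4)) stop("super-orthogroup code space (26^4) exhausted")
  vapply(i, function(k) {
    d <- integer(4)
    for (p in 4:1) { d[p] <- k %% 26; k <- k %/% 26 }
    paste(LETTERS[d + 1], collapse = "")
  }, "")
}

#' Write one protein FASTA per orthogroup
#'
#' @param run an \code{ortho_run} with completed multispecies stage.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_orthogroup_fastas <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- unlist(lapply(run$gene_sets, function(g) g$protein))
  m <- run$orthogroups$members
  for (og in unique(m$og_id)) {
    genes <- m$gene_id[m$og_id == og]
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot[genes]),
                                file.path(dir, paste0(og, ".fasta")))
  }
  invisible(dir)
}

#' Per-species summary of gene classes
#'
#' @param classes gene classification from [classify_genes()].
#' @return data.frame with one row per species: counts of the four classes
#'   and their total.
#' @export
class_summary <- function(classes) {
  lv <- c("ORTHOLOGUE_ALL", "ORTHOLOGUE_PARTIAL", "INPARALOGUE", "DE_NOVO")
  tab <- table(factor(classes$species), factor(classes$class, levels = lv))
  out <- as.data.frame.matrix(tab)
  out <- cbind(species = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  out
}
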