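#' Configuration for the genome-evolution simulator
#'
#' Defines the conditions under which multi-species inputs with planted
#' orthology truth are generated. An ancestral gene set evolves along a
#' species tree; on every branch genes may be lost or duplicated (tandem
#' copies inserted adjacently, others at random positions), de novo genes
#' are born, substitutions accumulate under a codon-aware nucleotide model
#' (mutations creating internal stops are reverted), local inversions
#' shuffle gene order, and at the tips gene models may be fragmented: the
#' contig breaks inside the gene, a short run of codons is lost at the break
#' (as at draft-assembly contig ends) and the two CDS segments are emitted
#' on consecutive contigs under the same gene ID.
#'
#' The default configuration is the package's standard validation fixture:
#' 4 species on a balanced tree with about 0.1 substitutions/site from root
#' to tip, 200 ancestral genes of 100-300 codons, duplication rate 0.1 per
#' gene per branch (half tandem), loss rate 0.05, 10 births and 2 inversions
#' per branch, and fragmentation probability 0.1.
#'
#' @param n_species number of species (ignored when \code{species_tree} is
#'   given).
#' @param species_tree optional Newick string; tip labels become species
#'   ids. Default: a balanced 4-species tree
#'   \code{"((sp1:0.067,sp2:0.067):0.033,(sp3:0.067,sp4:0.067):0.033);"}
#'   for \code{n_species = 4}, otherwise a seeded random topology scaled to
#'   0.1 root-to-tip.
#' @param n_ancestral_genes ancestral gene count.
#' @param gene_length_range gene length range in codons (excluding the stop).
#' @param duplication_rate per-gene per-branch duplication probability.
#' @param tandem_fraction fraction of duplications inserted adjacently.
#' @param loss_rate per-gene per-branch loss probability.
#' @param birth_rate expected de novo births per branch (Poisson).
#' @param inversion_rate expected inversions per branch (Poisson); each
#'   reverses (and strand-flips) a window of 2-8 adjacent genes.
#' @param substitution_rate substitutions per site per unit branch length.
#' @param fragmentation_prob per-gene probability of a fragmented model.
#' @param frag_loss_range range of the fraction of codons lost at the break.
#' @param genes_per_contig genes per contig before fragmentation breaks.
#' @param intergenic_range intergenic spacer length range (nt).
#' @param seed RNG seed (mandatory).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 4L, species_tree = NULL,
                       n_ancestral_genes = 200L,
                       gene_length_range = c(100L, 300L),
                       duplication_rate = 0.1, tandem_fraction = 0.5,
                       loss_rate = 0.05, birth_rate = 10,
                       inversion_rate = 2, substitution_rate = 1,
                       fragmentation_prob = 0.1,
                       frag_loss_range = c(0.05, 0.3),
                       genes_per_contig = 100L,
                       intergenic_range = c(100L, 300L), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_ancestral_genes >= 1,
            all(c(duplication_rate, loss_rate, birth_rate, inversion_rate,
                  substitution_rate) >= 0),
            tandem_fraction >= 0, tandem_fraction <= 1,
            fragmentation_prob >= 0, fragmentation_prob <= 1)
  cfg <- list(n_species = as.integer(n_species), species_tree = species_tree,
              n_ancestral_genes = as.integer(n_ancestral_genes),
              gene_length_range = gene_length_range,
              duplication_rate = duplication_rate,
              tandem_fraction = tandem_fraction, loss_rate = loss_rate,
              birth_rate = birth_rate, inversion_rate = inversion_rate,
              substitution_rate = substitution_rate,
              fragmentation_prob = fragmentation_prob,
              frag_loss_range = frag_loss_range,
              genes_per_contig = as.integer(genes_per_contig),
              intergenic_range = intergenic_range, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Named simulation fixtures
#'
#' Two frozen study conditions used throughout the package's validation:
#' \describe{
#'   \item{\code{"small"}}{the standard end-to-end fixture: 4 species on a
#'     balanced tree (~0.1 substitutions/site root to tip), 200 ancestral
#'     genes, duplication 0.1/gene/branch (half tandem), loss 0.05, 10
#'     births and 2 inversions per branch, fragmentation 0.1.}
#'   \item{\code{"fragment"}}{the fragment-stress condition for comparing
#'     the corrected score against the raw Smith-Waterman score: deeper
#'     divergence (~0.2 substitutions/site root to tip, so paralogue and
#'     orthologue identities overlap), duplication 0.2, fragmentation 0.3
#'     with 40-70\% of codons lost at the break, 100 ancestral genes.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed (default 42, the frozen fixture seed).
#' @return a [sim_config()].
#' @export
fixture_config <- function(name = c("small", "fragment"), seed = 42L) {
  name <- match.arg(name)
  switch(name,
    small = sim_config(seed = seed),
    fragment = sim_config(
      n_ancestral_genes = 100L,
      species_tree = "((sp1:0.13,sp2:0.13):0.07,(sp3:0.13,sp4:0.13):0.07);",
      duplication_rate = 0.2, birth_rate = 5,
      fragmentation_prob = 0.3, frag_loss_range = c(0.4, 0.7),
      seed = seed))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- character(0)
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# Apply substitutions at rate p per site; mutations that create an internal
# stop codon are reverted (the terminal stop is never touched).
mutate_cds <- function(seq, p) {
  if (p <= 0) return(seq)
  nt <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(nt)
  hit <- which(runif(n - 3L) < p)     # spare the terminal stop codon
  if (!length(hit)) return(seq)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  orig <- nt
  nt[hit] <- vapply(nt[hit], function(b)
    substring(alt[[b]], s <- sample.int(3, 1), s), "")
  cod_idx <- ((hit - 1L) %/% 3L) + 1L
  for (ci in unique(cod_idx)) {
    j <- (3L * ci - 2L):(3L * ci)
    if (paste(nt[j], collapse = "") %in% STOP_CODONS) nt[j] <- orig[j]
  }
  paste(nt, collapse = "")
}

# Registry of every lineage ever created (survivors or not), so parent
# chains of lost lineages still resolve when truth tables are built.
new_genome_env <- function() {
  e <- new.env(parent = emptyenv())
  e$next_lineage <- 1L
  e$reg <- list()
  e
}

register_lineage <- function(env, lineage, parent, ancestral_id, origin,
                             birth_node, tandem) {
  env$reg[[as.character(lineage)]] <- list(
    parent = parent, ancestral_id = ancestral_id, origin = origin,
    birth_node = birth_node, tandem = tandem)
}

# Insert a row after position `at` (0 = front).
insert_row <- function(genome, row, at) {
  n <- nrow(genome)
  rbind(genome[seq_len(at), , drop = FALSE], row,
        if (at < n) genome[(at + 1L):n, , drop = FALSE])
}

# Evolve a genome (data.frame of gene records, rows in genome order) along
# one branch ending at tree node `node`.
evolve_branch <- function(genome, blen, node, cfg, env) {
  n <- nrow(genome)
  if (n) {
    keep <- runif(n) >= cfg$loss_rate
    genome <- genome[keep, , drop = FALSE]
  }
  # duplications (select source lineages first: row indices shift as copies
  # are inserted)
  n <- nrow(genome)
  if (n) {
    dup_lineages <- genome$lineage[runif(n) < cfg$duplication_rate]
    for (src in dup_lineages) {
      at0 <- which(genome$lineage == src)
      copy <- genome[at0, , drop = FALSE]
      copy$lineage <- env$next_lineage; env$next_lineage <- env$next_lineage + 1L
      copy$parent_lineage <- src
      copy$origin <- "dup"
      copy$birth_node <- node
      tandem <- runif(1) < cfg$tandem_fraction
      copy$tandem <- tandem
      register_lineage(env, copy$lineage, src, NA_character_, "dup", node, tandem)
      at <- if (tandem) at0 else sample.int(nrow(genome), 1L)
      genome <- insert_row(genome, copy, at)
    }
  }
  # de novo births
  nb <- rpois(1, cfg$birth_rate)
  for (k in seq_len(nb)) {
    L <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
    born <- data.frame(lineage = env$next_lineage, parent_lineage = NA_integer_,
                       ancestral_id = NA_character_, origin = "birth",
                       birth_node = node, tandem = FALSE, strand = "+",
                       seq = random_cds(L), stringsAsFactors = FALSE)
    register_lineage(env, born$lineage, NA_integer_, NA_character_, "birth",
                     node, FALSE)
    env$next_lineage <- env$next_lineage + 1L
    at <- sample.int(nrow(genome) + 1L, 1L) - 1L
    genome <- insert_row(genome, born, at)
  }
  # substitutions
  p <- cfg$substitution_rate * blen
  if (p > 0 && nrow(genome))
    genome$seq <- vapply(genome$seq, mutate_cds, "", p = p)
  # inversions
  ni <- rpois(1, cfg$inversion_rate)
  for (k in seq_len(ni)) {
    n <- nrow(genome)
    if (n < 2) break
    w <- min(sample(2:8, 1L), n)
    s <- sample.int(n - w + 1L, 1L)
    idx <- s:(s + w - 1L)
    blk <- genome[rev(idx), , drop = FALSE]
    blk$strand <- ifelse(blk$strand == "+", "-", "+")
    genome[idx, ] <- blk
  }
  rownames(genome) <- NULL
  genome
}

#' Simulate annotated genomes with planted orthology truth
#'
#' Evolves an ancestral gene set along a species tree (see [sim_config()])
#' and writes, per species, a genome FASTA and GFF3 annotation plus
#' machine-readable truth tables. The truth records, per species pair, the
#' planted orthologue pairs (same gene lineage on both sides, where a
#' lineage splits only at duplications) and the pair-specific inparalogues
#' (lineages born by duplication after that pair's divergence), plus global
#' lists of births, of all gene copies with their ancestral gene, and the
#' generating species tree.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class \code{sim_result}: \code{fasta} and \code{gff3}
#'   (named file paths), \code{truth} (a \code{sim_truth} list), and
#'   \code{truth_dir}.
#' @export
simulate_genomes <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  tree <- if (!is.null(cfg$species_tree)) {
    ape::read.tree(text = cfg$species_tree)
  } else if (cfg$n_species == 4) {
    ape::read.tree(text = "((sp1:0.067,sp2:0.067):0.033,(sp3:0.067,sp4:0.067):0.033);")
  } else if (cfg$n_species == 2) {
    ape::read.tree(text = "(sp1:0.1,sp2:0.1);")
  } else {
    tr <- ape::rtree(cfg$n_species, rooted = TRUE, br = NULL)
    tr$tip.label <- paste0("sp", seq_len(cfg$n_species))
    depth <- max(ape::node.depth.edgelength(structure(
      c(tr, list(edge.length = rep(1, nrow(tr$edge)))), class = "phylo")))
    tr$edge.length <- rep(0.1 / depth, nrow(tr$edge))
    tr
  }
  species <- tree$tip.label
  env <- new_genome_env()
  L <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
              cfg$n_ancestral_genes, replace = TRUE)
  root_genome <- data.frame(
    lineage = seq_len(cfg$n_ancestral_genes),
    parent_lineage = NA_integer_,
    ancestral_id = sprintf("anc%04d", seq_len(cfg$n_ancestral_genes)),
    origin = "ancestral",
    birth_node = length(species) + 1L,  # root node id in ape numbering
    tandem = FALSE, strand = "+",
    seq = vapply(L, random_cds, ""), stringsAsFactors = FALSE)
  env$next_lineage <- cfg$n_ancestral_genes + 1L
  for (i in seq_len(cfg$n_ancestral_genes))
    register_lineage(env, i, NA_integer_, root_genome$ancestral_id[i],
                     "ancestral", length(species) + 1L, FALSE)
  root <- length(species) + 1L
  tips <- list()
  recurse <- function(node, genome) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) { tips[[species[node]]] <<- genome; return() }
    for (k in kids) {
      blen <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == k)]
      recurse(k, evolve_branch(genome, blen, k, cfg, env))
    }
  }
  recurse(root, root_genome)
  tips <- tips[species]

  # resolve ancestral ids for duplicated lineages by walking parent chains
  # through the registry (parents may themselves be lost lineages)
  reg <- env$reg
  anc_of <- vapply(names(reg), function(l) {
    while (is.na(reg[[l]]$ancestral_id) && !is.na(reg[[l]]$parent))
      l <- as.character(reg[[l]]$parent)
    reg[[l]]$ancestral_id
  }, "")

  # name genes, draw fragmentation, write FASTA/GFF3
  fasta <- gff3 <- character(0)
  gene_tabs <- list()
  for (sp in species) {
    g <- tips[[sp]]
    g$gene_id <- if (nrow(g)) sprintf("%s_g%04d", sp, seq_len(nrow(g))) else character(0)
    g$fragmented <- runif(nrow(g)) < cfg$fragmentation_prob
    paths <- write_species_genome(g, sp, cfg, out_dir)
    fasta[sp] <- paths$fasta; gff3[sp] <- paths$gff3
    g$emitted_len <- paths$emitted_len
    g$fragmented <- paths$fragmented
    gene_tabs[[sp]] <- g
  }

  truth <- build_truth(tree, species, gene_tabs, anc_of, reg)
  truth_dir <- file.path(out_dir, "truth")
  write_truth(truth, truth_dir)
  out <- list(fasta = fasta, gff3 = gff3, truth = truth, truth_dir = truth_dir)
  class(out) <- "sim_result"
  out
}

# Lay genes onto contigs (with intergenic spacers), breaking the contig
# inside fragmented genes, and write FASTA + GFF3 for one species.
write_species_genome <- function(g, sp, cfg, out_dir) {
  rnt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                           collapse = "")
  contigs <- list(); ctg_seq <- ""; ctg_feats <- list(); ctg_n <- 0L
  emitted_len <- integer(nrow(g))
  new_contig <- function() {
    if (nchar(ctg_seq) > 0) {
      contigs[[length(contigs) + 1]] <<- list(seq = ctg_seq, feats = ctg_feats)
    }
    ctg_seq <<- ""; ctg_feats <<- list(); ctg_n <<- 0L
  }
  add_feat <- function(gene_id, start, end, strand, part) {
    ctg_feats[[length(ctg_feats) + 1]] <<- data.frame(
      gene_id = gene_id, start = start, end = end, strand = strand,
      part = part, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(g))) {
    spacer <- rnt(sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1L))
    ctg_seq <- paste0(ctg_seq, spacer)
    seq <- g$seq[i]
    if (g$fragmented[i]) {
      ncod <- nchar(seq) / 3L
      cut <- sample(seq(max(2L, floor(ncod * 0.25)), ceiling(ncod * 0.75)), 1L)
      ndel <- max(1L, round(runif(1, cfg$frag_loss_range[1],
                                  cfg$frag_loss_range[2]) * ncod))
      ndel <- min(ndel, ncod - cut - 2L)
      if (ndel < 1L) { g$fragmented[i] <- FALSE }
      if (g$fragmented[i]) {
        part5 <- substring(seq, 1L, 3L * cut)
        part3 <- substring(seq, 3L * (cut + ndel) + 1L, nchar(seq))
        emitted_len[i] <- nchar(part5) + nchar(part3)
        # left genomic piece first; `part` records 5'->3' rank so the GFF3
        # can present segments in coding order across contigs
        plus <- g$strand[i] == "+"
        pieces <- if (plus) list(p1 = part5, p2 = part3)
                  else list(p1 = revcomp(part3), p2 = revcomp(part5))
        s <- nchar(ctg_seq) + 1L
        ctg_seq <- paste0(ctg_seq, pieces$p1)
        add_feat(g$gene_id[i], s, nchar(ctg_seq), g$strand[i],
                 if (plus) 1L else 2L)
        new_contig()
        ctg_seq <- rnt(sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1L))
        s <- nchar(ctg_seq) + 1L
        ctg_seq <- paste0(ctg_seq, pieces$p2)
        add_feat(g$gene_id[i], s, nchar(ctg_seq), g$strand[i],
                 if (plus) 2L else 1L)
        ctg_n <- ctg_n + 1L
        next
      }
    }
    emitted_len[i] <- nchar(seq)
    gseq <- if (g$strand[i] == "+") seq else revcomp(seq)
    s <- nchar(ctg_seq) + 1L
    ctg_seq <- paste0(ctg_seq, gseq)
    add_feat(g$gene_id[i], s, nchar(ctg_seq), g$strand[i], 1L)
    ctg_n <- ctg_n + 1L
    if (ctg_n >= cfg$genes_per_contig) new_contig()
  }
  ctg_seq <- paste0(ctg_seq, rnt(50L))
  new_contig()
  frag_final <- g$fragmented
  names(contigs) <- sprintf("%s_ctg%03d", sp, seq_along(contigs))
  fasta_path <- file.path(out_dir, paste0(sp, ".fasta"))
  gff3_path <- file.path(out_dir, paste0(sp, ".gff3"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(vapply(contigs, function(x) x$seq, "")),
    fasta_path)
  feats <- do.call(rbind, lapply(names(contigs), function(nm) {
    f <- do.call(rbind, contigs[[nm]]$feats)
    if (is.null(f)) return(NULL)
    f$contig <- nm
    f
  }))
  write_gff3(feats, gff3_path)
  list(fasta = fasta_path, gff3 = gff3_path, emitted_len = emitted_len,
       fragmented = frag_final)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# gene/mRNA/CDS rows; a fragmented gene contributes rows on two contigs
# under the same IDs.
write_gff3 <- function(feats, path) {
  lines <- "##gff-version 3"
  for (gid in unique(feats$gene_id)) {
    f <- feats[feats$gene_id == gid, , drop = FALSE]
    f <- f[order(f$part), , drop = FALSE]
    for (ci in unique(f$contig)) {
      fc <- f[f$contig == ci, , drop = FALSE]
      s <- min(fc$start); e <- max(fc$end); st <- fc$strand[1]
      lines <- c(lines,
        sprintf("%s\tsynorth_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ci, s, e, st, gid),
        sprintf("%s\tsynorth_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                ci, s, e, st, gid, gid),
        sprintf("%s\tsynorth_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                ci, fc$start, fc$end, st, gid, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

build_truth <- function(tree, species, gene_tabs, anc_of, reg) {
  desc_of <- lapply(seq_len(max(tree$edge)), function(n)
    c(n, setdiff(unlist(phangorn::Descendants(tree, n, "all")), n)))
  birth_node <- vapply(reg, function(r) r$birth_node, 0L)
  genes <- do.call(rbind, lapply(names(gene_tabs), function(sp) {
    g <- gene_tabs[[sp]]
    data.frame(species = sp, gene_id = g$gene_id, lineage = g$lineage,
               ancestral_id = unname(anc_of[as.character(g$lineage)]),
               origin = g$origin, fragmented = g$fragmented,
               emitted_len = g$emitted_len, stringsAsFactors = FALSE)
  }))
  # Orthology is defined relative to each species pair's divergence node:
  # two genes are orthologues when they descend from the same gene lineage
  # at the moment of that speciation. Copies from duplications below the
  # node form co-orthologue classes (either copy is a correct orthologue of
  # the partner gene); same-species classes of size >= 2 are that pair's
  # inparalogue sets (label-symmetric: which copy is "the original" is not
  # identifiable from the data and is not asserted).
  lineage_at <- function(lin, below) {
    l <- as.character(lin)
    repeat {
      r <- reg[[l]]
      if (!(r$birth_node %in% below)) return(l)
      if (is.na(r$parent)) return(NA_character_)  # born below the node
      l <- as.character(r$parent)
    }
  }
  pairs <- list(); inpar_pair <- list(); units <- list()
  if (length(species) >= 2) {
    sp_pairs <- combn(sort(species), 2)
    for (k in seq_len(ncol(sp_pairs))) {
      sa <- sp_pairs[1, k]; sb <- sp_pairs[2, k]
      ga <- gene_tabs[[sa]]; gb <- gene_tabs[[sb]]
      mrca <- ape::getMRCA(tree, c(sa, sb))
      below <- setdiff(desc_of[[mrca]], mrca)
      key <- species_pair_key(sa, sb)
      cls_a <- vapply(ga$lineage, lineage_at, "", below = below)
      cls_b <- vapply(gb$lineage, lineage_at, "", below = below)
      shared <- sort(intersect(cls_a[!is.na(cls_a)], cls_b[!is.na(cls_b)]))
      if (length(shared)) {
        pk <- lapply(shared, function(cl) {
          expand.grid(gene_a = ga$gene_id[which(cls_a == cl)],
                      gene_b = gb$gene_id[which(cls_b == cl)],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        })
        np <- vapply(pk, nrow, 0L)
        pairs[[k]] <- data.frame(
          species_a = sa, species_b = sb, do.call(rbind, pk),
          unit_id = paste0(key, ":", rep(shared, np)),
          stringsAsFactors = FALSE)
        units[[k]] <- data.frame(
          species_pair = key, unit_id = paste0(key, ":", shared),
          n_a = vapply(shared, function(cl) sum(cls_a == cl, na.rm = TRUE), 0L),
          n_b = vapply(shared, function(cl) sum(cls_b == cl, na.rm = TRUE), 0L),
          ancestral_id = unname(anc_of[shared]),
          stringsAsFactors = FALSE)
      }
      ip_side <- function(g, cls, sp) {
        t <- table(cls[!is.na(cls)])
        dup_cls <- names(t)[t >= 2]
        sel <- !is.na(cls) & cls %in% dup_cls
        if (!any(sel)) return(NULL)
        data.frame(species = sp, gene_id = g$gene_id[sel],
                   set_id = paste0(key, ":", cls[sel], ":", sp),
                   species_pair = key, stringsAsFactors = FALSE)
      }
      inpar_pair[[k]] <- rbind(ip_side(ga, cls_a, sa), ip_side(gb, cls_b, sb))
    }
  }
  pairs <- do.call(rbind, pairs)
  units <- do.call(rbind, units)
  inpar_pair <- do.call(rbind, inpar_pair) %||%
    data.frame(species = character(), gene_id = character(),
               set_id = character(), species_pair = character(),
               stringsAsFactors = FALSE)
  # a planted birth counts as de novo only while its family is a singleton:
  # births inherited by several species (or duplicated) have homologues in
  # the data set and are expected to be called orthologues/inparalogues
  founder <- vapply(names(reg), function(l) {
    while (reg[[l]]$origin == "dup" && !is.na(reg[[l]]$parent))
      l <- as.character(reg[[l]]$parent)
    l
  }, "")
  genes$birth_family <- ifelse(is.na(genes$ancestral_id),
                               founder[as.character(genes$lineage)], NA)
  fam_size <- table(genes$birth_family)
  singleton <- genes$origin == "birth" & !is.na(genes$birth_family) &
    fam_size[genes$birth_family] == 1
  births <- genes[singleton, c("species", "gene_id")]
  dups <- genes[genes$origin == "dup", c("species", "gene_id")]
  truth <- list(species_tree = tree,
                species = sort(species),
                pairs = pairs, units = units,
                inparalogues_pair = inpar_pair,
                duplicates = dups, births = births, genes = genes)
  class(truth) <- "sim_truth"
  truth
}

#' Write simulation truth tables
#'
#' Emits the species tree (Newick), one orthologue-pair TSV per species
#' pair, pair-specific inparalogue calls, birth and duplicate lists, and the
#' per-gene table (lineage, ancestral gene, origin, fragmentation).
#'
#' @param truth a \code{sim_truth}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(truth$species_tree, file.path(dir, "species_tree.nwk"))
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  p <- truth$pairs
  if (is.null(p) || !nrow(p)) {
    tsv(data.frame(species_a = character(), species_b = character(),
                   gene_a = character(), gene_b = character(),
                   unit_id = character()), "orthologue_pairs.tsv")
  } else {
    tsv(p, "orthologue_pairs.tsv")
    for (key in unique(species_pair_key(p$species_a, p$species_b))) {
      sel <- species_pair_key(p$species_a, p$species_b) == key
      tsv(p[sel, ], sprintf("orthologue_pairs_%s.tsv", gsub("\\|", "_", key)))
    }
  }
  if (!is.null(truth$units)) tsv(truth$units, "orthology_units.tsv")
  tsv(truth$inparalogues_pair, "inparalogues.tsv")
  tsv(truth$births, "births.tsv")
  tsv(truth$genes, "genes.tsv")
  invisible(dir)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$fasta), "species;",
      nrow(x$truth$genes), "genes;", nrow(x$truth$pairs %||% data.frame()),
      "true orthologue pairs\n")
  invisible(x)
}
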