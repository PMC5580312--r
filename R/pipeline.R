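#' Run the orthologue-prediction pipeline end to end
#'
#' Executes the five stages in order -- ingestion, all-vs-all similarity,
#' within-pair clustering and inparalogue detection, candidate building and
#' 1:1 matching with micro-synteny recalibration, and multi-species
#' assembly (orthologue-graph clustering, consensus species tree,
#' orthogroup reconciliation, gene classification, super-orthogroups) --
#' writing each stage's interchange files under \code{out_dir}. With fewer
#' than three species the consensus-tree stage is skipped with a warning.
#' Runs are deterministic for a fixed seed and inputs.
#'
#' @param species either a data.frame with columns \code{name},
#'   \code{fasta}, \code{gff3}, or a pre-built list of \code{gene_set}
#'   objects.
#' @param out_dir output directory (created). \code{NULL} disables all file
#'   output.
#' @param params a [scoring_params()] object.
#' @param seed seed for the consensus-tree cluster sample.
#' @param sample_n single-copy clusters concatenated for the species tree.
#' @param score_col similarity column used for ranking, matching and
#'   representative selection: \code{"s_prime"} (default, fragment-bias
#'   corrected) or \code{"raw50"} (uncorrected Smith-Waterman score, for
#'   comparison studies).
#' @param refine leave-one-out refinement of codon alignments.
#' @param resume reuse cached stage results found in \code{out_dir/cache}.
#' @param stop_after run only up to a stage: one of \code{"similarity"},
#'   \code{"inparalogues"}, \code{"pairwise"}, \code{"multispecies"}
#'   (default: the full pipeline).
#' @param hits optional precomputed hit table (skips the similarity stage;
#'   used when comparing scoring modes on identical alignments).
#' @param verbose log per-stage progress.
#' @return object of class \code{ortho_run}: list with \code{gene_sets},
#'   \code{gene_order}, \code{hits}, \code{inparalogues} (calls after
#'   rescue), \code{candidates}, \code{pairs}, \code{clusters},
#'   \code{species_tree}, \code{orthogroups}, \code{classes}, \code{sogs},
#'   \code{summary}, \code{params}.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_genomes(sim_config(n_ancestral_genes = 30, seed = 7), dir)
#' run <- run_pipeline(data.frame(name = names(sim$fasta), fasta = sim$fasta,
#'                                gff3 = sim$gff3),
#'                     out_dir = file.path(dir, "out"))
#' summary(run)
#' }
#' @export
run_pipeline <- function(species, out_dir = NULL, params = scoring_params(),
                         seed = 1L, sample_n = 50L, score_col = "s_prime",
                         refine = TRUE, resume = FALSE,
                         stop_after = "multispecies", hits = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[synorth] ", ...)
  stages <- c("similarity", "inparalogues", "pairwise", "multispecies")
  stop_after <- match.arg(stop_after, stages)
  cache_dir <- if (!is.null(out_dir) && resume) file.path(out_dir, "cache")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (resume) dir.create(cache_dir, showWarnings = FALSE)
  }
  cached <- function(tag, expr) {
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, paste0(tag, ".rds"))
      if (file.exists(f)) { say("reusing cached stage: ", tag); return(readRDS(f)) }
      v <- force(expr)
      saveRDS(v, f)
      return(v)
    }
    force(expr)
  }

  # stage 1: ingest
  gene_sets <- if (is.data.frame(species)) {
    say("ingesting ", nrow(species), " annotated genomes")
    stopifnot(all(c("name", "fasta", "gff3") %in% names(species)),
              nrow(species) >= 2)
    lapply(seq_len(nrow(species)), function(i)
      read_genome_annotation(species$fasta[i], species$gff3[i], species$name[i]))
  } else species
  stopifnot(length(gene_sets) >= 2)
  sp_names <- vapply(gene_sets, function(g) g$species_id, "")
  gene_order <- build_gene_order(gene_sets)
  if (!is.null(out_dir)) {
    for (gs in gene_sets)
      write_gene_fasta(gs, file.path(out_dir, paste0(gs$species_id, ".proteins.fasta")))
    write_gene_order(gene_order, file.path(out_dir, "gene_order.tsv"))
  }

  # stage 2: all-vs-all similarity
  if (is.null(hits)) {
    say("computing all-vs-all similarity")
    hits <- cached("hits", all_vs_all_scores(gene_sets, params))
  }
  if (!is.null(out_dir)) {
    key <- species_pair_key(hits$species_a, hits$species_b)
    for (k in unique(key))
      write_hits(hits[key == k, ],
                 file.path(out_dir, sprintf("hits_%s.tsv", gsub("\\|", "_", k))))
  }
  res <- list(gene_sets = gene_sets, gene_order = gene_order, hits = hits,
              params = params, score_col = score_col)
  class(res) <- "ortho_run"
  if (stop_after == "similarity") return(res)

  # stage 3: within-pair clustering + inparalogue detection
  say("detecting inparalogues per species pair")
  ip <- cached(paste0("inpar_", score_col),
               detect_inparalogues(gene_sets, hits, gene_order, params,
                                   score_col, refine))

  # stage 4: candidates, matching, micro-synteny recalibration
  say("assigning pairwise orthologues")
  cands <- build_candidates(hits, params, exclude = ip$calls, score_col)
  pairs0 <- assign_orthologues(cands, score_col)
  rec <- synteny_recalibrate(pairs0, hits, gene_order, ip$calls,
                             clusters = ip$clusters, params, score_col)
  res$candidates <- cands
  res$pairs <- rec$pairs
  res$inparalogues <- rec$inparalogues
  if (!is.null(out_dir)) {
    write.table(rec$pairs, file.path(out_dir, "orthologue_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rec$inparalogues, file.path(out_dir, "inparalogues.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stop_after %in% c("inparalogues", "pairwise")) return(res)

  # stage 5: multi-species assembly
  say("building orthogroups and super-orthogroups")
  if (nrow(rec$pairs)) {
    cl <- cluster_orthologue_graph(rec$pairs, inflation = params$inflation)
    tree <- NULL
    if (length(gene_sets) >= 3) {
      tree <- tryCatch(
        consensus_species_tree(cl, gene_sets, sample_n = sample_n, seed = seed,
                               params = params, refine = refine),
        error = function(e) { warning(conditionMessage(e)); NULL })
    } else warning("fewer than 3 species: consensus-tree stage skipped")
    og <- reconcile_orthogroups(cl, rec$pairs, n_species = length(gene_sets),
                                score_col = score_col)
  } else {
    warning("no orthologue pairs: downstream stages degenerate")
    cl <- NULL; tree <- NULL
    og <- reconcile_orthogroups(
      structure(list(clusters = list()), class = "cluster_set"),
      rec$pairs, n_species = length(gene_sets), score_col = score_col)
  }
  classes <- classify_genes(gene_sets, og, rec$inparalogues, hits, params)
  sogs <- build_super_orthogroups(og, classes, hits, params,
                                  inflation = params$inflation)
  res$clusters <- cl
  res$species_tree <- tree
  res$orthogroups <- og
  res$classes <- classes
  res$sogs <- sogs
  res$summary <- class_summary(classes)
  if (!is.null(out_dir)) {
    og_out <- merge(og$members,
                    merge(og$table,
                          sogs[sogs$member_type == "OG",
                               c("member_id", "sog_id", "sog_member_id")],
                          by.x = "og_id", by.y = "member_id", all.x = TRUE),
                    by = "og_id")
    write.table(og_out, file.path(out_dir, "orthogroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(classes, file.path(out_dir, "gene_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sogs, file.path(out_dir, "super_orthogroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$summary, file.path(out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree))
      ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
  }
  res
}

#' @export
print.ortho_run <- function(x, ...) {
  cat("<ortho_run>", length(x$gene_sets), "species,",
      sum(vapply(x$gene_sets, function(g) nrow(g$genes), 0L)), "genes\n")
  if (!is.null(x$pairs))
    cat("  pairwise orthologue pairs:", nrow(x$pairs), "\n")
  if (!is.null(x$orthogroups))
    cat("  orthogroups:", nrow(x$orthogroups$table), "(",
        sum(x$orthogroups$table$class == "ONE_TO_ONE_ALL"), "all-species )\n")
  invisible(x)
}

#' @export
summary.ortho_run <- function(object, ...) {
  print(object)
  if (!is.null(object$summary)) {
    cat("  gene classes per species:\n")
    print(object$summary, row.names = FALSE)
  }
  invisible(object$summary)
}
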