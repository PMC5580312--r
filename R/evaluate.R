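#' Score pipeline predictions against simulation truth
#'
#' Orthology truth is label-symmetric: after a duplication either copy is a
#' correct orthologue of the partner gene, so the truth tables record
#' co-orthologue classes per species pair (see [simulate_genomes()]).
#' Precision of the predicted 1:1 pairs is the fraction that are true
#' co-orthologue pairs; recall is class-level -- the fraction of
#' co-orthologue classes present in both species for which at least one
#' correct pair was predicted (one 1:1 call cannot cover a many-to-many
#' class twice). Inparalogue calls are scored against the pair-specific
#' duplicate sets: a call is correct when its gene lies in a same-species
#' set of two or more co-orthologous copies, and a set of k copies
#' contributes k-1 expected calls to recall. De novo precision/recall are
#' computed globally on the gene classification against the planted
#' singleton births. The number of all-species orthogroups and -- when
#' available -- the Robinson-Foulds distance between the consensus species
#' tree and the generating tree complete the report. Precision is \code{NA}
#' when nothing was predicted; recall is \code{NA} when truth is empty. A
#' recall restricted to classes involving fragmented gene models is
#' reported separately (the fragment-tolerance axis).
#'
#' @param run a pipeline result from [run_pipeline()] (or a compatible list
#'   with \code{pairs}, \code{inparalogues}, \code{classes},
#'   \code{orthogroups}, \code{species_tree}).
#' @param truth a \code{sim_truth} from [simulate_genomes()].
#' @return object of class \code{evaluation_report}: list with
#'   \code{per_pair} (data.frame) and \code{summary} (named list).
#' @export
score_predictions <- function(run, truth) {
  pred_pairs <- run$pairs
  known <- unique(truth$genes$gene_id)
  bad <- setdiff(unique(c(pred_pairs$gene_a, pred_pairs$gene_b)), known)
  if (length(bad))
    stop("predicted gene ids absent from truth (first few): ",
         paste(head(bad, 5), collapse = ", "))
  frag_genes <- truth$genes$gene_id[truth$genes$fragmented]
  species <- truth$species
  per_pair <- list()
  sp_pairs <- combn(species, 2)
  for (k in seq_len(ncol(sp_pairs))) {
    sa <- sp_pairs[1, k]; sb <- sp_pairs[2, k]
    key <- species_pair_key(sa, sb)
    tp <- truth$pairs[truth$pairs$species_a == sa & truth$pairs$species_b == sb, ]
    un <- truth$units[truth$units$species_pair == key, ]
    pp <- pred_pairs[pred_pairs$species_a == sa & pred_pairs$species_b == sb, ]
    true_keys <- paste(tp$gene_a, tp$gene_b)
    pred_keys <- paste(pp$gene_a, pp$gene_b)
    hit <- pred_keys %in% true_keys
    precision <- if (length(pred_keys)) mean(hit) else NA_real_
    hit_units <- unique(tp$unit_id[match(pred_keys[hit], true_keys)])
    recall <- if (nrow(un)) length(intersect(un$unit_id, hit_units)) / nrow(un)
              else NA_real_
    # fragment-restricted recall: classes with a fragmented member gene
    frag_units <- unique(tp$unit_id[tp$gene_a %in% frag_genes |
                                    tp$gene_b %in% frag_genes])
    frag_rec <- if (length(frag_units))
      length(intersect(frag_units, hit_units)) / length(frag_units)
    else NA_real_
    # inparalogues for this pair (set-based)
    ti <- truth$inparalogues_pair[truth$inparalogues_pair$species_pair == key, ]
    pin <- run$inparalogues[run$inparalogues$species_pair == key, ]
    ihit <- pin$gene_id %in% ti$gene_id
    ip_precision <- if (nrow(pin)) mean(ihit) else NA_real_
    set_sizes <- table(ti$set_id)
    n_expected <- sum(pmax(set_sizes - 1L, 0L))
    n_recovered <- 0L
    if (n_expected > 0 && any(ihit)) {
      called_sets <- table(ti$set_id[match(pin$gene_id[ihit], ti$gene_id)])
      n_recovered <- sum(pmin(called_sets,
                              set_sizes[names(called_sets)] - 1L))
    }
    ip_recall <- if (n_expected > 0) n_recovered / n_expected else NA_real_
    per_pair[[k]] <- data.frame(
      species_a = sa, species_b = sb,
      n_true = nrow(un), n_pred = length(pred_keys),
      precision = precision, recall = recall,
      n_frag = length(frag_units), frag_recall = frag_rec,
      inpar_n_true = n_expected, inpar_n_pred = nrow(pin),
      inpar_precision = ip_precision, inpar_recall = ip_recall,
      stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, per_pair)
  # de novo births (global, on the gene classification)
  pred_dnv <- run$classes$gene_id[run$classes$class == "DE_NOVO"]
  true_dnv <- truth$births$gene_id
  d <- list(precision = if (length(pred_dnv)) mean(pred_dnv %in% true_dnv)
                        else NA_real_,
            recall = if (length(true_dnv)) mean(true_dnv %in% pred_dnv)
                     else NA_real_)
  # gene-level fragmented recall: a fragmented gene with at least one true
  # partner counts as recovered when it participates in a correct predicted
  # pair (sensitive to fragments being sidelined in favour of full-length
  # copies, the failure mode the corrected score removes)
  all_true_keys <- paste(truth$pairs$gene_a, truth$pairs$gene_b)
  all_pred_keys <- paste(pred_pairs$gene_a, pred_pairs$gene_b)
  good <- pred_pairs[all_pred_keys %in% all_true_keys, ]
  recovered_genes <- unique(c(good$gene_a, good$gene_b))
  frag_with_partner <- intersect(frag_genes,
                                 unique(c(truth$pairs$gene_a, truth$pairs$gene_b)))
  frag_gene_recall <- if (length(frag_with_partner))
    mean(frag_with_partner %in% recovered_genes) else NA_real_
  rf <- NA_integer_
  if (!is.null(run$species_tree) && length(species) >= 4)
    rf <- robinson_foulds(run$species_tree, truth$species_tree)
  agg <- function(num, den) {
    s <- sum(num, na.rm = TRUE); t <- sum(den, na.rm = TRUE)
    if (t > 0) s / t else NA_real_
  }
  summary <- list(
    pairwise_precision = agg(per_pair$precision * per_pair$n_pred, per_pair$n_pred),
    pairwise_recall = agg(per_pair$recall * per_pair$n_true, per_pair$n_true),
    frag_recall = agg(per_pair$frag_recall * per_pair$n_frag, per_pair$n_frag),
    frag_gene_recall = frag_gene_recall,
    inparalogue_precision = agg(per_pair$inpar_precision * per_pair$inpar_n_pred,
                                per_pair$inpar_n_pred),
    inparalogue_recall = agg(per_pair$inpar_recall * per_pair$inpar_n_true,
                             per_pair$inpar_n_true),
    denovo_precision = d$precision, denovo_recall = d$recall,
    n_orthogroups_all = sum(run$orthogroups$table$class == "ONE_TO_ONE_ALL"),
    n_orthogroups = nrow(run$orthogroups$table),
    tree_rf = rf)
  out <- list(per_pair = per_pair, summary = summary)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat("<evaluation_report>\n")
  cat(sprintf("  pairwise orthologues: precision %.3f, recall %.3f\n",
              s$pairwise_precision, s$pairwise_recall))
  cat(sprintf("  inparalogues:         precision %.3f, recall %.3f\n",
              s$inparalogue_precision, s$inparalogue_recall))
  cat(sprintf("  de novo births:       precision %.3f, recall %.3f\n",
              s$denovo_precision, s$denovo_recall))
  cat(sprintf("  orthogroups: %d (%d with all species)\n",
              s$n_orthogroups, s$n_orthogroups_all))
  if (!is.na(s$tree_rf))
    cat(sprintf("  species-tree RF distance: %d\n", s$tree_rf))
  invisible(x)
}

#' Write an evaluation report to TSV
#' @param report an \code{evaluation_report}.
#' @param path output file for the per-pair table; the summary is written
#'   alongside with suffix \code{.summary.tsv}.
#' @return the path, invisibly.
#' @export
write_evaluation <- function(report, path) {
  write.table(report$per_pair, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- report$summary
  write.table(data.frame(metric = names(s), value = unlist(s)),
              paste0(path, ".summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
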