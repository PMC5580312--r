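#' Parse one species' genome annotation into gene models
#'
#' Reads a genome FASTA and a GFF3 annotation (gene/mRNA/CDS hierarchy) and
#' builds one gene model per gene: the spliced coding sequence (CDS exons
#' concatenated 5' to 3', minus-strand segments reverse-complemented), its
#' translation, and the gene's position in the genome. When a gene has
#' several splice variants the isoform with the longest CDS is retained
#' (length ties broken by lexicographically smallest transcript ID). Gene
#' models whose CDS rows fall on more than one contig -- as produced by
#' annotating fragmented draft assemblies -- are merged into a single model
#' and flagged \code{fragmented}.
#'
#' Internally all coordinates are 0-based half-open; GFF3 input is 1-based
#' inclusive.
#'
#' @param fasta_path path to the genome FASTA.
#' @param gff3_path path to the GFF3 annotation.
#' @param species_id short species label used in all downstream output.
#' @return An object of class \code{gene_set}: a list with elements
#'   \code{species_id}, \code{genes} (one row per gene: \code{gene_id},
#'   \code{transcript_id}, anchor \code{contig}/\code{start}/\code{end},
#'   \code{strand}, \code{n_segments}, \code{fragmented}, \code{partial},
#'   \code{isoform_count}), \code{segments} (CDS segments in 5'-to-3' order),
#'   and named character vectors \code{cds} and \code{protein}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_genomes(sim_config(n_species = 2, n_ancestral_genes = 5,
#'                                    seed = 1), dir)
#' gs <- read_genome_annotation(sim$fasta[1], sim$gff3[1], names(sim$fasta)[1])
#' gs
#' @export
read_genome_annotation <- function(fasta_path, gff3_path, species_id) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  build_gene_models(contigs, gff, species_id)
}

# Core of the parser, separated so simulated annotations can be ingested
# without touching disk.
build_gene_models <- function(contigs, gff, species_id) {
  type <- as.character(gff$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gff))) gff$ID else rep(NA_character_, length(gff))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gff))) {
    vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(gff))

  gene_rows <- which(type == "gene")
  if (!length(gene_rows)) {
    warning("no gene features found for species '", species_id, "'")
    return(empty_gene_set(species_id))
  }
  gene_ids <- ids[gene_rows]
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  tx_gene <- setNames(parents[tx_rows], ids[tx_rows])

  cds_rows <- which(type == "CDS")
  cds_parent <- parents[cds_rows]
  # resolve each CDS to (transcript, gene); CDS may also hang off a gene
  cds_tx <- ifelse(cds_parent %in% names(tx_gene), cds_parent,
                   ifelse(cds_parent %in% gene_ids, cds_parent, NA))
  cds_gene <- ifelse(cds_parent %in% names(tx_gene), tx_gene[cds_parent],
                     ifelse(cds_parent %in% gene_ids, cds_parent, NA))
  orphan <- is.na(cds_gene)
  if (any(orphan)) {
    warning(sum(orphan), " CDS record(s) without a parent gene skipped")
    cds_rows <- cds_rows[!orphan]
    cds_tx <- cds_tx[!orphan]; cds_gene <- cds_gene[!orphan]
  }
  if (!length(cds_rows)) {
    warning("no usable CDS features for species '", species_id, "'")
    return(empty_gene_set(species_id))
  }
  cds_contig <- as.character(GenomeInfoDb::seqnames(gff))[cds_rows]
  missing_ctg <- setdiff(unique(cds_contig), names(contigs))
  if (length(missing_ctg))
    stop("CDS reference contig(s) absent from the FASTA: ",
         paste(missing_ctg, collapse = ", "))
  cds <- data.frame(
    gene_id = cds_gene, transcript_id = cds_tx, contig = cds_contig,
    start = BiocGenerics::start(gff)[cds_rows] - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gff)[cds_rows],
    strand = as.character(BiocGenerics::strand(gff))[cds_rows],
    file_order = seq_along(cds_rows), stringsAsFactors = FALSE)

  # assemble each transcript, then keep the longest isoform per gene
  models <- lapply(split(cds, cds$transcript_id), assemble_transcript,
                   contigs = contigs)
  tx_tab <- data.frame(
    transcript_id = names(models),
    gene_id = vapply(models, function(m) m$gene_id, ""),
    cds_len = vapply(models, function(m) nchar(m$cds), 0L),
    stringsAsFactors = FALSE)
  tx_tab <- tx_tab[order(tx_tab$gene_id, -tx_tab$cds_len, tx_tab$transcript_id), ]
  keep <- tx_tab[!duplicated(tx_tab$gene_id), ]
  iso_n <- table(tx_tab$gene_id)

  chosen <- models[keep$transcript_id]
  segs <- do.call(rbind, lapply(chosen, function(m) {
    s <- m$segments
    s$gene_id <- m$gene_id
    s
  }))
  rownames(segs) <- NULL
  genes <- data.frame(
    gene_id = vapply(chosen, function(m) m$gene_id, ""),
    transcript_id = keep$transcript_id,
    contig = vapply(chosen, function(m) m$segments$contig[1], ""),
    start = vapply(chosen, function(m) m$segments$start[1], 0L),
    end = vapply(chosen, function(m) m$segments$end[1], 0L),
    strand = vapply(chosen, function(m) m$segments$strand[1], ""),
    n_segments = vapply(chosen, function(m) nrow(m$segments), 0L),
    fragmented = vapply(chosen, function(m) length(unique(m$segments$contig)) > 1L, TRUE),
    partial = vapply(chosen, function(m) m$partial, TRUE),
    isoform_count = as.integer(iso_n[vapply(chosen, function(m) m$gene_id, "")]),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  out <- list(
    species_id = species_id,
    genes = genes,
    segments = segs[, c("gene_id", "contig", "start", "end", "strand")],
    cds = setNames(vapply(chosen, function(m) m$cds, "")[match(genes$gene_id, vapply(chosen, function(m) m$gene_id, ""))],
                   genes$gene_id),
    protein = setNames(vapply(chosen, function(m) m$protein, "")[match(genes$gene_id, vapply(chosen, function(m) m$gene_id, ""))],
                       genes$gene_id))
  class(out) <- "gene_set"
  out
}

empty_gene_set <- function(species_id) {
  out <- list(species_id = species_id,
              genes = data.frame(gene_id = character(), transcript_id = character(),
                                 contig = character(), start = integer(), end = integer(),
                                 strand = character(), n_segments = integer(),
                                 fragmented = logical(), partial = logical(),
                                 isoform_count = integer(), stringsAsFactors = FALSE),
              segments = data.frame(gene_id = character(), contig = character(),
                                    start = integer(), end = integer(),
                                    strand = character(), stringsAsFactors = FALSE),
              cds = character(), protein = character())
  class(out) <- "gene_set"
  out
}

# One transcript: order CDS segments 5'->3' (contigs in file order; within a
# contig by coordinate, descending for the minus strand), splice, translate.
assemble_transcript <- function(seg, contigs) {
  ctg_order <- unique(seg$contig[order(seg$file_order)])
  seg$ctg_rank <- match(seg$contig, ctg_order)
  minus <- seg$strand[1] == "-"
  seg <- seg[order(seg$ctg_rank, if (minus) -seg$start else seg$start), ]
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    s <- as.character(Biostrings::subseq(contigs[[seg$contig[i]]],
                                         start = seg$start[i] + 1L,
                                         end = seg$end[i]))
    if (seg$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")
  cds <- paste(pieces, collapse = "")
  tr <- translate_cds(cds, warn_internal_stop = TRUE)
  list(gene_id = seg$gene_id[1], cds = cds, protein = tr$protein,
       partial = tr$partial,
       segments = seg[, c("contig", "start", "end", "strand")])
}

#' Translate a coding sequence with draft-genome tolerance
#'
#' Standard genetic code. A terminal stop codon is trimmed; codons containing
#' ambiguity characters translate to \code{'X'}; internal stops are kept as
#' \code{'*'} with a warning (rather than rejecting the gene, so that
#' pseudogenised or mis-annotated models in draft genomes still enter the
#' comparison). A trailing partial codon is dropped and the gene flagged
#' \code{partial}.
#'
#' @param cds_nt nucleotide string over \code{A,C,G,T,N} (case-insensitive).
#' @param warn_internal_stop warn when an internal stop is retained.
#' @return list with \code{protein} (amino-acid string) and \code{partial}
#'   (TRUE when the CDS length was not a multiple of 3).
#' @examples
#' translate_cds("ATGGCTTAA")$protein   # "MA"
#' translate_cds("ATGNNTGGA")$protein   # "MXG"
#' @export
translate_cds <- function(cds_nt, warn_internal_stop = TRUE) {
  x <- toupper(cds_nt)
  n <- nchar(x)
  partial <- (n %% 3L) != 0L
  n <- n - (n %% 3L)
  if (n == 0L) return(list(protein = "", partial = partial))
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (warn_internal_stop && any(aa == "*"))
    warning("internal stop codon(s) retained as '*'")
  list(protein = paste(aa, collapse = ""), partial = partial)
}

#' Genome gene order
#'
#' Orders genes along each contig by the start coordinate of their 5'-most
#' CDS segment; fragmented gene models are anchored to the contig of that
#' segment. Ties on coordinate are broken by gene ID. Ordinals restart at 0
#' on every contig; they are the positional coordinate used by the
#' micro-synteny window tests.
#'
#' @param x a \code{gene_set} or a list of them.
#' @return data.frame with columns \code{species}, \code{contig},
#'   \code{ordinal}, \code{gene_id}, \code{start}, \code{end}, \code{strand}.
#' @export
build_gene_order <- function(x) {
  if (inherits(x, "gene_set")) x <- list(x)
  out <- lapply(x, function(gs) {
    g <- gs$genes
    if (!nrow(g))
      return(data.frame(species = character(), contig = character(),
                        ordinal = integer(), gene_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    g <- g[order(g$contig, g$start, g$gene_id), ]
    ordinal <- as.integer(ave(seq_len(nrow(g)), g$contig, FUN = seq_along)) - 1L
    data.frame(species = gs$species_id, contig = g$contig, ordinal = ordinal,
               gene_id = g$gene_id, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> species:", x$species_id, "-", nrow(x$genes), "genes on",
      length(unique(x$genes$contig)), "contig(s);",
      sum(x$genes$fragmented), "fragmented,", sum(x$genes$partial), "partial\n")
  invisible(x)
}

#' Write protein or CDS sequences of a gene set to FASTA
#'
#' @param gs a \code{gene_set}.
#' @param path output file.
#' @param what \code{"protein"} or \code{"cds"}.
#' @return the path, invisibly.
#' @export
write_gene_fasta <- function(gs, path, what = c("protein", "cds")) {
  what <- match.arg(what)
  seqs <- gs[[what]]
  set <- if (what == "protein") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a gene-order table to TSV
#' @param gene_order output of [build_gene_order()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_order <- function(gene_order, path) {
  write.table(gene_order, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
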