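#' Scoring parameters for the similarity stage
#'
#' Bundles every tunable of the all-vs-all comparison. Defaults follow the
#' pipeline's standard settings: BLOSUM50 for the fragment-bias-corrected
#' score and BLOSUM50/62 gap penalties of -10 (open) and -1 (per residue
#' extended); a BLOSUM62 prefilter converted to bit score / e-value through
#' Karlin-Altschul statistics (gapped-BLOSUM62 constants lambda = 0.267,
#' K = 0.041) with thresholds bit >= 30 and E <= 1e-7; alignment coverage
#' > 50\% of at least one of the two genes; and the five best candidates
#' retained per gene and target species.
#'
#' The low gap-extension penalty (-1) deliberately tolerates the long gaps
#' produced by truncated or fragmented gene models.
#'
#' @param gap_open gap opening penalty (positive; a gap of length L costs
#'   \code{gap_open + L * gap_ext}).
#' @param gap_ext gap extension penalty per residue (positive).
#' @param lambda,K Karlin-Altschul constants for the BLOSUM62 prefilter.
#' @param min_bit minimum prefilter bit score.
#' @param max_evalue maximum prefilter e-value.
#' @param min_coverage minimum aligned fraction; by default applied to the
#'   better-covered of the two genes (\code{coverage_mode = "max"}) so short
#'   fragments are not penalised; set \code{coverage_mode = "min"} to require
#'   it of both.
#' @param top_k candidates kept per gene per target species.
#' @param coverage_mode \code{"max"} or \code{"min"}, see above.
#' @param kmer_k,min_shared_kmers k-mer prescreen: pairs of proteins sharing
#'   fewer than \code{min_shared_kmers} distinct k-mers skip the full
#'   alignment. The default (k = 4, at least one shared 4-mer) is
#'   conservative: proteins of these lengths with no common 4-mer cannot
#'   reach the bit-score threshold. Set \code{min_shared_kmers = 0} to
#'   disable.
#' @param window micro-synteny window (genes either side) used downstream.
#' @param inflation Markov-clustering inflation used downstream.
#' @return a list of class \code{scoring_params}.
#' @export
scoring_params <- function(gap_open = 10, gap_ext = 1,
                           lambda = 0.267, K = 0.041,
                           min_bit = 30, max_evalue = 1e-7,
                           min_coverage = 0.5, top_k = 5L,
                           coverage_mode = c("max", "min"),
                           kmer_k = 4L, min_shared_kmers = 1L,
                           window = 6L, inflation = 2) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(gap_ext == 1)  # the reduced extension penalty is a design constant
  p <- list(gap_open = gap_open, gap_ext = gap_ext, lambda = lambda, K = K,
            min_bit = min_bit, max_evalue = max_evalue,
            min_coverage = min_coverage, top_k = as.integer(top_k),
            coverage_mode = coverage_mode, kmer_k = as.integer(kmer_k),
            min_shared_kmers = as.integer(min_shared_kmers),
            window = as.integer(window), inflation = inflation)
  class(p) <- "scoring_params"
  p
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under affine gaps (a gap of length L costs
#' \code{gap_open + L * gap_ext}). Traceback is deterministic: the
#' highest-scoring cell with the smallest (i, j) is used and, among equal
#' moves, diagonal is preferred over up over left. Residues outside the
#' substitution alphabet are treated as \code{'X'} with a warning.
#'
#' Arguments are ordered canonically (lexicographically) before the dynamic
#' programme runs and the results swapped back, so every statistic is exactly
#' symmetric in the two sequences even when co-optimal alignments exist.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @param matrix \code{"BLOSUM50"} (scoring) or \code{"BLOSUM62"} (prefilter).
#' @param params a [scoring_params()] object.
#' @return list with \code{score}, \code{aln_len} (columns, gaps included),
#'   \code{n_ident}, \code{cov_a}, \code{cov_b} (aligned fraction of each
#'   protein) and the 1-based aligned ranges.
#' @examples
#' sw_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
sw_align <- function(protein_a, protein_b, matrix = "BLOSUM50",
                     params = scoring_params()) {
  mat <- blosum_matrix(matrix)
  swapped <- protein_b < protein_a
  if (swapped) { tmp <- protein_a; protein_a <- protein_b; protein_b <- tmp }
  a <- encode_protein(protein_a); b <- encode_protein(protein_b)
  r <- .cpp_sw_align(a - 1L, b - 1L, mat, params$gap_open, params$gap_ext)
  r$cov_a <- if (r$a_end > 0) (r$a_end - r$a_start + 1) / length(a) else 0
  r$cov_b <- if (r$b_end > 0) (r$b_end - r$b_start + 1) / length(b) else 0
  if (swapped) {
    r[c("a_start", "a_end", "b_start", "b_end", "cov_a", "cov_b")] <-
      r[c("b_start", "b_end", "a_start", "a_end", "cov_b", "cov_a")]
  }
  r
}

#' Fragment-bias-corrected similarity score
#'
#' The per-column-normalised local alignment score weighted by percent
#' identity: \code{(raw_score / aln_len) * (100 * n_ident / aln_len)}.
#' Normalising by alignment length removes the advantage long full-length
#' genes have over truncated fragments under the raw Smith-Waterman score,
#' so a fragment aligning perfectly over its whole (shorter) length scores
#' as highly per column as the full-length gene would.
#'
#' @param raw_score Smith-Waterman BLOSUM50 score.
#' @param aln_len alignment columns (gaps included); must be > 0.
#' @param n_ident identical aligned residue pairs.
#' @return the corrected score (>= 0 for non-negative raw scores).
#' @export
s_prime_score <- function(raw_score, aln_len, n_ident) {
  stopifnot(all(aln_len > 0))
  (raw_score / aln_len) * (100 * n_ident / aln_len)
}

#' Bit score and e-value from a raw prefilter score
#'
#' Karlin-Altschul statistics: \code{bit = (lambda * S - ln K) / ln 2} and
#' \code{E = len_a * db_residues * 2^-bit}, with \code{db_residues} the total
#' residue count of the target proteome.
#'
#' @param raw_score raw BLOSUM62 Smith-Waterman score(s).
#' @param len_a query protein length(s).
#' @param db_residues total residues in the target species' proteome.
#' @param lambda,K Karlin-Altschul constants.
#' @return data.frame with columns \code{bit} and \code{evalue}.
#' @export
bit_evalue <- function(raw_score, len_a, db_residues,
                       lambda = 0.267, K = 0.041) {
  bit <- (lambda * raw_score - log(K)) / log(2)
  data.frame(bit = bit, evalue = len_a * db_residues * 2^(-bit))
}

#' All-vs-all protein similarity for a set of species
#'
#' Computes, for every unordered pair of distinct genes (within and between
#' species), the BLOSUM62 prefilter alignment and -- where it can reach the
#' bit-score threshold -- the BLOSUM50 alignment with full statistics and the
#' fragment-bias-corrected score. Pairs sharing fewer than
#' \code{params$min_shared_kmers} k-mers are skipped. The per-pair e-value
#' uses the larger of the two directional values (query length times target
#' proteome size), so a kept hit passes from both directions.
#'
#' @param gene_sets list of \code{gene_set} objects (>= 1 species).
#' @param params a [scoring_params()] object.
#' @param verbose print per-pair progress.
#' @return data.frame (the pipeline's hit-table interchange format) with one
#'   row per unordered gene pair that reached the bit threshold: columns
#'   \code{gene_a}, \code{gene_b}, \code{species_a}, \code{species_b},
#'   \code{raw62}, \code{raw50}, \code{aln_len}, \code{n_ident},
#'   \code{pct_id}, \code{cov_a}, \code{cov_b}, \code{bit}, \code{evalue},
#'   \code{s_prime}.
#' @export
all_vs_all_scores <- function(gene_sets, params = scoring_params(),
                              verbose = FALSE) {
  prot <- unlist(lapply(gene_sets, function(g) g$protein))
  species <- rep(vapply(gene_sets, function(g) g$species_id, ""),
                 vapply(gene_sets, function(g) length(g$protein), 0L))
  ids <- unlist(lapply(gene_sets, function(g) names(g$protein)), use.names = FALSE)
  names(prot) <- ids
  keep <- nchar(prot) > 0
  prot <- prot[keep]; species <- species[keep]; ids <- ids[keep]
  n <- length(prot)
  if (n < 2) return(empty_hits())
  enc <- lapply(prot, function(p) encode_protein(p, warn = FALSE) - 1L)
  lens <- nchar(prot)
  db_res <- tapply(lens, species, sum)
  pr <- combn(n, 2L)
  raw62_min <- (params$min_bit * log(2) + log(params$K)) / params$lambda
  res <- .cpp_sw_batch(enc, pr[1, ], pr[2, ],
                       blosum_matrix("BLOSUM50"), blosum_matrix("BLOSUM62"),
                       params$gap_open, params$gap_ext, raw62_min,
                       params$kmer_k, params$min_shared_kmers)
  kept <- res[, 1] == 1
  if (!any(kept)) return(empty_hits())
  ia <- pr[1, kept]; ib <- pr[2, kept]; res <- res[kept, , drop = FALSE]
  aln_len <- res[, 4]
  hits <- data.frame(
    gene_a = ids[ia], gene_b = ids[ib],
    species_a = species[ia], species_b = species[ib],
    raw62 = res[, 2], raw50 = res[, 3],
    aln_len = as.integer(aln_len), n_ident = as.integer(res[, 5]),
    pct_id = 100 * res[, 5] / aln_len,
    cov_a = (res[, 7] - res[, 6] + 1) / lens[ia],
    cov_b = (res[, 9] - res[, 8] + 1) / lens[ib],
    stringsAsFactors = FALSE)
  be_ab <- bit_evalue(hits$raw62, lens[ia], db_res[species[ib]],
                      params$lambda, params$K)
  be_ba <- bit_evalue(hits$raw62, lens[ib], db_res[species[ia]],
                      params$lambda, params$K)
  hits$bit <- be_ab$bit
  hits$evalue <- pmax(be_ab$evalue, be_ba$evalue)
  hits$s_prime <- s_prime_score(hits$raw50, hits$aln_len, hits$n_ident)
  hits <- hits[hits$aln_len > 0, ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             species_a = character(), species_b = character(),
             raw62 = numeric(), raw50 = numeric(), aln_len = integer(),
             n_ident = integer(), pct_id = numeric(), cov_a = numeric(),
             cov_b = numeric(), bit = numeric(), evalue = numeric(),
             s_prime = numeric(), stringsAsFactors = FALSE)
}

# Rows of the hit table passing the three similarity filters
# (coverage, bit score, e-value).
passing_hits <- function(hits, params = scoring_params()) {
  cov <- if (params$coverage_mode == "max") pmax(hits$cov_a, hits$cov_b)
         else pmin(hits$cov_a, hits$cov_b)
  hits[cov > params$min_coverage & hits$bit >= params$min_bit &
       hits$evalue <= params$max_evalue, , drop = FALSE]
}

#' Top-k candidate orthologues per gene and target species
#'
#' Keeps, for every gene and every other species, the \code{top_k} genes with
#' the highest fragment-bias-corrected similarity among hits passing the
#' coverage / bit-score / e-value filters. Genes flagged as inparalogues for
#' a species pair are excluded as both query and target for that pair; a gene
#' is never its own candidate.
#'
#' @param hits hit table from [all_vs_all_scores()].
#' @param params a [scoring_params()] object.
#' @param exclude optional data.frame (\code{gene_id}, \code{species_pair})
#'   of genes to drop per species pair (the inparalogue calls).
#' @param score_col ranking column, \code{"s_prime"} (default) or
#'   \code{"raw50"} (uncorrected score, for comparison studies).
#' @return data.frame of directed candidate edges: \code{gene},
#'   \code{species}, \code{target_species}, \code{candidate}, score columns,
#'   \code{rank}.
#' @export
build_candidates <- function(hits, params = scoring_params(), exclude = NULL,
                             score_col = "s_prime") {
  h <- passing_hits(hits, params)
  h <- h[h$species_a != h$species_b & h$gene_a != h$gene_b, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    pair_ab <- species_pair_key(h$species_a, h$species_b)
    drop <- paste(h$gene_a, pair_ab) %in% paste(exclude$gene_id, exclude$species_pair) |
            paste(h$gene_b, pair_ab) %in% paste(exclude$gene_id, exclude$species_pair)
    h <- h[!drop, , drop = FALSE]
  }
  if (!nrow(h)) {
    return(data.frame(gene = character(), species = character(),
                      target_species = character(), candidate = character(),
                      s_prime = numeric(), raw50 = numeric(), bit = numeric(),
                      evalue = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  dir1 <- data.frame(gene = h$gene_a, species = h$species_a,
                     target_species = h$species_b, candidate = h$gene_b,
                     s_prime = h$s_prime, raw50 = h$raw50, bit = h$bit,
                     evalue = h$evalue, stringsAsFactors = FALSE)
  dir2 <- data.frame(gene = h$gene_b, species = h$species_b,
                     target_species = h$species_a, candidate = h$gene_a,
                     s_prime = h$s_prime, raw50 = h$raw50, bit = h$bit,
                     evalue = h$evalue, stringsAsFactors = FALSE)
  d <- rbind(dir1, dir2)
  d <- d[order(d$gene, d$target_species, -d[[score_col]], d$candidate), ]
  grp <- paste(d$gene, d$target_species)
  d$rank <- as.integer(ave(seq_len(nrow(d)), grp, FUN = seq_along))
  d <- d[d$rank <= params$top_k, , drop = FALSE]
  rownames(d) <- NULL
  d
}

species_pair_key <- function(sa, sb) {
  paste(pmin(sa, sb), pmax(sa, sb), sep = "|")
}

#' Write a hit table to TSV
#' @param hits hit table from [all_vs_all_scores()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
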