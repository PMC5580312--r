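cand_row <- function(gene, sp, tsp, cand, s) {
  data.frame(gene = gene, species = sp, target_species = tsp,
             candidate = cand, s_prime = s, raw50 = s, bit = 50,
             evalue = 1e-9, rank = 1L, stringsAsFactors = FALSE)
}

test_that("matching prefers total weight over the single best edge", {
  cands <- rbind(cand_row("a1", "A", "B", "b1", 10),
                 cand_row("a1", "A", "B", "b2", 9),
                 cand_row("a2", "A", "B", "b1", 9))
  p <- assign_orthologues(cands)
  expect_equal(nrow(p), 2L)
  expect_setequal(paste(p$gene_a, p$gene_b),
                  c("a1 b2", "a2 b1"))  # total 18 beats 10
})

test_that("a single candidate pair is matched", {
  p <- assign_orthologues(cand_row("a1", "A", "B", "b1", 7))
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene_a, "a1")
  expect_equal(p$gene_b, "b1")
  expect_true(p$ev_similarity)
})

test_that("matching weight equals the brute-force optimum on random instances", {
  set.seed(71)
  for (k in 1:15) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    w <- matrix(ifelse(runif(na * nb) < 0.5, round(runif(na * nb) * 100, 3), 0),
                na, nb)
    el <- which(w > 0, arr.ind = TRUE)
    if (!nrow(el)) next
    cands <- do.call(rbind, lapply(seq_len(nrow(el)), function(r)
      cand_row(paste0("a", el[r, 1]), "A", "B", paste0("b", el[r, 2]),
               w[el[r, 1], el[r, 2]])))
    p <- assign_orthologues(cands)
    expect_equal(sum(p$s_prime), matching_oracle(w), tolerance = 1e-9)
  }
})

# Colinear toy genomes: ten 1:1 gene slots, with slot 4 deliberately
# unmatched so the micro-synteny pass has a gap to fill.
make_colinear <- function() {
  go <- rbind(
    data.frame(species = "A", contig = "cA", ordinal = 0:9,
               gene_id = sprintf("a%d", 1:10), start = 0L, end = 0L,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(species = "B", contig = "cB", ordinal = 0:9,
               gene_id = sprintf("b%d", 1:10), start = 0L, end = 0L,
               strand = "+", stringsAsFactors = FALSE))
  pairs <- data.frame(
    gene_a = sprintf("a%d", c(1:3, 5:10)), gene_b = sprintf("b%d", c(1:3, 5:10)),
    species_a = "A", species_b = "B", s_prime = 400, raw50 = 400,
    positional = FALSE, rescued = FALSE, ev_similarity = TRUE,
    ev_synteny = FALSE, ev_phylogeny = FALSE, stringsAsFactors = FALSE)
  hits <- data.frame(
    gene_a = "a4", gene_b = "b4", species_a = "A", species_b = "B",
    raw62 = 100, raw50 = 300, aln_len = 50L, n_ident = 45L, pct_id = 90,
    cov_a = 0.9, cov_b = 0.9, bit = 50, evalue = 1e-9, s_prime = 300,
    stringsAsFactors = FALSE)
  list(go = go, pairs = pairs, hits = hits)
}

test_that("micro-synteny gap filling adds the anchored pair as positional", {
  fx <- make_colinear()
  empty_ip <- data.frame(gene_id = character(), representative_id = character(),
                         syntenic = logical(), species = character(),
                         species_pair = character(), stringsAsFactors = FALSE)
  rec <- synteny_recalibrate(fx$pairs, fx$hits, fx$go, empty_ip)
  added <- rec$pairs[rec$pairs$gene_a == "a4", ]
  expect_equal(nrow(added), 1L)
  expect_equal(added$gene_b, "b4")
  expect_true(added$positional)
  expect_true(added$ev_synteny)
})

test_that("no fill happens without at least two matched anchors", {
  fx <- make_colinear()
  # strip the matching down to one anchor near the gap
  fx$pairs <- fx$pairs[fx$pairs$gene_a == "a3", ]
  empty_ip <- data.frame(gene_id = character(), representative_id = character(),
                         syntenic = logical(), species = character(),
                         species_pair = character(), stringsAsFactors = FALSE)
  rec <- synteny_recalibrate(fx$pairs, fx$hits, fx$go, empty_ip)
  expect_false("a4" %in% rec$pairs$gene_a)
})

test_that("a flagged inparalogue satisfying the anchor test is rescued", {
  fx <- make_colinear()
  ip <- data.frame(gene_id = "a4", representative_id = "a3", syntenic = TRUE,
                   species = "A", species_pair = "A|B",
                   stringsAsFactors = FALSE)
  rec <- synteny_recalibrate(fx$pairs, fx$hits, fx$go, ip)
  added <- rec$pairs[rec$pairs$gene_a == "a4", ]
  expect_equal(nrow(added), 1L)
  expect_true(added$rescued)
  # the withdrawn call no longer appears in the surviving inparalogue list
  expect_equal(nrow(rec$inparalogues), 0L)
})

test_that("anchored pairs gain synteny evidence and the 1:1 property holds", {
  fx <- make_colinear()
  empty_ip <- data.frame(gene_id = character(), representative_id = character(),
                         syntenic = logical(), species = character(),
                         species_pair = character(), stringsAsFactors = FALSE)
  rec <- synteny_recalibrate(fx$pairs, fx$hits, fx$go, empty_ip)
  # interior colinear pairs see >= 2 matched anchors in their windows
  expect_true(all(rec$pairs$ev_synteny[rec$pairs$gene_a %in%
                                         sprintf("a%d", 3:8)]))
  expect_false(anyDuplicated(rec$pairs$gene_a) > 0)
  expect_false(anyDuplicated(rec$pairs$gene_b) > 0)
})

test_that("the pipeline's matching keeps every gene in at most one pair per species pair", {
  fx <- fixture_small_run()
  p <- fx$run$pairs
  key <- paste(p$species_a, p$species_b)
  for (k in unique(key)) {
    blk <- p[key == k, ]
    expect_false(anyDuplicated(blk$gene_a) > 0, info = k)
    expect_false(anyDuplicated(blk$gene_b) > 0, info = k)
  }
  expect_true(all(p$ev_similarity | p$ev_synteny | p$ev_phylogeny))
})
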