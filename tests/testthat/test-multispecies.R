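mk_pairs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_a = r[[1]], gene_b = r[[2]],
               species_a = r[[3]], species_b = r[[4]],
               s_prime = as.numeric(r[[5]]), raw50 = as.numeric(r[[5]]),
               positional = FALSE, rescued = FALSE, ev_similarity = TRUE,
               ev_synteny = FALSE, ev_phylogeny = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("triangles and chains of pairwise calls cluster together; disjoint families apart", {
  tri <- mk_pairs(list("a", "b", "A", "B", 500), list("b", "c", "B", "C", 500),
                  list("a", "c", "A", "C", 500))
  expect_length(cluster_orthologue_graph(tri)$clusters, 1L)
  two <- rbind(tri, mk_pairs(list("x", "y", "A", "B", 500),
                             list("y", "z", "B", "C", 500),
                             list("x", "z", "A", "C", 500)))
  expect_length(cluster_orthologue_graph(two)$clusters, 2L)
  chain <- mk_pairs(list("a", "b", "A", "B", 500), list("b", "c", "B", "C", 500))
  cl <- cluster_orthologue_graph(chain)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters[[1]], c("a", "b", "c"))
})

test_that("a clean cross-species triangle reconciles into one orthogroup", {
  tri <- mk_pairs(list("a", "b", "A", "B", 500), list("b", "c", "B", "C", 500),
                  list("a", "c", "A", "C", 500))
  cl <- cluster_orthologue_graph(tri)
  og <- reconcile_orthogroups(cl, tri, n_species = 3)
  expect_equal(nrow(og$table), 1L)
  expect_equal(og$table$class, "ONE_TO_ONE_ALL")
  expect_setequal(og$members$gene_id, c("a", "b", "c"))
})

test_that("with two same-species competitors the higher scorer joins first", {
  pairs <- mk_pairs(list("a1", "b", "A", "B", 500), list("a2", "b", "A", "B", 400),
                    list("a1", "c", "A", "C", 480), list("a2", "c", "A", "C", 380),
                    list("b", "c", "B", "C", 500))
  cl <- structure(list(clusters = list(c("a1", "a2", "b", "c"))),
                  class = "cluster_set")
  og <- reconcile_orthogroups(cl, pairs, n_species = 3)
  first <- og$members[og$members$og_id == og$table$og_id[1], ]
  expect_true("a1" %in% first$gene_id)
  expect_false("a2" %in% first$gene_id)
  # the loser remains available for a later extraction round (here: none,
  # as its remaining partners are used)
  expect_false("a2" %in% og$members$gene_id)
})

test_that("orthogroups never contain two genes of one species", {
  fx <- fixture_small_run()
  og <- fx$run$orthogroups
  dup <- tapply(og$members$species, og$members$og_id,
                function(x) anyDuplicated(x) > 0)
  expect_false(any(dup))
  # class definition: all-species orthogroups span every species
  nsp <- tapply(og$members$species, og$members$og_id,
                function(x) length(unique(x)))
  expect_equal(as.vector(nsp[og$table$og_id]) == length(fx$run$gene_sets),
               og$table$class == "ONE_TO_ONE_ALL")
})

test_that("gene classes partition the gene set", {
  fx <- fixture_small_run()
  cls <- fx$run$classes
  all_genes <- unlist(lapply(fx$run$gene_sets, function(g) g$genes$gene_id))
  expect_setequal(cls$gene_id, all_genes)
  expect_false(anyDuplicated(cls$gene_id) > 0)
  expect_true(all(cls$class %in% c("ORTHOLOGUE_ALL", "ORTHOLOGUE_PARTIAL",
                                   "INPARALOGUE", "DE_NOVO")))
  # summary row sums equal per-species gene counts
  s <- class_summary(cls)
  for (gs in fx$run$gene_sets)
    expect_equal(s$total[s$species == gs$species_id], nrow(gs$genes))
})

test_that("super-orthogroup codes and numbering are deterministic", {
  fx <- fixture_small_run()
  sogs <- fx$run$sogs
  # first (largest) group takes the first code; numbering is dense from 0001
  expect_equal(sogs$sog_id[1], "AAAA")
  first <- sogs[sogs$sog_id == "AAAA" & sogs$member_type == "OG", ]
  expect_equal(first$sog_member_id,
               sprintf("AAAA-%04d", seq_len(nrow(first))))
  # every orthogroup appears in exactly one SOG
  og_ids <- fx$run$orthogroups$table$og_id
  expect_setequal(sogs$member_id[sogs$member_type == "OG"], og_ids)
  # DUP/DNV members carry their class codes
  loose <- fx$run$classes[fx$run$classes$class %in% c("INPARALOGUE", "DE_NOVO"), ]
  expect_setequal(sogs$member_id[sogs$member_type %in% c("DUP", "DNV")],
                  loose$gene_id)
})

test_that("an isolated de novo gene forms a singleton SOG", {
  og <- list(members = data.frame(og_id = "OG00001",
                                  gene_id = c("a", "b"),
                                  species = c("A", "B"),
                                  stringsAsFactors = FALSE),
             table = data.frame(og_id = "OG00001", n_species = 2L,
                                class = "ONE_TO_ONE_ALL",
                                stringsAsFactors = FALSE))
  classes <- data.frame(gene_id = c("a", "b", "lonely"),
                        species = c("A", "B", "A"),
                        class = c("ORTHOLOGUE_ALL", "ORTHOLOGUE_ALL", "DE_NOVO"),
                        stringsAsFactors = FALSE)
  hits <- data.frame(gene_a = "a", gene_b = "b", species_a = "A",
                     species_b = "B", raw62 = 100, raw50 = 100, aln_len = 50L,
                     n_ident = 45L, pct_id = 90, cov_a = 0.9, cov_b = 0.9,
                     bit = 50, evalue = 1e-12, s_prime = 300,
                     stringsAsFactors = FALSE)
  sogs <- build_super_orthogroups(og, classes, hits)
  lonely <- sogs[sogs$member_id == "lonely", ]
  expect_equal(nrow(lonely), 1L)
  expect_equal(lonely$member_type, "DNV")
  expect_equal(sum(sogs$sog_id == lonely$sog_id), 1L)
})

test_that("the four-letter code space is dense, ordered and bounded", {
  expect_equal(synorth:::sog_code(0L), "AAAA")
  expect_equal(synorth:::sog_code(1L), "AAAB")
  expect_equal(synorth:::sog_code(26L), "AABA")
  expect_equal(synorth:::sog_code(26L^4 - 1L), "ZZZZ")
  expect_error(synorth:::sog_code(26L^4), "exhausted")
})

test_that("the consensus species tree is deterministic for a fixed seed", {
  fx <- fixture_small_run()
  t1 <- consensus_species_tree(fx$run$clusters, fx$run$gene_sets,
                               sample_n = 10, seed = 3)
  t2 <- consensus_species_tree(fx$run$clusters, fx$run$gene_sets,
                               sample_n = 10, seed = 3)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, vapply(fx$run$gene_sets,
                                       function(g) g$species_id, ""))
})
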