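# Minimal hand-built truth + prediction objects for exercising the scoring
# arithmetic without a simulation.
toy_truth <- function() {
  genes <- data.frame(
    species = rep(c("A", "B"), each = 10),
    gene_id = c(sprintf("a%d", 1:10), sprintf("b%d", 1:10)),
    lineage = c(1:10, 1:10), ancestral_id = sprintf("anc%02d", c(1:10, 1:10)),
    origin = "ancestral", fragmented = FALSE,
    emitted_len = 300L, stringsAsFactors = FALSE)
  pairs <- data.frame(
    species_a = "A", species_b = "B",
    gene_a = sprintf("a%d", 1:10), gene_b = sprintf("b%d", 1:10),
    unit_id = sprintf("A|B:%d", 1:10), stringsAsFactors = FALSE)
  units <- data.frame(species_pair = "A|B", unit_id = sprintf("A|B:%d", 1:10),
                      n_a = 1L, n_b = 1L, ancestral_id = sprintf("anc%02d", 1:10),
                      stringsAsFactors = FALSE)
  structure(list(species_tree = ape::read.tree(text = "(A:1,B:1);"),
                 species = c("A", "B"), pairs = pairs, units = units,
                 inparalogues_pair = data.frame(
                   species = character(), gene_id = character(),
                   set_id = character(), species_pair = character(),
                   stringsAsFactors = FALSE),
                 births = data.frame(species = character(),
                                     gene_id = character(),
                                     stringsAsFactors = FALSE),
                 genes = genes),
            class = "sim_truth")
}

toy_run <- function(pred_idx_a, pred_idx_b) {
  n <- length(pred_idx_a)
  pairs <- data.frame(
    gene_a = sprintf("a%d", pred_idx_a), gene_b = sprintf("b%d", pred_idx_b),
    species_a = rep("A", n), species_b = rep("B", n),
    s_prime = rep(400, n), raw50 = rep(400, n),
    positional = rep(FALSE, n), rescued = rep(FALSE, n),
    ev_similarity = rep(TRUE, n), ev_synteny = rep(FALSE, n),
    ev_phylogeny = rep(FALSE, n), stringsAsFactors = FALSE)
  list(pairs = pairs,
       inparalogues = data.frame(gene_id = character(),
                                 species_pair = character(),
                                 stringsAsFactors = FALSE),
       classes = data.frame(gene_id = character(), species = character(),
                            class = character(), stringsAsFactors = FALSE),
       orthogroups = list(table = data.frame(og_id = character(),
                                             n_species = integer(),
                                             class = character(),
                                             stringsAsFactors = FALSE)),
       species_tree = NULL)
}

test_that("perfect predictions score precision and recall of one", {
  ev <- score_predictions(toy_run(1:10, 1:10), toy_truth())
  expect_equal(ev$summary$pairwise_precision, 1)
  expect_equal(ev$summary$pairwise_recall, 1)
})

test_that("empty predictions give null precision and zero recall", {
  ev <- score_predictions(toy_run(integer(0), integer(0)), toy_truth())
  expect_true(is.na(ev$summary$pairwise_precision))
  expect_equal(ev$summary$pairwise_recall, 0)
})

test_that("partially correct predictions follow the precision/recall arithmetic", {
  # eight predictions, seven correct (a8 paired to the wrong partner)
  ev <- score_predictions(toy_run(1:8, c(1:7, 9)), toy_truth())
  expect_equal(ev$summary$pairwise_precision, 7 / 8)
  expect_equal(ev$summary$pairwise_recall, 7 / 10)
})

test_that("predictions outside the truth universe are fatal", {
  expect_error(score_predictions(toy_run(1, 11), toy_truth()),
               "absent from truth")
})

test_that("co-orthologue classes accept either duplicate copy as correct", {
  tr <- toy_truth()
  # a1 and a99 are co-orthologous copies of the same class
  tr$genes <- rbind(tr$genes,
                    data.frame(species = "A", gene_id = "a99", lineage = 99L,
                               ancestral_id = "anc01", origin = "dup",
                               fragmented = FALSE, emitted_len = 300L,
                               stringsAsFactors = FALSE))
  tr$pairs <- rbind(tr$pairs,
                    data.frame(species_a = "A", species_b = "B",
                               gene_a = "a99", gene_b = "b1",
                               unit_id = "A|B:1", stringsAsFactors = FALSE))
  tr$units$n_a[1] <- 2L
  tr$inparalogues_pair <- data.frame(
    species = "A", gene_id = c("a1", "a99"), set_id = "A|B:1:A",
    species_pair = "A|B", stringsAsFactors = FALSE)
  # the pipeline matched the copy, not the labelled original, and flagged
  # the original as the pair's inparalogue
  run <- toy_run(c(99, 2:10), 1:10)
  run$inparalogues <- data.frame(gene_id = "a1", species_pair = "A|B",
                                 stringsAsFactors = FALSE)
  ev <- score_predictions(run, tr)
  expect_equal(ev$summary$pairwise_precision, 1)
  expect_equal(ev$summary$pairwise_recall, 1)
  # one flag expected for the two-copy set, and it was placed correctly
  expect_equal(ev$summary$inparalogue_precision, 1)
  expect_equal(ev$summary$inparalogue_recall, 1)
})

test_that("evaluation reports are written as TSV with their summary", {
  ev <- score_predictions(toy_run(1:10, 1:10), toy_truth())
  f <- tempfile(fileext = ".tsv")
  write_evaluation(ev, f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".summary.tsv")))
  s <- read.delim(paste0(f, ".summary.tsv"))
  expect_true("pairwise_precision" %in% s$metric)
})
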