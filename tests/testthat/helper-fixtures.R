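# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# Full pipeline run + evaluation on the standard 4-species fixture.
fixture_small_run <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- tempfile("fixture_small_")
    dir.create(dir)
    sim <- simulate_genomes(fixture_config("small"), dir)
    run <- run_pipeline(
      data.frame(name = names(sim$fasta), fasta = unname(sim$fasta),
                 gff3 = unname(sim$gff3), stringsAsFactors = FALSE),
      out_dir = file.path(dir, "out"))
    .fixture_env$small <- list(sim = sim, run = run,
                               report = score_predictions(run, sim$truth))
  }
  .fixture_env$small
}

# Hand-built two-contig mini genome for ingest tests: writes FASTA + GFF3
# and returns their paths together with the raw sequences used.
write_mini_genome <- function(dir = tempfile("mini_")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(99)
  ctg1 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  ctg2 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  fasta <- file.path(dir, "mini.fasta")
  writeLines(c(">ctg1", ctg1, ">ctg2", ctg2), fasta)
  list(dir = dir, fasta = fasta, ctg1 = ctg1, ctg2 = ctg2)
}

write_gff_lines <- function(dir, lines) {
  gff <- file.path(dir, "mini.gff3")
  writeLines(c("##gff-version 3", lines), gff)
  gff
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
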