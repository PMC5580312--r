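test_that("minus-strand multi-exon CDS is spliced 5' to 3' with reverse complement", {
  g <- write_mini_genome()
  # exon1 at 200..298, exon2 at 100..150 (1-based inclusive), minus strand:
  # coding order is exon1 (rightmost) first
  gff <- write_gff_lines(g$dir, c(
    "ctg1\tsrc\tgene\t100\t298\t.\t-\t.\tID=g1",
    "ctg1\tsrc\tmRNA\t100\t298\t.\t-\t.\tID=g1.t1;Parent=g1",
    "ctg1\tsrc\tCDS\t200\t298\t.\t-\t0\tID=c1;Parent=g1.t1",
    "ctg1\tsrc\tCDS\t100\t150\t.\t-\t0\tID=c2;Parent=g1.t1"))
  gs <- suppressWarnings(read_genome_annotation(g$fasta, gff, "mini"))
  expected <- paste0(revcomp_chr(substring(g$ctg1, 200, 298)),
                     revcomp_chr(substring(g$ctg1, 100, 150)))
  expect_equal(unname(gs$cds["g1"]), expected)
  expect_equal(gs$genes$n_segments, 2L)
  expect_false(gs$genes$fragmented)
})

test_that("a gene with CDS rows on two contigs becomes one fragmented model", {
  g <- write_mini_genome()
  gff <- write_gff_lines(g$dir, c(
    "ctg1\tsrc\tgene\t10\t60\t.\t+\t.\tID=gX",
    "ctg1\tsrc\tmRNA\t10\t60\t.\t+\t.\tID=gX.t1;Parent=gX",
    "ctg1\tsrc\tCDS\t10\t60\t.\t+\t0\tID=ca;Parent=gX.t1",
    "ctg2\tsrc\tgene\t20\t70\t.\t+\t.\tID=gX",
    "ctg2\tsrc\tmRNA\t20\t70\t.\t+\t.\tID=gX.t1;Parent=gX",
    "ctg2\tsrc\tCDS\t20\t70\t.\t+\t0\tID=cb;Parent=gX.t1"))
  gs <- suppressWarnings(read_genome_annotation(g$fasta, gff, "mini"))
  expect_equal(nrow(gs$genes), 1L)
  expect_true(gs$genes$fragmented)
  expect_setequal(gs$segments$contig, c("ctg1", "ctg2"))
  expect_equal(unname(gs$cds["gX"]),
               paste0(substring(g$ctg1, 10, 60), substring(g$ctg2, 20, 70)))
})

test_that("annotations without genes and orphan CDS records are handled with warnings", {
  g <- write_mini_genome()
  gff <- write_gff_lines(g$dir, "ctg1\tsrc\tregion\t1\t400\t.\t+\t.\tID=r1")
  expect_warning(gs <- read_genome_annotation(g$fasta, gff, "mini"),
                 "no gene features")
  expect_equal(nrow(gs$genes), 0L)

  gff2 <- write_gff_lines(g$dir, c(
    "ctg1\tsrc\tgene\t10\t39\t.\t+\t.\tID=g1",
    "ctg1\tsrc\tmRNA\t10\t39\t.\t+\t.\tID=g1.t1;Parent=g1",
    "ctg1\tsrc\tCDS\t10\t39\t.\t+\t0\tID=ca;Parent=g1.t1",
    "ctg1\tsrc\tCDS\t50\t70\t.\t+\t0\tID=cb;Parent=nosuch"))
  expect_warning(gs2 <- read_genome_annotation(g$fasta, gff2, "mini"),
                 "without a parent")
  expect_equal(nrow(gs2$genes), 1L)
})

test_that("a CDS on a contig missing from the FASTA is fatal", {
  g <- write_mini_genome()
  gff <- write_gff_lines(g$dir, c(
    "ctg9\tsrc\tgene\t10\t39\t.\t+\t.\tID=g1",
    "ctg9\tsrc\tmRNA\t10\t39\t.\t+\t.\tID=g1.t1;Parent=g1",
    "ctg9\tsrc\tCDS\t10\t39\t.\t+\t0\tID=ca;Parent=g1.t1"))
  expect_error(read_genome_annotation(g$fasta, gff, "mini"), "absent from the FASTA")
})

test_that("the longest isoform is retained, with ID tie-break, and the count recorded", {
  g <- write_mini_genome()
  gff <- write_gff_lines(g$dir, c(
    "ctg1\tsrc\tgene\t10\t160\t.\t+\t.\tID=g1",
    "ctg1\tsrc\tmRNA\t10\t160\t.\t+\t.\tID=g1.t2;Parent=g1",
    "ctg1\tsrc\tCDS\t10\t159\t.\t+\t0\tID=ca;Parent=g1.t2",   # 150 nt
    "ctg1\tsrc\tmRNA\t10\t120\t.\t+\t.\tID=g1.t1;Parent=g1",
    "ctg1\tsrc\tCDS\t10\t99\t.\t+\t0\tID=cb;Parent=g1.t1",    # 90 nt
    "ctg1\tsrc\tgene\t200\t300\t.\t+\t.\tID=g2",
    "ctg1\tsrc\tmRNA\t200\t300\t.\t+\t.\tID=g2.tB;Parent=g2",
    "ctg1\tsrc\tCDS\t200\t259\t.\t+\t0\tID=cc;Parent=g2.tB",  # 60 nt
    "ctg1\tsrc\tmRNA\t200\t300\t.\t+\t.\tID=g2.tA;Parent=g2",
    "ctg1\tsrc\tCDS\t220\t279\t.\t+\t0\tID=cd;Parent=g2.tA")) # 60 nt, tie
  gs <- suppressWarnings(read_genome_annotation(g$fasta, gff, "mini"))
  expect_equal(gs$genes$transcript_id[gs$genes$gene_id == "g1"], "g1.t2")
  expect_equal(gs$genes$isoform_count[gs$genes$gene_id == "g1"], 2L)
  # tie broken by lexicographically smallest transcript id
  expect_equal(gs$genes$transcript_id[gs$genes$gene_id == "g2"], "g2.tA")
})

test_that("translation follows the standard code with draft-genome tolerance", {
  expect_equal(translate_cds("ATGGCTTAA")$protein, "MA")
  expect_equal(translate_cds("ATGNNTGGA")$protein, "MXG")
  expect_warning(tr <- translate_cds("ATGTGATGG"), "internal stop")
  expect_equal(tr$protein, "M*W")
  # trailing partial codon dropped and flagged
  tr2 <- translate_cds("ATGGCTTC")
  expect_equal(tr2$protein, "MA")
  expect_true(tr2$partial)
  expect_false(translate_cds("ATGGCTTAA")$partial)
})

test_that("gene order sorts by start within contigs, restarting ordinals per contig", {
  g <- write_mini_genome()
  gff <- write_gff_lines(g$dir, c(
    "ctg1\tsrc\tgene\t101\t130\t.\t+\t.\tID=gA",
    "ctg1\tsrc\tmRNA\t101\t130\t.\t+\t.\tID=gA.t;Parent=gA",
    "ctg1\tsrc\tCDS\t101\t130\t.\t+\t0\tID=c1;Parent=gA.t",
    "ctg1\tsrc\tgene\t301\t330\t.\t+\t.\tID=gB",
    "ctg1\tsrc\tmRNA\t301\t330\t.\t+\t.\tID=gB.t;Parent=gB",
    "ctg1\tsrc\tCDS\t301\t330\t.\t+\t0\tID=c2;Parent=gB.t",
    "ctg1\tsrc\tgene\t201\t230\t.\t+\t.\tID=gC",
    "ctg1\tsrc\tmRNA\t201\t230\t.\t+\t.\tID=gC.t;Parent=gC",
    "ctg1\tsrc\tCDS\t201\t230\t.\t+\t0\tID=c3;Parent=gC.t",
    "ctg2\tsrc\tgene\t11\t40\t.\t+\t.\tID=gD",
    "ctg2\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=gD.t;Parent=gD",
    "ctg2\tsrc\tCDS\t11\t40\t.\t+\t0\tID=c4;Parent=gD.t"))
  gs <- suppressWarnings(read_genome_annotation(g$fasta, gff, "mini"))
  go <- build_gene_order(gs)
  expect_equal(go$ordinal[match(c("gA", "gC", "gB"), go$gene_id)], c(0L, 1L, 2L))
  expect_equal(go$ordinal[go$gene_id == "gD"], 0L)  # new contig restarts at 0
})

test_that("simulated annotations re-ingest losslessly (round trip)", {
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_genomes(sim_config(n_species = 2, n_ancestral_genes = 20,
                                     fragmentation_prob = 0.3, seed = 5), dir)
  for (sp in names(sim$fasta)) {
    gs <- read_genome_annotation(sim$fasta[sp], sim$gff3[sp], sp)
    tg <- sim$truth$genes[sim$truth$genes$species == sp, ]
    expect_setequal(gs$genes$gene_id, tg$gene_id)
    expect_equal(unname(nchar(gs$cds)[tg$gene_id]), tg$emitted_len)
    # no internal stops in emitted proteins
    expect_false(any(grepl("[*]", gs$protein)))
    # fragmented models merged back into one gene
    expect_equal(sort(gs$genes$gene_id[gs$genes$fragmented]),
                 sort(tg$gene_id[tg$fragmented]))
  }
})
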