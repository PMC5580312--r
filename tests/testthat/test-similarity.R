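test_that("Smith-Waterman handles identity, hopeless pairs and known alignments", {
  r <- sw_align("AAAA", "AAAA")
  m_AA <- synorth:::blosum_matrix("BLOSUM50")["A", "A"]
  expect_equal(r$score, 4 * m_AA)
  expect_equal(r$aln_len, 4L)
  expect_equal(r$n_ident, 4L)
  expect_equal(r$cov_a, 1)

  # all cross-scores negative: empty local alignment, score 0
  r0 <- sw_align("WWWW", "PPPP")
  expect_equal(r0$score, 0)
  expect_equal(r0$aln_len, 0L)
})

test_that("Smith-Waterman scores match the exhaustive-chain oracle on random peptides", {
  set.seed(31)
  for (k in 1:60) {
    a <- random_protein(sample(2:8, 1))
    b <- random_protein(sample(2:8, 1))
    expect_equal(sw_align(a, b)$score, sw_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("alignments are symmetric in their arguments", {
  set.seed(32)
  for (k in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    r1 <- sw_align(a, b); r2 <- sw_align(b, a)
    expect_equal(r1$score, r2$score)
    expect_equal(r1$aln_len, r2$aln_len)
    expect_equal(r1$n_ident, r2$n_ident)
  }
})

test_that("residues outside the substitution alphabet are treated as X with warning", {
  expect_warning(r <- sw_align("MAUA", "MAXA"), "treated as 'X'")
  expect_gt(r$score, 0)
})

test_that("bit scores and e-values follow the Karlin-Altschul closed form", {
  be <- bit_evalue(100, len_a = 300, db_residues = 1e5)
  expect_equal(be$bit, (0.267 * 100 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(round(be$bit, 2), 43.13)
  # one extra bit halves E at fixed lengths
  be2 <- bit_evalue(100 + log(2) / 0.267, 300, 1e5)
  expect_equal(be2$evalue, be$evalue / 2, tolerance = 1e-9)
  # zero score: bit far below the reporting threshold, enormous E --
  # always filtered (bit = -ln(K)/ln 2 is slightly positive for K < 1)
  be0 <- bit_evalue(0, 300, 1e5)
  expect_lt(be0$bit, 30)
  expect_gt(be0$evalue, 1e6)
})

test_that("the corrected score is per-column score times percent identity", {
  m_AA <- synorth:::blosum_matrix("BLOSUM50")["A", "A"]
  expect_equal(s_prime_score(4 * m_AA, 4, 4), m_AA * 100)
  expect_equal(s_prime_score(17, 10, 0), 0)       # no identities -> 0
  expect_equal(s_prime_score(50, 10, 5), 5 * 50)  # (50/10) * (100*5/10)
})

test_that("a half-length fragment keeps the corrected score of the full gene", {
  set.seed(33)
  for (k in 1:20) {
    full <- random_protein(120)
    orth <- full  # identical overlap
    half <- substring(full, 1, 60)
    s_full <- with(sw_align(full, orth), s_prime_score(score, aln_len, n_ident))
    s_half <- with(sw_align(half, orth), s_prime_score(score, aln_len, n_ident))
    expect_gte(s_half, 0.9 * s_full)
  }
})

test_that("candidate sets enforce the three filters and the top-5 rule", {
  p <- scoring_params()
  row <- function(a, b, sa, sb, bit, ev, cov, sp) {
    data.frame(gene_a = a, gene_b = b, species_a = sa, species_b = sb,
               raw62 = 100, raw50 = 100, aln_len = 50L, n_ident = 40L,
               pct_id = 80, cov_a = cov, cov_b = cov, bit = bit, evalue = ev,
               s_prime = sp, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    row("a1", "b1", "A", "B", 29, 1e-9, 0.9, 500),   # bit below threshold
    row("a1", "b2", "A", "B", 50, 1e-9, 0.4, 500),   # coverage too low
    row("a1", "b3", "A", "B", 50, 1e-5, 0.9, 500),   # e-value too large
    row("a1", "b4", "A", "B", 50, 1e-9, 0.9, 400))
  cand <- build_candidates(hits, p)
  expect_equal(cand$candidate[cand$gene == "a1"], "b4")
  # seven passing hits -> the five with highest corrected score retained
  hits7 <- do.call(rbind, lapply(1:7, function(i)
    row("a1", paste0("b", i), "A", "B", 50, 1e-9, 0.9, 100 * i)))
  cand7 <- build_candidates(hits7, p)
  expect_equal(nrow(cand7[cand7$gene == "a1", ]), 5L)
  expect_setequal(cand7$candidate[cand7$gene == "a1"],
                  paste0("b", 3:7))
  # no passing hits -> empty candidate set
  expect_equal(nrow(build_candidates(hits[1:3, ], p)), 0L)
})

test_that("flagged inparalogues are excluded from both sides of a pair's candidates", {
  p <- scoring_params()
  hits <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b1"),
                     species_a = "A", species_b = "B",
                     raw62 = 100, raw50 = 100, aln_len = 50L, n_ident = 40L,
                     pct_id = 80, cov_a = 0.9, cov_b = 0.9, bit = 50,
                     evalue = 1e-9, s_prime = c(500, 400),
                     stringsAsFactors = FALSE)
  excl <- data.frame(gene_id = "a2", species_pair = "A|B",
                     stringsAsFactors = FALSE)
  cand <- build_candidates(hits, p, exclude = excl)
  expect_false("a2" %in% cand$gene)
  expect_false("a2" %in% cand$candidate)
  expect_true("a1" %in% cand$gene)
})

test_that("all-vs-all hit tables are complete and self-consistent on a small set", {
  set.seed(34)
  mk <- function(sp, prots) {
    gs <- list(species_id = sp,
               genes = data.frame(gene_id = names(prots),
                                  fragmented = FALSE, partial = FALSE,
                                  stringsAsFactors = FALSE),
               cds = setNames(vapply(prots, cds_for_protein, ""), names(prots)),
               protein = prots)
    class(gs) <- "gene_set"
    gs
  }
  base <- random_protein(80)
  mut <- function(x, n) {
    ch <- strsplit(x, "")[[1]]
    i <- sample(length(ch), n)
    ch[i] <- sample(AA20, n, replace = TRUE)
    paste(ch, collapse = "")
  }
  ga <- mk("A", c(a1 = base, a2 = random_protein(90)))
  gb <- mk("B", c(b1 = mut(base, 4), b2 = random_protein(70)))
  hits <- all_vs_all_scores(list(ga, gb))
  # the planted homologue pair is found with high identity
  h <- hits[(hits$gene_a == "a1" & hits$gene_b == "b1") |
            (hits$gene_a == "b1" & hits$gene_b == "a1"), ]
  expect_equal(nrow(h), 1L)
  expect_gt(h$pct_id, 80)
  expect_gt(h$bit, 30)
  # corrected score column agrees with its definition
  expect_equal(hits$s_prime,
               (hits$raw50 / hits$aln_len) * (100 * hits$n_ident / hits$aln_len))
})
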