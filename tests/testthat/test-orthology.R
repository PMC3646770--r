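# Ortholog identification: best hits, reciprocity, the two
# paralog-exclusion filters and the funnel report.

mk_hits <- function(q, s, bitscore, evalue = 1e-20) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
             mismatch = 10, gapopen = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

mk_annot <- function(id, prot, name) {
  data.frame(transcript_id = id, protein_accession = prot, gene_name = name,
             go_terms = "", stringsAsFactors = FALSE)
}

test_that("best_hits picks the maximal bitscore and applies the E-value cutoff", {
  hits <- rbind(mk_hits("q1", "s1", 200), mk_hits("q1", "s2", 150),
                mk_hits("q2", "s3", 90, evalue = 1e-3))
  bh <- best_hits(hits)
  expect_equal(unname(bh["q1"]), "s1")
  expect_false("q2" %in% names(bh))   # only hit above the cutoff
  expect_equal(length(best_hits(hits[0, ])), 0)
})

test_that("best_hits tie-break is lower evalue then lexicographic subject", {
  hits <- rbind(mk_hits("q1", "sB", 100, 1e-30), mk_hits("q1", "sA", 100, 1e-20))
  expect_equal(unname(best_hits(hits)["q1"]), "sB")
  hits2 <- rbind(mk_hits("q1", "sB", 100, 1e-30), mk_hits("q1", "sA", 100, 1e-30))
  expect_equal(unname(best_hits(hits2)["q1"]), "sA")
})

test_that("best_hits equals a brute-force scan on a random table", {
  set.seed(1234)
  n <- 400
  hits <- mk_hits(sprintf("q%02d", sample(50, n, TRUE)),
                  sprintf("s%02d", sample(60, n, TRUE)),
                  bitscore = sample(50:500, n, TRUE),
                  evalue = 10^-sample(3:40, n, TRUE))
  expect_equal(best_hits(hits), oracle_best_hits(hits))
})

test_that("reciprocal_best_hits keeps mutual pairs only", {
  ab <- rbind(mk_hits("a1", "b1", 200), mk_hits("a2", "b2", 150))
  ba <- rbind(mk_hits("b1", "a1", 190), mk_hits("b2", "a1", 160))
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(pairs$idA, "a1")   # a2/b2 asymmetric: b2's best is a1
  expect_equal(pairs$idB, "b1")
})

test_that("reciprocal_best_hits is symmetric under swapping the species", {
  set.seed(99)
  n <- 150
  ab <- mk_hits(sprintf("a%02d", sample(25, n, TRUE)),
                sprintf("b%02d", sample(25, n, TRUE)),
                bitscore = sample(50:400, n, TRUE))
  ba <- mk_hits(sprintf("b%02d", sample(25, n, TRUE)),
                sprintf("a%02d", sample(25, n, TRUE)),
                bitscore = sample(50:400, n, TRUE))
  p1 <- reciprocal_best_hits(ab, ba)
  p2 <- reciprocal_best_hits(ba, ab)
  expect_equal(p1[order(p1$idA), c("idA", "idB")],
               setNames(p2[order(p2$idB), c("idB", "idA")], c("idA", "idB")),
               ignore_attr = TRUE)
})

test_that("same-protein filter requires identical accessions and annotation", {
  pairs <- data.frame(idA = c("a1", "a2", "a3"), idB = c("b1", "b2", "b3"),
                      stage = "bbh", stringsAsFactors = FALSE)
  annot_a <- mk_annot(c("a1", "a2"), c("P12345", "P12345"), c("g1", "g2"))
  annot_b <- mk_annot(c("b1", "b2"), c("P12345", "P99999"), c("g1", "g2"))
  out <- filter_same_protein(pairs, annot_a, annot_b)
  expect_equal(out$idA, "a1")            # a2: different protein; a3: unannotated
  expect_equal(out$best_protein, "P12345")
})

test_that("unique-name filter counts over the full annotation tables", {
  pairs <- data.frame(idA = c("a1", "a2"), idB = c("b1", "b2"),
                      stage = "same_protein", best_protein = "P1",
                      stringsAsFactors = FALSE)
  annot_a <- mk_annot(c("a1", "a2", "a9"), c("P1", "P2", "P9"),
                      c("myh7", "dup", "DUP"))   # a9 unpaired but counted
  annot_b <- mk_annot(c("b1", "b2"), c("P1", "P2"), c("MYH7", "dup"))
  out <- filter_unique_gene_name(pairs, annot_a, annot_b)
  expect_equal(out$idA, "a1")   # "dup" appears twice in A (case-insensitive)
})

test_that("funnel report is monotone and exact with planted decoys", {
  sim <- simulate_ortholog_pairs(15, t = 0.3, n_codons = 80, seed = 41)
  tabs <- simulate_hit_tables(sim$truth, sim$fastaA, sim$fastaB,
                              n_decoys = c(nonreciprocal = 1, protein = 4,
                                           name = 3), seed = 41)
  orth <- ortholog_funnel(tabs$hits_ab, tabs$hits_ba, tabs$prot_a,
                          tabs$prot_b, tabs$annot_a, tabs$annot_b)
  expect_equal(orth$funnel$n_pairs, c(15 + 4 + 3, 15 + 3, 15))
  expect_true(all(diff(orth$funnel$n_pairs) <= 0))
})

test_that("empty inputs give an all-zero funnel, not an error", {
  empty <- mk_hits("x", "y", 1)[0, ]
  orth <- ortholog_funnel(empty, empty, empty, empty,
                          mk_annot("x", "P", "g")[0, ],
                          mk_annot("x", "P", "g")[0, ])
  expect_equal(orth$funnel$n_pairs, c(0L, 0L, 0L))
})

test_that("malformed hit tables are rejected with the offending line", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.tsv")
  writeLines(c(paste(c("q1", "s1", "90", "100", "10", "0", "1", "100",
                       "1", "100", "1e-20", "200"), collapse = "\t"),
               "q2\ts2\tbroken"), f)
  expect_error(read_hit_table(f), "line 2")
})

test_that("hit tables round-trip through write and read", {
  hits <- rbind(mk_hits("q1", "s1", 200), mk_hits("q2", "s2", 99, 2.5e-8))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "h.tsv")
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_equal(back, hits)
})
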