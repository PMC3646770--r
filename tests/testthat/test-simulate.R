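# The synthetic-data generator: codon-model ortholog pairs, hit tables,
# pileups, SSR planting and GO fixtures, each against its ground truth.

test_that("zero divergence leaves both descendants identical to each other", {
  sim <- simulate_ortholog_pairs(3, omega = 0.5, kappa = 2, t = 0,
                                 n_codons = 50, seed = 11)
  expect_equal(as.character(sim$fastaA), as.character(sim$fastaB),
               ignore_attr = TRUE)
  aln <- codon_alignment(as.character(sim$fastaA[[1]]),
                         as.character(sim$fastaB[[1]]))
  r <- ng86(aln)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
})

test_that("simulated sequences are stop-free and in frame", {
  sim <- simulate_ortholog_pairs(5, omega = 1, kappa = 2, t = 0.8,
                                 n_codons = 200, seed = 3)
  for (s in c(as.character(sim$fastaA), as.character(sim$fastaB))) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- split3(s)
    expect_false(any(oracle_translate(codons) == "*"))
  }
})

test_that("fixed seed gives byte-identical FASTA output", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a1.fa"); f2 <- file.path(dir, "a2.fa")
  s1 <- simulate_ortholog_pairs(4, omega = 0.5, t = 0.4, n_codons = 100,
                                seed = 42)
  s2 <- simulate_ortholog_pairs(4, omega = 0.5, t = 0.4, n_codons = 100,
                                seed = 42)
  write_fasta(s1$fastaA, f1); write_fasta(s2$fastaA, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- simulate_ortholog_pairs(4, omega = 0.5, t = 0.4, n_codons = 100,
                                seed = 43)
  expect_false(identical(as.character(s1$fastaA), as.character(s3$fastaA)))
})

test_that("generator rejects degenerate parameters", {
  expect_error(simulate_ortholog_pairs(2, omega = 0), "omega")
  expect_error(simulate_ortholog_pairs(2, kappa = -1), "kappa")
  expect_error(simulate_ortholog_pairs(2, t = -0.1), "t must")
  expect_error(simulate_ortholog_pairs(2, n_codons = 5), "n_codons")
})

test_that("neutral simulation matches the enumerated nonsynonymous fraction", {
  # omega = 1, kappa = 1, uniform codon frequencies: among single-nucleotide
  # differences the proportion of nonsynonymous ones should match the
  # neutral fraction from exhaustive enumeration of the 61 x 9 change matrix
  sim <- simulate_ortholog_pairs(1, omega = 1, kappa = 1, t = 0.1,
                                 n_codons = 10000, seed = 202)
  ca <- split3(as.character(sim$fastaA[[1]]))
  cb <- split3(as.character(sim$fastaB[[1]]))
  one_diff <- mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), ca, cb) == 1
  syn <- oracle_translate(ca[one_diff]) == oracle_translate(cb[one_diff])
  frac_non <- mean(!syn)
  expected <- oracle_neutral_nonsyn_fraction()
  # ~1000 substitutions: allow 4 binomial standard deviations
  tol <- 4 * sqrt(expected * (1 - expected) / sum(one_diff))
  expect_lt(abs(frac_non - expected), tol)
})

test_that("substitution counts scale linearly in t for small t", {
  # pooled over 10 replicate pairs of 10,000 codons so the per-t rate has
  # ~2-3% sampling noise, well inside the 10% linearity band
  n <- 10000
  rate <- vapply(c(0.01, 0.05), function(t) {
    sim <- simulate_ortholog_pairs(10, omega = 1, kappa = 2, t = t,
                                   n_codons = n, seed = 77)
    d <- sum(vapply(1:10, function(i) {
      a <- strsplit(as.character(sim$fastaA[[i]]), "")[[1]]
      b <- strsplit(as.character(sim$fastaB[[i]]), "")[[1]]
      sum(a != b)
    }, numeric(1)))
    d / (10 * n) / t
  }, numeric(1))
  expect_lt(abs(rate[2] / rate[1] - 1), 0.1)
})

test_that("hit tables with no decoys recover exactly the truth by BBH", {
  sim <- simulate_ortholog_pairs(20, t = 0.3, n_codons = 100, seed = 5)
  tabs <- simulate_hit_tables(sim$truth, sim$fastaA, sim$fastaB,
                              n_decoys = 0, seed = 5)
  bbh <- reciprocal_best_hits(tabs$hits_ab, tabs$hits_ba)
  expect_equal(bbh$idA, sim$truth$ortholog_map$idA)
  expect_equal(bbh$idB, sim$truth$ortholog_map$idB)
})

test_that("true-pair evalues clear the 1e-6 threshold", {
  sim <- simulate_ortholog_pairs(10, t = 0.3, n_codons = 100, seed = 6)
  tabs <- simulate_hit_tables(sim$truth, sim$fastaA, sim$fastaB,
                              n_decoys = 3, seed = 6)
  truth_rows <- tabs$hits_ab$qseqid %in% sim$truth$ortholog_map$idA &
    tabs$hits_ab$sseqid == sim$truth$ortholog_map$idB[
      match(tabs$hits_ab$qseqid, sim$truth$ortholog_map$idA)]
  expect_true(all(tabs$hits_ab$evalue[truth_rows] < 1e-6))
})

test_that("each decoy type violates exactly its filter", {
  sim <- simulate_ortholog_pairs(10, t = 0.3, n_codons = 100, seed = 9)
  tabs <- simulate_hit_tables(sim$truth, sim$fastaA, sim$fastaB,
                              n_decoys = c(nonreciprocal = 2, protein = 3,
                                           name = 2), seed = 9)
  orth <- ortholog_funnel(tabs$hits_ab, tabs$hits_ba, tabs$prot_a,
                          tabs$prot_b, tabs$annot_a, tabs$annot_b)
  counts <- setNames(orth$funnel$n_pairs, orth$funnel$stage)
  expect_equal(unname(counts["bbh"]), 10 + 3 + 2)          # protein + name pass BBH
  expect_equal(unname(counts["same_protein"]), 10 + 2)     # name decoys remain
  expect_equal(unname(counts["unique_name"]), 10)
  expect_setequal(orth$pairs$idA, sim$truth$ortholog_map$idA)
})

test_that("error-free pileup without variants is monoallelic", {
  sp <- simulate_pileup(100, snps = NULL, depth = 30, error_rate = 0,
                        seed = 4)
  cnt <- as.matrix(sp$pileup[, 3:8])
  expect_true(all(rowSums(cnt > 0) == 1))
  expect_true(all(rowSums(cnt) == 30))
})

test_that("planted SNP allele counts follow the requested fraction", {
  snps <- data.frame(pos = c(10, 50), ref = c("A", "C"), alt = c("G", "T"),
                     alt_fraction = c(0.5, 0.5))
  sp <- simulate_pileup(100, snps, depth = 400, error_rate = 0, seed = 12)
  row <- sp$pileup[sp$pileup$pos == 10, ]
  expect_equal(row$countA + row$countG, 400)
  expect_lt(abs(row$countG - 200), 4 * sqrt(400 * 0.25))
  expect_identical(sp$pileup,
                   simulate_pileup(100, snps, depth = 400, error_rate = 0,
                                   seed = 12)$pileup)
})

test_that("pileup rejects bad variant specifications", {
  expect_error(simulate_pileup(100, data.frame(pos = c(5, 5),
    ref = "A", alt = "G", alt_fraction = 0.5), seed = 1), "collision")
  expect_error(simulate_pileup(100, data.frame(pos = 5,
    ref = "A", alt = "G", alt_fraction = 1.5), seed = 1), "alt_fraction")
})

test_that("planted SSR tracts carry correct spans and qualification", {
  res <- plant_ssrs(2, 400, data.frame(motif = c("ATC", "AT"),
                                       n_repeats = c(5, 7)), seed = 21)
  tr <- res$truth
  atc <- tr[tr$motif == "ATC", ]
  expect_equal(atc$total_len, 15)
  expect_true(atc$qualifies)
  at <- tr[tr$motif == "AT", ]
  expect_equal(at$total_len, 14)
  expect_false(at$qualifies)  # 2 x 7 = 14 < 15: negative control
  for (i in seq_len(nrow(tr))) {
    s <- as.character(res$fasta[[tr$seq_id[i]]])
    span <- substr(s, tr$start[i] + 1, tr$end[i])
    expect_equal(span, strrep(tr$motif[i], tr$n_repeats[i]))
  }
})

test_that("clean background yields no detector hits when nothing is planted", {
  res <- plant_ssrs(3, 500, data.frame(motif = character(0),
                                       n_repeats = integer(0)), seed = 31)
  expect_equal(nrow(scan_ssrs(res$fasta)), 0)
})

test_that("GO fixture plants one enriched term and is reproducible", {
  fix <- simulate_go_annotations(100, 8, study_fraction_with_term = 0.9,
                                 background_fraction = 0.1, seed = 17)
  graph <- load_obo(fix$obo)
  enr <- hypergeometric_enrichment(fix$study, fix$annotations$gene,
                                   fix$annotations, graph)
  enr <- enr[enr$term_id != fix$truth$root, ]
  expect_equal(enr$term_id[1], fix$truth$enriched_term)
  fix2 <- simulate_go_annotations(100, 8, study_fraction_with_term = 0.9,
                                  background_fraction = 0.1, seed = 17)
  expect_identical(fix$annotations, fix2$annotations)
})

test_that("fully annotated study set against rare background is highly significant", {
  fix <- simulate_go_annotations(100, 5, study_fraction_with_term = 1,
                                 background_fraction = 0.02, seed = 23,
                                 study_size = 15)
  graph <- load_obo(fix$obo)
  enr <- hypergeometric_enrichment(fix$study, fix$annotations$gene,
                                   fix$annotations, graph)
  p <- enr$p_value[enr$term_id == fix$truth$enriched_term]
  expect_lt(p, 1e-3)
})
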