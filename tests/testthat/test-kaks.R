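# Ka/Ks machinery: CDS extraction, stop screening, codon alignment, the
# NG86 and YN00 estimators, the Fisher significance test and selection
# classification.

test_that("extract_cds slices, handles strand and trims to frame", {
  tx <- "ATGAAATGACCC"
  hit <- data.frame(qstart = 1, qend = 9)
  expect_equal(extract_cds(tx, hit), "ATGAAATGA")
  # reverse strand: qstart > qend
  hit_rev <- data.frame(qstart = 9, qend = 1)
  expect_equal(extract_cds(tx, hit_rev),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGAAATGA"))))
  # length-10 slice trimmed to 9
  hit10 <- data.frame(qstart = 1, qend = 10)
  expect_equal(nchar(extract_cds(tx, hit10)), 9)
  expect_error(extract_cds(tx, data.frame(qstart = 1, qend = 99)), "beyond")
})

test_that("stop screening fails internal stops and strips terminal ones", {
  expect_false(screen_stops("ATGTAAAAA")$pass)
  scr <- screen_stops("ATGAAATAA")
  expect_true(scr$pass)
  expect_equal(scr$cds, "ATGAAA")
  sim <- simulate_ortholog_pairs(1, t = 0.5, n_codons = 100, seed = 8)
  expect_true(screen_stops(as.character(sim$fastaA[[1]]))$pass)
})

test_that("codon alignment threads codons through the protein alignment", {
  cds <- "ATGGCTGAACGTATC"
  aln <- align_codons(cds, cds)
  expect_equal(aln$n_codons, 5)
  expect_equal(aln$codonsA, aln$codonsB)
  # delete the middle codon of B: one gap column discarded, rest identical
  cds_del <- "ATGGCTCGTATC"
  aln2 <- align_codons(cds, cds_del)
  expect_equal(aln2$n_codons, 4)
  expect_equal(aln2$codonsA, aln2$codonsB)
  expect_equal(aln2$n_gap_cols, 1)
})

test_that("simulated indel-free pairs align exactly as naive column pairing", {
  sim <- simulate_ortholog_pairs(3, t = 0.5, n_codons = 120, seed = 19)
  for (i in 1:3) {
    a <- as.character(sim$fastaA[[i]]); b <- as.character(sim$fastaB[[i]])
    guided <- align_codons(a, b)
    naive <- codon_alignment(a, b)
    expect_equal(guided$codonsA, naive$codonsA)
    expect_equal(guided$codonsB, naive$codonsB)
  }
})

test_that("NG86 reproduces the hand-worked three-codon example", {
  r <- ng86(codon_alignment("TTTGGGAAA", "TTCGGGAAA"))
  expect_equal(r$S, 5 / 3, tolerance = 1e-12)
  expect_equal(r$N, 22 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
})

test_that("NG86 per-codon sites and pairwise differences match the oracle", {
  # sites for every sense codon; differences on a random sample of pairs
  # (the full 61 x 61 grid is exercised in the acceptance suite)
  env <- asNamespace("compara")
  s <- env$ng86_syn_sites()
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  expect_equal(s, vapply(sense, oracle_syn_sites, numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-12)
  m <- env$ng86_diff_matrices()
  set.seed(7)
  for (k in 1:60) {
    ij <- sample(61, 2)
    o <- oracle_ng86_diffs(sense[ij[1]], sense[ij[2]])
    expect_equal(m$Sd[ij[1], ij[2]], unname(o["Sd"]), tolerance = 1e-12)
    expect_equal(m$Nd[ij[1], ij[2]], unname(o["Nd"]), tolerance = 1e-12)
  }
})

test_that("site counts conserve S + N = 3L and results are swap-symmetric", {
  sim <- simulate_ortholog_pairs(4, omega = c(0.2, 0.5, 1, 2), t = 0.4,
                                 n_codons = 300, seed = 55)
  for (i in 1:4) {
    a <- as.character(sim$fastaA[[i]]); b <- as.character(sim$fastaB[[i]])
    for (fn in list(ng86, yn00)) {
      r <- fn(codon_alignment(a, b))
      expect_lt(abs(r$S + r$N - nchar(a)), 1e-6)
      r_swap <- fn(codon_alignment(b, a))
      expect_lt(abs(r$Ka - r_swap$Ka), 1e-9)
      expect_lt(abs(r$Ks - r_swap$Ks), 1e-9)
      expect_lt(abs(r$omega - r_swap$omega), 1e-9)
    }
  }
})

test_that("identical sequences give zero distances for both methods", {
  cds <- "ATGGCTGAACGTATCAAGCTGTGGCCA"
  for (fn in list(ng86, yn00)) {
    r <- suppressWarnings(fn(codon_alignment(cds, cds)))
    expect_equal(r$Sd, 0)
    expect_equal(r$Nd, 0)
    expect_equal(r$Ka, 0)
    expect_equal(r$Ks, 0)
    expect_true(is.na(r$omega))
  }
})

test_that("YN00 agrees with NG86 in the no-bias limit", {
  # kappa = 1 and uniform codon frequencies: the YN00 weighting reduces
  # towards NG86.  A small systematic offset (~5%) remains because the two
  # methods count sites at codons adjacent to stops differently (NG86
  # treats mutations into stops as nonsynonymous; YN00's mutation-weighted
  # counting excludes them), so the band is 8%.
  sim <- simulate_ortholog_pairs(8, omega = 0.5, kappa = 1, t = 0.3,
                                 n_codons = 2000, seed = 66)
  ratio <- vapply(1:8, function(i) {
    aln <- codon_alignment(as.character(sim$fastaA[[i]]),
                           as.character(sim$fastaB[[i]]))
    yn00(aln)$omega / ng86(aln)$omega
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.08)
})

test_that("YN00 recovers omega and kappa on matched simulations", {
  n_rep <- 12
  sim <- simulate_ortholog_pairs(n_rep, omega = 0.5, kappa = 2, t = 0.4,
                                 n_codons = 2000, seed = 71)
  res <- lapply(1:n_rep, function(i)
    yn00(codon_alignment(as.character(sim$fastaA[[i]]),
                         as.character(sim$fastaB[[i]]))))
  expect_lt(abs(mean(vapply(res, `[[`, numeric(1), "omega")) - 0.5), 0.075)
  expect_lt(abs(mean(vapply(res, `[[`, numeric(1), "kappa")) - 2), 0.6)
})

test_that("Fisher significance equals the exact enumeration oracle", {
  r <- list(Sd = 10, Nd = 0, S = 100, N = 100)
  expect_equal(kaks_significance(r),
               oracle_fisher_p(matrix(c(10, 0, 90, 100), 2, byrow = TRUE)),
               tolerance = 1e-9)
  # homogeneous proportions: p = 1
  expect_equal(kaks_significance(list(Sd = 5, Nd = 5, S = 50, N = 50)), 1)
  # negative corrected cells are clamped, not fatal
  expect_true(is.finite(kaks_significance(list(Sd = 10, Nd = 0, S = 9.4,
                                               N = 50))))
})

test_that("selection classification follows omega and p jointly", {
  res <- data.frame(omega = c(2.5, 0.9, 0.2, NA), p_value = c(0.01, 0.3, 0.001, NA))
  expect_equal(classify_selection(res),
               c("fast_evolving", "neutral", "constrained", "undefined"))
  s <- selection_summary(res)
  expect_equal(s$n_pairs[s$class == "omega_lt_1"], 2)
  expect_equal(s$n_pairs[s$class == "significant_lt_1"], 1)
  expect_equal(s$n_pairs[s$class == "significant_gt_1"], 1)
  expect_error(classify_selection(res, alpha = 0))
})

test_that("kaks_pairs drops internal-stop pairs with a flag and labels the rest", {
  sim <- simulate_ortholog_pairs(4, omega = 0.2, t = 0.4, n_codons = 200,
                                 seed = 91)
  fastaA <- sim$fastaA; fastaB <- sim$fastaB
  # corrupt one pair with an internal stop
  s <- as.character(fastaA[[2]])
  substr(s, 31, 33) <- "TAA"
  fastaA[[2]] <- Biostrings::DNAString(s)
  pairs <- sim$truth$ortholog_map
  out <- kaks_pairs(pairs, fastaA, fastaB, method = "yn00")
  expect_equal(nrow(out), 4)
  expect_equal(out$flags[2], "internal_stop")
  expect_true(is.na(out$omega[2]))
  ok <- out[-2, ]
  expect_true(all(ok$omega < 1))
  expect_true(all(ok$label %in% c("constrained", "neutral")))
})
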