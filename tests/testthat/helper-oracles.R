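# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately share no code with R/: pathway
# counting is done by recursion over intermediate codons, best hits by a
# per-query scan, and hypergeometric tails by direct summation of binomial
# coefficients.

.GC <- Biostrings::GENETIC_CODE
.SENSE <- names(.GC)[.GC != "*"]

oracle_translate <- function(codon) unname(.GC[codon])

# Per-codon synonymous sites, NG86 convention: per position the fraction of
# the three alternative bases giving a synonymous sense codon; stops count
# as nonsynonymous.
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) != "*" && oracle_translate(mut) == aa0)
        s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged (equal weights) synonymous/nonsynonymous difference
# counts between two sense codons, recursively enumerating all orders of
# the differing positions; pathways passing through a stop codon are
# discarded unless all of them do.
oracle_ng86_diffs <- function(c1, c2) {
  walk <- function(cur, target) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(d)) {
      return(list(list(syn = 0, non = 0, stop = FALSE)))
    }
    out <- list()
    for (pos in d) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      syn_step <- oracle_translate(cur) != "*" &&
        oracle_translate(nxt) != "*" &&
        oracle_translate(cur) == oracle_translate(nxt)
      hits_stop <- oracle_translate(nxt) == "*"
      for (tail in walk(nxt, target)) {
        out[[length(out) + 1L]] <- list(
          syn = tail$syn + as.numeric(syn_step),
          non = tail$non + as.numeric(!syn_step),
          stop = tail$stop || hits_stop)
      }
    }
    out
  }
  paths <- walk(c1, c2)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (any(ok)) paths <- paths[ok]
  c(Sd = mean(vapply(paths, `[[`, numeric(1), "syn")),
    Nd = mean(vapply(paths, `[[`, numeric(1), "non")))
}

# Best subject per query by a plain scan over all rows.
oracle_best_hits <- function(hits, evalue_max = 1e-6) {
  res <- character(0)
  for (q in sort(unique(hits$qseqid))) {
    rows <- hits[hits$qseqid == q & hits$evalue <= evalue_max, , drop = FALSE]
    if (!nrow(rows)) next
    best <- NULL
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (is.null(best) ||
          r$bitscore > best$bitscore ||
          (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
          (r$bitscore == best$bitscore && r$evalue == best$evalue &&
           r$sseqid < best$sseqid)) best <- r
    }
    res[q] <- best$sseqid
  }
  res
}

# Upper-tail hypergeometric probability by direct summation.
oracle_hyper_p <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table by enumeration over all tables
# with the observed margins, summing the probabilities of tables no more
# probable than the observed one (the fisher.test convention).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  }
  p_obs <- prob(tab[1, 1])
  sum(vapply(lo:hi, function(a) {
    p <- prob(a)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# Fraction of single-nucleotide changes among sense codons (stop targets
# excluded) that are nonsynonymous, under uniform codon usage: the neutral
# expectation for the proportion of nonsynonymous substitutions.
oracle_neutral_nonsyn_fraction <- function() {
  bases <- c("A", "C", "G", "T")
  n_syn <- n_non <- 0L
  for (cod in .SENSE) {
    for (pos in 1:3) {
      for (b in bases) {
        if (substr(cod, pos, pos) == b) next
        mut <- cod
        substr(mut, pos, pos) <- b
        if (oracle_translate(mut) == "*") next
        if (oracle_translate(mut) == oracle_translate(cod))
          n_syn <- n_syn + 1L else n_non <- n_non + 1L
      }
    }
  }
  n_non / (n_syn + n_non)
}

# Shortest-path level of a term by exhaustive path enumeration over is_a
# edges (root = level 1).
oracle_term_level <- function(parents, term) {
  if (!length(parents[[term]])) return(1L)
  1L + min(vapply(parents[[term]], function(p)
    oracle_term_level(parents, p), integer(1)))
}

# Shared small fixture: split a codon string for test assertions.
split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
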