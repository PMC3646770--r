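# Pairwise Ka/Ks estimation on ortholog CDS pairs.
#
# Two approximate methods are provided: the Nei-Gojobori (1986) pathway
# method with Jukes-Cantor correction, and the Yang-Nielsen (2000) method,
# which weights site and difference counting by the transition/transversion
# ratio and F3x4 codon frequencies and iterates the omega-dependent pathway
# weights to convergence.  Significance of omega != 1 is assessed with a
# two-sided Fisher exact test on the sites/differences contingency table.

#' Extract a coding sequence from a transcript using a similarity hit
#'
#' Takes the query interval \code{[qstart, qend]} (1-based inclusive) of the
#' transcript-vs-protein hit, reverse-complements it when the hit is on the
#' reverse strand (encoded by \code{qstart > qend}), and trims the 3' end to
#' a multiple of 3.
#'
#' @param transcript Character scalar or \code{DNAString}.
#' @param hit One-row data.frame with \code{qstart} and \code{qend}.
#' @return Character scalar: the in-frame coding sequence.
#' @export
extract_cds <- function(transcript, hit) {
  seq <- as.character(transcript)
  qs <- hit$qstart[1]; qe <- hit$qend[1]
  rev <- qs > qe
  lo <- min(qs, qe); hi <- max(qs, qe)
  if (lo < 1 || hi > nchar(seq))
    stop("hit coordinates [", lo, ", ", hi, "] beyond sequence length ",
         nchar(seq))
  cds <- substr(seq, lo, hi)
  if (rev)
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  keep <- (nchar(cds) %/% 3L) * 3L
  substr(cds, 1L, keep)
}

#' Screen a CDS for internal stop codons
#'
#' Fails iff any codon before the final one translates to a stop under the
#' standard code; a terminal stop codon is allowed and stripped.
#'
#' @param cds Character scalar, length a multiple of 3.
#' @return List with \code{pass} (logical) and \code{cds} (the sequence
#'   with any terminal stop removed; NA when \code{pass} is FALSE).
#' @export
screen_stops <- function(cds) {
  codons <- split_codons(cds)
  ct <- codon_tables()
  aa <- ct$aa[match(codons, ct$codons)]
  n <- length(codons)
  if (n && !is.na(aa[n]) && aa[n] == "*") {
    codons <- codons[-n]
    aa <- aa[-n]
  }
  if (any(!is.na(aa) & aa == "*"))
    return(list(pass = FALSE, cds = NA_character_))
  list(pass = TRUE, cds = paste(codons, collapse = ""))
}

#' Protein-guided codon alignment of two CDSs
#'
#' Globally aligns the two translations with a standard substitution matrix,
#' threads the codons back through the protein alignment, and discards
#' columns containing a gap or an ambiguity codon (counted in the QC
#' fields).
#'
#' @param cds_a,cds_b In-frame stop-screened CDSs (character).
#' @param substitution_matrix Name of the protein scoring matrix (default
#'   \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Gap penalties (default 10 / 0.5).
#' @return An object of class \code{codon_alignment}: list with
#'   \code{codonsA}, \code{codonsB}, \code{n_codons}, \code{code},
#'   \code{n_gap_cols}, \code{n_ambiguous_cols}.
#' @export
align_codons <- function(cds_a, cds_b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  aa_a <- Biostrings::translate(Biostrings::DNAString(cds_a),
                                if.fuzzy.codon = "solve")
  aa_b <- Biostrings::translate(Biostrings::DNAString(cds_b),
                                if.fuzzy.codon = "solve")
  aln <- Biostrings::pairwiseAlignment(
    aa_a, aa_b, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  ncol_aln <- length(pat)
  outA <- outB <- character(ncol_aln)
  keep <- logical(ncol_aln)
  for (k in seq_len(ncol_aln)) {
    ga <- pat[k] == "-"; gb <- sub[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      outA[k] <- cod_a[ia]; outB[k] <- cod_b[ib]
      keep[k] <- TRUE
    }
  }
  codonsA <- outA[keep]; codonsB <- outB[keep]
  n_gap <- ncol_aln - length(codonsA)
  clean <- !grepl("[^ACGT]", codonsA) & !grepl("[^ACGT]", codonsB)
  n_amb <- sum(!clean)
  codonsA <- codonsA[clean]; codonsB <- codonsB[clean]
  if (!length(codonsA)) stop("empty codon alignment after gap removal")
  structure(list(codonsA = codonsA, codonsB = codonsB,
                 n_codons = length(codonsA), code = "standard",
                 n_gap_cols = n_gap, n_ambiguous_cols = n_amb),
            class = "codon_alignment")
}

#' Construct a codon alignment from two equal-length in-frame CDSs
#'
#' Naive column pairing (no indels), for pre-aligned sequences such as the
#' simulator's output.
#'
#' @param cds_a,cds_b In-frame CDSs of equal length.
#' @return A \code{codon_alignment}.
#' @export
codon_alignment <- function(cds_a, cds_b) {
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  stopifnot(length(cod_a) == length(cod_b))
  structure(list(codonsA = cod_a, codonsB = cod_b,
                 n_codons = length(cod_a), code = "standard",
                 n_gap_cols = 0L, n_ambiguous_cols = 0L),
            class = "codon_alignment")
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

kaks_result <- function(S, N, Sd, Nd, kappa, Ka, Ks, omega, method,
                        flags = character(0)) {
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
                 Ka = Ka, Ks = Ks, omega = omega, p_value = NA_real_,
                 method = method,
                 flags = paste(flags, collapse = ";")),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("%s: S=%.2f N=%.2f Sd=%.2f Nd=%.2f kappa=%.3f\n",
              x$method, x$S, x$N, x$Sd, x$Nd, x$kappa))
  cat(sprintf("  Ka=%.4f Ks=%.4f omega=%.4f p=%.4g%s\n", x$Ka, x$Ks,
              x$omega, x$p_value,
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Nei-Gojobori (1986) pairwise Ka/Ks
#'
#' Sites are counted per codon as the fraction of the nine single-nucleotide
#' changes that are synonymous (changes into stop codons count as
#' nonsynonymous), averaged over the two sequences.  Differences are counted
#' by averaging over all shortest mutational pathways between differing
#' codons (equal weights; pathways through stop codons excluded).  The
#' proportions pS = Sd/S and pN = Nd/N receive the Jukes-Cantor correction
#' d = -(3/4) ln(1 - (4/3) p); a proportion >= 3/4 leaves the corresponding
#' distance undefined (NA) with a \code{saturated} flag.
#'
#' @param alignment A \code{codon_alignment}.
#' @return A \code{kaks_result} (with the Fisher p-value filled in).
#' @export
ng86 <- function(alignment) {
  ia <- codon_indices(alignment$codonsA)
  ib <- codon_indices(alignment$codonsB)
  if (anyNA(ia) || anyNA(ib))
    stop("alignment contains stop or invalid codons")
  n <- length(ia)
  s_sites <- ng86_syn_sites()
  S <- (sum(s_sites[ia]) + sum(s_sites[ib])) / 2
  N <- 3 * n - S
  m <- ng86_diff_matrices()
  Sd <- sum(m$Sd[cbind(ia, ib)])
  Nd <- sum(m$Nd[cbind(ia, ib)])
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  flags <- character(0)
  if (is.na(Ks) || is.na(Ka)) flags <- c(flags, "saturated")
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(omega) && !("saturated" %in% flags)) flags <- c(flags, "Ks_zero")
  res <- kaks_result(S, N, Sd, Nd, NA_real_, Ka, Ks, omega, "NG86", flags)
  res$p_value <- kaks_significance(res)
  res
}

# F3x4 codon frequencies from the two sequences of a pair: positional
# nucleotide frequencies (pooled over both sequences, with a small
# pseudocount so no observed codon gets zero weight), multiplied across the
# three positions, zeroed at stops and renormalised over sense codons.
f3x4_freqs <- function(codonsA, codonsB, pseudocount = 0.1) {
  bases <- c("A", "C", "G", "T")
  all_cod <- c(codonsA, codonsB)
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (p in 1:3) {
    tab <- table(factor(substr(all_cod, p, p), levels = bases))
    posfreq[p, ] <- (as.numeric(tab) + pseudocount) /
      (sum(tab) + 4 * pseudocount)
  }
  ct <- codon_tables()
  pi <- vapply(ct$sense, function(cod) {
    prod(posfreq[cbind(1:3, match(strsplit(cod, "")[[1]], bases))])
  }, numeric(1))
  unname(pi / sum(pi))
}

# K80 transitional (A) and transversional (B) distance components from
# proportions P (transitions) and Q (transversions); NA when saturated.
k80_components <- function(P, Q) {
  a <- unname(1 - 2 * P - Q)
  b <- unname(1 - 2 * Q)
  if (a <= 0 || b <= 0) return(c(A = NA_real_, B = NA_real_))
  c(A = -0.5 * log(a) + 0.25 * log(b), B = -0.25 * log(b))
}

k80_distance <- function(P, Q) {
  comp <- k80_components(P, Q)
  unname(comp["A"] + 2 * comp["B"])
}

codon_base_matrix <- function() {
  m <- .compara_cache$codon_base_matrix
  if (!is.null(m)) return(m)
  ct <- codon_tables()
  m <- do.call(rbind, strsplit(ct$sense, ""))
  .compara_cache$codon_base_matrix <- m
  m
}

# Estimate kappa from fourfold-degenerate and nondegenerate sites, K80
# corrected per class and combined by weighting the distance components
# with the class site counts.  Sites are used only where the two codons
# agree at the other two positions, so differences are unambiguous.
estimate_kappa <- function(ia, ib, default = 2) {
  dg <- codon_degeneracy()
  cb <- codon_base_matrix()
  b1 <- cb[ia, , drop = FALSE]; b2 <- cb[ib, , drop = FALSE]
  diffm <- b1 != b2
  ndiff <- rowSums(diffm)
  l <- ts <- tv <- c(nondeg = 0, fourfold = 0)
  for (p in 1:3) {
    usable <- (ndiff - diffm[, p]) == 0
    is_ts_p <- diffm[, p] & (((b1[, p] %in% PURINES) == (b2[, p] %in% PURINES)))
    nd <- usable & dg$nondeg[ia, p] & dg$nondeg[ib, p]
    l["nondeg"] <- l["nondeg"] + sum(nd)
    ts["nondeg"] <- ts["nondeg"] + sum(nd & is_ts_p)
    tv["nondeg"] <- tv["nondeg"] + sum(nd & diffm[, p] & !is_ts_p)
    if (p == 3L) {
      ff <- usable & dg$fourfold[ia] & dg$fourfold[ib]
      l["fourfold"] <- l["fourfold"] + sum(ff)
      ts["fourfold"] <- ts["fourfold"] + sum(ff & is_ts_p)
      tv["fourfold"] <- tv["fourfold"] + sum(ff & diffm[, p] & !is_ts_p)
    }
  }
  comp <- rbind(
    if (l["nondeg"] > 0) k80_components(ts["nondeg"] / l["nondeg"],
                                        tv["nondeg"] / l["nondeg"]),
    if (l["fourfold"] > 0) k80_components(ts["fourfold"] / l["fourfold"],
                                          tv["fourfold"] / l["fourfold"]))
  if (is.null(comp)) return(list(kappa = default, ok = FALSE))
  wts <- c(l["nondeg"], l["fourfold"])[c(l["nondeg"] > 0, l["fourfold"] > 0)]
  valid <- !is.na(comp[, "A"]) & !is.na(comp[, "B"]) & comp[, "B"] > 0
  if (!any(valid)) return(list(kappa = default, ok = FALSE))
  A <- sum(comp[valid, "A"] * wts[valid]) / sum(wts[valid])
  B <- sum(comp[valid, "B"] * wts[valid]) / sum(wts[valid])
  if (B <= 0 || !is.finite(A / B) || A / B <= 0)
    return(list(kappa = default, ok = FALSE))
  list(kappa = A / B, ok = TRUE)
}

# Mutation-weighted site counts: per sense codon, the expected fraction of
# single-nucleotide mutations (rate pi[target] * kappa^transition, stops
# excluded) that are synonymous, scaled to 3 sites per codon.
yn00_site_counts <- function(pi, kappa) {
  nb <- codon_neighbors()
  keep <- !nb$to_stop
  w <- pi[nb$to[keep]] * ifelse(nb$is_ts[keep], kappa, 1)
  from <- nb$from[keep]
  tot <- as.vector(rowsum(w, from))
  syn <- as.vector(rowsum(w * nb$is_syn[keep], from))
  3 * syn / tot
}

#' Yang-Nielsen (2000) pairwise Ka/Ks
#'
#' F3x4 codon frequencies are estimated from the pair; the
#' transition/transversion ratio kappa is estimated from fourfold-degenerate
#' and nondegenerate sites (K80-corrected, classes combined by site-count
#' weighting); synonymous/nonsynonymous site counts are weighted by the
#' mutational bias (target-codon frequency and kappa); differences are
#' counted by pathway averaging with pathway weights proportional to the
#' product over steps of pi[target] * kappa^transition *
#' omega^nonsynonymous, and the omega-dependent weights are iterated to
#' convergence (change < 1e-6, at most 100 iterations).  Transitional and
#' transversional difference proportions per site class receive the K80
#' correction to give Ks and Ka.
#'
#' @param alignment A \code{codon_alignment}.
#' @param min_codons Below this many codons a warning is issued (default
#'   30).
#' @return A \code{kaks_result} (with the Fisher p-value filled in).
#' @export
yn00 <- function(alignment, min_codons = 30L) {
  ia <- codon_indices(alignment$codonsA)
  ib <- codon_indices(alignment$codonsB)
  if (anyNA(ia) || anyNA(ib))
    stop("alignment contains stop or invalid codons")
  n <- length(ia)
  if (n < min_codons)
    warning("only ", n, " codons; YN00 estimates will be unstable")
  flags <- character(0)
  pi <- f3x4_freqs(alignment$codonsA, alignment$codonsB)
  kap <- estimate_kappa(ia, ib)
  if (!kap$ok) flags <- c(flags, "kappa_default")
  kappa <- kap$kappa
  s_sites <- yn00_site_counts(pi, kappa)
  S <- (sum(s_sites[ia]) + sum(s_sites[ib])) / 2
  N <- 3 * n - S

  diff <- ia != ib
  if (!any(diff)) {
    res <- kaks_result(S, N, 0, 0, kappa, 0, 0, NA_real_, "YN00",
                       c(flags, "no_differences"))
    res$p_value <- kaks_significance(res)
    return(res)
  }
  # both directions at half weight, so the estimate is symmetric in the
  # two sequences
  keys <- c((ia[diff] - 1L) * 61L + ib[diff],
            (ib[diff] - 1L) * 61L + ia[diff])
  tab <- table(keys)
  mult_pair <- as.numeric(tab) / 2
  names(mult_pair) <- names(tab)

  pt <- yn00_path_table()
  sel <- pt$pair_key %in% as.integer(names(mult_pair))
  p_key <- pt$pair_key[sel]
  p_to <- pt$step_to[sel, , drop = FALSE]
  p_ts <- pt$step_ts[sel, , drop = FALSE]
  p_syn <- pt$step_syn[sel, , drop = FALSE]
  p_cnt <- pt$counts[sel, , drop = FALSE]
  p_mult <- mult_pair[as.character(p_key)]
  key_fac <- factor(p_key)

  step_factor <- function(col, omega) {
    f <- rep(1, length(p_key))
    has <- !is.na(p_to[, col])
    f[has] <- pi[p_to[has, col]] *
      ifelse(p_ts[has, col], kappa, 1) *
      ifelse(p_syn[has, col], 1, omega)
    f
  }

  omega <- 1
  ds <- dn <- NA_real_
  converged <- FALSE
  for (iter in 1:100) {
    w <- step_factor(1, omega) * step_factor(2, omega) * step_factor(3, omega)
    wsum <- tapply(w, key_fac, sum)
    denom <- as.numeric(wsum[key_fac])
    zero <- denom <= 0 | !is.finite(denom)
    if (any(zero)) {
      # degenerate weights: fall back to equal pathway weighting
      npath <- tapply(rep(1, length(p_key)), key_fac, sum)
      w[zero] <- 1
      denom[zero] <- as.numeric(npath[key_fac])[zero]
    }
    wn <- w / denom * p_mult
    totals <- colSums(p_cnt * wn)  # ts_syn, tv_syn, ts_non, tv_non
    ds_new <- k80_distance(totals[1] / S, totals[2] / S)
    dn_new <- k80_distance(totals[3] / N, totals[4] / N)
    if (is.na(ds_new) || is.na(dn_new)) {
      flags <- c(flags, "saturated")
      ds <- ds_new; dn <- dn_new
      break
    }
    omega_new <- if (ds_new > 0) dn_new / ds_new else NA_real_
    if (is.na(omega_new)) {
      ds <- ds_new; dn <- dn_new
      break
    }
    delta <- abs(omega_new - omega) +
      (if (is.na(ds)) Inf else abs(ds_new - ds) + abs(dn_new - dn))
    omega <- omega_new; ds <- ds_new; dn <- dn_new
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged && !("saturated" %in% flags)) {
    if (is.na(ds) || ds <= 0) flags <- c(flags, "Ks_zero")
    else flags <- c(flags, "not_converged")
  }
  w <- step_factor(1, if (is.na(omega)) 1 else omega) *
    step_factor(2, if (is.na(omega)) 1 else omega) *
    step_factor(3, if (is.na(omega)) 1 else omega)
  wsum <- tapply(w, key_fac, sum)
  denom <- as.numeric(wsum[key_fac])
  bad <- denom <= 0 | !is.finite(denom)
  if (any(bad)) {
    npath <- tapply(rep(1, length(p_key)), key_fac, sum)
    w[bad] <- 1
    denom[bad] <- as.numeric(npath[key_fac])[bad]
  }
  wn <- w / denom * p_mult
  totals <- colSums(p_cnt * wn)
  Sd <- totals[1] + totals[2]
  Nd <- totals[3] + totals[4]
  omega_out <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  res <- kaks_result(S, N, unname(Sd), unname(Nd), kappa,
                     Ka = dn, Ks = ds, omega = omega_out, "YN00", flags)
  res$p_value <- kaks_significance(res)
  res
}

#' Fisher exact test of omega different from 1
#'
#' Two-sided Fisher exact test on the 2x2 table
#' \code{[[round(Sd), round(Nd)], [round(S - Sd), round(N - Nd)]]}: does the
#' proportion of differences among synonymous sites differ from that among
#' nonsynonymous sites?  Negative rounded cells (possible when counts exceed
#' sites) are clamped to 0.
#'
#' @param result A \code{kaks_result} (or any list with S, N, Sd, Nd).
#' @return The p-value.
#' @export
kaks_significance <- function(result) {
  v <- c(result$Sd, result$Nd, result$S - result$Sd, result$N - result$Nd)
  if (anyNA(v) || any(!is.finite(v))) return(NA_real_)
  tab <- matrix(pmax(round(v), 0), 2, 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Classify selection per pair
#'
#' \code{fast_evolving} iff omega > 1 and p < alpha; \code{constrained} iff
#' omega < 1 and p < alpha; otherwise \code{neutral} (pairs with undefined
#' omega are labelled \code{undefined}).
#'
#' @param results data.frame with columns \code{omega} and \code{p_value}
#'   (e.g. from \code{\link{kaks_pairs}}).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of labels.
#' @export
classify_selection <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  omega <- results$omega; p <- results$p_value
  lab <- rep("neutral", length(omega))
  lab[!is.na(omega) & !is.na(p) & omega > 1 & p < alpha] <- "fast_evolving"
  lab[!is.na(omega) & !is.na(p) & omega < 1 & p < alpha] <- "constrained"
  lab[is.na(omega)] <- "undefined"
  lab
}

#' Selection-class count table
#'
#' Mirrors the reporting convention for two-species Ka/Ks screens: counts
#' of pairs with omega < 1 (and significantly so), omega > 1 (and
#' significantly so), and pairs with undefined omega.
#'
#' @param results data.frame with \code{omega} and \code{p_value}.
#' @param alpha Significance level.
#' @return data.frame (class, n_pairs).
#' @export
selection_summary <- function(results, alpha = 0.05) {
  omega <- results$omega; p <- results$p_value
  def <- !is.na(omega)
  sig <- def & !is.na(p) & p < alpha
  data.frame(
    class = c("omega_lt_1", "significant_lt_1", "omega_gt_1",
              "significant_gt_1", "undefined"),
    n_pairs = c(sum(def & omega < 1), sum(sig & omega < 1),
                sum(def & omega > 1), sum(sig & omega > 1), sum(!def)),
    stringsAsFactors = FALSE)
}

#' Batch Ka/Ks over an ortholog pair table
#'
#' For each pair: extract the CDS of each member (using the highest-bitscore
#' transcript-vs-protein HSP when hit tables are given, otherwise the whole
#' transcript trimmed to frame), screen for internal stop codons, align
#' codons, estimate Ka/Ks and test significance.
#'
#' @param pairs data.frame with \code{idA}, \code{idB}.
#' @param fastaA,fastaB DNAStringSets of the two transcript collections.
#' @param prot_a,prot_b Optional transcript-vs-protein hit tables supplying
#'   CDS coordinates.
#' @param method \code{"yn00"} (default) or \code{"ng86"}.
#' @param alpha Significance level for the selection label.
#' @param p_adjust If TRUE, Benjamini-Hochberg adjust the p-values before
#'   labelling.
#' @return data.frame: idA, idB, n_codons, S, N, Sd, Nd, kappa, Ka, Ks,
#'   omega, p_value, label, flags.  Pairs failing the stop-codon screen are
#'   kept with NA estimates and flag \code{internal_stop}.
#' @export
kaks_pairs <- function(pairs, fastaA, fastaB, prot_a = NULL, prot_b = NULL,
                       method = c("yn00", "ng86"), alpha = 0.05,
                       p_adjust = FALSE) {
  method <- match.arg(method)
  fn <- if (method == "yn00") yn00 else ng86
  best_hsp <- function(prot, id) {
    if (is.null(prot)) return(NULL)
    rows <- prot[prot$qseqid == id, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    rows[order(-rows$bitscore, rows$evalue), ][1, ]
  }
  get_cds <- function(fasta, id, prot) {
    seq <- as.character(fasta[[id]])
    hsp <- best_hsp(prot, id)
    if (is.null(hsp)) {
      keep <- (nchar(seq) %/% 3L) * 3L
      substr(seq, 1L, keep)
    } else extract_cds(seq, hsp)
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    idA <- pairs$idA[i]; idB <- pairs$idB[i]
    scrA <- screen_stops(get_cds(fastaA, idA, prot_a))
    scrB <- screen_stops(get_cds(fastaB, idB, prot_b))
    if (!scrA$pass || !scrB$pass) {
      rows[[i]] <- data.frame(idA = idA, idB = idB, n_codons = NA_integer_,
        S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
        kappa = NA_real_, Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
        p_value = NA_real_, flags = "internal_stop",
        stringsAsFactors = FALSE)
      next
    }
    aln <- align_codons(scrA$cds, scrB$cds)
    r <- suppressWarnings(fn(aln))
    rows[[i]] <- data.frame(idA = idA, idB = idB, n_codons = aln$n_codons,
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, kappa = r$kappa,
      Ka = r$Ka, Ks = r$Ks, omega = r$omega, p_value = r$p_value,
      flags = r$flags, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$label <- classify_selection(out, alpha)
  out
}
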