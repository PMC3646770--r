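# Synthetic dual-transcriptome generator.  Produces every input the
# comparison pipeline consumes -- paired FASTA files, similarity-hit tables,
# annotations, allele-count pileups, SSR-bearing sequences and GO fixtures --
# together with the ground truth needed to test the downstream stages.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default codon frequencies
#'
#' Uniform frequencies over the 61 sense codons of the standard code.
#'
#' @return Named numeric vector of length 61 summing to 1.
#' @export
uniform_codon_freqs <- function() {
  ct <- codon_tables()
  stats::setNames(rep(1 / 61, 61), ct$sense)
}

# GY94-style codon rate matrix: single-nucleotide changes only, rate
# proportional to the target codon frequency, times kappa for transitions
# and omega for nonsynonymous changes.  Scaled so that the expected number
# of substitutions per codon per unit time is 1 at stationarity (pi).
codon_rate_matrix <- function(omega, kappa, pi) {
  nb <- codon_neighbors()
  Q <- matrix(0, 61, 61)
  keep <- !nb$to_stop
  rate <- pi[nb$to[keep]] *
    ifelse(nb$is_ts[keep], kappa, 1) *
    ifelse(nb$is_syn[keep], 1, omega)
  Q[cbind(nb$from[keep], nb$to[keep])] <- rate
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))
  Q / mean_rate
}

# Evolve codon states (1..61) for `time` expected substitutions per codon
# under rate matrix Q, by uniformisation: the number of (possibly virtual)
# jump events per site is Poisson, and events are applied in vectorised
# rounds from the jump matrix I + Q/lambda.
evolve_codons <- function(states, Q, time) {
  if (time <= 0) return(states)
  lambda <- max(-diag(Q))
  P <- diag(61) + Q / lambda
  cumP <- t(apply(P, 1, cumsum))
  cumP[, 61] <- 1  # guard against rounding
  n_ev <- stats::rpois(length(states), lambda * time)
  active <- which(n_ev > 0L)
  while (length(active)) {
    u <- stats::runif(length(active))
    st <- states[active]
    states[active] <- rowSums(cumP[st, , drop = FALSE] < u) + 1L
    n_ev[active] <- n_ev[active] - 1L
    active <- active[n_ev[active] > 0L]
  }
  states
}

#' Simulate diverged orthologous CDS pairs
#'
#' Draws, for each pair, an ancestral in-frame coding sequence from the
#' supplied codon frequencies (stop codons excluded) and evolves two
#' independent lineages for \code{t/2} expected substitutions per codon each
#' under a GY94-style codon substitution process: single-nucleotide changes
#' only, rate proportional to the target codon frequency, multiplied by
#' \code{kappa} for transitions and by \code{omega} for nonsynonymous
#' changes.  The pairwise divergence of a pair is therefore \code{t}.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param omega Nonsynonymous/synonymous rate ratio; scalar or one value per
#'   pair.
#' @param kappa Transition/transversion rate ratio (scalar).
#' @param t Expected substitutions per codon between the two sequences of a
#'   pair.
#' @param n_codons Codons per sequence (>= 10); scalar or per pair.
#' @param codon_freqs Frequencies of the 61 sense codons (default uniform).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param prefix Length-2 character: id prefixes for the two transcriptomes.
#' @return A list with \code{fastaA}, \code{fastaB}
#'   (\code{Biostrings::DNAStringSet}) and \code{truth}, a list whose
#'   \code{ortholog_map} records idA, idB, true_omega, true_kappa, true_t.
#' @export
simulate_ortholog_pairs <- function(n_pairs, omega = 0.5, kappa = 2, t = 0.4,
                                    n_codons = 500, codon_freqs = NULL,
                                    seed = 1, prefix = c("spA", "spB")) {
  stopifnot(n_pairs >= 1)
  if (any(omega <= 0)) stop("omega must be > 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (t < 0) stop("t must be >= 0")
  if (any(n_codons < 10)) stop("n_codons must be >= 10")
  omega <- rep_len(omega, n_pairs)
  n_codons <- rep_len(as.integer(n_codons), n_pairs)
  pi <- if (is.null(codon_freqs)) uniform_codon_freqs() else {
    stopifnot(length(codon_freqs) == 61, all(codon_freqs >= 0))
    codon_freqs / sum(codon_freqs)
  }
  ct <- codon_tables()
  with_seed(seed, {
    Qs <- lapply(unique(omega), function(w) codon_rate_matrix(w, kappa, pi))
    names(Qs) <- as.character(unique(omega))
    seqA <- seqB <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      Q <- Qs[[as.character(omega[i])]]
      anc <- sample.int(61, n_codons[i], replace = TRUE, prob = pi)
      a <- evolve_codons(anc, Q, t / 2)
      b <- evolve_codons(anc, Q, t / 2)
      seqA[i] <- paste(ct$sense[a], collapse = "")
      seqB[i] <- paste(ct$sense[b], collapse = "")
    }
    idA <- sprintf("%s_t%04d", prefix[1], seq_len(n_pairs))
    idB <- sprintf("%s_t%04d", prefix[2], seq_len(n_pairs))
    fastaA <- Biostrings::DNAStringSet(stats::setNames(seqA, idA))
    fastaB <- Biostrings::DNAStringSet(stats::setNames(seqB, idB))
    truth <- list(
      ortholog_map = data.frame(idA = idA, idB = idB, true_omega = omega,
                                true_kappa = kappa, true_t = t,
                                stringsAsFactors = FALSE),
      paralog_ids = character(0),
      snp_truth = NULL, ssr_truth = NULL
    )
    list(fastaA = fastaA, fastaB = fastaB, truth = truth)
  })
}

# Fabricated bitscore: monotone in alignment identity and length; the exact
# formula is arbitrary (it only needs to rank hits deterministically).
fake_bitscore <- function(identity, len) round(2 * identity * len)

fake_evalue <- function(bitscore) {
  e <- signif(10^(-bitscore / 10), 3)
  pmax(e, 1e-180)
}

hit_row <- function(q, s, pident, len, qstart, qend, sstart, send, bitscore,
                    evalue = fake_evalue(bitscore)) {
  data.frame(qseqid = q, sseqid = s, pident = round(pident, 2), length = len,
             mismatch = round(len * (1 - pident / 100)), gapopen = 0L,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Fabricate similarity-search tables and annotations for a simulated study
#'
#' Builds the four tabular search outputs (cross-species in both directions,
#' and transcript-vs-protein for each species) plus the two annotation
#' tables, so that every true ortholog pair is a mutual best hit sharing a
#' best protein accession and a unique gene name.  Decoys are planted so
#' that each violates exactly one paralog-exclusion filter:
#' \code{nonreciprocal} (best hit not reciprocated), \code{protein} (mutual
#' best hits whose members best-match different proteins) and \code{name}
#' (mutual best hits whose gene name is duplicated in transcriptome A).
#'
#' @param truth Truth list from \code{\link{simulate_ortholog_pairs}}.
#' @param fastaA,fastaB The simulated transcript sets.
#' @param n_decoys Total decoys, distributed round-robin over the three
#'   types; or a named integer vector with elements \code{nonreciprocal},
#'   \code{protein}, \code{name}.
#' @param seed Integer seed.
#' @param go_map_a,go_map_b Optional named character vectors (transcript id
#'   -> semicolon-joined GO ids) merged into the annotation tables.
#' @return List with \code{hits_ab}, \code{hits_ba}, \code{prot_a},
#'   \code{prot_b}, \code{annot_a}, \code{annot_b}, and \code{decoys}
#'   (data.frame: idA, idB, type).
#' @export
simulate_hit_tables <- function(truth, fastaA, fastaB, n_decoys = 0,
                                seed = 1, go_map_a = NULL, go_map_b = NULL) {
  om <- truth$ortholog_map
  if (!all(om$idA %in% names(fastaA)) || !all(om$idB %in% names(fastaB)))
    stop("truth ids not found in the FASTA inputs")
  if (is.null(names(n_decoys))) {
    types <- rep_len(c("nonreciprocal", "protein", "name"), sum(n_decoys))
  } else {
    types <- rep(names(n_decoys), n_decoys)
  }
  with_seed(seed, {
    n <- nrow(om)
    lenA <- Biostrings::width(fastaA)[match(om$idA, names(fastaA))]
    ident <- vapply(seq_len(n), function(i) {
      a <- strsplit(as.character(fastaA[[om$idA[i]]]), "")[[1]]
      b <- strsplit(as.character(fastaB[[om$idB[i]]]), "")[[1]]
      mean(a == b)
    }, numeric(1))
    bs <- fake_bitscore(ident, lenA)
    prot <- sprintf("P%05d", seq_len(n))
    gene <- sprintf("gene%04d", seq_len(n))

    hits_ab <- hit_row(om$idA, om$idB, 100 * ident, lenA, 1L, lenA, 1L, lenA, bs)
    hits_ba <- hit_row(om$idB, om$idA, 100 * ident, lenA, 1L, lenA, 1L, lenA, bs)
    # weaker cross hits so "best" is a real maximum, not the only row
    if (n >= 2) {
      alt <- c(seq_len(n)[-1], 1L)
      hits_ab <- rbind(hits_ab,
        hit_row(om$idA, om$idB[alt], 60, lenA, 1L, lenA, 1L, lenA,
                pmax(round(bs * 0.5), 40)))
    }
    aa_len <- (lenA %/% 3L)
    prot_a <- hit_row(om$idA, prot, 95, aa_len, 1L, aa_len * 3L, 1L, aa_len,
                      pmax(bs - 10, 50))
    prot_b <- hit_row(om$idB, prot, 95, aa_len, 1L, aa_len * 3L, 1L, aa_len,
                      pmax(bs - 10, 50))
    annot_a <- data.frame(transcript_id = om$idA, protein_accession = prot,
                          gene_name = gene, go_terms = "",
                          stringsAsFactors = FALSE)
    annot_b <- data.frame(transcript_id = om$idB, protein_accession = prot,
                          gene_name = gene, go_terms = "",
                          stringsAsFactors = FALSE)

    decoys <- data.frame(idA = character(0), idB = character(0),
                         type = character(0), stringsAsFactors = FALSE)
    for (k in seq_along(types)) {
      ty <- types[k]
      if (ty == "nonreciprocal") {
        id <- sprintf("spA_nrx%03d", k)
        tgt <- om$idB[1 + (k %% n)]
        hits_ab <- rbind(hits_ab, hit_row(id, tgt, 70, 300L, 1L, 300L,
                                          1L, 300L, 80))
        decoys <- rbind(decoys, data.frame(idA = id, idB = tgt, type = ty))
      } else if (ty == "protein") {
        ia <- sprintf("spA_pdx%03d", k); ib <- sprintf("spB_pdx%03d", k)
        hits_ab <- rbind(hits_ab, hit_row(ia, ib, 90, 300L, 1L, 300L, 1L, 300L, 400))
        hits_ba <- rbind(hits_ba, hit_row(ib, ia, 90, 300L, 1L, 300L, 1L, 300L, 400))
        pa <- sprintf("PDXA%03d", k); pb <- sprintf("PDXB%03d", k)
        prot_a <- rbind(prot_a, hit_row(ia, pa, 90, 100L, 1L, 300L, 1L, 100L, 300))
        prot_b <- rbind(prot_b, hit_row(ib, pb, 90, 100L, 1L, 300L, 1L, 100L, 300))
        annot_a <- rbind(annot_a, data.frame(transcript_id = ia,
          protein_accession = pa, gene_name = sprintf("pdgeneA%03d", k),
          go_terms = ""))
        annot_b <- rbind(annot_b, data.frame(transcript_id = ib,
          protein_accession = pb, gene_name = sprintf("pdgeneB%03d", k),
          go_terms = ""))
        decoys <- rbind(decoys, data.frame(idA = ia, idB = ib, type = ty))
      } else if (ty == "name") {
        ia <- sprintf("spA_ndx%03d", k); ib <- sprintf("spB_ndx%03d", k)
        fill <- sprintf("spA_fil%03d", k)
        hits_ab <- rbind(hits_ab, hit_row(ia, ib, 92, 300L, 1L, 300L, 1L, 300L, 420))
        hits_ba <- rbind(hits_ba, hit_row(ib, ia, 92, 300L, 1L, 300L, 1L, 300L, 420))
        pn <- sprintf("PNDX%03d", k); gn <- sprintf("dupname%03d", k)
        prot_a <- rbind(prot_a, hit_row(ia, pn, 92, 100L, 1L, 300L, 1L, 100L, 320))
        prot_b <- rbind(prot_b, hit_row(ib, pn, 92, 100L, 1L, 300L, 1L, 100L, 320))
        # the duplicated name: once on the decoy pair, once on a filler
        # transcript of A that has no hits at all
        annot_a <- rbind(annot_a,
          data.frame(transcript_id = ia, protein_accession = pn,
                     gene_name = gn, go_terms = ""),
          data.frame(transcript_id = fill, protein_accession = sprintf("PFIL%03d", k),
                     gene_name = gn, go_terms = ""))
        annot_b <- rbind(annot_b, data.frame(transcript_id = ib,
          protein_accession = pn, gene_name = gn, go_terms = ""))
        decoys <- rbind(decoys, data.frame(idA = ia, idB = ib, type = ty))
      } else stop("unknown decoy type: ", ty)
    }
    if (!is.null(go_map_a))
      annot_a$go_terms <- ifelse(is.na(go_map_a[annot_a$transcript_id]), "",
                                 go_map_a[annot_a$transcript_id])
    if (!is.null(go_map_b))
      annot_b$go_terms <- ifelse(is.na(go_map_b[annot_b$transcript_id]), "",
                                 go_map_b[annot_b$transcript_id])
    rownames(hits_ab) <- rownames(hits_ba) <- NULL
    rownames(prot_a) <- rownames(prot_b) <- NULL
    list(hits_ab = hits_ab, hits_ba = hits_ba, prot_a = prot_a,
         prot_b = prot_b, annot_a = annot_a, annot_b = annot_b,
         decoys = decoys)
  })
}

#' Simulate a per-position allele-count pileup with planted variants
#'
#' Per position, \code{depth} reads are drawn; at planted variant positions
#' each read carries the alternative allele with probability
#' \code{alt_fraction}.  Substitution sequencing errors then flip each
#' base-allele read to a uniformly chosen other base with probability
#' \code{error_rate}.
#'
#' @param contig_len Contig length in bp.
#' @param snps data.frame with columns \code{pos} (0-based), \code{ref},
#'   \code{alt} (one of A/C/G/T, \code{"del"}, or \code{"ins:<seq>"}),
#'   \code{alt_fraction} in [0, 1]; or NULL for none.
#' @param depth Reads per position (>= 1).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return List with \code{pileup} (data.frame: contig, pos, countA, countC,
#'   countG, countT, countDel, countIns) and \code{truth} (the planted
#'   variant table, with the reference allele per position).
#' @export
simulate_pileup <- function(contig_len, snps = NULL, depth = 40,
                            error_rate = 0.001, seed = 1,
                            contig = "contig1") {
  stopifnot(contig_len >= 1, depth >= 1, error_rate >= 0, error_rate < 1)
  bases <- c("A", "C", "G", "T")
  if (!is.null(snps) && nrow(snps)) {
    if (anyDuplicated(snps$pos)) stop("position collisions in planted snps")
    if (any(snps$pos < 0 | snps$pos >= contig_len))
      stop("snp position outside contig")
    if (any(snps$alt_fraction < 0 | snps$alt_fraction > 1))
      stop("alt_fraction outside [0, 1]")
  }
  with_seed(seed, {
    ref <- sample(bases, contig_len, replace = TRUE)
    if (!is.null(snps) && nrow(snps)) {
      given <- !is.na(snps$ref) & nzchar(snps$ref)
      ref[snps$pos[given] + 1L] <- snps$ref[given]
    }
    counts <- matrix(0L, contig_len, 6,
                     dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
    counts[cbind(seq_len(contig_len), match(ref, bases))] <- as.integer(depth)
    if (!is.null(snps) && nrow(snps)) {
      n_alt <- stats::rbinom(nrow(snps), depth, snps$alt_fraction)
      for (i in seq_len(nrow(snps))) {
        row <- snps$pos[i] + 1L
        alt <- snps$alt[i]
        col <- if (alt == "del") "del" else if (startsWith(alt, "ins")) "ins"
               else alt
        counts[row, match(ref[row], bases)] <-
          counts[row, match(ref[row], bases)] - n_alt[i]
        counts[row, col] <- counts[row, col] + n_alt[i]
      }
    }
    if (error_rate > 0) {
      # substitution errors on base-allele reads only
      for (b in 1:4) {
        n_err <- stats::rbinom(contig_len, counts[, b], error_rate)
        pos_err <- which(n_err > 0L)
        for (row in pos_err) {
          tgt <- sample((1:4)[-b], n_err[row], replace = TRUE)
          counts[row, b] <- counts[row, b] - n_err[row]
          for (tg in tgt) counts[row, tg] <- counts[row, tg] + 1L
        }
      }
    }
    pileup <- data.frame(contig = contig, pos = seq_len(contig_len) - 1L,
                         countA = counts[, 1], countC = counts[, 2],
                         countG = counts[, 3], countT = counts[, 4],
                         countDel = counts[, 5], countIns = counts[, 6],
                         stringsAsFactors = FALSE)
    truth <- if (is.null(snps) || !nrow(snps)) {
      data.frame(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), alt_fraction = numeric(0))
    } else {
      data.frame(contig = contig, pos = snps$pos, ref = ref[snps$pos + 1L],
                 alt = snps$alt, alt_fraction = snps$alt_fraction,
                 stringsAsFactors = FALSE)
    }
    list(pileup = pileup, truth = truth)
  })
}

#' Plant microsatellite tracts in random background sequence
#'
#' Inserts perfect repeat tracts at recorded non-overlapping positions in
#' otherwise random sequence, and regenerates any background in which the
#' detector (at the canonical thresholds: total length >= 15 bp and >= 3
#' repeats, motifs 2-6 bp) would find loci other than exactly the qualifying
#' planted tracts, so the truth table is exhaustive.
#'
#' @param n_seqs Number of sequences.
#' @param seq_length Length of each sequence (bp).
#' @param tracts data.frame with columns \code{motif}, \code{n_repeats}
#'   (integer full copies); tracts are assigned round-robin to sequences.
#' @param seed Integer seed.
#' @return List with \code{fasta} (DNAStringSet) and \code{truth}
#'   (data.frame: seq_id, start, end (0-based half-open), motif, n_repeats,
#'   total_len, qualifies).
#' @export
plant_ssrs <- function(n_seqs, seq_length, tracts, seed = 1) {
  stopifnot(n_seqs >= 1, seq_length >= 30)
  tracts <- as.data.frame(tracts)
  if (nrow(tracts)) {
    ml <- nchar(tracts$motif)
    if (any(ml < 2 | ml > 6)) stop("motif length must be in [2, 6]")
    if (any(ml * tracts$n_repeats > seq_length - 2))
      stop("tract longer than sequence")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    for (attempt in 1:200) {
      seqs <- vapply(seq_len(n_seqs), function(i)
        paste(sample(bases, seq_length, replace = TRUE), collapse = ""),
        character(1))
      truth <- NULL
      ok <- TRUE
      if (nrow(tracts)) {
        assign_to <- rep_len(seq_len(n_seqs), nrow(tracts))
        offsets <- lapply(seq_len(n_seqs), function(i) integer(0))
        rows <- vector("list", nrow(tracts))
        for (k in seq_len(nrow(tracts))) {
          s <- assign_to[k]
          tl <- nchar(tracts$motif[k]) * tracts$n_repeats[k]
          # place away from existing tracts (2 bp guard)
          placed <- FALSE
          for (try in 1:50) {
            st <- sample.int(seq_length - tl - 2L, 1) + 1L  # 1-based start >= 2
            span <- c(st - 2L, st + tl + 1L)
            clash <- any(vapply(offsets[[s]], function(o)
              span[1] <= o[2] && o[1] <= span[2], logical(1)))
            if (!clash) { placed <- TRUE; break }
          }
          if (!placed) { ok <- FALSE; break }
          offsets[[s]] <- c(offsets[[s]], list(span))
          tract_seq <- strrep(tracts$motif[k], tracts$n_repeats[k])
          substr(seqs[s], st, st + tl - 1L) <- tract_seq
          rows[[k]] <- data.frame(
            seq_id = sprintf("seq%03d", s), start = st - 1L,
            end = st - 1L + tl, motif = tracts$motif[k],
            n_repeats = tracts$n_repeats[k], total_len = tl,
            qualifies = tl >= 15 && tracts$n_repeats[k] >= 3,
            stringsAsFactors = FALSE)
        }
        if (!ok) next
        truth <- do.call(rbind, rows)
      }
      names(seqs) <- sprintf("seq%03d", seq_len(n_seqs))
      # verify the background: the detector must see exactly the qualifying
      # planted tracts
      found <- do.call(rbind, lapply(names(seqs), function(id) {
        f <- find_ssrs(seqs[[id]])
        if (nrow(f)) cbind(seq_id = id, f) else NULL
      }))
      want <- if (is.null(truth)) NULL else truth[truth$qualifies, ]
      n_found <- if (is.null(found)) 0L else nrow(found)
      n_want <- if (is.null(want)) 0L else nrow(want)
      if (n_want > 0L) want <- want[order(want$seq_id, want$start), ]
      if (n_found > 0L) found <- found[order(found$seq_id, found$start), ]
      if (n_found == n_want &&
          (n_want == 0L ||
           (all(found$seq_id == want$seq_id) &&
            all(found$start == want$start) && all(found$end == want$end)))) {
        return(list(fasta = Biostrings::DNAStringSet(seqs), truth = truth))
      }
    }
    stop("could not generate a clean background in 200 attempts")
  })
}

#' Simulate GO annotations with one planted enriched term
#'
#' Builds a toy two-level ontology (one biological_process root whose
#' children are the terms) and assigns terms to genes at a background rate,
#' except for the planted term, which is assigned to genes of the designated
#' study set at a higher rate.
#'
#' @param n_genes Population size.
#' @param n_terms Number of leaf terms (>= 2).
#' @param enriched_term Id of the planted term (must be one of the generated
#'   term ids \code{GO:1000002 ...}; default the first).
#' @param study_fraction_with_term Probability a study gene carries the
#'   planted term.
#' @param background_fraction Probability any other (gene, term) assignment
#'   is made.
#' @param seed Integer seed.
#' @param study_size Size of the study set (default 1/5 of the population,
#'   at least 5).
#' @return List with \code{annotations} (data.frame: gene, go_terms),
#'   \code{obo} (character scalar, minimal OBO text), \code{study}
#'   (character vector of study genes) and \code{truth}.
#' @export
simulate_go_annotations <- function(n_genes, n_terms, enriched_term = NULL,
                                    study_fraction_with_term = 0.8,
                                    background_fraction = 0.1, seed = 1,
                                    study_size = max(5L, n_genes %/% 5L)) {
  stopifnot(n_genes >= 10, n_terms >= 2,
            study_fraction_with_term >= 0, study_fraction_with_term <= 1,
            background_fraction >= 0, background_fraction <= 1)
  if (study_fraction_with_term < background_fraction)
    stop("study fraction must be >= background fraction for the planted term")
  term_ids <- sprintf("GO:1%06d", 1L + seq_len(n_terms))
  root <- "GO:1000001"
  if (is.null(enriched_term)) enriched_term <- term_ids[1]
  if (!enriched_term %in% term_ids) stop("enriched_term not among term ids")
  obo <- paste(c(
    "format-version: 1.2",
    "",
    "[Term]",
    paste0("id: ", root),
    "name: biological_process",
    "namespace: biological_process",
    unlist(lapply(term_ids, function(id) c(
      "",
      "[Term]",
      paste0("id: ", id),
      paste0("name: term ", id),
      "namespace: biological_process",
      paste0("is_a: ", root, " ! biological_process")
    )))), collapse = "\n")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    study <- genes[seq_len(min(study_size, n_genes))]
    has <- matrix(stats::runif(n_genes * n_terms) < background_fraction,
                  n_genes, n_terms)
    ei <- match(enriched_term, term_ids)
    si <- seq_along(study)
    has[si, ei] <- stats::runif(length(si)) < study_fraction_with_term
    go_terms <- vapply(seq_len(n_genes), function(i)
      paste(term_ids[has[i, ]], collapse = ";"), character(1))
    list(
      annotations = data.frame(gene = genes, go_terms = go_terms,
                               stringsAsFactors = FALSE),
      obo = obo,
      study = study,
      truth = list(enriched_term = enriched_term, root = root,
                   term_ids = term_ids,
                   study_fraction = study_fraction_with_term,
                   background_fraction = background_fraction)
    )
  })
}
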