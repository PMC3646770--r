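# Putative 1:1 ortholog identification between two transcriptomes:
# bidirectional best hits followed by two paralog-exclusion filters
# (shared best protein match; gene name unique within each transcriptome),
# with a funnel report of the counts surviving each stage.

#' Best hit per query
#'
#' For every query, the subject with the maximal bitscore among hits with
#' \code{evalue <= evalue_max}.  Ties are broken by lower evalue, then by
#' lexicographic subject id, so the result is deterministic.
#'
#' @param hits Hit table (data.frame, see \code{\link{read_hit_table}}).
#' @param evalue_max E-value cutoff (default 1e-6).
#' @return Named character vector: query id -> best subject id.
#' @export
best_hits <- function(hits, evalue_max = 1e-6) {
  validate_hits(hits)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, ]
  top <- hits[!duplicated(hits$qseqid), ]
  stats::setNames(top$sseqid, top$qseqid)
}

#' Reciprocal best hits between two transcriptomes
#'
#' Retains the pair (a, b) iff a's best hit in B is b and b's best hit in A
#' is a, both at \code{evalue <= evalue_max}.
#'
#' @param hits_ab Hits of A-transcripts against B.
#' @param hits_ba Hits of B-transcripts against A.
#' @param evalue_max E-value cutoff.
#' @return data.frame (idA, idB, stage = "bbh"), sorted by idA.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-6) {
  ab <- best_hits(hits_ab, evalue_max)
  ba <- best_hits(hits_ba, evalue_max)
  keep <- !is.na(ba[ab]) & ba[ab] == names(ab)
  keep[is.na(keep)] <- FALSE
  pairs <- data.frame(idA = names(ab)[keep], idB = unname(ab[keep]),
                      stage = rep("bbh", sum(keep)),
                      stringsAsFactors = FALSE)
  pairs[order(pairs$idA), , drop = FALSE]
}

#' Keep pairs whose members best-match the same protein
#'
#' A pair survives iff both members have a best protein match (from the
#' annotation tables' \code{protein_accession}, typically derived from the
#' transcript-vs-protein search via \code{\link{annotate_best_protein}})
#' and the accessions are identical.  Pairs with an unannotated member are
#' dropped, not errored.
#'
#' @param pairs data.frame from \code{\link{reciprocal_best_hits}}.
#' @param annot_a,annot_b Annotation tables (see
#'   \code{\link{read_annotations}}).
#' @return data.frame (idA, idB, stage = "same_protein", best_protein).
#' @export
filter_same_protein <- function(pairs, annot_a, annot_b) {
  pa <- annot_a$protein_accession[match(pairs$idA, annot_a$transcript_id)]
  pb <- annot_b$protein_accession[match(pairs$idB, annot_b$transcript_id)]
  ok <- !is.na(pa) & !is.na(pb) & nzchar(pa) & nzchar(pb) & pa == pb
  out <- pairs[ok, c("idA", "idB"), drop = FALSE]
  out$stage <- rep("same_protein", nrow(out))
  out$best_protein <- pa[ok]
  rownames(out) <- NULL
  out
}

#' Derive best protein accessions from a transcript-vs-protein hit table
#'
#' Replaces the \code{protein_accession} column of an annotation table with
#' the best protein hit (maximal bitscore at \code{evalue <= evalue_max});
#' transcripts with no qualifying protein hit get an empty accession.
#' Transcripts present in the hit table but absent from the annotation table
#' are appended with an empty gene name.
#'
#' @param annot Annotation table.
#' @param prot_hits Transcript-vs-protein hit table.
#' @param evalue_max E-value cutoff.
#' @return The updated annotation table.
#' @export
annotate_best_protein <- function(annot, prot_hits, evalue_max = 1e-6) {
  best <- best_hits(prot_hits, evalue_max)
  extra <- setdiff(names(best), annot$transcript_id)
  if (length(extra))
    annot <- rbind(annot, data.frame(
      transcript_id = extra, protein_accession = "", gene_name = "",
      go_terms = "", stringsAsFactors = FALSE))
  acc <- best[annot$transcript_id]
  annot$protein_accession <- ifelse(is.na(acc), "", unname(acc))
  annot
}

normalize_gene_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Keep pairs whose gene name is unique within each transcriptome
#'
#' Gene-name multiplicity is computed over each FULL annotation table (not
#' only the paired transcripts), case-insensitively after whitespace
#' normalisation.  A pair is retained iff the gene name of its A member
#' occurs exactly once in A's table and the gene name of its B member occurs
#' exactly once in B's table.  Pairs with empty gene names are dropped.
#'
#' @param pairs data.frame from \code{\link{filter_same_protein}}.
#' @param annot_a,annot_b Annotation tables.
#' @return data.frame at stage \code{unique_name}.
#' @export
filter_unique_gene_name <- function(pairs, annot_a, annot_b) {
  na_all <- normalize_gene_name(annot_a$gene_name)
  nb_all <- normalize_gene_name(annot_b$gene_name)
  cnt_a <- table(na_all[nzchar(na_all)])
  cnt_b <- table(nb_all[nzchar(nb_all)])
  ga <- na_all[match(pairs$idA, annot_a$transcript_id)]
  gb <- nb_all[match(pairs$idB, annot_b$transcript_id)]
  ok <- !is.na(ga) & !is.na(gb) & nzchar(ga) & nzchar(gb) &
    as.vector(cnt_a[ga]) == 1L & as.vector(cnt_b[gb]) == 1L
  ok[is.na(ok)] <- FALSE
  out <- pairs[ok, , drop = FALSE]
  out$stage <- rep("unique_name", nrow(out))
  rownames(out) <- NULL
  out
}

#' Funnel report of ortholog-filtering stages
#'
#' @param stages Named list of pair data.frames, in funnel order
#'   (\code{bbh}, \code{same_protein}, \code{unique_name}).
#' @return data.frame (stage, n_pairs); counts are checked to be monotone
#'   non-increasing.
#' @export
funnel_report <- function(stages) {
  counts <- vapply(stages, nrow, integer(1))
  if (any(diff(counts) > 0))
    stop("funnel counts are not monotone non-increasing")
  data.frame(stage = names(stages), n_pairs = unname(counts),
             stringsAsFactors = FALSE)
}

#' Run the full ortholog-identification funnel
#'
#' Convenience wrapper: reciprocal best hits, then the same-protein and
#' unique-gene-name filters, with best protein accessions derived from the
#' transcript-vs-protein hit tables.
#'
#' @param hits_ab,hits_ba Cross-species hit tables.
#' @param prot_a,prot_b Transcript-vs-protein hit tables.
#' @param annot_a,annot_b Annotation tables.
#' @param evalue_max E-value cutoff for all searches.
#' @return List with \code{pairs} (the final stage), \code{stages} (list of
#'   all three), and \code{funnel} (the report).
#' @export
ortholog_funnel <- function(hits_ab, hits_ba, prot_a, prot_b,
                            annot_a, annot_b, evalue_max = 1e-6) {
  annot_a <- annotate_best_protein(annot_a, prot_a, evalue_max)
  annot_b <- annotate_best_protein(annot_b, prot_b, evalue_max)
  bbh <- reciprocal_best_hits(hits_ab, hits_ba, evalue_max)
  same_prot <- filter_same_protein(bbh, annot_a, annot_b)
  uniq <- filter_unique_gene_name(same_prot, annot_a, annot_b)
  stages <- list(bbh = bbh, same_protein = same_prot, unique_name = uniq)
  list(pairs = uniq, stages = stages, funnel = funnel_report(stages),
       annot_a = annot_a, annot_b = annot_b)
}
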