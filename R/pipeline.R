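# End-to-end orchestration: a flat YAML config names the inputs and
# thresholds; run_comparison() executes the ortholog funnel, CDS
# extraction/screening, codon alignment, YN00 Ka/Ks, significance
# classification and GO enrichment; run_markers() executes SNP and SSR
# discovery for each transcriptome.  Every stage materialises its output as
# TSV in the output directory so any stage can be re-run in isolation, and
# a machine-readable JSON report collects the headline numbers.  Reports
# contain no timestamps, so identical config + seed gives byte-identical
# output; timestamped logging goes to standard error.

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [compara] ", ...)
}

#' Read and validate a pipeline configuration
#'
#' A flat YAML file of input paths and thresholds.  Defaults: evalue 1e-6,
#' alpha 0.05, min_reads 8, min_maf 0.25, ssr_min_len 15, ssr_min_repeats
#' 3, seed 1.  All referenced files must exist.
#'
#' @param path YAML file path, or a named list (validated as-is).
#' @return Named list of class \code{compara_config}.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(evalue = 1e-6, alpha = 0.05, min_reads = 8,
                   min_maf = 0.25, ssr_min_len = 15, ssr_min_repeats = 3,
                   seed = 1, outdir = "compara_out")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  num <- c("evalue", "alpha", "min_reads", "min_maf", "ssr_min_len",
           "ssr_min_repeats")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config threshold '", nm, "' must be a positive number")
  path_keys <- intersect(names(cfg),
    c("fasta_a", "fasta_b", "hits_ab", "hits_ba", "prot_a", "prot_b",
      "annot_a", "annot_b", "obo", "pileup_a", "pileup_b"))
  for (nm in path_keys)
    if (!file.exists(cfg[[nm]]))
      stop("config input '", nm, "' does not exist: ", cfg[[nm]])
  class(cfg) <- c("compara_config", "list")
  cfg
}

require_inputs <- function(cfg, keys, stage) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop(stage, " requires config entries: ", paste(missing, collapse = ", "))
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the two-species comparison pipeline
#'
#' Ortholog funnel (reciprocal best hits, same-protein filter, unique-name
#' filter), CDS extraction from the transcript-vs-protein coordinates,
#' stop-codon screening, protein-guided codon alignment, YN00 Ka/Ks with
#' Fisher significance, selection classification, and (when an ontology and
#' GO annotations are configured) hypergeometric GO enrichment of the
#' constrained and fast-evolving sets against all analysed pairs.
#'
#' @param config Path to a YAML config or a named list (see
#'   \code{\link{read_config}}).  Required entries: fasta_a, fasta_b,
#'   hits_ab, hits_ba, prot_a, prot_b, annot_a, annot_b; optional: obo.
#' @param method Ka/Ks method, \code{"yn00"} (default) or \code{"ng86"}.
#' @return The report, invisibly.  Side effects: stage TSVs and
#'   \code{report.json} under \code{config$outdir}.
#' @export
run_comparison <- function(config, method = "yn00") {
  cfg <- read_config(config)
  require_inputs(cfg, c("fasta_a", "fasta_b", "hits_ab", "hits_ba",
                        "prot_a", "prot_b", "annot_a", "annot_b"),
                 "run_comparison")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg("run_comparison: seed=", cfg$seed, " evalue=", cfg$evalue,
          " alpha=", cfg$alpha)

  log_msg("stage orthology")
  hits_ab <- read_hit_table(cfg$hits_ab)
  hits_ba <- read_hit_table(cfg$hits_ba)
  prot_a <- read_hit_table(cfg$prot_a)
  prot_b <- read_hit_table(cfg$prot_b)
  annot_a <- read_annotations(cfg$annot_a)
  annot_b <- read_annotations(cfg$annot_b)
  orth <- ortholog_funnel(hits_ab, hits_ba, prot_a, prot_b,
                          annot_a, annot_b, evalue_max = cfg$evalue)
  write_tsv(orth$pairs, file.path(cfg$outdir, "ortholog_pairs.tsv"))
  write_tsv(orth$funnel, file.path(cfg$outdir, "funnel.tsv"))

  log_msg("stage kaks (", method, ") on ", nrow(orth$pairs), " pairs")
  fastaA <- read_fasta(cfg$fasta_a)
  fastaB <- read_fasta(cfg$fasta_b)
  kk <- kaks_pairs(orth$pairs, fastaA, fastaB, prot_a, prot_b,
                   method = method, alpha = cfg$alpha)
  write_tsv(kk, file.path(cfg$outdir, "kaks.tsv"))
  classes <- selection_summary(kk, alpha = cfg$alpha)
  write_tsv(classes, file.path(cfg$outdir, "selection_classes.tsv"))

  enrichment <- NULL
  profiles <- NULL
  if (!is.null(cfg$obo)) {
    log_msg("stage GO profiling and enrichment")
    graph <- load_obo(cfg$obo)
    annot_sets_a <- annotation_sets(orth$annot_a)
    population <- kk$idA
    study_constrained <- kk$idA[kk$label == "constrained"]
    study_fast <- kk$idA[kk$label == "fast_evolving"]
    enr <- list()
    for (set_name in c("constrained", "fast_evolving")) {
      study <- if (set_name == "constrained") study_constrained else study_fast
      if (length(study)) {
        e <- hypergeometric_enrichment(study, population, annot_sets_a,
                                       graph, alpha = cfg$alpha)
        write_tsv(e, file.path(cfg$outdir,
                               paste0("enrichment_", set_name, ".tsv")))
        enr[[set_name]] <- e
      }
    }
    enrichment <- enr
    prof_a <- rollup_to_level(orth$annot_a, graph, level = 3)
    prof_b <- rollup_to_level(orth$annot_b, graph, level = 3)
    write_tsv(prof_a, file.path(cfg$outdir, "go_profile_a.tsv"))
    write_tsv(prof_b, file.path(cfg$outdir, "go_profile_b.tsv"))
    profiles <- list(A = prof_a, B = prof_b)
  }

  report <- list(
    parameters = list(evalue = cfg$evalue, alpha = cfg$alpha,
                      method = method, seed = cfg$seed),
    funnel = stats::setNames(as.list(orth$funnel$n_pairs),
                             orth$funnel$stage),
    n_pairs_analysed = nrow(kk),
    n_pairs_flagged = sum(nzchar(kk$flags)),
    selection_classes = stats::setNames(as.list(classes$n_pairs),
                                        classes$class),
    enrichment = lapply(enrichment, function(e)
      e[, c("term_id", "k", "n", "K", "N", "p_value", "significant")]),
    go_profiles = if (!is.null(profiles))
      list(n_level3_terms_A = nrow(profiles$A),
           n_level3_terms_B = nrow(profiles$B))
  )
  write_report(report, file.path(cfg$outdir, "report.json"))
  log_msg("run_comparison done")
  invisible(report)
}

#' Run marker discovery (SNPs and SSRs) for each transcriptome
#'
#' SNP calling on the configured pileups with the depth and MAF thresholds,
#' and perfect-SSR detection on each FASTA, each summarised per species.
#'
#' @param config Path to a YAML config or a named list.  Required entries:
#'   fasta_a, fasta_b, pileup_a, pileup_b.
#' @return The report, invisibly; stage TSVs and \code{markers.json} under
#'   \code{config$outdir}.
#' @export
run_markers <- function(config) {
  cfg <- read_config(config)
  require_inputs(cfg, c("fasta_a", "fasta_b", "pileup_a", "pileup_b"),
                 "run_markers")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = list(min_reads = cfg$min_reads,
                                   min_maf = cfg$min_maf,
                                   ssr_min_len = cfg$ssr_min_len,
                                   ssr_min_repeats = cfg$ssr_min_repeats,
                                   seed = cfg$seed))
  for (sp in c("a", "b")) {
    log_msg("markers for transcriptome ", toupper(sp))
    fasta <- read_fasta(cfg[[paste0("fasta_", sp)]])
    total_bp <- sum(Biostrings::width(fasta))
    pile <- read_pileup(cfg[[paste0("pileup_", sp)]])
    calls <- call_snps(pile, min_reads_per_allele = cfg$min_reads,
                       min_maf = cfg$min_maf)
    write_tsv(calls, file.path(cfg$outdir, paste0("snps_", sp, ".tsv")))
    snp_sum <- snp_summary(calls, total_bp)
    write_tsv(snp_sum$by_type,
              file.path(cfg$outdir, paste0("snp_types_", sp, ".tsv")))
    loci <- scan_ssrs(fasta, min_total_len = cfg$ssr_min_len,
                      min_repeats = cfg$ssr_min_repeats)
    write_tsv(loci, file.path(cfg$outdir, paste0("ssrs_", sp, ".tsv")))
    ssr_sum <- ssr_summary(loci)
    write_tsv(ssr_sum,
              file.path(cfg$outdir, paste0("ssr_summary_", sp, ".tsv")))
    report[[paste0("species_", sp)]] <- list(
      n_snp_calls = snp_sum$n_calls,
      one_per_bp = snp_sum$one_per_bp,
      snp_types = stats::setNames(as.list(snp_sum$by_type$n),
                                  snp_sum$by_type$type),
      n_ssr_loci = nrow(loci),
      ssr_classes = if (nrow(ssr_sum))
        stats::setNames(as.list(ssr_sum$count), ssr_sum$ssr_type)
      else list())
  }
  write_report(report, file.path(cfg$outdir, "markers.json"))
  log_msg("run_markers done")
  invisible(report)
}
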