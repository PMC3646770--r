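# SNP and indel calling from per-position allele counts, using joint depth
# and minor-allele-frequency thresholds, with type classification
# (transition / transversion / indel) and a frequency summary.

ALLELE_ORDER <- c("A", "C", "G", "T", "del", "ins")

#' Call SNPs and indels from an allele-count pileup
#'
#' A site is called iff the two most frequent alleles each have at least
#' \code{min_reads_per_allele} reads AND the minor allele frequency is at
#' least \code{min_maf} (both thresholds inclusive).  By default the MAF
#' denominator is the depth of the top two alleles; reads of any third
#' allele are ignored for the call but counted in the \code{other_reads} QC
#' column.  Ties in allele counts are resolved in the fixed order A, C, G,
#' T, del, ins, so calls are invariant to permutation of the input columns.
#'
#' @param pileup data.frame from \code{\link{read_pileup}} or
#'   \code{\link{simulate_pileup}}, sorted by (contig, pos).
#' @param min_reads_per_allele Minimum reads for each of the two alleles
#'   (default 8).
#' @param min_maf Minimum minor allele frequency (default 0.25).
#' @param maf_denominator \code{"top_two"} (default) or \code{"total"}.
#' @return data.frame (contig, pos, ref_allele, alt_allele, ref_reads,
#'   alt_reads, other_reads, depth, maf, type).
#' @export
call_snps <- function(pileup, min_reads_per_allele = 8, min_maf = 0.25,
                      maf_denominator = c("top_two", "total")) {
  maf_denominator <- match.arg(maf_denominator)
  o <- order(pileup$contig, pileup$pos)
  if (any(o != seq_len(nrow(pileup))))
    stop("pileup is not sorted by (contig, pos)")
  cnt <- as.matrix(pileup[, c("countA", "countC", "countG", "countT",
                              "countDel", "countIns")])
  colnames(cnt) <- ALLELE_ORDER
  if (any(cnt < 0)) stop("negative allele counts")
  depth <- rowSums(cnt)
  # top two alleles with deterministic tie-break on the fixed allele order
  rank2 <- t(apply(cnt, 1, function(x) order(-x, seq_along(x))[1:2]))
  c1 <- cnt[cbind(seq_len(nrow(cnt)), rank2[, 1])]
  c2 <- cnt[cbind(seq_len(nrow(cnt)), rank2[, 2])]
  denom <- if (maf_denominator == "top_two") c1 + c2 else depth
  maf <- ifelse(denom > 0, c2 / denom, 0)
  called <- c2 >= min_reads_per_allele & c1 >= min_reads_per_allele &
    maf >= min_maf
  idx <- which(called)
  ref <- ALLELE_ORDER[rank2[idx, 1]]
  alt <- ALLELE_ORDER[rank2[idx, 2]]
  out <- data.frame(
    contig = pileup$contig[idx], pos = pileup$pos[idx],
    ref_allele = ref, alt_allele = alt,
    ref_reads = c1[idx], alt_reads = c2[idx],
    other_reads = depth[idx] - c1[idx] - c2[idx],
    depth = depth[idx], maf = maf[idx],
    type = mapply(classify_snp, ref, alt, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a variant by its allele pair
#'
#' A-G and C-T pairs are transitions, other base pairs transversions, and
#' anything involving a deletion or insertion allele is an indel.
#'
#' @param ref,alt Alleles (A/C/G/T/del/ins).
#' @return One of \code{"transition"}, \code{"transversion"},
#'   \code{"indel"}.
#' @export
classify_snp <- function(ref, alt) {
  if (!ref %in% ALLELE_ORDER || !alt %in% ALLELE_ORDER)
    stop("unknown allele: ", ref, "/", alt)
  if (ref %in% c("del", "ins") || alt %in% c("del", "ins")) return("indel")
  if ((ref %in% PURINES) == (alt %in% PURINES)) "transition" else "transversion"
}

#' Summarise SNP calls
#'
#' Counts and proportions per variant type, plus the overall frequency
#' expressed as "one per X bp" with
#' \code{X = round(total_assembled_bp / n_calls)}.
#'
#' @param calls data.frame from \code{\link{call_snps}}.
#' @param total_assembled_bp Total assembled length the calls were screened
#'   over.
#' @return List with \code{by_type} (data.frame type, n, proportion),
#'   \code{n_calls}, \code{total_assembled_bp} and \code{one_per_bp} (NA
#'   when there are no calls).
#' @export
snp_summary <- function(calls, total_assembled_bp) {
  stopifnot(total_assembled_bp > 0)
  types <- c("transition", "transversion", "indel")
  n <- vapply(types, function(t) sum(calls$type == t), integer(1))
  total <- nrow(calls)
  list(
    by_type = data.frame(type = types, n = unname(n),
                         proportion = if (total) unname(n) / total
                                      else rep(NA_real_, 3),
                         stringsAsFactors = FALSE),
    n_calls = total,
    total_assembled_bp = total_assembled_bp,
    one_per_bp = if (total) round(total_assembled_bp / total) else NA_real_)
}

#' Write SNP calls as a minimal VCF 4.2
#'
#' Substitutions carry their alleles; deletion and insertion calls use the
#' symbolic alleles \code{<DEL>} and \code{<INS>}.  INFO holds DP (top-two
#' depth) and AF (minor allele frequency).
#'
#' @param calls data.frame from \code{\link{call_snps}}.
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Top-two allele depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    ref <- ifelse(calls$ref_allele %in% c("del", "ins"), "N",
                  calls$ref_allele)
    alt <- ifelse(calls$alt_allele == "del", "<DEL>",
                  ifelse(calls$alt_allele == "ins", "<INS>",
                         calls$alt_allele))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                       calls$contig, calls$pos + 1L, ref, alt,
                       calls$ref_reads + calls$alt_reads, calls$maf), con)
  }
  invisible(path)
}
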