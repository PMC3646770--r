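# Perfect microsatellite (SSR) detection for motif lengths 2-6 bp, with
# canonical motif classes (rotation + reverse complement) and a per-class
# summary.  Thresholds follow the common EST-screening convention: minimum
# total tract length 15 bp AND minimum 3 repeats, applied jointly.

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch)
           paste(rev(ch), collapse = ""), character(1)))
}

rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substr(motif, k + 1L, n), substr(motif, 1L, k)), character(1))
}

smallest_period <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), n %/% p)) return(p)
  }
  n
}

#' Canonical motif class
#'
#' The lexicographically smallest string among all rotations of the motif
#' and all rotations of its reverse complement; repeats of e.g. TA and GAT
#' thereby fall into the classes AT and ATC.
#'
#' @param motif Repeat unit over A/C/G/T, length 2-6, not itself a
#'   repetition of a shorter unit.
#' @return Character scalar: the canonical class.
#' @export
canonical_motif <- function(motif) {
  n <- nchar(motif)
  if (n < 2 || n > 6) stop("motif length must be in [2, 6]")
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  if (smallest_period(motif) < n)
    stop("motif ", motif, " is a repetition of a shorter unit")
  min(c(rotations(motif), rotations(revcomp_chr(motif))))
}

# Maximal perfect tandem tracts of period m in one sequence, with a
# fractional trailing partial repeat.  Returns 0-based half-open spans.
scan_period <- function(seq, m, count_partial = TRUE) {
  re <- sprintf("([ACGT]{%d})\\1+", m)
  hits <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  starts <- as.vector(hits)
  lens <- attr(hits, "match.length")
  n <- nchar(seq)
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    st <- starts[i]; L <- lens[i]
    motif <- substr(seq, st, st + m - 1L)
    if (smallest_period(motif) < m) next
    # extend with a trailing partial repeat
    j <- st + L
    while (j <= n && substr(seq, j, j) ==
           substr(motif, ((j - st) %% m) + 1L, ((j - st) %% m) + 1L)) {
      L <- L + 1L; j <- j + 1L
    }
    total_len <- if (count_partial) L else (L %/% m) * m
    rows[[i]] <- data.frame(
      start = st - 1L, end = st - 1L + total_len, motif = motif,
      n_repeats = total_len / m, total_len = total_len,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Find perfect SSR tracts in a sequence
#'
#' Scans for maximal perfect tandem repeats of 2-6 bp motifs.  A trailing
#' partial repeat extends the tract (and the repeat count, fractionally)
#' unless \code{count_partial} is FALSE.  A tract is reported iff its total
#' length is at least \code{min_total_len} AND its repeat count at least
#' \code{min_repeats}.  Where a region qualifies under several motif
#' lengths the shortest period wins; remaining overlaps are resolved
#' left-to-right, longest tract first.  Positions with ambiguity codes
#' break tracts.
#'
#' @param sequence Character scalar (or DNAString).
#' @param min_total_len Minimum tract length in bp (default 15).
#' @param min_repeats Minimum number of repeats (default 3).
#' @param motif_lens Motif lengths to scan (default 2:6).
#' @param count_partial Count a trailing partial repeat toward the tract
#'   (default TRUE).
#' @return data.frame (start, end, motif, canonical_class, n_repeats,
#'   total_len), 0-based half-open, sorted by start.
#' @export
find_ssrs <- function(sequence, min_total_len = 15, min_repeats = 3,
                      motif_lens = 2:6, count_partial = TRUE) {
  seq <- toupper(as.character(sequence))
  loci <- list()
  for (m in sort(motif_lens)) {
    found <- scan_period(seq, m, count_partial)
    if (!is.null(found)) {
      found$period <- m
      loci[[length(loci) + 1L]] <- found
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), canonical_class = character(0),
                      n_repeats = numeric(0), total_len = integer(0))
  if (!length(loci)) return(empty)
  loci <- do.call(rbind, loci)
  loci <- loci[loci$total_len >= min_total_len &
               loci$n_repeats >= min_repeats, , drop = FALSE]
  if (!nrow(loci)) return(empty)
  # shortest period first, then left-to-right, longest first
  loci <- loci[order(loci$period, loci$start, -loci$total_len), , drop = FALSE]
  kept <- logical(nrow(loci))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(loci))) {
    s <- loci$start[i]; e <- loci$end[i]
    if (!nrow(occupied) ||
        all(e <= occupied[, 1] | occupied[, 2] <= s)) {
      kept[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  loci <- loci[kept, , drop = FALSE]
  loci$canonical_class <- vapply(loci$motif, canonical_motif, character(1))
  loci <- loci[order(loci$start), c("start", "end", "motif",
                                    "canonical_class", "n_repeats",
                                    "total_len")]
  rownames(loci) <- NULL
  loci
}

#' Scan a sequence collection for SSRs
#'
#' @param fasta DNAStringSet or named character vector.
#' @param ... Passed to \code{\link{find_ssrs}}.
#' @return data.frame with a \code{seq_id} column prepended.
#' @export
scan_ssrs <- function(fasta, ...) {
  seqs <- if (methods::is(fasta, "DNAStringSet"))
    stats::setNames(as.character(fasta), names(fasta)) else fasta
  out <- lapply(names(seqs), function(id) {
    f <- find_ssrs(seqs[[id]], ...)
    if (nrow(f)) cbind(seq_id = id, f, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      canonical_class = character(0),
                      n_repeats = numeric(0), total_len = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise SSR loci by motif-length class
#'
#' For each motif length (dinucleotides ... hexanucleotides): the number of
#' distinct canonical motifs, the total locus count, and the most frequent
#' canonical motif (ties broken lexicographically and flagged).
#'
#' @param loci data.frame from \code{\link{find_ssrs}} or
#'   \code{\link{scan_ssrs}}.
#' @return data.frame (ssr_type, motif_length, n_motifs, count,
#'   major_motif, major_tie).
#' @export
ssr_summary <- function(loci) {
  type_names <- c(`2` = "Dinucleotides", `3` = "Trinucleotides",
                  `4` = "Tetranucleotides", `5` = "Pentanucleotides",
                  `6` = "Hexanucleotides")
  if (!nrow(loci))
    return(data.frame(ssr_type = character(0), motif_length = integer(0),
                      n_motifs = integer(0), count = integer(0),
                      major_motif = character(0), major_tie = logical(0)))
  ml <- nchar(loci$canonical_class)
  rows <- lapply(sort(unique(ml)), function(m) {
    cls <- loci$canonical_class[ml == m]
    tab <- sort(table(cls), decreasing = TRUE)
    top <- tab[tab == max(tab)]
    data.frame(ssr_type = unname(type_names[as.character(m)]),
               motif_length = m, n_motifs = length(tab),
               count = length(cls),
               major_motif = min(names(top)),
               major_tie = length(top) > 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
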