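# Codon-level machinery shared by the simulator and the Ka/Ks estimators:
# the standard genetic code, single-nucleotide codon neighbourhoods, and
# pathway enumerations between codon pairs.  Everything is precomputed once
# per session and cached.

.compara_cache <- new.env(parent = emptyenv())

PURINES <- c("A", "G")

#' Standard genetic code tables
#'
#' Internal accessor for the standard genetic code as used throughout the
#' package: the 64 codons, their amino acids, and the 61 sense codons with
#' a stable index (alphabetical codon order, as in
#' \code{Biostrings::GENETIC_CODE}).
#'
#' @return A list with elements \code{codons}, \code{aa}, \code{sense}
#'   (61 sense codons), \code{sense_aa}, and \code{index} (named integer
#'   vector mapping sense codon string to its 1..61 index).
#' @keywords internal
codon_tables <- function() {
  ct <- .compara_cache$codon_tables
  if (!is.null(ct)) return(ct)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  ct <- list(
    codons = codons,
    aa = aa,
    sense = sense,
    sense_aa = aa[aa != "*"],
    index = stats::setNames(seq_along(sense), sense),
    stops = codons[aa == "*"]
  )
  .compara_cache$codon_tables <- ct
  ct
}

is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES) & b1 != b2
}

#' Single-nucleotide codon neighbourhood
#'
#' For each of the 61 sense codons, lists the 9 codons reachable by a single
#' nucleotide change, with the change classified as transition/transversion
#' and synonymous/nonsynonymous.  Changes into stop codons are recorded
#' (\code{to_stop = TRUE}) and treated as nonsynonymous.
#'
#' @return A data.frame with one row per (codon, position, alternative base):
#'   \code{from} (1..61 sense index), \code{pos} (1..3), \code{to_codon},
#'   \code{to} (sense index or NA), \code{is_ts}, \code{is_syn},
#'   \code{to_stop}.
#' @keywords internal
codon_neighbors <- function() {
  nb <- .compara_cache$codon_neighbors
  if (!is.null(nb)) return(nb)
  ct <- codon_tables()
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", 61L * 9L)
  k <- 0L
  for (i in seq_along(ct$sense)) {
    cod <- strsplit(ct$sense[i], "")[[1]]
    aa_from <- ct$sense_aa[i]
    for (pos in 1:3) {
      for (b in setdiff(bases, cod[pos])) {
        tc <- cod
        tc[pos] <- b
        tcod <- paste(tc, collapse = "")
        aa_to <- ct$aa[match(tcod, ct$codons)]
        k <- k + 1L
        rows[[k]] <- data.frame(
          from = i, pos = pos, to_codon = tcod,
          to = if (aa_to == "*") NA_integer_ else unname(ct$index[tcod]),
          is_ts = is_transition(cod[pos], b),
          is_syn = aa_to != "*" && aa_to == aa_from,
          to_stop = aa_to == "*",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  nb <- do.call(rbind, rows)
  .compara_cache$codon_neighbors <- nb
  nb
}

# NG86 per-codon synonymous site counts: per position, the fraction of the
# three possible changes that are synonymous; stops count as nonsynonymous.
ng86_syn_sites <- function() {
  s <- .compara_cache$ng86_syn_sites
  if (!is.null(s)) return(s)
  nb <- codon_neighbors()
  s <- as.vector(rowsum(as.numeric(nb$is_syn), nb$from)) / 3
  .compara_cache$ng86_syn_sites <- s
  s
}

# All orderings of k positions, k <= 3.
.position_perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Enumerate mutational pathways from codon string c1 to c2 (both sense).
# Returns a list of pathways; each pathway is a data.frame of steps with
# columns from_codon, to_codon, is_ts, is_syn, via_stop (whether the step's
# TARGET is a stop; endpoint codons are sense so only intermediates can be).
enumerate_paths <- function(c1, c2) {
  ct <- codon_tables()
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  d <- which(a1 != a2)
  k <- length(d)
  if (k == 0L) return(list())
  perms <- .position_perms[[as.character(k)]]
  lapply(perms, function(ord) {
    cur <- a1
    steps <- vector("list", k)
    for (s in seq_len(k)) {
      pos <- d[ord[s]]
      nxt <- cur
      nxt[pos] <- a2[pos]
      from_cod <- paste(cur, collapse = "")
      to_cod <- paste(nxt, collapse = "")
      aa_from <- ct$aa[match(from_cod, ct$codons)]
      aa_to <- ct$aa[match(to_cod, ct$codons)]
      steps[[s]] <- data.frame(
        from_codon = from_cod, to_codon = to_cod,
        is_ts = is_transition(cur[pos], nxt[pos]),
        is_syn = aa_from != "*" && aa_to != "*" && aa_from == aa_to,
        via_stop = aa_to == "*" || aa_from == "*",
        stringsAsFactors = FALSE
      )
      cur <- nxt
    }
    do.call(rbind, steps)
  })
}

# NG86 pairwise difference matrices: for every sense codon pair, the average
# numbers of synonymous and nonsynonymous differences over all shortest
# mutational pathways (equal weights; pathways through stop codons excluded
# unless none remain).
ng86_diff_matrices <- function() {
  m <- .compara_cache$ng86_diff
  if (!is.null(m)) return(m)
  ct <- codon_tables()
  n <- length(ct$sense)
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      paths <- enumerate_paths(ct$sense[i], ct$sense[j])
      ok <- !vapply(paths, function(p) any(p$via_stop), logical(1))
      if (any(ok)) paths <- paths[ok]
      syn <- vapply(paths, function(p) sum(p$is_syn), numeric(1))
      tot <- vapply(paths, function(p) nrow(p), numeric(1))
      Sd[i, j] <- Sd[j, i] <- mean(syn)
      Nd[i, j] <- Nd[j, i] <- mean(tot - syn)
    }
  }
  m <- list(Sd = Sd, Nd = Nd)
  .compara_cache$ng86_diff <- m
  m
}

# Flattened directed pathway table used by the YN00 iteration.  For every
# ordered sense codon pair (i, j), i != j, all mutational pathways are laid
# out with up to three steps; per-step attributes allow the pathway weight
# pi[target] * kappa^is_ts * omega^(!is_syn) to be evaluated vectorised.
# Pathways through stop codons are dropped (if a pair would lose all its
# pathways they are all kept instead).  Per-path difference-category counts
# (syn ts, syn tv, nonsyn ts, nonsyn tv) are precomputed.
yn00_path_table <- function() {
  pt <- .compara_cache$yn00_paths
  if (!is.null(pt)) return(pt)
  ct <- codon_tables()
  n <- length(ct$sense)
  cod_idx <- ct$index

  pair_key <- integer(0)
  step_to <- matrix(NA_integer_, 0, 3)   # sense index of each step's target
  step_ts <- matrix(NA, 0, 3)
  step_syn <- matrix(NA, 0, 3)
  cnt <- matrix(0, 0, 4)                 # ts_syn, tv_syn, ts_non, tv_non

  keys <- list(); tos <- list(); tss <- list(); syns <- list(); cnts <- list()
  b <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      paths <- enumerate_paths(ct$sense[i], ct$sense[j])
      ok <- !vapply(paths, function(p) any(p$via_stop), logical(1))
      if (any(ok)) paths <- paths[ok]
      np <- length(paths)
      to_m <- matrix(NA_integer_, np, 3)
      ts_m <- matrix(FALSE, np, 3)
      sy_m <- matrix(TRUE, np, 3)        # neutral defaults: weight factor 1
      c_m <- matrix(0, np, 4)
      for (p in seq_len(np)) {
        st <- paths[[p]]
        for (s in seq_len(nrow(st))) {
          to_m[p, s] <- unname(cod_idx[st$to_codon[s]])
          ts_m[p, s] <- st$is_ts[s]
          sy_m[p, s] <- st$is_syn[s]
        }
        c_m[p, ] <- c(sum(st$is_syn & st$is_ts), sum(st$is_syn & !st$is_ts),
                      sum(!st$is_syn & st$is_ts), sum(!st$is_syn & !st$is_ts))
      }
      b <- b + 1L
      keys[[b]] <- rep.int((i - 1L) * n + j, np)
      tos[[b]] <- to_m; tss[[b]] <- ts_m; syns[[b]] <- sy_m; cnts[[b]] <- c_m
    }
  }
  pt <- list(
    pair_key = unlist(keys),
    step_to = do.call(rbind, tos),
    step_ts = do.call(rbind, tss),
    step_syn = do.call(rbind, syns),
    counts = do.call(rbind, cnts),
    n_sense = n
  )
  .compara_cache$yn00_paths <- pt
  pt
}

# Degeneracy classes used for the YN00 kappa estimate: for each sense codon
# and position, whether the position is nondegenerate (every change is
# nonsynonymous) or, at position 3, fourfold degenerate (every change is
# synonymous).
codon_degeneracy <- function() {
  dg <- .compara_cache$degeneracy
  if (!is.null(dg)) return(dg)
  nb <- codon_neighbors()
  nondeg <- matrix(FALSE, 61, 3)
  fourfold <- rep(FALSE, 61)
  for (i in 1:61) {
    for (pos in 1:3) {
      rows <- nb$from == i & nb$pos == pos
      nondeg[i, pos] <- !any(nb$is_syn[rows])
      if (pos == 3L) fourfold[i] <- all(nb$is_syn[rows])
    }
  }
  dg <- list(nondeg = nondeg, fourfold = fourfold)
  .compara_cache$degeneracy <- dg
  dg
}

# Split codon strings "ATGAAA..." into a character matrix of codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0)
    stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

codon_indices <- function(codons) {
  ct <- codon_tables()
  unname(ct$index[codons])
}
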