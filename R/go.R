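# Gene Ontology utilities: a minimal OBO reader (is_a edges only), term
# levels by shortest path from the namespace root, level-k rollup profiles,
# and hypergeometric enrichment of gene sets.

#' Load a minimal OBO ontology
#'
#' Parses \code{[Term]} stanzas with \code{id}, \code{name},
#' \code{namespace} and \code{is_a} lines (other lines and relationship
#' types are ignored; obsolete terms are skipped).  The resulting graph must
#' be acyclic; terms with no path to a root produce a warning when levels
#' are computed.
#'
#' @param x Path to an OBO file, or the OBO text itself (character scalar
#'   containing newlines).
#' @return An object of class \code{go_graph}: list with \code{terms}
#'   (data.frame id, name, namespace) and \code{parents} (named list of
#'   character vectors).
#' @export
load_obo <- function(x) {
  lines <- if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else readLines(x)
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  ends <- c(which(grepl("^\\[", lines) & lines != "[Term]"),
            length(lines) + 1L)
  ids <- names <- namespaces <- character(0)
  parents <- list()
  for (si in seq_along(starts)) {
    s <- starts[si]
    e <- min(c(starts[starts > s], ends[ends > s])) - 1L
    stanza <- lines[(s + 1L):e]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ":"), stanza, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    if (any(grepl("^is_obsolete: *true", stanza))) next
    id <- get1("id")
    if (is.na(id)) stop("OBO stanza ", si, " lacks an id")
    ns <- get1("namespace")
    if (is.na(ns)) stop("OBO stanza for ", id, " lacks a namespace")
    isa <- sub("\\s*!.*$", "",
               sub("^is_a: *", "", grep("^is_a:", stanza, value = TRUE)))
    ids <- c(ids, id); names <- c(names, get1("name"))
    namespaces <- c(namespaces, ns)
    parents[[id]] <- isa
  }
  g <- structure(list(
    terms = data.frame(id = ids, name = names, namespace = namespaces,
                       stringsAsFactors = FALSE),
    parents = parents,
    cache = new.env(parent = emptyenv())
  ), class = "go_graph")
  if (has_cycle(g)) stop("is_a cycle detected in ontology")
  g
}

# DFS cycle check over the is_a edges.
has_cycle <- function(graph) {
  color <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- mget(id, color, ifnotfound = "white")[[1]]
    if (st == "grey") return(TRUE)
    if (st == "black") return(FALSE)
    assign(id, "grey", color)
    for (p in graph$parents[[id]])
      if (!is.null(graph$parents[[p]]) || p %in% graph$terms$id)
        if (visit(p)) return(TRUE)
    assign(id, "black", color)
    FALSE
  }
  any(vapply(graph$terms$id, visit, logical(1)))
}

# Levels of all terms: roots (no parents) are level 1; every other term is
# 1 + the length of the SHORTEST is_a path to a root.  Computed once per
# graph and cached.  Terms that cannot reach a root get NA with a warning.
term_levels <- function(graph) {
  lv <- graph$cache$levels
  if (!is.null(lv)) return(lv)
  ids <- graph$terms$id
  lv <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[vapply(ids, function(i) length(graph$parents[[i]]) == 0L,
                      logical(1))]
  lv[roots] <- 1L
  children <- list()
  for (id in ids) for (p in graph$parents[[id]])
    children[[p]] <- c(children[[p]], id)
  frontier <- roots
  level <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier]))
    nxt <- nxt[is.na(lv[nxt])]
    level <- level + 1L
    lv[nxt] <- level
    frontier <- nxt
  }
  if (anyNA(lv))
    warning(sum(is.na(lv)), " term(s) cannot reach a namespace root")
  graph$cache$levels <- lv
  lv
}

#' Level of a GO term
#'
#' The namespace root has level 1; every other term has level 1 + the
#' length of the shortest is_a path to the root.
#'
#' @param graph A \code{go_graph}.
#' @param term_id Term id.
#' @return Integer level.
#' @export
term_level <- function(graph, term_id) {
  if (!term_id %in% graph$terms$id) stop("term ", term_id, " not in graph")
  lv <- term_levels(graph)[[term_id]]
  if (is.na(lv)) stop("term ", term_id, " cannot reach a namespace root")
  lv
}

# All is_a ancestors of a term, including itself; memoised per graph.
term_ancestors <- function(graph, term_id) {
  anc_env <- graph$cache$ancestors
  if (is.null(anc_env)) {
    anc_env <- new.env(parent = emptyenv())
    graph$cache$ancestors <- anc_env
  }
  got <- mget(term_id, anc_env, ifnotfound = list(NULL))[[1]]
  if (!is.null(got)) return(got)
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier])), seen)
  }
  assign(term_id, seen, anc_env)
  seen
}

# Split semicolon-joined GO ids; accepts a data.frame with gene/go_terms
# columns (gene or transcript_id) or a named list of character vectors.
annotation_sets <- function(annotations) {
  if (is.data.frame(annotations)) {
    gene_col <- intersect(c("gene", "transcript_id"), names(annotations))[1]
    sets <- strsplit(annotations$go_terms, ";", fixed = TRUE)
    sets <- lapply(sets, function(x) x[nzchar(x)])
    names(sets) <- annotations[[gene_col]]
    sets
  } else annotations
}

#' Roll GO annotations up to an ontology level
#'
#' Each annotated term is propagated to all of its ancestors at the
#' requested level; a gene counts once per level-k term (a term with several
#' level-k ancestors contributes to each, so counts may exceed gene totals).
#' Fractions are relative to the number of annotated genes per namespace.
#'
#' @param annotations data.frame (gene/transcript_id, go_terms
#'   semicolon-joined) or named list of term-id vectors.
#' @param graph A \code{go_graph}.
#' @param level Target level (>= 2).
#' @return data.frame (namespace, term_id, name, n_genes, fraction), sorted
#'   by namespace then decreasing count.
#' @export
rollup_to_level <- function(annotations, graph, level = 3L) {
  stopifnot(level >= 2)
  sets <- annotation_sets(annotations)
  lv <- term_levels(graph)
  ns <- stats::setNames(graph$terms$namespace, graph$terms$id)
  n_unknown <- 0L
  per_gene <- lapply(sets, function(terms) {
    known <- terms[terms %in% graph$terms$id]
    n_unknown <<- n_unknown + (length(terms) - length(known))
    anc <- unique(unlist(lapply(known, term_ancestors, graph = graph)))
    anc[!is.na(lv[anc]) & lv[anc] == level]
  })
  counts <- table(unlist(per_gene))
  if (n_unknown) warning(n_unknown, " annotation term(s) not in the graph")
  if (!length(counts))
    return(data.frame(namespace = character(0), term_id = character(0),
                      name = character(0), n_genes = integer(0),
                      fraction = numeric(0)))
  term_id <- names(counts)
  namespace <- unname(ns[term_id])
  # genes annotated (anywhere) per namespace
  gene_ns <- lapply(sets, function(terms) {
    known <- terms[terms %in% graph$terms$id]
    unique(unname(ns[known]))
  })
  ns_totals <- table(unlist(gene_ns))
  out <- data.frame(
    namespace = namespace, term_id = term_id,
    name = graph$terms$name[match(term_id, graph$terms$id)],
    n_genes = as.integer(counts),
    fraction = as.integer(counts) / as.numeric(ns_totals[namespace]),
    stringsAsFactors = FALSE)
  out <- out[order(out$namespace, -out$n_genes, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO enrichment
#'
#' Annotations are propagated to all ancestors before counting.  For each
#' term carried by at least one study gene, the upper-tail hypergeometric
#' probability of observing at least k study genes with the term is
#' computed: p = sum_{i = k}^{min(n, K)} C(K, i) C(N - K, n - i) / C(N, n),
#' with N the population size, K the population genes with the term and n
#' the study size.
#'
#' @param study Character vector of study genes (must be a subset of the
#'   population).
#' @param population Character vector of population genes.
#' @param annotations data.frame or named list (see
#'   \code{\link{rollup_to_level}}).
#' @param graph A \code{go_graph}.
#' @param alpha Significance level used for the \code{significant} flag.
#' @param p_adjust If TRUE, Benjamini-Hochberg adjust p-values.
#' @return data.frame (term_id, name, namespace, k, n, K, N, p_value,
#'   significant), sorted by p-value.
#' @export
hypergeometric_enrichment <- function(study, population, annotations, graph,
                                      alpha = 0.05, p_adjust = FALSE) {
  if (!all(study %in% population))
    stop("study set is not a subset of the population")
  sets <- annotation_sets(annotations)
  prop <- lapply(sets, function(terms) {
    known <- terms[terms %in% graph$terms$id]
    unique(unlist(lapply(known, term_ancestors, graph = graph)))
  })
  pop_sets <- prop[intersect(population, names(prop))]
  study_sets <- prop[intersect(study, names(prop))]
  N <- length(population)
  n <- length(study)
  K <- table(unlist(pop_sets))
  k <- table(unlist(study_sets))
  if (!length(k))
    return(data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), significant = logical(0)))
  term_id <- names(k)
  kk <- as.integer(k)
  KK <- as.integer(K[term_id])
  p <- stats::phyper(kk - 1L, KK, N - KK, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = term_id,
    name = graph$terms$name[match(term_id, graph$terms$id)],
    namespace = graph$terms$namespace[match(term_id, graph$terms$id)],
    k = kk, n = n, K = KK, N = N, p_value = p,
    stringsAsFactors = FALSE)
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
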