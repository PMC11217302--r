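# Confidence-weighted de Bruijn assembly of predicted peptides into
# contigs: k-mers are nodes, (k+1)-mer overlaps are edges, weights sum the
# per-window prediction confidence, and contigs are extracted by greedy
# heaviest-path walks (a simplified reimplementation of the assembler
# stage's input/output contract).

#' Build a confidence-weighted de Bruijn graph from peptides
#'
#' Nodes are k-mers; an edge joins two k-mers that overlap in a
#' (k+1)-mer of some peptide. A node's weight is the sum, over all its
#' occurrences in the peptide set, of the window confidence (mean
#' per-residue confidence across the k residues). Peptides shorter than
#' k are dropped and counted. Because leucine and isoleucine have
#' identical masses, they are collapsed to L before assembly by default
#' (avoids artificial branch points); disable with
#' \code{collapse_il = FALSE}.
#'
#' @param peptides character vector of predicted peptides
#' @param confidences list of per-residue confidence vectors (same
#'   lengths as the peptides), or a single numeric vector of one overall
#'   confidence per peptide
#' @param k k-mer size (default 7)
#' @param ids peptide identifiers (default index); recorded as support
#' @param collapse_il collapse I to L before assembly (default TRUE)
#' @return object of class \code{debruijn_graph}: node weights, edges,
#'   per-node supporting peptide ids; attribute \code{n_dropped} counts
#'   peptides shorter than k
#' @export
build_graph <- function(peptides, confidences, k = 7L,
                        ids = as.character(seq_along(peptides)),
                        collapse_il = TRUE) {
  stopifnot(k >= 2L, length(peptides) == length(ids))
  if (!is.list(confidences))
    confidences <- lapply(seq_along(peptides), function(i)
      rep(confidences[i], nchar(peptides[i])))
  stopifnot(length(confidences) == length(peptides))
  if (collapse_il) peptides <- gsub("I", "L", peptides, fixed = TRUE)

  too_short <- nchar(peptides) < k
  n_dropped <- sum(too_short)
  if (n_dropped)
    message(n_dropped, " peptide(s) shorter than k = ", k, " dropped")
  node_w <- new.env(parent = emptyenv())
  node_support <- new.env(parent = emptyenv())
  edge_w <- new.env(parent = emptyenv())
  for (i in which(!too_short)) {
    pep <- peptides[i]
    conf <- confidences[[i]]
    stopifnot(length(conf) == nchar(pep))
    n <- nchar(pep)
    kmers <- substring(pep, 1:(n - k + 1L), k:n)
    wins <- vapply(seq_along(kmers), function(j)
      mean(conf[j:(j + k - 1L)]), numeric(1))
    for (j in seq_along(kmers)) {
      km <- kmers[j]
      node_w[[km]] <- (if (is.null(node_w[[km]])) 0 else node_w[[km]]) + wins[j]
      node_support[[km]] <- union(node_support[[km]], ids[i])
      if (j < length(kmers)) {
        e <- paste0(km, ">", kmers[j + 1L])
        edge_w[[e]] <- (if (is.null(edge_w[[e]])) 0 else edge_w[[e]]) +
          (wins[j] + wins[j + 1L]) / 2
      }
    }
  }
  nodes <- ls(node_w)
  weights <- vapply(nodes, function(n) node_w[[n]], numeric(1))
  edges <- ls(edge_w)
  edf <- if (length(edges)) {
    parts <- strsplit(edges, ">", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, character(1), 1L),
               to = vapply(parts, `[`, character(1), 2L),
               weight = vapply(edges, function(e) edge_w[[e]], numeric(1)),
               row.names = NULL)
  } else data.frame(from = character(0), to = character(0),
                    weight = numeric(0))
  structure(list(k = as.integer(k),
                 nodes = stats::setNames(unname(weights), nodes),
                 edges = edf,
                 support = stats::setNames(
                   lapply(nodes, function(n) node_support[[n]]), nodes)),
            class = "debruijn_graph", n_dropped = n_dropped)
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("debruijn_graph: k=%d, %d nodes, %d edges\n",
              x$k, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract contigs by greedy heaviest-path walks
#'
#' Repeatedly seeds at the heaviest unvisited node and extends in both
#' directions, always stepping to the heaviest unvisited neighbour
#' (lighter branches -- low-confidence spurs -- are not traversed).
#' Visited nodes are consumed, so contigs never share a node. Contigs
#' are ranked by score (sum of member node weights) and the top_n kept.
#'
#' @param graph a \code{\link{build_graph}} result
#' @param top_n contigs to keep (default 20, the depth typically carried
#'   into protein inference)
#' @return data.frame: \code{contig}, \code{score}, \code{n_support},
#'   and list-column \code{support} (contributing peptide ids), ranked
#'   by score; zero rows for an empty graph
#' @export
extract_contigs <- function(graph, top_n = 20L) {
  nodes <- graph$nodes
  if (!length(nodes)) {
    out <- data.frame(contig = character(0), score = numeric(0),
                      n_support = integer(0))
    out$support <- list()
    return(out)
  }
  succ <- split(graph$edges$to, graph$edges$from)
  pred <- split(graph$edges$from, graph$edges$to)
  visited <- stats::setNames(rep(FALSE, length(nodes)), names(nodes))
  contigs <- list()
  ord <- names(sort(nodes, decreasing = TRUE))
  for (seed in ord) {
    if (visited[seed]) next
    path <- seed
    visited[seed] <- TRUE
    repeat {   # extend right
      nxt <- setdiff(succ[[path[length(path)]]], names(visited)[visited])
      if (!length(nxt)) break
      best <- nxt[order(-nodes[nxt], nxt)][1L]
      path <- c(path, best)
      visited[best] <- TRUE
    }
    repeat {   # extend left
      prv <- setdiff(pred[[path[1L]]], names(visited)[visited])
      if (!length(prv)) break
      best <- prv[order(-nodes[prv], prv)][1L]
      path <- c(best, path)
      visited[best] <- TRUE
    }
    seqn <- paste0(path[1L],
                   paste(substring(path[-1L], graph$k, graph$k),
                         collapse = ""))
    contigs[[length(contigs) + 1L]] <- list(
      contig = seqn,
      score = sum(nodes[path]),
      support = sort(unique(unlist(graph$support[path]))),
      path = path)
  }
  ordc <- order(-vapply(contigs, `[[`, numeric(1), "score"))
  contigs <- contigs[ordc][seq_len(min(top_n, length(contigs)))]
  out <- data.frame(
    contig = vapply(contigs, `[[`, character(1), "contig"),
    score = vapply(contigs, `[[`, numeric(1), "score"),
    n_support = vapply(contigs, function(cg) length(cg$support), integer(1)))
  out$support <- lapply(contigs, `[[`, "support")
  attr(out, "paths") <- lapply(contigs, `[[`, "path")
  out
}
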