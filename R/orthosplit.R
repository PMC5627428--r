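#' Species-overlap classification of gene-tree nodes
#'
#' Classifies every internal node of a rooted gene family tree as a
#' speciation or a duplication with the species-overlap (SO) algorithm. For
#' a node, the overlap set is the set of species present in at least two of
#' its child subtrees (this generalizes the left/right definition to
#' multifurcations), and the overlap score is the overlap size divided by
#' the size of the union of the child species sets. A node is a duplication
#' when its score exceeds \code{threshold}; at the default threshold of 0.0
#' any non-empty overlap is a duplication.
#'
#' @param tree rooted gene family tree (\code{phylo}).
#' @param map a \code{species_map} for the gene leaves.
#' @param threshold species-overlap score threshold in \code{[0, 1)}.
#' @return a data frame of class \code{node_events}, one row per internal
#'   node: \code{node} (ape node number), \code{n_children},
#'   \code{overlap_size}, \code{union_size}, \code{overlap_score},
#'   \code{event} ("speciation"/"duplication") and
#'   \code{paralog_generating} (filled by
#'   \code{\link{find_paralog_generating}}; \code{NA} here). The per-child
#'   species sets are kept in the \code{"child_species_sets"} attribute
#'   (a list indexed by row).
#' @export
so_events <- function(tree, map, threshold = 0) {
  stopifnot(inherits(tree, "phylo"), threshold >= 0, threshold < 1)
  sp <- map_species(tree, map)
  if (length(attr(sp, "dropped"))) {
    tree <- prune_to_leafset(tree, names(sp))
  }
  ntip <- length(tree$tip.label)
  if (.is_single_tip(tree)) {
    out <- data.frame(node = integer(0), n_children = integer(0),
                      overlap_size = integer(0), union_size = integer(0),
                      overlap_score = numeric(0), event = character(0),
                      paralog_generating = logical(0))
    attr(out, "child_species_sets") <- list()
    class(out) <- c("node_events", "data.frame")
    return(out)
  }
  kids <- .phylo_children(tree)
  # species set per node, bottom-up (postorder over edges)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- unname(sp[tree$tip.label[i]])
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    if (is.null(sets[[p]])) {
      child_sets <- lapply(kids[[p]], function(v) unique(sets[[v]]))
      sets[[p]] <- unique(unlist(child_sets, use.names = FALSE))
    }
  }
  internal <- sort(unique(edge[, 1L]))
  rows <- lapply(internal, function(v) {
    child_sets <- lapply(kids[[v]], function(ch) unique(sets[[ch]]))
    tab <- table(unlist(child_sets, use.names = FALSE))
    overlap <- names(tab)[tab >= 2L]
    uni <- names(tab)
    score <- if (length(uni)) length(overlap) / length(uni) else 0
    is_dup <- if (threshold == 0) length(overlap) > 0L else score > threshold
    list(row = data.frame(node = v, n_children = length(child_sets),
                          overlap_size = length(overlap),
                          union_size = length(uni),
                          overlap_score = score,
                          event = if (is_dup) "duplication" else "speciation",
                          paralog_generating = NA,
                          stringsAsFactors = FALSE),
         sets = child_sets,
         overlap = overlap)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "child_species_sets") <- lapply(rows, `[[`, "sets")
  attr(out, "overlap_sets") <- lapply(rows, `[[`, "overlap")
  class(out) <- c("node_events", "data.frame")
  out
}

#' Find paralog-generating nodes
#'
#' A paralog-generating node is an internal node whose child subtrees share
#' at least \code{min_common} species. With the default \code{min_common =
#' 2} this is the splitting criterion used to carve a gene family tree into
#' ortholog sets while leaving species-specific duplications (overlap of a
#' single species) alone; with \code{min_common = 1} it reduces to plain SO
#' duplication detection at threshold 0.0.
#'
#' @inheritParams so_events
#' @param min_common minimum number of shared species (>= 1).
#' @return the \code{node_events} rows for flagged nodes, with
#'   \code{paralog_generating = TRUE}; the full event table is available in
#'   the \code{"all_events"} attribute.
#' @export
find_paralog_generating <- function(tree, map, min_common = 2L) {
  stopifnot(min_common >= 1L)
  ev <- so_events(tree, map, threshold = 0)
  flag <- ev$overlap_size >= min_common
  out <- ev[flag, , drop = FALSE]
  out$paralog_generating <- rep(TRUE, nrow(out))
  attr(out, "child_species_sets") <- attr(ev, "child_species_sets")[flag]
  attr(out, "all_events") <- ev
  class(out) <- c("node_events", "data.frame")
  out
}

#' Split a gene family tree at chosen nodes
#'
#' Dissolves each flagged node: its child subtrees are released as
#' independent trees and the flagged node disappears (the remainder of the
#' tree, if any, is kept with unary nodes suppressed). Flagged nodes are
#' processed root-first, and released subtrees are re-scanned for remaining
#' flagged nodes, so nested flags are handled deterministically. The
#' returned forest partitions the leaf set.
#'
#' @param tree a \code{phylo} object.
#' @param nodes integer vector of internal node numbers (ape numbering) to
#'   dissolve.
#' @return list of \code{ortholog_set} objects, each with elements
#'   \code{labels} (member leaf labels), \code{tree} (the extracted
#'   \code{phylo}), \code{provenance} (\code{"n<id>.<k>"} for the k-th child
#'   of dissolved node id, or \code{"root"} for the residual part) and
#'   \code{size}.
#' @export
split_at_nodes <- function(tree, nodes) {
  stopifnot(inherits(tree, "phylo"))
  nodes <- as.integer(nodes)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  bad <- nodes[nodes <= ntip | nodes > n_all]
  if (length(bad)) stop("not an internal node of the tree: ",
                        paste(bad, collapse = ", "))
  tn <- .as_tnode(tree)
  sets <- list()
  rec <- function(x) {
    # returns the residual tnode (or NULL if x dissolved entirely);
    # released sets accumulate in `sets`
    if (.tn_is_leaf(x)) return(x)
    if (x$id %in% nodes) {
      # dissolve x: each child's residual is released as an independent tree
      for (k in seq_along(x$children)) {
        rel <- rec(x$children[[k]])
        if (!is.null(rel)) {
          sets[[length(sets) + 1L]] <<-
            .make_ortholog_set(rel, sprintf("n%d.%d", x$id, k))
        }
      }
      return(NULL)
    }
    residuals <- list()
    for (ch in x$children) {
      res <- rec(ch)
      if (!is.null(res)) residuals <- c(residuals, list(res))
    }
    if (length(residuals) == 0L) return(NULL)
    x$children <- residuals
    x
  }
  res <- rec(tn)
  if (!is.null(res)) {
    sets[[length(sets) + 1L]] <- .make_ortholog_set(res, "root")
  }
  all_labels <- sort(unlist(lapply(sets, `[[`, "labels"), use.names = FALSE))
  stopifnot(identical(all_labels, sort(.tree_tips(tree))))
  sets
}

.make_ortholog_set <- function(tn, provenance) {
  tn <- .tn_suppress_unary(tn)
  tn$len <- NA_real_
  labels <- .tn_leaves(tn)
  structure(list(labels = labels, tree = .tnode_to_phylo(tn),
                 provenance = provenance, size = length(labels)),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("Ortholog set (", x$size, " members, from ", x$provenance, "): ",
      paste(utils::head(x$labels, 5L), collapse = ", "),
      if (x$size > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Extract ortholog sets from a gene family tree
#'
#' Finds paralog-generating nodes (child subtrees sharing at least
#' \code{min_common} species) and splits the family tree at them, yielding
#' ortholog sets whose member lists partition the gene leaves.
#'
#' @inheritParams find_paralog_generating
#' @return list of \code{ortholog_set} objects (see
#'   \code{\link{split_at_nodes}}).
#' @export
extract_ortholog_sets <- function(tree, map, min_common = 2L) {
  flagged <- find_paralog_generating(tree, map, min_common)
  if (nrow(flagged) == 0L) {
    tn <- .as_tnode(tree)
    return(list(.make_ortholog_set(tn, "root")))
  }
  split_at_nodes(tree, flagged$node)
}

#' Regraft re-estimated ortholog trees into a family tree
#'
#' Reattaches subtrees (for example ortholog trees re-estimated under a
#' multispecies-coalescent model) at the positions recorded when the family
#' tree was split, restoring a full family tree over the original leaf set.
#' Each replacement subtree must carry exactly the leaf set of the original
#' ortholog set detached at that position.
#'
#' @param parent_backbone the original family tree the split was computed
#'   on (\code{phylo}).
#' @param subtrees list of \code{phylo} replacement trees.
#' @param attachment character vector of provenance ids
#'   (\code{"n<id>.<k>"}) parallel to \code{subtrees}.
#' @return a \code{phylo} family tree.
#' @export
graft_orthologs <- function(parent_backbone, subtrees, attachment) {
  stopifnot(inherits(parent_backbone, "phylo"),
            length(subtrees) == length(attachment))
  tn <- .as_tnode(parent_backbone)
  for (i in seq_along(subtrees)) {
    prov <- attachment[i]
    sub <- subtrees[[i]]
    if (identical(prov, "root")) {
      if (!setequal(.tree_tips(sub), .tree_tips(parent_backbone))) {
        stop("leaf-set mismatch for attachment 'root'")
      }
      tn <- .as_tnode(sub)
      next
    }
    m <- regmatches(prov, regexec("^n([0-9]+)\\.([0-9]+)$", prov))[[1L]]
    if (length(m) != 3L) stop("malformed attachment id: ", prov)
    node_id <- as.integer(m[2L]); child_idx <- as.integer(m[3L])
    new_tn <- .as_tnode(sub)
    tn <- .graft_rec(tn, node_id, child_idx, new_tn, prov)
  }
  .tnode_to_phylo(tn)
}

.graft_rec <- function(x, node_id, child_idx, new_tn, prov) {
  if (x$id == node_id) {
    if (child_idx > length(x$children)) {
      stop("attachment ", prov, ": node has no child ", child_idx)
    }
    old <- x$children[[child_idx]]
    if (!setequal(.tn_leaves(old), .tn_leaves(new_tn))) {
      stop("leaf-set mismatch at attachment ", prov)
    }
    new_tn$len <- old$len
    x$children[[child_idx]] <- new_tn
    return(x)
  }
  x$children <- lapply(x$children, .graft_rec, node_id = node_id,
                       child_idx = child_idx, new_tn = new_tn, prov = prov)
  x
}
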