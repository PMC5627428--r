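#' Non-trivial bipartitions of a tree
#'
#' Returns the set of non-trivial bipartitions (splits) of a tree under the
#' unrooted interpretation: one bipartition per internal edge, with the
#' artificial split at the root merged, and splits with a side smaller than
#' two leaves excluded. Each bipartition is stored as its canonical
#' (lexicographically smaller) side.
#'
#' @param tree a \code{phylo} object.
#' @return an object of class \code{bipartition_set}: list with
#'   \code{universe} (sorted leaf labels), \code{splits} (character keys,
#'   member labels joined by \code{"|"}) and \code{sides} (list of label
#'   vectors).
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  universe <- sort(.tree_tips(tree))
  n <- length(universe)
  if (n < 4L) {
    return(structure(list(universe = universe, splits = character(0),
                          sides = list()), class = "bipartition_set"))
  }
  ntip <- length(tree$tip.label)
  root <- .phylo_root(tree)
  # leaf set below each node, bottom-up
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  internal <- setdiff(unique(edge[, 1L]), root)
  keys <- character(0); sides <- list()
  seen <- new.env(parent = emptyenv())
  for (v in internal) {
    side <- sort(below[[v]])
    if (length(side) < 2L || length(side) > n - 2L) next
    other <- setdiff(universe, side)
    k1 <- paste(side, collapse = "|")
    k2 <- paste(other, collapse = "|")
    if (k2 < k1) { side <- other; k1 <- k2 }
    if (!is.null(seen[[k1]])) next
    assign(k1, TRUE, envir = seen)
    keys <- c(keys, k1)
    sides <- c(sides, list(side))
  }
  structure(list(universe = universe, splits = keys, sides = sides),
            class = "bipartition_set")
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat("Bipartition set:", length(x$splits), "non-trivial splits over",
      length(x$universe), "leaves\n")
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Prunes both trees to their common leaves and computes the symmetric
#' Robinson-Foulds distance on the unrooted interpretation:
#' \code{rf = |B1 symdiff B2|}, \code{max_rf = |B1| + |B2|} (which is
#' \code{2(n-3)} for two binary trees) and \code{nrf = rf / max_rf}. When
#' fewer than four leaves are shared, RF is degenerate and the comparison
#' is flagged as skipped.
#'
#' @param t1,t2 \code{phylo} objects sharing at least one leaf label.
#' @return an object of class \code{distance_report}: list with \code{rf},
#'   \code{max_rf}, \code{nrf}, \code{n_common_leaves}, \code{skipped},
#'   \code{reason}.
#' @export
rf_distance <- function(t1, t2) {
  common <- intersect(.tree_tips(t1), .tree_tips(t2))
  if (length(common) == 0L) stop("trees have no common leaf labels")
  if (length(common) < 4L) {
    return(structure(list(rf = NA_integer_, max_rf = NA_integer_,
                          nrf = NA_real_, n_common_leaves = length(common),
                          skipped = TRUE,
                          reason = "fewer than 4 common leaves"),
                     class = "distance_report"))
  }
  b1 <- bipartitions(prune_to_leafset(t1, common))
  b2 <- bipartitions(prune_to_leafset(t2, common))
  rf <- length(setdiff(b1$splits, b2$splits)) +
        length(setdiff(b2$splits, b1$splits))
  max_rf <- length(b1$splits) + length(b2$splits)
  nrf <- if (max_rf > 0L) rf / max_rf else 0
  structure(list(rf = as.integer(rf), max_rf = as.integer(max_rf),
                 nrf = nrf, n_common_leaves = length(common),
                 skipped = FALSE, reason = NA_character_),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  if (x$skipped) {
    cat("RF comparison skipped (", x$reason, "; ", x$n_common_leaves,
        " common leaves)\n", sep = "")
  } else {
    cat(sprintf("RF = %d / %d (nRF = %.4f) over %d common leaves\n",
                x$rf, x$max_rf, x$nrf, x$n_common_leaves))
  }
  invisible(x)
}

#' Decompose an ortholog tree into single-copy species trees
#'
#' Recursively splits a gene tree at every species-overlap duplication node
#' (score threshold \code{so_threshold}; at 0.0 any non-empty overlap
#' splits). Every returned subtree then contains at most one gene per
#' species, and its leaves are relabelled to species names so it can be
#' compared directly with the species tree.
#'
#' @param ortholog_tree a \code{phylo} gene tree.
#' @param map a \code{species_map}.
#' @param so_threshold species-overlap score threshold.
#' @return list of \code{phylo} trees with species-name leaves.
#' @export
treeko_decompose <- function(ortholog_tree, map, so_threshold = 0) {
  sp <- map_species(ortholog_tree, map)
  if (length(attr(sp, "dropped"))) {
    ortholog_tree <- prune_to_leafset(ortholog_tree, names(sp))
  }
  relabel <- function(tree) {
    tree$tip.label <- unname(sp[tree$tip.label])
    if (anyDuplicated(tree$tip.label)) {
      stop("internal error: duplicate species in a decomposed subtree")
    }
    tree
  }
  if (.is_single_tip(ortholog_tree)) return(list(relabel(ortholog_tree)))
  ev <- so_events(ortholog_tree, map, threshold = so_threshold)
  dup_nodes <- ev$node[ev$event == "duplication"]
  if (length(dup_nodes) == 0L) return(list(relabel(ortholog_tree)))
  pieces <- split_at_nodes(ortholog_tree, dup_nodes)
  lapply(pieces, function(p) relabel(p$tree))
}

#' Duplication-aware average normalized RF distance of a gene family tree
#'
#' The family-level distance between a gene family tree and the species
#' tree: the family tree is split into ortholog trees at its
#' paralog-generating nodes (child subtrees sharing at least
#' \code{min_common} species); each ortholog tree is decomposed at its
#' remaining SO duplication nodes into single-copy subtrees; each subtree
#' is compared with the species tree by normalized RF restricted to the
#' common species; per-ortholog-tree means are taken over non-skipped
#' subtrees, and the overall value is the unweighted mean of the
#' per-ortholog-tree means. Subtrees sharing fewer than four species with
#' the species tree are skipped and counted.
#'
#' @param family_tree rooted gene family tree (\code{phylo}).
#' @param species_tree rooted species tree whose leaves cover every species
#'   appearing in the family.
#' @param map a \code{species_map}.
#' @param min_common paralog-generating threshold (shared species).
#' @param so_threshold SO score threshold for the decomposition step.
#' @return an object of class \code{family_distance_report}: list with
#'   \code{per_subtree} (data frame: ortholog, subtree, n_common_leaves,
#'   rf, max_rf, nrf, skipped), \code{per_ortholog} (data frame: ortholog,
#'   provenance, size, n_subtrees, n_skipped, mean_nrf),
#'   \code{overall_nrf} (unweighted mean of ortholog means),
#'   \code{pooled_nrf} (mean over all non-skipped subtrees),
#'   \code{n_skipped}, \code{all_skipped}.
#' @export
family_nrf <- function(family_tree, species_tree, map, min_common = 2L,
                       so_threshold = 0) {
  sp <- map_species(family_tree, map)
  unknown <- setdiff(unique(sp), .tree_tips(species_tree))
  if (length(unknown)) {
    stop("species not in species tree: ", paste(unknown, collapse = ", "))
  }
  sets <- extract_ortholog_sets(family_tree, map, min_common)
  per_subtree <- list()
  per_ortholog <- list()
  for (i in seq_along(sets)) {
    subtrees <- treeko_decompose(sets[[i]]$tree, map, so_threshold)
    rows <- lapply(seq_along(subtrees), function(j) {
      st <- subtrees[[j]]
      common <- intersect(.tree_tips(st), .tree_tips(species_tree))
      if (length(common) < 4L) {
        data.frame(ortholog = i, subtree = j,
                   n_common_leaves = length(common),
                   rf = NA_integer_, max_rf = NA_integer_, nrf = NA_real_,
                   skipped = TRUE)
      } else {
        r <- rf_distance(st, species_tree)
        data.frame(ortholog = i, subtree = j,
                   n_common_leaves = r$n_common_leaves,
                   rf = r$rf, max_rf = r$max_rf, nrf = r$nrf,
                   skipped = FALSE)
      }
    })
    df <- do.call(rbind, rows)
    per_subtree[[i]] <- df
    usable <- df$nrf[!df$skipped]
    per_ortholog[[i]] <- data.frame(
      ortholog = i, provenance = sets[[i]]$provenance,
      size = sets[[i]]$size, n_subtrees = nrow(df),
      n_skipped = sum(df$skipped),
      mean_nrf = if (length(usable)) mean(usable) else NA_real_)
  }
  per_subtree <- do.call(rbind, per_subtree)
  per_ortholog <- do.call(rbind, per_ortholog)
  means <- per_ortholog$mean_nrf[!is.na(per_ortholog$mean_nrf)]
  pooled <- per_subtree$nrf[!per_subtree$skipped]
  structure(list(
    per_subtree = per_subtree,
    per_ortholog = per_ortholog,
    overall_nrf = if (length(means)) mean(means) else NA_real_,
    pooled_nrf = if (length(pooled)) mean(pooled) else NA_real_,
    n_skipped = sum(per_subtree$skipped),
    all_skipped = all(per_subtree$skipped)),
    class = "family_distance_report")
}

#' @export
print.family_distance_report <- function(x, ...) {
  cat("Family vs species tree, duplication-aware normalized RF\n")
  cat("  ortholog trees:", nrow(x$per_ortholog),
      " decomposed subtrees:", nrow(x$per_subtree),
      " skipped:", x$n_skipped, "\n")
  for (i in seq_len(nrow(x$per_ortholog))) {
    cat(sprintf("  ortholog %d (%d members): mean nRF = %s over %d subtree(s)\n",
                i, x$per_ortholog$size[i],
                ifelse(is.na(x$per_ortholog$mean_nrf[i]), "NA",
                       sprintf("%.4f", x$per_ortholog$mean_nrf[i])),
                x$per_ortholog$n_subtrees[i] - x$per_ortholog$n_skipped[i]))
  }
  if (x$all_skipped) {
    cat("  overall nRF undefined: all subtrees skipped\n")
  } else {
    cat(sprintf("  overall nRF = %.4f (pooled %.4f)\n",
                x$overall_nrf, x$pooled_nrf))
  }
  invisible(x)
}
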