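# LCA-mapping reconciliation of a gene tree against a species tree.

# parent vector, children list, depth (edges from root) for a phylo
.species_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  n_all <- ntip + species_tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  root <- .phylo_root(species_tree)
  depth <- rep(NA_integer_, n_all)
  depth[root] <- 0L
  edge <- ape::reorder.phylo(species_tree, "cladewise")$edge
  for (i in seq_len(nrow(edge))) {
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + 1L
  }
  list(ntip = ntip, n_all = n_all, parent = parent, root = root,
       depth = depth, children = .phylo_children(species_tree))
}

.species_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else if (idx$depth[b] < idx$depth[a]) a <- idx$parent[a]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

# path of species nodes from ancestor `from` down to descendant `to`
.species_path_down <- function(idx, from, to) {
  path <- to
  while (to != from) {
    to <- idx$parent[to]
    if (is.na(to)) stop("internal error: nodes not on an ancestral path")
    path <- c(to, path)
  }
  path
}

.species_node_label <- function(species_tree, v) {
  ntip <- length(species_tree$tip.label)
  if (v <= ntip) return(species_tree$tip.label[v])
  if (!is.null(species_tree$node.label) &&
      nzchar(species_tree$node.label[v - ntip])) {
    return(species_tree$node.label[v - ntip])
  }
  sprintf("node%d", v)
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every gene-tree node to a species-tree node: a gene leaf maps to
#' its species, and an internal gene node maps to the species-tree LCA of
#' its children's images. The image of a node is always ancestral to (or
#' equal to) the images of its children.
#'
#' @param gene_tree rooted gene tree (\code{phylo}).
#' @param species_tree rooted species tree containing every species of the
#'   gene leaves.
#' @param map a \code{species_map}.
#' @return an object of class \code{lca_map}: integer vector indexed by
#'   gene-tree node number giving the image species-tree node number, with
#'   attributes \code{gene_tree} and \code{species_tree}.
#' @export
lca_map <- function(gene_tree, species_tree, map) {
  sp <- map_species(gene_tree, map)
  if (length(attr(sp, "dropped"))) {
    gene_tree <- prune_to_leafset(gene_tree, names(sp))
  }
  unknown <- setdiff(unique(sp), .tree_tips(species_tree))
  if (length(unknown)) {
    stop("species not in species tree: ", paste(unknown, collapse = ", "))
  }
  idx <- .species_index(species_tree)
  sp_tip <- match(unname(sp), species_tree$tip.label)
  names(sp_tip) <- names(sp)
  ntip_g <- length(gene_tree$tip.label)
  M <- rep(NA_integer_, ntip_g + gene_tree$Nnode)
  for (i in seq_len(ntip_g)) M[i] <- sp_tip[[gene_tree$tip.label[i]]]
  if (!.is_single_tip(gene_tree)) {
    edge <- ape::reorder.phylo(gene_tree, "postorder")$edge
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1L]; ch <- edge[i, 2L]
      M[p] <- if (is.na(M[p])) M[ch] else .species_lca(idx, M[p], M[ch])
    }
  }
  structure(M, class = "lca_map", gene_tree = gene_tree,
            species_tree = species_tree)
}

#' Duplication and loss inference by LCA reconciliation
#'
#' Reconciles a gene tree with the species tree under the parsimony
#' duplication-loss model. An internal gene node \code{v} is a duplication
#' when its image equals the image of one of its children; otherwise it is
#' a speciation. Losses on the gene edge \code{v -> c} follow the standard
#' convention: the number of species-tree edges between the images of
#' \code{v} and \code{c}, minus one if \code{v} is a speciation; each loss
#' is assigned to the species-tree branch where the lineage disappears (an
#' off-path child branch of a species node traversed by the edge).
#' Species present in the species tree but absent below (or beside) the
#' gene root are accounted separately, relative to an assumed single copy
#' at the species root, in the \code{absence_losses} component.
#'
#' @inheritParams lca_map
#' @return an object of class \code{event_table}: list with
#'   \code{node_events} (data frame: gene node, event, species node and
#'   label of the image), \code{branch_events} (data frame: one row per
#'   species-tree node/branch with \code{dup_count} and \code{loss_count}),
#'   \code{absence_losses} (same layout, stem/absence losses),
#'   \code{total_duplications}, \code{total_losses}.
#' @export
dl_events <- function(gene_tree, species_tree, map) {
  sp <- map_species(gene_tree, map)
  if (length(attr(sp, "dropped"))) {
    gene_tree <- prune_to_leafset(gene_tree, names(sp))
  }
  M <- lca_map(gene_tree, species_tree, map)
  idx <- .species_index(species_tree)
  ntip_g <- length(gene_tree$tip.label)
  dup_count <- integer(idx$n_all)
  loss_count <- integer(idx$n_all)
  absence <- integer(idx$n_all)
  kids_g <- if (.is_single_tip(gene_tree)) NULL else .phylo_children(gene_tree)
  internal_g <- if (.is_single_tip(gene_tree)) integer(0) else
    sort(unique(gene_tree$edge[, 1L]))
  event <- character(length(internal_g))
  for (k in seq_along(internal_g)) {
    v <- internal_g[k]
    ch <- kids_g[[v]]
    is_dup <- any(M[ch] == M[v])
    event[k] <- if (is_dup) "duplication" else "speciation"
    if (is_dup) dup_count[M[v]] <- dup_count[M[v]] + 1L
    for (c in ch) {
      path <- .species_path_down(idx, M[v], M[c])
      # species nodes at which the lineage passes and can shed a copy:
      # all path nodes except the last; for a speciation the first is the
      # speciation itself and sheds nothing
      if (length(path) < 2L) next
      start <- if (is_dup) 1L else 2L
      if (start > length(path) - 1L) next
      for (t in seq.int(start, length(path) - 1L)) {
        s <- path[t]; nxt <- path[t + 1L]
        for (w in idx$children[[s]]) {
          if (w != nxt) loss_count[w] <- loss_count[w] + 1L
        }
      }
    }
  }
  # absence section: losses along the stem from the species root down to
  # the image of the gene root, assuming one ancestral copy at the root
  root_img <- if (.is_single_tip(gene_tree)) M[1L] else
    M[.phylo_root(gene_tree)]
  if (root_img != idx$root) {
    path <- .species_path_down(idx, idx$root, root_img)
    for (t in seq_len(length(path) - 1L)) {
      s <- path[t]; nxt <- path[t + 1L]
      for (w in idx$children[[s]]) {
        if (w != nxt) absence[w] <- absence[w] + 1L
      }
    }
  }
  labels <- vapply(seq_len(idx$n_all), function(v)
    .species_node_label(species_tree, v), character(1))
  branch_events <- data.frame(species_node = seq_len(idx$n_all),
                              label = labels,
                              dup_count = dup_count,
                              loss_count = loss_count)
  absence_losses <- data.frame(species_node = seq_len(idx$n_all),
                               label = labels, loss_count = absence)
  node_events <- data.frame(gene_node = internal_g, event = event,
                            species_node = M[internal_g],
                            species_label = labels[M[internal_g]],
                            stringsAsFactors = FALSE)
  structure(list(node_events = node_events,
                 branch_events = branch_events,
                 absence_losses = absence_losses,
                 total_duplications = sum(dup_count),
                 total_losses = sum(loss_count)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Reconciliation events:", x$total_duplications, "duplication(s),",
      x$total_losses, "loss(es);",
      sum(x$absence_losses$loss_count), "stem/absence loss(es)\n")
  invisible(x)
}

#' Per-branch event summary
#'
#' Flattens an event table into one row per species-tree branch (the
#' branch above each node), with duplication, loss and stem/absence loss
#' counts — ready to write as TSV or to annotate a species tree figure.
#'
#' @param table an \code{event_table} from \code{\link{dl_events}}.
#' @param species_tree the species tree the table was computed against.
#' @return a data frame: \code{species_node}, \code{parent},
#'   \code{label}, \code{dup_count}, \code{loss_count},
#'   \code{absence_loss_count}.
#' @export
events_by_branch <- function(table, species_tree) {
  stopifnot(inherits(table, "event_table"))
  idx <- .species_index(species_tree)
  data.frame(species_node = table$branch_events$species_node,
             parent = idx$parent[table$branch_events$species_node],
             label = table$branch_events$label,
             dup_count = table$branch_events$dup_count,
             loss_count = table$branch_events$loss_count,
             absence_loss_count = table$absence_losses$loss_count)
}
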