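# Internal recursive tree representation used for tree surgery.
#
# A "tnode" is a plain list:
#   label    leaf label (character, NA for internal nodes)
#   nlabel   internal node label / support (character, NA if absent)
#   len      branch length above the node (NA = no length information)
#   id       node number in the originating phylo object (stable reference)
#   children list of tnodes (empty for leaves)
#
# phylo objects remain the public currency; conversions preserve labels,
# lengths and internal node labels.

.tn_new <- function(label = NA_character_, nlabel = NA_character_,
                    len = NA_real_, id = NA_integer_, children = list()) {
  list(label = label, nlabel = nlabel, len = len, id = id,
       children = children)
}

.tn_is_leaf <- function(tn) length(tn$children) == 0L

# children of each node in a phylo, as a list indexed by node number
.phylo_children <- function(phy) {
  n_all <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

.phylo_root <- function(phy) {
  ntip <- length(phy$tip.label)
  setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])[1L]
}

.as_tnode <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip == 1L && phy$Nnode == 1L) {
    len <- if (!is.null(phy$edge.length)) phy$edge.length[1L] else NA_real_
    return(.tn_new(label = phy$tip.label[1L], len = len, id = 1L))
  }
  kids <- .phylo_children(phy)
  elen <- rep(NA_real_, ntip + phy$Nnode)
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2L]] <- phy$edge.length
  nlab <- phy$node.label
  build <- function(v) {
    if (v <= ntip) {
      return(.tn_new(label = phy$tip.label[v], len = elen[v], id = v))
    }
    nl <- if (!is.null(nlab) && nzchar(nlab[v - ntip])) nlab[v - ntip] else NA_character_
    .tn_new(nlabel = nl, len = elen[v], id = v,
            children = lapply(kids[[v]], build))
  }
  build(.phylo_root(phy))
}

.tn_leaves <- function(tn) {
  if (.tn_is_leaf(tn)) return(tn$label)
  unlist(lapply(tn$children, .tn_leaves), use.names = FALSE)
}

.tn_count <- function(tn) {
  if (.tn_is_leaf(tn)) return(c(tips = 1L, nodes = 0L))
  sub <- vapply(tn$children, .tn_count, integer(2))
  c(tips = sum(sub[1L, ]), nodes = 1L + sum(sub[2L, ]))
}

# collapse unary chains, summing branch lengths along suppressed paths;
# lengths that are all NA stay NA (absent is "no information", not zero)
.tn_suppress_unary <- function(tn) {
  tn$children <- lapply(tn$children, .tn_suppress_unary)
  while (length(tn$children) == 1L) {
    child <- tn$children[[1L]]
    lens <- c(tn$len, child$len)
    child$len <- if (all(is.na(lens))) NA_real_ else sum(lens, na.rm = TRUE)
    tn <- child
    tn$children <- lapply(tn$children, .tn_suppress_unary)
  }
  tn
}

.single_tip_phylo <- function(label, len = NA_real_) {
  phy <- list(edge = matrix(c(2L, 1L), 1L, 2L),
              tip.label = label, Nnode = 1L)
  if (!is.na(len)) phy$edge.length <- len
  class(phy) <- "phylo"
  phy
}

.tnode_to_phylo <- function(tn) {
  if (.tn_is_leaf(tn)) return(.single_tip_phylo(tn$label, tn$len))
  cnt <- .tn_count(tn)
  ntip <- cnt[["tips"]]; nnode <- cnt[["nodes"]]
  edge <- matrix(0L, ntip + nnode - 1L, 2L)
  elen <- numeric(ntip + nnode - 1L)
  tip.label <- character(ntip)
  node.label <- character(nnode)
  env <- new.env(parent = emptyenv())
  env$tip <- 0L; env$node <- ntip; env$edge <- 0L
  assign_num <- function(x) {
    if (.tn_is_leaf(x)) {
      env$tip <- env$tip + 1L
      tip.label[env$tip] <<- x$label
      env$tip
    } else {
      env$node <- env$node + 1L
      me <- env$node
      node.label[me - ntip] <<- if (is.na(x$nlabel)) "" else x$nlabel
      for (ch in x$children) {
        child_num <- assign_num(ch)
        env$edge <- env$edge + 1L
        edge[env$edge, ] <<- c(me, child_num)
        elen[env$edge] <<- ch$len
      }
      me
    }
  }
  assign_num(tn)
  phy <- list(edge = edge, tip.label = tip.label, Nnode = nnode)
  if (any(!is.na(elen))) phy$edge.length <- elen
  if (any(nzchar(node.label))) phy$node.label <- node.label
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

.tree_tips <- function(tree) tree$tip.label

.is_single_tip <- function(tree) length(tree$tip.label) == 1L
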