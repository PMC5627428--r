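# Independent oracles and enumeration helpers shared by the tests.
# Everything here recomputes quantities from first principles (or through
# phangorn), never through the package's own code paths.

# ---- enumeration of tree topologies ----------------------------------------

# all rooted binary trees on the given labels, as nested lists
# (leaf = label string, internal = list(left, right)); (2n-3)!! of them
enum_rooted <- function(labels) {
  if (length(labels) == 1L) return(list(labels[[1L]]))
  insert <- function(t, x) {
    res <- list(list(t, x))
    if (is.list(t)) {
      for (w in insert(t[[1L]], x)) res <- c(res, list(list(w, t[[2L]])))
      for (w in insert(t[[2L]], x)) res <- c(res, list(list(t[[1L]], w)))
    }
    res
  }
  out <- list(labels[[1L]])
  for (i in seq_along(labels)[-1L]) {
    out <- unlist(lapply(out, insert, x = labels[[i]]), recursive = FALSE)
  }
  out
}

nested_to_newick <- function(t) {
  rec <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", paste(vapply(x, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(t), ";")
}

# all unrooted binary topologies on the labels, represented with a
# trifurcating top node; (2n-5)!! of them
enum_unrooted <- function(labels) {
  stopifnot(length(labels) >= 3L)
  insert_edge <- function(t, x) {
    # attach x above some node of subtree t (subdividing its root edge
    # or an edge inside it)
    res <- list(list(t, x))
    if (is.list(t)) {
      for (w in insert_edge(t[[1L]], x)) res <- c(res, list(list(w, t[[2L]])))
      for (w in insert_edge(t[[2L]], x)) res <- c(res, list(list(t[[1L]], w)))
    }
    res
  }
  out <- list(list(labels[[1L]], labels[[2L]], labels[[3L]]))
  for (i in seq_along(labels)[-(1:3)]) {
    x <- labels[[i]]
    new_out <- list()
    for (t in out) {
      for (j in 1:3) {
        for (w in insert_edge(t[[j]], x)) {
          t2 <- t
          t2[[j]] <- w
          new_out <- c(new_out, list(t2))
        }
      }
    }
    out <- new_out
  }
  out
}

# ---- brute-force split enumeration -----------------------------------------

# non-trivial splits of an unrooted tree by subset enumeration: a leaf
# subset A is a split side iff the edges spanned by within-A paths are
# disjoint from the edges spanned by within-complement paths
brute_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  tipnum <- match(tips, phy$tip.label)
  path_edges <- function(set) {
    if (length(set) < 2L) return(character(0))
    out <- character(0)
    for (i in seq_len(length(set) - 1L)) {
      for (j in seq.int(i + 1L, length(set))) {
        np <- ape::nodepath(phy, tipnum[set[i]], tipnum[set[j]])
        for (k in seq_len(length(np) - 1L)) {
          e <- sort(c(np[k], np[k + 1L]))
          out <- c(out, paste(e, collapse = "-"))
        }
      }
    }
    unique(out)
  }
  keys <- character(0)
  for (size in 2:(n - 2L)) {
    for (comb in utils::combn(seq_len(n), size, simplify = FALSE)) {
      if (!(1L %in% comb)) next  # canonical: side containing first tip
      other <- setdiff(seq_len(n), comb)
      if (length(intersect(path_edges(comb), path_edges(other))) == 0L) {
        side <- tips[comb]
        oside <- tips[other]
        k1 <- paste(sort(side), collapse = "|")
        k2 <- paste(sort(oside), collapse = "|")
        keys <- c(keys, min(k1, k2))
      }
    }
  }
  unique(keys)
}

# ---- independent species-overlap recomputation -----------------------------

# SO events recomputed from scratch with ape/phangorn machinery: species
# sets per child subtree from Descendants(), overlap by table counting
so_oracle <- function(phy, species) {
  # species: named character vector, tip label -> species
  ntip <- length(phy$tip.label)
  internal <- seq.int(ntip + 1L, ntip + phy$Nnode)
  out <- lapply(internal, function(v) {
    kids <- phy$edge[phy$edge[, 1L] == v, 2L]
    child_sets <- lapply(kids, function(ch) {
      tipset <- if (ch <= ntip) ch else
        phangorn::Descendants(phy, ch, type = "tips")[[1L]]
      unique(unname(species[phy$tip.label[tipset]]))
    })
    tab <- table(unlist(child_sets))
    overlap <- sum(tab >= 2L)
    union_n <- length(tab)
    data.frame(node = v, overlap_size = overlap, union_size = union_n,
               overlap_score = if (union_n) overlap / union_n else 0,
               event = if (overlap > 0L) "duplication" else "speciation",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- simulator moment oracle -----------------------------------------------

# expected number of duplication events under a pure-duplication process:
# forward recursion of the expected copy number (N0 * exp(lambda * L) per
# branch), with E[events on a branch] = N_in * (exp(lambda * L) - 1)
expected_dup_count <- function(species_tree, dup_rate, root_copies = 1) {
  ntip <- length(species_tree$tip.label)
  parent <- rep(NA_integer_, ntip + species_tree$Nnode)
  parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  root <- setdiff(unique(species_tree$edge[, 1L]),
                  species_tree$edge[, 2L])[1L]
  elen <- rep(NA_real_, ntip + species_tree$Nnode)
  elen[species_tree$edge[, 2L]] <- species_tree$edge.length
  n_in <- rep(NA_real_, ntip + species_tree$Nnode)
  n_in[root] <- root_copies
  total <- 0
  edge <- ape::reorder.phylo(species_tree, "cladewise")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    growth <- exp(dup_rate * elen[ch])
    total <- total + n_in[p] * (growth - 1)
    n_in[ch] <- n_in[p] * growth
  }
  total
}

# ---- misc -------------------------------------------------------------------

# canonical rooted newick (children sorted by smallest descendant label),
# topology and labels only — used for isomorphism checks
canonical_topology <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip == 1L) return(paste0(phy$tip.label, ";"))
  kids <- lapply(seq_len(ntip + phy$Nnode), function(v)
    phy$edge[phy$edge[, 1L] == v, 2L])
  root <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])[1L]
  rec <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    parts <- sort(vapply(kids[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

# random gene labels over a species set, used to build species maps
rand_species_assignment <- function(labels, species_pool) {
  stats::setNames(sample(species_pool, length(labels), replace = TRUE),
                  labels)
}
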