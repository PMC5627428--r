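# Posterior tree-sample summarization (clade frequencies, MCC tree).

.clade_keys <- function(tree) {
  # rooted clades: leaf set below every internal node (root included)
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(character(0))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    below[[p]] <- c(below[[p]], below[[edge[i, 2L]]])
  }
  internal <- sort(unique(edge[, 1L]))
  vapply(internal, function(v) paste(sort(below[[v]]), collapse = "|"),
         character(1))
}

#' Rooted clade frequencies of a tree sample
#'
#' Counts every rooted clade (the leaf set below an internal node) over the
#' post-burn-in trees of a sample and reports its frequency.
#'
#' @param sample a \code{tree_sample} (see \code{\link{read_tree_sample}}).
#' @return an object of class \code{clade_table}: data frame with
#'   \code{clade} (labels joined by \code{"|"}), \code{size} and
#'   \code{freq}, ordered by decreasing frequency; the number of counted
#'   trees is in the \code{"n_trees"} attribute.
#' @export
clade_frequencies <- function(sample) {
  trees <- post_burnin(sample)
  if (length(trees) == 0L) stop("empty post-burn-in sample")
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (k in .clade_keys(tr)) {
      counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
    }
  }
  keys <- ls(counts)
  n <- length(trees)
  out <- data.frame(
    clade = keys,
    size = vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1)),
    freq = vapply(keys, function(k) counts[[k]], integer(1)) / n,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$freq, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trees") <- n
  class(out) <- c("clade_table", "data.frame")
  out
}

#' Maximum clade credibility tree of a sample
#'
#' Selects the sampled tree maximizing the sum of log clade frequencies
#' over its rooted clades (the log clade credibility), breaking ties by the
#' earliest post-burn-in sample index. Internal nodes of the returned tree
#' are annotated with their posterior clade support in \code{node.label}.
#' When every post-burn-in tree is ultrametric, mean clade heights across
#' the trees containing each clade are reported in the
#' \code{"clade_heights"} attribute.
#'
#' @param sample a \code{tree_sample}.
#' @return a \code{phylo} tree drawn from the sample, with attributes
#'   \code{"log_clade_credibility"}, \code{"sample_index"} (index among
#'   post-burn-in trees), \code{"posterior"} (numeric supports parallel to
#'   internal nodes) and optionally \code{"clade_heights"}.
#' @export
mcc_tree <- function(sample) {
  trees <- post_burnin(sample)
  if (length(trees) == 0L) stop("empty post-burn-in sample")
  ct <- clade_frequencies(sample)
  freq <- stats::setNames(ct$freq, ct$clade)
  keys_by_tree <- lapply(trees, .clade_keys)
  scores <- vapply(keys_by_tree, function(k) sum(log(freq[k])), numeric(1))
  best <- which.max(scores)  # which.max returns the first maximum
  tree <- trees[[best]]
  keys <- keys_by_tree[[best]]
  support <- unname(freq[keys])
  tree$node.label <- sprintf("%.6g", support)
  attr(tree, "posterior") <- support
  attr(tree, "log_clade_credibility") <- scores[best]
  attr(tree, "sample_index") <- best
  ultra <- all(vapply(trees, function(t)
    !is.null(t$edge.length) && ape::is.ultrametric(t, option = 2),
    logical(1)))
  if (ultra) {
    hsum <- new.env(parent = emptyenv())
    hn <- new.env(parent = emptyenv())
    for (tr in trees) {
      depth <- ape::node.depth.edgelength(tr)
      height <- max(depth) - depth
      ntip <- length(tr$tip.label)
      ks <- .clade_keys(tr)
      internal <- seq.int(ntip + 1L, ntip + tr$Nnode)
      # .clade_keys returns keys for sorted internal node numbers
      for (i in seq_along(ks)) {
        k <- ks[i]
        v <- internal[i]
        hsum[[k]] <- if (is.null(hsum[[k]])) height[v] else hsum[[k]] + height[v]
        hn[[k]] <- if (is.null(hn[[k]])) 1L else hn[[k]] + 1L
      }
    }
    attr(tree, "clade_heights") <- stats::setNames(
      vapply(keys, function(k) hsum[[k]] / hn[[k]], numeric(1)), keys)
  }
  tree
}
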