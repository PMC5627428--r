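#' Parse a newick string into a rooted tree
#'
#' Reads a single newick tree into an ape \code{phylo} object. Quoted labels
#' are supported (quotes stripped), \code{[...]} comments are dropped,
#' underscores are kept literal, and unary internal nodes are suppressed on
#' read. Numeric internal node labels are retained in \code{node.label} and
#' interpreted downstream as support values.
#'
#' @param text a non-empty newick string terminated by \code{";"}.
#' @return a \code{phylo} object; single-leaf trees (\code{"A;"}) are
#'   represented as a degenerate one-tip \code{phylo}.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  text <- .strip_comments(text)
  .check_parens(text)
  if (!grepl(";\\s*$", text)) stop("newick string must be terminated by ';'")
  body <- sub(";\\s*$", "", text)
  if (!nzchar(trimws(body))) stop("empty tree")
  # single leaf, e.g. "A;" or "A:1.5;" (ape mishandles this form)
  if (!grepl("[(),]", body)) {
    parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
    lab <- .unquote_label(trimws(parts[1L]))
    if (!nzchar(lab)) stop("empty tree")
    len <- if (length(parts) > 1L) as.numeric(parts[2L]) else NA_real_
    return(.single_tip_phylo(lab, len))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("newick parse error")
  phy$tip.label <- vapply(phy$tip.label, .unquote_label, character(1),
                          USE.NAMES = FALSE)
  if (!is.null(phy$node.label)) {
    phy$node.label <- vapply(phy$node.label, .unquote_label, character(1),
                             USE.NAMES = FALSE)
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  phy <- ape::collapse.singles(phy)
  phy
}

.strip_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

.unquote_label <- function(x) {
  if (grepl("^'.*'$", x)) x <- gsub("''", "'", substr(x, 2L, nchar(x) - 1L))
  x
}

.check_parens <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses at position ", nchar(text))
  invisible(TRUE)
}

#' Serialize a tree to newick
#'
#' Writes a \code{phylo} object as a newick string. Branch lengths are
#' printed with a fixed number of decimal places (trailing zeros trimmed);
#' internal node labels (supports) are emitted when present. Labels
#' containing newick metacharacters are single-quoted.
#'
#' @param tree a \code{phylo} object.
#' @param precision number of decimal places for branch lengths.
#' @return a newick string terminated by \code{";"}.
#' @export
write_newick <- function(tree, precision = 6L) {
  stopifnot(inherits(tree, "phylo"))
  tn <- .as_tnode(tree)
  paste0(.tn_newick(tn, precision), ";")
}

.quote_label <- function(x) {
  if (grepl("[ (),:;\\[\\]']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

.fmt_len <- function(x, precision) {
  s <- sprintf(paste0("%.", precision, "f"), x)
  if (grepl("\\.", s)) s <- sub("\\.?0+$", "", s)
  if (!nzchar(s) || s == "-") s <- "0"
  s
}

.tn_newick <- function(tn, precision) {
  if (.tn_is_leaf(tn)) {
    out <- .quote_label(tn$label)
  } else {
    out <- paste0("(",
                  paste(vapply(tn$children, .tn_newick, character(1),
                               precision = precision), collapse = ","),
                  ")")
    if (!is.na(tn$nlabel)) out <- paste0(out, .quote_label(tn$nlabel))
  }
  if (!is.na(tn$len)) out <- paste0(out, ":", .fmt_len(tn$len, precision))
  out
}

#' Read a posterior sample of trees
#'
#' Reads a set of trees sharing one leaf universe, either as newick
#' one-per-line text or as a NEXUS trees block (BEAST dialect; Translate
#' blocks are resolved to labels). The first
#' \code{floor(burnin_fraction * N)} trees are flagged as burn-in and
#' excluded from downstream summaries; the remaining trees must have
#' identical leaf sets.
#'
#' @param source path to a file, or the text itself.
#' @param burnin_fraction fraction of trees to discard, in \code{[0, 1)}.
#' @return an object of class \code{tree_sample} with elements
#'   \code{trees} (all trees), \code{n_excluded}, \code{burnin_fraction}.
#' @export
read_tree_sample <- function(source, burnin_fraction = 0) {
  stopifnot(is.numeric(burnin_fraction), length(burnin_fraction) == 1L,
            burnin_fraction >= 0, burnin_fraction < 1)
  txt <- source
  if (length(source) == 1L && !grepl("\n", source) &&
      !grepl(";", source) && file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  trees <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    f <- tempfile(fileext = ".nex")
    writeLines(txt, f)
    on.exit(unlink(f))
    tr <- ape::read.nexus(f)
    if (inherits(tr, "phylo")) list(tr) else
      unclass(ape::.uncompressTipLabel(tr))
  } else {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lapply(lines, parse_newick)
  }
  n <- length(trees)
  if (n == 0L) stop("no trees found in sample")
  n_excluded <- floor(burnin_fraction * n)
  kept <- trees[seq.int(n_excluded + 1L, n)]
  ref <- sort(.tree_tips(kept[[1L]]))
  for (i in seq_along(kept)) {
    if (!identical(sort(.tree_tips(kept[[i]])), ref)) {
      stop("post-burn-in tree ", n_excluded + i,
           " has a leaf set differing from tree ", n_excluded + 1L)
    }
  }
  structure(list(trees = trees, n_excluded = n_excluded,
                 burnin_fraction = burnin_fraction),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "trees (",
      x$n_excluded, "burn-in,", length(x$trees) - x$n_excluded,
      "retained),", length(post_burnin(x)[[1L]]$tip.label), "leaves\n")
  invisible(x)
}

#' Post-burn-in trees of a sample
#' @param sample a \code{tree_sample}.
#' @return list of \code{phylo} trees after burn-in removal.
#' @export
post_burnin <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  sample$trees[seq.int(sample$n_excluded + 1L, length(sample$trees))]
}

# ---- species maps -----------------------------------------------------------

#' Gene-leaf to species mapping rules
#'
#' A \code{species_map} maps gene leaf labels to species labels. Three modes
#' are available: an explicit lookup table, a delimiter rule (split the label
#' on a character and take a field, counting from the left or the right), or
#' a regular expression with exactly one capture group. The
#' \code{on_unmapped} policy controls whether a leaf with no species is an
#' error or is dropped (with a warning).
#'
#' @param table named character vector (names = gene labels, values =
#'   species), or a two-column data frame.
#' @param delimiter single splitting character.
#' @param field 1-based field index.
#' @param from_end take \code{field} counting from the last field.
#' @param pattern regular expression with exactly one capture group.
#' @param on_unmapped \code{"error"} or \code{"drop"}.
#' @return an object of class \code{species_map}.
#' @name species_map
NULL

#' @rdname species_map
#' @export
species_map_table <- function(table, on_unmapped = c("error", "drop")) {
  if (is.data.frame(table)) {
    stopifnot(ncol(table) >= 2L)
    table <- stats::setNames(as.character(table[[2L]]),
                             as.character(table[[1L]]))
  }
  stopifnot(is.character(table), !is.null(names(table)))
  structure(list(mode = "table", table = table,
                 on_unmapped = match.arg(on_unmapped)),
            class = "species_map")
}

#' @rdname species_map
#' @export
species_map_delimiter <- function(delimiter = "_", field = 1L,
                                  from_end = TRUE,
                                  on_unmapped = c("error", "drop")) {
  stopifnot(nchar(delimiter) == 1L, field >= 1L)
  structure(list(mode = "delimiter", delimiter = delimiter,
                 field = as.integer(field), from_end = isTRUE(from_end),
                 on_unmapped = match.arg(on_unmapped)),
            class = "species_map")
}

#' @rdname species_map
#' @export
species_map_regex <- function(pattern, on_unmapped = c("error", "drop")) {
  ngroups <- .count_capture_groups(pattern)
  if (ngroups != 1L) {
    stop("regex species map requires exactly one capture group, found ",
         ngroups)
  }
  structure(list(mode = "regex", pattern = pattern,
                 on_unmapped = match.arg(on_unmapped)),
            class = "species_map")
}

.count_capture_groups <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  n <- 0L
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "\\") { i <- i + 2L; next }
    if (chars[i] == "(" && !(i + 1L <= length(chars) && chars[i + 1L] == "?"))
      n <- n + 1L
    i <- i + 1L
  }
  n
}

#' Read a species map from a TSV file
#'
#' Two tab-separated columns: gene label, species label. Lines starting with
#' \code{#} are comments.
#'
#' @param path file path.
#' @param on_unmapped policy for unmapped leaves.
#' @return a table-mode \code{species_map}.
#' @export
read_species_map <- function(path, on_unmapped = c("error", "drop")) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("species map TSV needs two columns")
  species_map_table(df, on_unmapped = on_unmapped)
}

#' Map the leaves of a tree to species
#'
#' Applies a \code{species_map} to every leaf of a tree. With
#' \code{on_unmapped = "error"} an unmapped leaf is an error naming the
#' leaf; with \code{"drop"} unmapped leaves are excluded from the returned
#' map (and reported via the \code{"dropped"} attribute and a warning), so
#' that callers can prune them.
#'
#' @param tree a \code{phylo} object.
#' @param map a \code{species_map}.
#' @return named character vector, leaf label -> species label, with
#'   attribute \code{"dropped"} listing unmapped leaves.
#' @export
map_species <- function(tree, map) {
  stopifnot(inherits(map, "species_map"))
  labels <- if (inherits(tree, "phylo")) .tree_tips(tree) else tree
  sp <- switch(map$mode,
    table = unname(map$table[labels]),
    delimiter = vapply(labels, function(l) {
      parts <- strsplit(l, map$delimiter, fixed = TRUE)[[1L]]
      k <- if (map$from_end) length(parts) - map$field + 1L else map$field
      if (k >= 1L && k <= length(parts)) parts[k] else NA_character_
    }, character(1), USE.NAMES = FALSE),
    regex = vapply(labels, function(l) {
      m <- regmatches(l, regexec(map$pattern, l))[[1L]]
      if (length(m) >= 2L) m[2L] else NA_character_
    }, character(1), USE.NAMES = FALSE))
  bad <- labels[is.na(sp) | !nzchar(ifelse(is.na(sp), "", sp))]
  if (length(bad)) {
    if (map$on_unmapped == "error") {
      stop("leaf with no species mapping: ", paste(bad, collapse = ", "))
    }
    warning("dropping unmapped leaves: ", paste(bad, collapse = ", "))
  }
  keep <- !(labels %in% bad)
  out <- stats::setNames(sp[keep], labels[keep])
  if (length(bad)) attr(out, "dropped") <- bad
  out
}

#' Prune a tree to a subset of leaves
#'
#' Returns the subtree induced by \code{keep}: other leaves are removed and
#' unary nodes suppressed, with branch lengths summed along suppressed
#' paths.
#'
#' @param tree a \code{phylo} object.
#' @param keep character vector of leaf labels to retain (subset of the
#'   tree's leaves, at least one).
#' @return a \code{phylo} object with leaf set exactly \code{keep}.
#' @export
prune_to_leafset <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"), length(keep) >= 1L)
  keep <- unique(keep)
  missing <- setdiff(keep, .tree_tips(tree))
  if (length(missing)) {
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # induced subtree is the leaf itself; sum the root-to-leaf path length
    len <- NA_real_
    if (!is.null(tree$edge.length)) {
      tip <- match(keep, tree$tip.label)
      d <- ape::node.depth.edgelength(tree)
      len <- d[tip]
    }
    return(.single_tip_phylo(keep, len))
  }
  ape::keep.tip(tree, keep)
}
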