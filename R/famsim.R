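# Gene-family evolution simulator: birth-death duplication-loss-transfer
# process along a dated species tree, with a ground-truth event log.

#' Simulation parameters
#'
#' Event rates are per gene lineage per unit of species-tree branch time.
#' The defaults are a moderately duplicating, weakly losing,
#' transfer-free regime suitable for vertebrate-like gene families.
#'
#' @param dup_rate duplication rate (>= 0).
#' @param loss_rate loss rate (>= 0).
#' @param transfer_rate transfer rate (>= 0); a positive rate requires an
#'   ultrametric (dated) species tree so that donor and recipient branches
#'   co-exist in time.
#' @param root_copies number of gene copies at the species-tree root.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(dup_rate = 0.1, loss_rate = 0.05,
                       transfer_rate = 0, root_copies = 1L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, transfer_rate >= 0,
            root_copies >= 1L)
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 transfer_rate = transfer_rate,
                 root_copies = as.integer(root_copies)),
            class = "sim_params")
}

#' Example dated species tree
#'
#' An eight-species ultrametric tree (crown age 4 time units) with two old
#' crown radiations and recent sister-species splits, used as the default
#' fixture for simulation-based checks.
#'
#' @return an ultrametric \code{phylo} with tips \code{s1..s8}.
#' @export
example_dated_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((s1:0.6,s2:0.6):1.4,(s3:0.6,s4:0.6):1.4):2,",
    "((s5:0.6,s6:0.6):1.4,(s7:0.6,s8:0.6):1.4):2);"))
}

#' Simulate the evolution of a gene family along a species tree
#'
#' Runs a Gillespie birth-death process per gene lineage along the species
#' tree, from the root towards the tips. Waiting times between events are
#' exponential with rate \code{dup_rate + loss_rate + transfer_rate}; a
#' duplication splits the lineage in place, a loss terminates it, and a
#' transfer copies it onto a species-tree branch chosen uniformly among
#' the branches co-existing at that moment (the donor excluded). At every
#' species-tree node each surviving lineage bifurcates into both daughter
#' branches. Extant leaves are labelled \code{g<k>_<species>}; the
#' observable tree is the full tree with extinct lineages pruned.
#'
#' @param species_tree rooted \code{phylo} with strictly positive branch
#'   lengths; must be ultrametric (tolerance 1e-6) when
#'   \code{transfer_rate > 0}.
#' @param params a \code{sim_params} object.
#' @param seed integer seed; the result is fully reproducible from it.
#' @return an object of class \code{sim_result}: list with
#'   \code{full_tree} (\code{phylo} including extinct lineages; internal
#'   node labels "D"/"S"/"T" record the generating event),
#'   \code{observable_tree} (\code{phylo}, or \code{NULL} when the family
#'   went extinct), \code{extinct} flag, \code{events} (data frame:
#'   event, time, branch, lineage, recipient), \code{species_map} (a
#'   regex \code{species_map} for the simulated labels), \code{params},
#'   \code{seed}.
#' @export
simulate_family <- function(species_tree, params = sim_params(), seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(species_tree$edge.length) ||
      any(species_tree$edge.length <= 0)) {
    stop("species tree must have strictly positive branch lengths")
  }
  if (params$transfer_rate > 0 &&
      !ape::is.ultrametric(species_tree, tol = 1e-6)) {
    stop("transfer_rate > 0 requires an ultrametric (dated) species tree")
  }
  set.seed(as.integer(seed))
  idx <- .species_index(species_tree)
  t_end <- ape::node.depth.edgelength(species_tree)  # time from root
  t_start <- ifelse(is.na(idx$parent), 0, t_end[idx$parent])
  rate_total <- params$dup_rate + params$loss_rate + params$transfer_rate
  env <- new.env(parent = emptyenv())
  env$gene <- 0L; env$lineage <- 0L; env$lost <- 0L
  env$events <- list()
  log_event <- function(type, time, branch, lineage, recipient = NA_character_) {
    env$events[[length(env$events) + 1L]] <-
      data.frame(event = type, time = time,
                 branch = .species_node_label(species_tree, branch),
                 lineage = lineage, recipient = recipient,
                 stringsAsFactors = FALSE)
  }
  new_lineage <- function() { env$lineage <- env$lineage + 1L; env$lineage }
  # one gene lineage entering the branch above species node s at time t0;
  # returns a tnode carrying absolute `time` fields
  sim_lineage <- function(s, t0, lin) {
    w <- if (rate_total > 0) stats::rexp(1L, rate_total) else Inf
    t1 <- t0 + w
    if (t1 >= t_end[s]) {
      if (s <= idx$ntip) {
        env$gene <- env$gene + 1L
        lab <- sprintf("g%d_%s", env$gene, species_tree$tip.label[s])
        tn <- .tn_new(label = lab)
        tn$time <- t_end[s]
        return(tn)
      }
      kids <- idx$children[[s]]
      tn <- .tn_new(nlabel = "S",
                    children = lapply(kids, function(d)
                      sim_lineage(d, t_end[s], new_lineage())))
      tn$time <- t_end[s]
      return(tn)
    }
    type <- sample(c("duplication", "loss", "transfer"), 1L,
                   prob = c(params$dup_rate, params$loss_rate,
                            params$transfer_rate))
    if (type == "duplication") {
      log_event("duplication", t1, s, lin)
      tn <- .tn_new(nlabel = "D",
                    children = list(sim_lineage(s, t1, new_lineage()),
                                    sim_lineage(s, t1, new_lineage())))
      tn$time <- t1
      return(tn)
    }
    if (type == "loss") {
      env$lost <- env$lost + 1L
      log_event("loss", t1, s, lin)
      tn <- .tn_new(label = sprintf("lost_%d", env$lost))
      tn$time <- t1
      tn$extinct <- TRUE
      return(tn)
    }
    # transfer: recipient uniform among co-existing branches, donor excluded
    alive <- which(t_start < t1 & t1 < t_end)
    alive <- setdiff(alive, s)
    if (length(alive) == 0L) {
      # no co-existing branch: the event has no effect, lineage continues
      return(sim_lineage(s, t1, lin))
    }
    r <- alive[sample.int(length(alive), 1L)]
    log_event("transfer", t1, s, lin,
              recipient = .species_node_label(species_tree, r))
    tn <- .tn_new(nlabel = "T",
                  children = list(sim_lineage(s, t1, lin),
                                  sim_lineage(r, t1, new_lineage())))
    tn$time <- t1
    return(tn)
  }
  root_kids <- idx$children[[idx$root]]
  one_copy <- function() {
    tn <- .tn_new(nlabel = "S",
                  children = lapply(root_kids, function(d)
                    sim_lineage(d, 0, new_lineage())))
    tn$time <- 0
    tn
  }
  full <- if (params$root_copies == 1L) one_copy() else {
    # several ancestral copies: join them under an origin node at time 0
    tn <- .tn_new(nlabel = "O",
                  children = replicate(params$root_copies, one_copy(),
                                       simplify = FALSE))
    tn$time <- 0
    tn
  }
  full <- .tn_times_to_lengths(full, 0)
  events <- if (length(env$events)) {
    do.call(rbind, env$events)
  } else {
    data.frame(event = character(0), time = numeric(0),
               branch = character(0), lineage = integer(0),
               recipient = character(0), stringsAsFactors = FALSE)
  }
  res <- structure(list(full_tree = .tnode_to_phylo(full),
                        observable_tree = NULL, extinct = FALSE,
                        events = events,
                        species_map = species_map_regex("^g[0-9]+_(.+)$"),
                        params = params, seed = as.integer(seed)),
                   class = "sim_result")
  obs <- prune_extinct(res)
  res$observable_tree <- obs
  res$extinct <- is.null(obs)
  res
}

.tn_times_to_lengths <- function(tn, parent_time) {
  tn$len <- tn$time - parent_time
  tn$children <- lapply(tn$children, .tn_times_to_lengths, parent_time = tn$time)
  tn
}

#' Prune extinct lineages from a simulated gene tree
#'
#' Removes every lineage without extant descendants (leaves labelled
#' \code{lost_<k>}) from the full simulated tree and suppresses the
#' resulting unary nodes, summing branch lengths. Node labels recording
#' the generating events ("D"/"S"/"T") are retained on surviving nodes.
#'
#' @param result a \code{sim_result}.
#' @return the observable \code{phylo} tree, or \code{NULL} when every
#'   lineage went extinct.
#' @export
prune_extinct <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  tn <- .as_tnode(result$full_tree)
  keep <- function(x) {
    if (.tn_is_leaf(x)) {
      if (startsWith(x$label, "lost_")) return(NULL)
      return(x)
    }
    x$children <- Filter(Negate(is.null), lapply(x$children, keep))
    if (length(x$children) == 0L) return(NULL)
    x
  }
  tn <- keep(tn)
  if (is.null(tn)) return(NULL)
  tn <- .tn_suppress_unary(tn)
  .tnode_to_phylo(tn)
}

#' @export
print.sim_result <- function(x, ...) {
  n_ext <- if (x$extinct) 0L else length(x$observable_tree$tip.label)
  cat("Simulated gene family:", n_ext, "extant gene(s);",
      sum(x$events$event == "duplication"), "duplication(s),",
      sum(x$events$event == "loss"), "loss(es),",
      sum(x$events$event == "transfer"), "transfer(s)",
      if (x$extinct) "[family extinct]" else "", "\n")
  invisible(x)
}
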