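#' Construct a class map
#'
#' A class map holds the binary response of an evolutionary sparse learning
#' analysis: one row per taxon with a label in \{+1, -1\} (+1 is the focal
#' class) and a nonnegative sample weight. Weights are normalized to sum to 1.
#'
#' @param taxa Character vector of taxon names. Duplicates are only permitted
#'   when `allow_duplicates = TRUE` (rows duplicated by up-sampling).
#' @param labels Integer vector of +1/-1 labels, one per taxon.
#' @param weights Optional nonnegative weights; default uniform.
#' @param allow_duplicates Allow repeated taxon names (post-up-sampling).
#' @return A `class_map`: a data frame with columns `taxon`, `label`, `weight`.
#' @export
class_map <- function(taxa, labels, weights = NULL, allow_duplicates = FALSE) {
  taxa <- as.character(taxa)
  if (length(taxa) == 0L) stop2("class map is empty")
  if (!allow_duplicates && anyDuplicated(taxa)) {
    stop2("duplicate taxon in class map: ",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  labels <- as.integer(labels)
  if (length(labels) != length(taxa) || !all(labels %in% c(1L, -1L))) {
    stop2("labels must be +1 or -1, one per taxon")
  }
  if (is.null(weights)) weights <- rep(1, length(taxa))
  weights <- as.numeric(weights)
  if (length(weights) != length(taxa) || any(weights < 0) || sum(weights) <= 0) {
    stop2("weights must be nonnegative and not all zero")
  }
  weights <- weights / sum(weights)
  out <- data.frame(taxon = taxa, label = labels, weight = weights,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_map", "data.frame")
  out
}

#' Read a two-column class file
#'
#' Parses a tab-separated file with taxon names in column 1 and a class
#' designation (+1 or -1) in column 2; +1 marks the focal class. Empty lines
#' are ignored.
#'
#' @param path Path to the class file.
#' @return A [class_map()].
#' @export
read_class_file <- function(path) {
  if (!file.exists(path)) stop2("class file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("class file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  if (any(bad)) {
    stop2("class file line(s) without two tab-separated columns: ",
          paste(which(bad), collapse = ", "))
  }
  taxa <- trimws(vapply(parts, `[[`, "", 1L))
  raw <- trimws(vapply(parts, `[[`, "", 2L))
  ok <- raw %in% c("+1", "1", "-1")
  if (!all(ok)) {
    stop2("invalid class label(s): ", paste(unique(raw[!ok]), collapse = ", "),
          " (expected +1 or -1)")
  }
  labels <- ifelse(raw == "-1", -1L, 1L)
  class_map(taxa, labels)
}

#' Construct a clade hypothesis
#'
#' @param name Unique hypothesis name (used for output file naming).
#' @param map A [class_map()].
#' @param provenance `"class-file"` or `"tree-node"`.
#' @return A `clade_hypothesis` list.
#' @export
clade_hypothesis <- function(name, map, provenance = c("class-file", "tree-node")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(map, "class_map"))
  structure(list(name = as.character(name), class_map = map,
                 provenance = provenance),
            class = "clade_hypothesis")
}

#' @export
print.clade_hypothesis <- function(x, ...) {
  n_pos <- sum(x$class_map$label == 1L)
  n_neg <- sum(x$class_map$label == -1L)
  cat(sprintf("<clade_hypothesis '%s' (%s): %d taxa (+1: %d, -1: %d)>\n",
              x$name, x$provenance, nrow(x$class_map), n_pos, n_neg))
  invisible(x)
}

# Tip label sets for every node (1..Ntip+Nnode), built by one postorder sweep.
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]
    sets[[p]] <- c(sets[[p]], sets[[eo$edge[k, 2L]]])
  }
  lapply(sets, function(ix) tree$tip.label[sort(ix)])
}

# Internal nodes in the order their subtrees complete in a postorder sweep.
postorder_internal_nodes <- function(tree) {
  eo <- stats::reorder(tree, "postorder")
  unique(eo$edge[, 1L])
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop2("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop2("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop2("tree has duplicate tip labels")
  invisible(tree)
}

#' Derive clade hypotheses from a rooted tree
#'
#' Each selected internal node defines one hypothesis: tips in its subtree are
#' labeled +1 (the focal clade) and all remaining tips -1. Nodes are selected
#' by name (`clade_list`), by size range (`gen_clade_list`), or — when neither
#' is given — the single labeled internal node of the tree.
#'
#' @param tree A rooted `phylo` tree (internal-node labels mark candidate
#'   clades).
#' @param clade_list Optional character vector of internal-node labels to use.
#' @param gen_clade_list Optional `c(min_size, max_size)`: auto-select every
#'   internal node whose tip count `c` satisfies
#'   `min_size <= c <= min(max_size, Ntip - min_size)`, naming unlabeled nodes
#'   `"cladeN"` by postorder index.
#' @return A list of [clade_hypothesis()] objects.
#' @export
clades_from_tree <- function(tree, clade_list = NULL, gen_clade_list = NULL) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  sets <- clade_tip_sets(tree)
  internal <- postorder_internal_nodes(tree)
  node_label <- function(node) {
    lab <- tree$node.label
    if (is.null(lab)) return("")
    l <- lab[node - ntip]
    if (is.na(l)) "" else l
  }
  make_h <- function(node, name) {
    pos <- sets[[node]]
    if (length(pos) == ntip) {
      stop2("clade '", name, "' covers every leaf; the -1 class would be empty")
    }
    labels <- ifelse(tree$tip.label %in% pos, 1L, -1L)
    clade_hypothesis(name, class_map(tree$tip.label, labels), "tree-node")
  }

  if (!is.null(gen_clade_list)) {
    if (length(gen_clade_list) != 2L) stop2("gen_clade_list must be c(min_size, max_size)")
    mn <- as.integer(gen_clade_list[1]); mx <- as.integer(gen_clade_list[2])
    if (mn < 1L || mn > mx) stop2("gen_clade_list requires 1 <= min_size <= max_size")
    out <- list()
    for (i in seq_along(internal)) {
      node <- internal[i]
      csize <- length(sets[[node]])
      if (csize >= mn && csize <= ntip - mn && csize <= mx) {
        nm <- node_label(node)
        if (!nzchar(nm)) nm <- sprintf("clade%d", i)
        out[[length(out) + 1L]] <- make_h(node, nm)
      }
    }
    names(out) <- vapply(out, `[[`, "", "name")
    if (anyDuplicated(names(out))) stop2("duplicate clade names among selected nodes")
    return(out)
  }

  labs <- tree$node.label
  labeled_nodes <- if (is.null(labs)) integer(0) else which(nzchar(labs) & !is.na(labs)) + ntip
  if (!is.null(clade_list)) {
    out <- lapply(clade_list, function(nm) {
      hit <- labeled_nodes[vapply(labeled_nodes, node_label, "") == nm]
      if (length(hit) == 0L) stop2("clade '", nm, "' not found among internal-node labels")
      if (length(hit) > 1L) stop2("clade label '", nm, "' is not unique in the tree")
      make_h(hit, nm)
    })
    names(out) <- clade_list
    return(out)
  }

  if (length(labeled_nodes) == 0L) {
    stop2("no labeled internal node; provide clade_list or gen_clade_list")
  }
  if (length(labeled_nodes) > 1L) {
    stop2("multiple labeled internal nodes (",
          paste(vapply(labeled_nodes, node_label, ""), collapse = ", "),
          "); use clade_list to pick the focal clade")
  }
  nm <- node_label(labeled_nodes)
  out <- list(make_h(labeled_nodes, nm))
  names(out) <- nm
  out
}

terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  term <- tree$edge[, 2L] <= ntip
  bl <- rep(NA_real_, ntip)
  bl[tree$edge[term, 2L]] <- tree$edge.length[term]
  if (anyNA(bl)) stop2("tree is missing terminal branch lengths")
  stats::setNames(bl, tree$tip.label)
}

# Tips in postorder visiting order: used as a deterministic tie-break when
# several taxa share the shortest terminal branch.
postorder_tip_rank <- function(tree) {
  eo <- stats::reorder(tree, "postorder")
  tips <- eo$edge[eo$edge[, 2L] <= length(tree$tip.label), 2L]
  stats::setNames(seq_along(tips), tree$tip.label[tips])
}

balance_phylo <- function(h, tree) {
  check_tree(tree)
  bl <- terminal_branch_lengths(tree)
  rank <- postorder_tip_rank(tree)
  cm <- h$class_map
  pos <- cm$taxon[cm$label == 1L]
  if (!all(pos %in% tree$tip.label)) {
    stop2("phylo balancing requires a tree containing every focal-clade taxon")
  }
  sets <- clade_tip_sets(tree)
  ntip <- length(tree$tip.label)
  focal <- if (length(pos) == 1L) {
    match(pos, tree$tip.label)
  } else {
    ape::getMRCA(tree, pos)
  }
  if (!setequal(sets[[focal]], pos)) {
    stop2("focal class is not a clade of the supplied tree; ",
          "phylo balancing needs a tree-derived hypothesis")
  }
  root <- ntip + 1L
  # Walk from the focal clade toward the root; at each step all tips under the
  # sister lineage(s) join the -1 class ("first cousins", then "second", ...).
  neg <- character(0)
  cur <- focal
  while (length(neg) < length(pos)) {
    parent_edge <- which(tree$edge[, 2L] == cur)
    if (length(parent_edge) == 0L) break  # reached the root: taxa exhausted
    parent <- tree$edge[parent_edge, 1L]
    siblings <- tree$edge[tree$edge[, 1L] == parent, 2L]
    siblings <- siblings[siblings != cur]
    for (s in siblings) neg <- c(neg, sets[[s]])
    cur <- parent
  }
  # Equalize by pruning the shortest terminal branch from the larger class.
  pos <- pos[order(rank[pos])]
  neg <- neg[order(rank[neg])]
  while (length(pos) != length(neg)) {
    if (length(neg) > length(pos)) {
      drop <- neg[which.min(bl[neg])]
      neg <- setdiff(neg, drop)
    } else {
      drop <- pos[which.min(bl[pos])]
      pos <- setdiff(pos, drop)
    }
  }
  if (length(pos) == 0L || length(neg) == 0L) {
    stop2("phylo balancing removed an entire class")
  }
  keep <- c(pos, neg)
  keep <- keep[order(rank[keep])]
  labels <- ifelse(keep %in% pos, 1L, -1L)
  clade_hypothesis(h$name, class_map(keep, labels), h$provenance)
}

#' Balance the two classes of a hypothesis
#'
#' Equalizes the contribution of the +1 and -1 classes before model fitting.
#' `"up"` duplicates randomly sampled minority-class taxa (with replacement)
#' until class sizes match; `"down"` removes randomly sampled majority-class
#' taxa; `"weighted"` keeps all taxa but assigns each taxon weight
#' `1/(2 * class size)` so each class carries total weight 1/2; `"phylo"`
#' rebuilds the -1 class from progressively more distant sister clades of the
#' focal clade and then prunes the shortest-terminal-branch taxon from the
#' larger class until sizes match (requires a tree with branch lengths).
#'
#' @param h A [clade_hypothesis()].
#' @param method One of `"up"`, `"down"`, `"weighted"`, `"phylo"`.
#' @param tree Tree required for `"phylo"`.
#' @param seed Integer seed for the sampling methods.
#' @return A balanced [clade_hypothesis()].
#' @export
balance_classes <- function(h, method = c("up", "down", "weighted", "phylo"),
                            tree = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(h, "clade_hypothesis"))
  cm <- h$class_map
  n_pos <- sum(cm$label == 1L)
  n_neg <- sum(cm$label == -1L)
  if (n_pos == 0L || n_neg == 0L) stop2("both classes must be non-empty")

  if (method == "phylo") {
    if (is.null(tree)) stop2("phylo balancing requires a tree")
    if (n_pos == n_neg) {
      return(clade_hypothesis(h$name, class_map(cm$taxon, cm$label), h$provenance))
    }
    return(balance_phylo(h, tree))
  }
  if (method == "weighted") {
    size <- ifelse(cm$label == 1L, n_pos, n_neg)
    return(clade_hypothesis(h$name, class_map(cm$taxon, cm$label, 1 / (2 * size)),
                            h$provenance))
  }
  if (n_pos == n_neg) {
    return(clade_hypothesis(h$name, class_map(cm$taxon, cm$label), h$provenance))
  }
  minority <- if (n_pos < n_neg) 1L else -1L
  min_tx <- cm$taxon[cm$label == minority]
  maj_tx <- cm$taxon[cm$label == -minority]
  k <- length(maj_tx) - length(min_tx)
  if (method == "up") {
    extra <- with_seed(seed, sample(min_tx, k, replace = TRUE))
    taxa <- c(cm$taxon, extra)
    labels <- c(cm$label, rep(minority, k))
    return(clade_hypothesis(h$name,
                            class_map(taxa, labels, allow_duplicates = TRUE),
                            h$provenance))
  }
  # down
  if (length(min_tx) == 0L) stop2("down-sampling would empty a class")
  drop <- with_seed(seed, sample(maj_tx, k, replace = FALSE))
  keep <- !(cm$taxon %in% drop)
  clade_hypothesis(h$name, class_map(cm$taxon[keep], cm$label[keep]), h$provenance)
}
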