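#' Specification for a synthetic test dataset
#'
#' Describes a simulated study: a random rooted bifurcating tree, a focal
#' clade, and grouped nucleotide alignments in which a chosen group carries
#' perfectly clade-diagnostic ("planted") sites — state `A` inside the focal
#' clade, `C` outside — against a background of clade-independent variation.
#' Background sites draw an ancestral state uniformly from A/C/G/T and each
#' taxon substitutes it with probability `background_sub_prob` (uniformly to
#' another state); background characters are replaced by the gap character
#' with probability `missing_prob`. Planted sites are deterministic and never
#' gapped so encoder and solver tests have exact expectations.
#'
#' @param n_taxa Number of taxa (tips).
#' @param n_groups Number of groups (genes).
#' @param sites_per_group Alignment length of each group.
#' @param n_planted Number of planted diagnostic sites in `planted_group`.
#' @param planted_group Name of the group carrying the planted sites.
#' @param background_sub_prob Per-taxon substitution probability at
#'   background sites.
#' @param missing_prob Per-character gap probability at background sites.
#' @param seed Seed governing tree shape, site placement and background noise.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_taxa = 16L, n_groups = 5L, sites_per_group = 50L,
                         n_planted = 3L, planted_group = "g3",
                         background_sub_prob = 0.3, missing_prob = 0.02,
                         seed = 1L) {
  stopifnot(n_taxa >= 4L, n_groups >= 1L, sites_per_group >= 1L,
            n_planted >= 0L, n_planted <= sites_per_group,
            background_sub_prob >= 0, background_sub_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_groups = as.integer(n_groups),
                 sites_per_group = as.integer(sites_per_group),
                 n_planted = as.integer(n_planted),
                 planted_group = planted_group,
                 background_sub_prob = background_sub_prob,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "fixture_spec")
}

# deterministic focal-clade choice: internal node with tip count closest to
# n/2 (preferring the earliest in postorder on ties), never the root
pick_focal_node <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- clade_tip_sets(tree)
  internal <- postorder_internal_nodes(tree)
  sizes <- vapply(internal, function(nd) length(sets[[nd]]), integer(1))
  ok <- sizes >= 2L & sizes <= ntip - 2L
  cand <- internal[ok]
  internal[ok][which.min(abs(sizes[ok] - ntip / 2))]
}

#' Generate a synthetic tree + alignments with known ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture` list: `tree` (rooted, branch lengths, the focal node
#'   labeled `"focal"`), `groups` (list of `alignment_group`s),
#'   `focal_taxa`, `clade_name`, and `truth` (data frame of planted
#'   `group`/`position` pairs; empty when `n_planted = 0`).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  states <- c("A", "C", "G", "T")
  with_seed(spec$seed, {
    tree <- ape::rtree(spec$n_taxa, rooted = TRUE)
    tree$tip.label <- sprintf("t%02d", seq_len(spec$n_taxa))
    focal_node <- pick_focal_node(tree)
    labs <- rep("", tree$Nnode)
    labs[focal_node - spec$n_taxa] <- "focal"
    tree$node.label <- labs
    focal_taxa <- clade_tip_sets(tree)[[focal_node]]

    gnames <- sprintf("g%d", seq_len(spec$n_groups))
    planted_pos <- integer(0)
    if (spec$n_planted > 0L) {
      if (!(spec$planted_group %in% gnames)) {
        stop2("planted_group '", spec$planted_group, "' is not among the groups")
      }
      planted_pos <- sort(sample(spec$sites_per_group, spec$n_planted))
    }
    groups <- lapply(gnames, function(gn) {
      m <- matrix("", nrow = spec$n_taxa, ncol = spec$sites_per_group,
                  dimnames = list(tree$tip.label, NULL))
      for (s in seq_len(spec$sites_per_group)) {
        if (gn == spec$planted_group && s %in% planted_pos) {
          m[, s] <- ifelse(rownames(m) %in% focal_taxa, "A", "C")
        } else {
          anc <- sample(states, 1L)
          col <- rep(anc, spec$n_taxa)
          mut <- stats::runif(spec$n_taxa) < spec$background_sub_prob
          col[mut] <- vapply(which(mut), function(i)
            sample(setdiff(states, anc), 1L), "")
          gap <- stats::runif(spec$n_taxa) < spec$missing_prob
          col[gap] <- "-"
          m[, s] <- col
        }
      }
      seqs <- apply(m, 1L, paste, collapse = "")
      structure(list(name = gn, seqs = seqs), class = "alignment_group")
    })
    names(groups) <- gnames
    truth <- if (spec$n_planted > 0L) {
      data.frame(group = spec$planted_group, position = planted_pos,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = character(0), position = integer(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(tree = tree, groups = groups, focal_taxa = focal_taxa,
                   clade_name = "focal", truth = truth, spec = spec),
              class = "fixture")
  })
}

#' Write a fixture to disk as Newick + FASTA
#'
#' @param fx A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `list(tree, fastas, truth)` with the paths written.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(fx$tree, file = tree_path)
  fastas <- vapply(fx$groups, function(g) {
    p <- file.path(dir, paste0(g$name, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(g$seqs), filepath = p)
    p
  }, "")
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(fx$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(tree = tree_path, fastas = unname(fastas), truth = truth_path))
}
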