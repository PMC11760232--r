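#' Configure an end-to-end run
#'
#' Collects every option of the analysis pipeline. Exactly one of `classes`
#' (two-column class file) or `tree` (rooted Newick with labeled internal
#' node(s)) must be given.
#'
#' @param alignments Directory of aligned FASTA files, or a vector of paths
#'   (one file per group; file stem = group name).
#' @param classes Optional class-file path.
#' @param tree Optional Newick tree path.
#' @param clade_list Optional internal-node labels naming the focal clade(s).
#' @param gen_clade_list Optional `c(min_size, max_size)` to auto-enumerate
#'   clades.
#' @param class_bal `NULL` (none) or one of `"up"`, `"down"`, `"weighted"`,
#'   `"phylo"`.
#' @param data_type Character-validity mode, see [data_type_policy()].
#' @param bit_ct Minimum-count bit filter (0 disables).
#' @param lambda1,lambda2 Penalty levels for a single fit.
#' @param lambda1_grid,lambda2_grid Optional `c(min, max, step)`; when both
#'   are given a grid search replaces the single fit.
#' @param no_group_penalty Drop the group-norm penalty.
#' @param group_wt Optional group-weight file path.
#' @param kfold Optional fold count for cross-validation.
#' @param min_group_ct Early-stop threshold for the grid search.
#' @param stats_out Letters over \{P, G, H, S\} selecting output tables.
#' @param drphylo Also write the taxa-by-group contribution matrix.
#' @param absolute_lambdas Treat lambdas as absolute penalties, not fractions.
#' @param seed Seed for all stochastic steps (sampling balance, CV folds).
#' @param out Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(alignments, classes = NULL, tree = NULL,
                       clade_list = NULL, gen_clade_list = NULL,
                       class_bal = NULL, data_type = "default", bit_ct = 0L,
                       lambda1 = 0.1, lambda2 = 0.1,
                       lambda1_grid = NULL, lambda2_grid = NULL,
                       no_group_penalty = FALSE, group_wt = NULL,
                       kfold = NULL, min_group_ct = 1L, stats_out = "PGHS",
                       drphylo = FALSE, absolute_lambdas = FALSE,
                       seed = 42L, out = "esl_out") {
  if (is.null(classes) == is.null(tree)) {
    stop2("exactly one of 'classes' or 'tree' must be provided")
  }
  if (!is.null(class_bal)) {
    class_bal <- match.arg(class_bal, c("up", "down", "weighted", "phylo"))
    if (class_bal == "phylo" && is.null(tree)) {
      stop2("phylo class balancing requires a tree hypothesis")
    }
  }
  if (xor(is.null(lambda1_grid), is.null(lambda2_grid))) {
    stop2("lambda1_grid and lambda2_grid must be given together")
  }
  structure(list(alignments = alignments, classes = classes, tree = tree,
                 clade_list = clade_list, gen_clade_list = gen_clade_list,
                 class_bal = class_bal, data_type = data_type,
                 bit_ct = as.integer(bit_ct),
                 lambda1 = lambda1, lambda2 = lambda2,
                 lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 no_group_penalty = isTRUE(no_group_penalty),
                 group_wt = group_wt, kfold = kfold,
                 min_group_ct = as.integer(min_group_ct),
                 stats_out = stats_out, drphylo = isTRUE(drphylo),
                 absolute_lambdas = isTRUE(absolute_lambdas),
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

run_one_hypothesis <- function(h, groups, config, tree, gw) {
  hdir <- file.path(config$out, h$name)
  dir.create(hdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  warnings <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(wc) {
      warnings <<- c(warnings, conditionMessage(wc))
      invokeRestart("muffleWarning")
    })
  }
  t0 <- proc.time()[["elapsed"]]

  if (!is.null(config$class_bal)) {
    h <- balance_classes(h, config$class_bal, tree = tree, seed = config$seed)
  }
  cm <- h$class_map
  counts$taxa <- nrow(cm)
  counts$taxa_pos <- sum(cm$label == 1L)
  counts$taxa_neg <- sum(cm$label == -1L)

  policy <- data_type_policy(config$data_type)
  m <- wcollect(one_hot_encode(groups, cm$taxon, policy))
  counts$sites <- sum(m$group_lengths)
  counts$encoded_bits <- ncol(m$X)
  mf <- filter_bits(m, bit_ct = config$bit_ct)
  rc <- attr(mf, "removal_counts")
  counts$kept_bits <- unname(rc[["kept"]])
  counts$removed_monomorphic <- unname(rc[["monomorphic"]])
  counts$removed_singleton <- unname(rc[["singleton"]])
  counts$removed_bit_ct <- unname(rc[["bit_ct"]])
  utils::write.table(attr(mf, "removal_log"),
                     file.path(hdir, paste0(h$name, "_removed_bits.txt")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  opts <- solver_options(
    lambda_scale = if (config$absolute_lambdas) "absolute" else "fraction",
    group_penalty = !config$no_group_penalty)

  grid <- NULL
  if (!is.null(config$lambda1_grid)) {
    grid <- grid_search(mf, cm$label, cm$weight,
                        lambda1_grid = config$lambda1_grid,
                        lambda2_grid = config$lambda2_grid,
                        min_group_ct = config$min_group_ct,
                        group_weights = gw, opts = opts)
    utils::write.table(grid$results,
                       file.path(hdir, paste0(h$name, "_lambda_grid.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cv <- NULL
  if (!is.null(config$kfold)) {
    cv <- kfold_cv(m, cm, k = config$kfold, lambda1 = config$lambda1,
                   lambda2 = config$lambda2, bit_ct = config$bit_ct,
                   seed = config$seed, opts = opts)
    utils::write.table(cv$summary,
                       file.path(hdir, paste0(h$name, "_cv.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fit <- wcollect(fit_sgl_logistic(mf, cm$label, cm$weight,
                                   lambda1 = config$lambda1,
                                   lambda2 = config$lambda2,
                                   group_weights = gw, opts = opts))
  counts$nonzero_bits <- sum(fit$beta != 0)
  counts$selected_groups <- n_selected_groups(fit)
  report <- sparsity_scores(fit, data = mf)
  counts$selected_positions <- nrow(report$pss)
  write_stats(report, which = config$stats_out, outdir = hdir, name = h$name)
  write_esl_model(fit, file.path(hdir, paste0(h$name, "_model.txt")))
  if (config$drphylo) {
    dg <- drphylo_grid(fit, mf)
    utils::write.table(data.frame(taxon = rownames(dg), dg,
                                  check.names = FALSE),
                       file.path(hdir, paste0(h$name, "_drphylo_grid.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  manifest <- list(hypothesis = h$name, provenance = h$provenance,
                   counts = counts, converged = fit$converged,
                   warnings = warnings)
  jsonlite::write_json(manifest, file.path(hdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(name = h$name, status = "ok", counts = counts, model = fit,
       report = report, cv = cv, grid = grid, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' For each requested clade hypothesis: balance classes, one-hot encode the
#' alignments, filter bit-columns, fit (single penalty pair, and optionally a
#' grid search and/or cross-validation), compute sparsity scores, and write
#' tab-separated outputs plus a JSON manifest of stage-by-stage counts under
#' `out/<clade_name>/`. A failure in one hypothesis is logged and does not
#' stop the others.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `run_result` list: per-hypothesis results (fitted
#'   model, report, counts or error message) and `ok` (TRUE iff every
#'   hypothesis succeeded).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  groups <- read_alignment_groups(config$alignments)
  gw <- if (!is.null(config$group_wt)) read_group_weights(config$group_wt) else NULL
  tree <- NULL
  if (!is.null(config$tree)) {
    tree <- ape::read.tree(config$tree)
    hyps <- clades_from_tree(tree, clade_list = config$clade_list,
                             gen_clade_list = config$gen_clade_list)
  } else {
    hyps <- list(clade_hypothesis("hypothesis", read_class_file(config$classes),
                                  "class-file"))
  }
  results <- lapply(hyps, function(h) {
    tryCatch(run_one_hypothesis(h, groups, config, tree, gw),
             error = function(e) {
               message("hypothesis '", h$name, "' failed: ", conditionMessage(e))
               list(name = h$name, status = "error",
                    error = conditionMessage(e))
             })
  })
  names(results) <- vapply(hyps, `[[`, "", "name")
  ok <- all(vapply(results, `[[`, "", "status") == "ok")
  input_files <- c(config$classes, config$tree,
                   if (length(config$alignments) == 1L && dir.exists(config$alignments))
                     list.files(config$alignments, full.names = TRUE)
                   else config$alignments)
  manifest <- list(
    package = "sparseclade",
    version = as.character(utils::packageVersion("sparseclade")),
    seed = config$seed,
    config = config[setdiff(names(config), "out")],
    input_md5 = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    hypotheses = lapply(results, function(r) {
      r[setdiff(names(r), c("model", "report", "cv", "grid"))]
    }),
    ok = ok)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(list(results = results, ok = ok, out = config$out),
                      class = "run_result"))
}

#' @export
print.run_result <- function(x, ...) {
  st <- vapply(x$results, `[[`, "", "status")
  cat(sprintf("<run_result: %d hypothesis/es (%d ok, %d failed) in '%s'>\n",
              length(st), sum(st == "ok"), sum(st != "ok"), x$out))
  invisible(x)
}
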