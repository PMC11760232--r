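align_columns <- function(model, newdata, warn_extra = TRUE) {
  stopifnot(inherits(newdata, "bit_matrix"))
  ids <- names(model$beta)
  if (is.null(ids)) stop2("model has no feature IDs; cannot align new data")
  hit <- match(ids, newdata$features$id)
  frac_missing <- mean(is.na(hit))
  if (frac_missing > 0.5) {
    stop2(sprintf("%.0f%% of model features are absent from the new data",
                  100 * frac_missing))
  }
  extra <- sum(!(newdata$features$id %in% ids))
  if (warn_extra && extra > 0L) {
    warn2(extra, " bit-column(s) in the new data are not in the model and ",
          "were ignored")
  }
  X <- Matrix::Matrix(0, nrow = nrow(newdata$X), ncol = length(ids), sparse = TRUE)
  ok <- !is.na(hit)
  X[, ok] <- newdata$X[, hit[ok], drop = FALSE]
  X
}

#' Species prediction scores and probabilities
#'
#' `SPS = x . beta + intercept` (the linear predictor),
#' `SPP = 1 / (1 + exp(-SPS))`. A taxon is classified +1 iff `SPS > 0`
#' (ties at exactly 0 go to -1). Columns of `newdata` are aligned to the
#' model's feature IDs; model features absent from the new data contribute 0.
#'
#' @param object An `esl_model`.
#' @param newdata A `bit_matrix` of taxa to score. When omitted the model
#'   cannot be applied (no training data is stored on the model).
#' @param warn_extra Warn when `newdata` carries bit-columns unknown to the
#'   model (they are always ignored).
#' @param ... Unused.
#' @return Data frame: `taxon`, `SPS`, `SPP`, `class`.
#' @export
predict.esl_model <- function(object, newdata, warn_extra = TRUE, ...) {
  X <- align_columns(object, newdata, warn_extra = warn_extra)
  sps <- as.numeric(X %*% object$beta) + object$intercept
  data.frame(taxon = newdata$taxa,
             SPS = sps,
             SPP = stats::plogis(sps),
             class = ifelse(sps > 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Position, group and hypothesis sparsity scores
#'
#' Aggregates coefficient magnitudes: `PSS(position) = sum |beta|` over the
#' position's bit-columns, `GSS(group) = sum PSS` over the group's positions
#' (reported raw and normalized by the maximum GSS), and
#' `HSS = sum_g GSS(g) = sum |beta|`. Positions and groups whose score is
#' zero are omitted.
#'
#' @param model An `esl_model` fitted on a `bit_matrix`.
#' @param data Optional `bit_matrix` of the taxa to score; when given, the
#'   report also carries the SPS/SPP prediction table.
#' @return A `sparsity_report`: `list(pss, gss, hss, predictions)`.
#' @export
sparsity_scores <- function(model, data = NULL) {
  feats <- model$features
  if (is.null(feats)) stop2("model carries no feature metadata")
  ab <- abs(model$beta)
  key <- paste(feats$group, feats$pos, sep = "\r")
  agg <- rowsum(ab, key, reorder = FALSE)
  pss <- data.frame(group = sub("\r.*", "", rownames(agg)),
                    position = as.integer(sub(".*\r", "", rownames(agg))),
                    PSS = as.numeric(agg), stringsAsFactors = FALSE)
  pss <- pss[pss$PSS > 0, , drop = FALSE]
  pss <- pss[order(match(pss$group, model$groups$name), pss$position), , drop = FALSE]
  rownames(pss) <- NULL
  gagg <- rowsum(ab, feats$group, reorder = FALSE)
  gss <- data.frame(group = rownames(gagg), GSS = as.numeric(gagg),
                    stringsAsFactors = FALSE)
  gss <- gss[gss$GSS > 0, , drop = FALSE]
  gss$GSS_norm <- if (nrow(gss)) gss$GSS / max(gss$GSS) else numeric(0)
  gss <- gss[order(-gss$GSS), , drop = FALSE]
  rownames(gss) <- NULL
  structure(list(pss = pss, gss = gss, hss = sum(ab),
                 predictions = if (!is.null(data)) predict(model, data) else NULL),
            class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("<sparsity_report: %d position(s), %d group(s), HSS = %.4g>\n",
              nrow(x$pss), nrow(x$gss), x$hss))
  invisible(x)
}

#' Per-group contribution matrix (taxa x groups)
#'
#' Cell `(t, g)` is the additive contribution of group `g`'s bit-columns to
#' taxon `t`'s prediction score; row sums plus the intercept reproduce SPS
#' exactly. Visualizing this matrix localizes gene-species combinations that
#' pull a taxon away from its clade (fragile placements).
#'
#' @param model An `esl_model`.
#' @param data A `bit_matrix` of taxa to decompose.
#' @return Numeric matrix with taxa as rows and group names as columns.
#' @export
drphylo_grid <- function(model, data) {
  X <- align_columns(model, data)
  g <- model$groups
  out <- matrix(0, nrow = nrow(X), ncol = nrow(g),
                dimnames = list(data$taxa, g$name))
  for (k in seq_len(nrow(g))) {
    ix <- g$start[k]:g$end[k]
    out[, k] <- as.numeric(X[, ix, drop = FALSE] %*% model$beta[ix])
  }
  out
}

#' Stratified k-fold cross-validation
#'
#' Splits taxa into `k` folds preserving class proportions, refits on each
#' training set — with the monomorphic/singleton/`bit_ct` filters re-derived
#' on the training taxa only, to avoid information leakage — and scores the
#' held-out taxa. Classification accuracy thresholds SPP at 0.5; RMSE
#' compares SPP with the 0/1 class indicator.
#'
#' @param m An unfiltered `bit_matrix` over all taxa in `cm`.
#' @param cm A [class_map()] (row order must match `m$taxa`).
#' @param k Number of folds (>= 2; each class must have >= k members).
#' @param lambda1,lambda2 Penalty fractions for every fold's fit.
#' @param bit_ct Minimum-count filter re-applied within each fold.
#' @param seed Seed for fold assignment.
#' @param opts [solver_options()].
#' @return A `cv_result`: per-fold table (`fold`, `n_test`, `accuracy`,
#'   `rmse`, `n_selected_groups`), the fold assignment, and fold models.
#' @export
kfold_cv <- function(m, cm, k, lambda1 = 0.1, lambda2 = 0.1, bit_ct = 0L,
                     seed = 1L, opts = solver_options()) {
  stopifnot(inherits(m, "bit_matrix"), inherits(cm, "class_map"))
  if (!identical(m$taxa, cm$taxon)) stop2("bit matrix rows do not match the class map")
  k <- as.integer(k)
  if (k < 2L) stop2("k must be at least 2")
  n_class <- table(factor(cm$label, levels = c(-1L, 1L)))
  if (any(n_class < k)) {
    stop2("each class needs at least k = ", k, " members for cross-validation ",
          "(classes have ", n_class[["1"]], " and ", n_class[["-1"]],
          "); avoid cross-validation for very small focal clades")
  }
  fold <- integer(nrow(cm))
  with_seed(seed, {
    for (lab in c(1L, -1L)) {
      ix <- which(cm$label == lab)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    mt <- filter_bits(subset_taxa(m, train), bit_ct = bit_ct)
    fit <- fit_sgl_logistic(mt, cm$label[train], cm$weight[train],
                            lambda1 = lambda1, lambda2 = lambda2, opts = opts)
    pr <- predict(fit, subset_taxa(m, test), warn_extra = FALSE)
    ind <- as.integer(cm$label[test] == 1L)
    list(test_taxa = cm$taxon[test], model = fit, predictions = pr,
         accuracy = mean(pr$class == cm$label[test]),
         rmse = sqrt(mean((pr$SPP - ind)^2)))
  })
  summary <- data.frame(fold = seq_len(k),
                        n_test = vapply(folds, function(f) length(f$test_taxa), integer(1)),
                        accuracy = vapply(folds, `[[`, numeric(1), "accuracy"),
                        rmse = vapply(folds, `[[`, numeric(1), "rmse"),
                        n_selected_groups = vapply(folds, function(f)
                          n_selected_groups(f$model), integer(1)))
  structure(list(summary = summary, fold = fold, folds = folds, k = k,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, mean accuracy %.3f, mean RMSE %.3f>\n",
              x$k, mean(x$summary$accuracy), mean(x$summary$rmse)))
  invisible(x)
}

lambda_seq <- function(grid) {
  if (length(grid) == 1L) return(as.numeric(grid))
  if (length(grid) != 3L) stop2("a lambda grid must be c(min, max, step)")
  mn <- grid[1]; mx <- grid[2]; st <- grid[3]
  if (st <= 0 || mn < 0 || mx > 1 || mn > mx) {
    stop2("lambda grid requires 0 <= min <= max <= 1 and step > 0")
  }
  vals <- seq(mn, mx, by = st)
  round(vals, 10)
}

#' Grid search over the (lambda1, lambda2) penalty space
#'
#' Fits a model for each cell of the Cartesian grid, iterating lambda values
#' in ascending order. Within each lambda2 row, once a fitted model selects
#' fewer than `min_group_ct` groups, the remaining (larger) lambda1 values in
#' that row are skipped and marked `stopped_early` — larger penalties can only
#' be sparser, so those models are never useful.
#'
#' @param m A filtered `bit_matrix`.
#' @param y Responses in \{+1, -1\}.
#' @param w Sample weights.
#' @param lambda1_grid,lambda2_grid `c(min, max, step)` on the fractional
#'   scale (or a single value).
#' @param min_group_ct Early-stop threshold on the selected-group count.
#' @param group_weights,opts Passed to [fit_sgl_logistic()].
#' @return A `lambda_grid`: results data frame (`lambda1`, `lambda2`,
#'   `n_selected_groups`, `n_nonzero`, `stopped_early`) plus the fitted models.
#' @export
grid_search <- function(m, y, w = NULL, lambda1_grid, lambda2_grid,
                        min_group_ct = 1L, group_weights = NULL,
                        opts = solver_options()) {
  l1s <- lambda_seq(lambda1_grid)
  l2s <- lambda_seq(lambda2_grid)
  if (length(l1s) == 0L || length(l2s) == 0L) stop2("empty lambda grid")
  rows <- list(); models <- list()
  for (l2 in l2s) {
    stopped <- FALSE
    for (l1 in l1s) {
      if (stopped) {
        rows[[length(rows) + 1L]] <- data.frame(lambda1 = l1, lambda2 = l2,
                                                n_selected_groups = NA_integer_,
                                                n_nonzero = NA_integer_,
                                                stopped_early = TRUE)
        models[length(models) + 1L] <- list(NULL)
        next
      }
      fit <- fit_sgl_logistic(m, y, w, lambda1 = l1, lambda2 = l2,
                              group_weights = group_weights, opts = opts)
      ng <- n_selected_groups(fit)
      rows[[length(rows) + 1L]] <- data.frame(lambda1 = l1, lambda2 = l2,
                                              n_selected_groups = ng,
                                              n_nonzero = sum(fit$beta != 0),
                                              stopped_early = FALSE)
      models[[length(models) + 1L]] <- fit
      if (ng < min_group_ct) stopped <- TRUE
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res, models = models,
                 min_group_ct = as.integer(min_group_ct)),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  fitted <- sum(!x$results$stopped_early)
  cat(sprintf("<lambda_grid: %d cell(s), %d fitted, %d skipped (min_group_ct = %d)>\n",
              nrow(x$results), fitted, nrow(x$results) - fitted, x$min_group_ct))
  invisible(x)
}

#' Write sparsity-score tables as tab-separated files
#'
#' One file per requested letter: `P` (position scores), `G` (group scores),
#' `H` (the hypothesis score), `S` (per-taxon SPS/SPP/class; requires that
#' the report was built with prediction data).
#'
#' @param report A [sparsity_scores()] report.
#' @param which String over \{P, G, H, S\}, e.g. `"PGHS"`.
#' @param outdir Output directory (created if absent).
#' @param name Hypothesis name used as the file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_stats <- function(report, which = "PGHS", outdir = ".", name = "hypothesis") {
  letters_req <- strsplit(which, "", fixed = TRUE)[[1]]
  if (length(letters_req) == 0L) stop2("'which' must be a non-empty string over PGHS")
  bad <- setdiff(letters_req, c("P", "G", "H", "S"))
  if (length(bad)) stop2("unknown stats letter(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- character(0)
  for (l in unique(letters_req)) {
    paths <- c(paths, switch(l,
      P = wr(report$pss, file.path(outdir, paste0(name, "_PSS.txt"))),
      G = wr(report$gss, file.path(outdir, paste0(name, "_GSS.txt"))),
      H = wr(data.frame(hypothesis = name, HSS = report$hss),
             file.path(outdir, paste0(name, "_HSS.txt"))),
      S = {
        if (is.null(report$predictions)) {
          stop2("report has no predictions; build it with sparsity_scores(model, data)")
        }
        wr(report$predictions, file.path(outdir, paste0(name, "_SPS_SPP.txt")))
      }))
  }
  invisible(paths)
}

#' Serialize a fitted model to a text file
#'
#' Writes a versioned, diff-able tab-separated file: header lines (prefixed
#' `#`) carry the intercept, penalty levels, data-type policy, and per-group
#' alignment lengths and weights; body rows list the nonzero coefficients by
#' feature ID (`group|position|state`).
#'
#' @param model An `esl_model` fitted on a `bit_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_esl_model <- function(model, path) {
  if (is.null(names(model$beta))) stop2("model has no feature IDs")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t"), con)
  wl("#esl_model_version", "1")
  wl("#intercept", format(model$intercept, digits = 17))
  wl("#lambda1", format(model$lambda1, digits = 17))
  wl("#lambda2", format(model$lambda2, digits = 17))
  wl("#lambda1_abs", format(model$lambda1_abs, digits = 17))
  wl("#lambda2_abs", format(model$lambda2_abs, digits = 17))
  wl("#data_type", model$data_type %||% "default")
  for (k in seq_len(nrow(model$groups))) {
    nm <- model$groups$name[k]
    len <- if (!is.null(model$group_lengths)) model$group_lengths[[nm]] else NA
    wl("#group", nm, len, format(model$groups$weight[k], digits = 17))
  }
  wl("feature_id", "beta")
  nz <- which(model$beta != 0)
  for (ix in nz) {
    wl(names(model$beta)[ix], format(model$beta[ix], digits = 17))
  }
  invisible(path)
}

#' Read a serialized model
#'
#' @param path File written by [write_esl_model()].
#' @return A `saved_esl_model` list: nonzero coefficients, intercept,
#'   penalties, data type, and per-group lengths/weights.
#' @export
read_esl_model <- function(path) {
  if (!file.exists(path)) stop2("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  hv <- function(key) {
    hit <- hdr[startsWith(hdr, paste0(key, "\t"))]
    if (length(hit) == 0L) stop2("model file lacks header ", key)
    strsplit(hit[1], "\t", fixed = TRUE)[[1]][-1]
  }
  glines <- hdr[startsWith(hdr, "#group\t")]
  gparts <- strsplit(glines, "\t", fixed = TRUE)
  groups <- data.frame(name = vapply(gparts, `[[`, "", 2L),
                       length = as.integer(vapply(gparts, `[[`, "", 3L)),
                       weight = as.numeric(vapply(gparts, `[[`, "", 4L)),
                       stringsAsFactors = FALSE)
  body <- body[nzchar(body)]
  if (length(body) == 0L || body[1] != "feature_id\tbeta") {
    stop2("malformed model file: ", path)
  }
  beta <- numeric(0)
  if (length(body) > 1L) {
    bp <- strsplit(body[-1], "\t", fixed = TRUE)
    beta <- stats::setNames(as.numeric(vapply(bp, `[[`, "", 2L)),
                            vapply(bp, `[[`, "", 1L))
  }
  structure(list(beta = beta,
                 intercept = as.numeric(hv("#intercept")),
                 lambda1 = as.numeric(hv("#lambda1")),
                 lambda2 = as.numeric(hv("#lambda2")),
                 lambda1_abs = as.numeric(hv("#lambda1_abs")),
                 lambda2_abs = as.numeric(hv("#lambda2_abs")),
                 data_type = hv("#data_type"),
                 groups = groups),
            class = "saved_esl_model")
}

#' Score new taxa with a saved model
#'
#' Reads aligned FASTA files for the groups that carry nonzero coefficients,
#' verifies their alignment lengths against the lengths stored in the model,
#' sets each stored bit (`group|position|state`) to 1 when the taxon carries
#' exactly that state at that position (0 for gaps, missing data, and unseen
#' states), and computes SPS/SPP.
#'
#' @param model_file Path written by [write_esl_model()] (or a
#'   `saved_esl_model`).
#' @param alignments Directory or vector of FASTA paths covering the model's
#'   groups with nonzero coefficients.
#' @param out Optional path for a tab-separated prediction table.
#' @return Data frame `taxon`, `SPS`, `SPP`, `class`.
#' @export
apply_saved_model <- function(model_file, alignments, out = NULL) {
  sm <- if (inherits(model_file, "saved_esl_model")) model_file else read_esl_model(model_file)
  policy <- data_type_policy(sm$data_type)
  groups <- read_alignment_groups(alignments)
  ids <- names(sm$beta)
  feat_group <- sub("\\|.*$", "", ids)
  rest <- sub("^[^|]*\\|", "", ids)
  feat_pos <- as.integer(sub("\\|.*$", "", rest))
  feat_state <- sub("^[^|]*\\|", "", rest)
  need <- unique(feat_group)
  missing_groups <- setdiff(need, names(groups))
  if (length(missing_groups)) {
    stop2("alignment file(s) missing for model group(s): ",
          paste(missing_groups, collapse = ", "))
  }
  for (nm in need) {
    stored <- sm$groups$length[sm$groups$name == nm]
    actual <- nchar(groups[[nm]]$seqs[[1]])
    if (length(stored) == 1L && !is.na(stored) && stored != actual) {
      stop2("alignment length mismatch for group '", nm, "': model expects ",
            stored, ", file has ", actual)
    }
  }
  taxa <- sort(unique(unlist(lapply(groups[need], function(g) names(g$seqs)))))
  sps <- rep(sm$intercept, length(taxa))
  names(sps) <- taxa
  for (nm in need) {
    g <- groups[[nm]]
    sel <- which(feat_group == nm)
    chars <- matrix(unlist(strsplit(g$seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(g$seqs), byrow = TRUE)
    chars <- matrix(normalize_chars(chars, policy), nrow = length(g$seqs))
    rownames(chars) <- names(g$seqs)
    for (f in sel) {
      carriers <- rownames(chars)[!is.na(chars[, feat_pos[f]]) &
                                    chars[, feat_pos[f]] == feat_state[f]]
      sps[carriers] <- sps[carriers] + sm$beta[f]
    }
  }
  res <- data.frame(taxon = taxa, SPS = as.numeric(sps),
                    SPP = stats::plogis(as.numeric(sps)),
                    class = ifelse(sps > 0, 1L, -1L),
                    stringsAsFactors = FALSE)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
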