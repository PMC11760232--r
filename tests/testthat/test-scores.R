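fit_fixture_model <- function(seed = 1, lambda1 = 0.1, lambda2 = 0.1) {
  ds <- fixture_dataset(seed = seed)
  fit <- fit_sgl_logistic(ds$mf, ds$cm$label, ds$cm$weight,
                          lambda1 = lambda1, lambda2 = lambda2)
  list(ds = ds, fit = fit)
}

test_that("predictions follow the logistic link and the SPS > 0 rule", {
  r <- fit_fixture_model(seed = 1, lambda1 = 1, lambda2 = 0)  # null model
  fit <- r$fit
  fit$intercept <- 0
  pr <- predict(fit, r$ds$mf)
  expect_equal(pr$SPS, rep(0, nrow(pr)))
  expect_equal(pr$SPP, rep(0.5, nrow(pr)))
  expect_equal(pr$class, rep(-1L, nrow(pr)))  # tie at 0 goes to -1
  fit$intercept <- 1
  pr1 <- predict(fit, r$ds$mf)
  expect_equal(pr1$SPP, rep(1 / (1 + exp(-1)), nrow(pr1)))
  expect_equal(pr1$SPP[1], 0.731059, tolerance = 1e-6)
  expect_equal(pr1$class, rep(1L, nrow(pr1)))
})

test_that("training predictions separate a planted-signal fixture", {
  r <- fit_fixture_model(seed = 1)
  pr <- predict(r$fit, r$ds$mf)
  lab <- r$ds$cm$label
  expect_true(all(pr$SPP[lab == 1] > 0.5))
  expect_true(all(pr$SPP[lab == -1] < 0.5))
  expect_equal(pr$class, lab)
})

test_that("sparsity scores aggregate |beta| by position, group and hypothesis", {
  r <- fit_fixture_model(seed = 1)
  fit <- r$fit
  rep_ <- sparsity_scores(fit, data = r$ds$mf)
  expect_equal(rep_$hss, sum(abs(fit$beta)))
  expect_equal(sum(rep_$gss$GSS), rep_$hss)
  expect_equal(sum(rep_$pss$PSS), rep_$hss)
  expect_true(all(rep_$pss$PSS > 0))
  expect_equal(max(rep_$gss$GSS_norm), 1)
  expect_false(is.null(rep_$predictions))

  # hand case: one position with beta (0.5, -0.5), every other group silent
  f <- fit$features
  key <- paste(f$group, f$pos)
  two_bit <- names(which(table(key) >= 2))[1]
  same_pos <- which(key == two_bit)
  fit$beta[] <- 0
  fit$beta[same_pos[1:2]] <- c(0.5, -0.5)
  rp <- sparsity_scores(fit)
  expect_equal(nrow(rp$pss), 1L)
  expect_equal(rp$pss$PSS, 1)
  expect_equal(rp$gss$GSS, 1)
  expect_equal(rp$hss, 1)
  expect_equal(rp$gss$group, f$group[same_pos[1]])

  # all-zero model: empty tables, zero hypothesis score
  fit$beta[] <- 0
  r0 <- sparsity_scores(fit)
  expect_equal(nrow(r0$pss), 0L)
  expect_equal(nrow(r0$gss), 0L)
  expect_equal(r0$hss, 0)
})

test_that("the per-group contribution matrix is an exact SPS decomposition", {
  r <- fit_fixture_model(seed = 2)
  dg <- drphylo_grid(r$fit, r$ds$mf)
  pr <- predict(r$fit, r$ds$mf)
  expect_equal(dim(dg), c(length(r$ds$mf$taxa), 5L))
  expect_lt(max(abs(rowSums(dg) + r$fit$intercept - pr$SPS)), 1e-12)
  # single-group restriction: that column is SPS - intercept
  nz_groups <- colnames(dg)[colSums(dg != 0) > 0]
  other <- setdiff(colnames(dg), nz_groups)
  expect_true(all(dg[, other] == 0))
})

test_that("stratified k-fold CV partitions taxa and aces a separable fixture", {
  taxa <- sprintf("t%02d", 1:10)
  labels <- rep(c(1L, -1L), each = 5)
  cm <- class_map(taxa, labels)
  set.seed(5)
  diag_seq <- ifelse(labels == 1L, "AAA", "CCC")
  noise <- replicate(10, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                               collapse = ""))
  g1 <- make_group("g1", setNames(paste0(diag_seq, substr(noise, 1, 9)), taxa))
  g2 <- make_group("g2", setNames(noise, taxa))
  m <- one_hot_encode(list(g1 = g1, g2 = g2), taxa, data_type_policy("nucleotide"))
  cv <- kfold_cv(m, cm, k = 5, lambda1 = 0.05, lambda2 = 0.05, seed = 3)
  expect_equal(cv$summary$n_test, rep(2L, 5))
  held <- unlist(lapply(cv$folds, `[[`, "test_taxa"))
  expect_setequal(held, taxa)        # every taxon held out exactly once
  expect_equal(length(held), 10L)
  # folds are stratified: one taxon of each class per fold
  for (f in cv$folds) {
    expect_equal(sum(cm$label[match(f$test_taxa, cm$taxon)] == 1L), 1L)
  }
  expect_equal(mean(cv$summary$accuracy), 1)
  # deterministic under a fixed seed
  cv2 <- kfold_cv(m, cm, k = 5, lambda1 = 0.05, lambda2 = 0.05, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$summary, cv2$summary)
  # a 3-member class cannot support 5 folds
  cm_small <- class_map(taxa, c(rep(1L, 3), rep(-1L, 7)))
  expect_error(kfold_cv(m, cm_small, k = 5), "at least k")
})

test_that("grid search walks the lambda lattice and stops rows early", {
  expect_equal(sparseclade:::lambda_seq(c(0.1, 0.3, 0.1)), c(0.1, 0.2, 0.3))
  expect_error(sparseclade:::lambda_seq(c(0.3, 0.1, 0.1)), "min <= max")

  ds <- fixture_dataset(seed = 1)
  gr <- grid_search(ds$mf, ds$cm$label, ds$cm$weight,
                    lambda1_grid = c(0.1, 0.9, 0.2), lambda2_grid = 0.2,
                    min_group_ct = 2L)
  res <- gr$results
  expect_equal(res$lambda1, seq(0.1, 0.9, 0.2))
  # once a model selects < 2 groups, later cells in the row are skipped
  trig <- which(res$n_selected_groups < 2)[1]
  expect_false(is.na(trig))
  if (trig < nrow(res)) {
    expect_true(all(res$stopped_early[(trig + 1):nrow(res)]))
    expect_true(all(is.na(res$n_selected_groups[(trig + 1):nrow(res)])))
  }
  # fitted cells: nonzero counts non-increasing in lambda1
  fitted <- res[!res$stopped_early, ]
  expect_true(all(diff(fitted$n_nonzero) <= 0))
})

test_that("stats files round-trip and respect the PGHS selector", {
  r <- fit_fixture_model(seed = 1)
  rep_ <- sparsity_scores(r$fit, data = r$ds$mf)
  dir <- withr::local_tempdir()
  paths <- write_stats(rep_, "PGHS", outdir = dir, name = "focal")
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  p_in <- utils::read.table(file.path(dir, "focal_PSS.txt"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  expect_equal(p_in, rep_$pss)
  s_in <- utils::read.table(file.path(dir, "focal_SPS_SPP.txt"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  expect_equal(names(s_in), c("taxon", "SPS", "SPP", "class"))
  expect_length(write_stats(rep_, "S", outdir = dir, name = "s_only"), 1L)
  expect_error(write_stats(rep_, "PQ", outdir = dir), "unknown stats letter")
  expect_error(write_stats(sparsity_scores(r$fit), "S", outdir = dir),
               "no predictions")
})

test_that("saved models reproduce training scores and handle novel taxa", {
  r <- fit_fixture_model(seed = 2)
  fx <- r$ds$fixture
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  mp <- withr::local_tempfile(fileext = ".model")
  write_esl_model(r$fit, mp)
  sm <- read_esl_model(mp)
  expect_equal(sort(names(sm$beta)),
               sort(names(r$fit$beta[r$fit$beta != 0])))

  pr_new <- apply_saved_model(mp, dir)
  pr_train <- predict(r$fit, r$ds$mf)
  hit <- match(pr_train$taxon, pr_new$taxon)
  expect_equal(pr_new$SPS[hit], pr_train$SPS, tolerance = 1e-12)
  expect_equal(pr_new$SPP[hit], pr_train$SPP, tolerance = 1e-12)

  # an all-gap taxon scores exactly the intercept
  dir2 <- file.path(dir, "aug")
  dir.create(dir2)
  for (g in fx$groups) {
    seqs <- c(g$seqs, allgap = strrep("-", nchar(g$seqs[[1]])))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                                file.path(dir2, paste0(g$name, ".fasta")))
  }
  pr_gap <- apply_saved_model(mp, dir2)
  gap_row <- pr_gap[pr_gap$taxon == "allgap", ]
  expect_equal(gap_row$SPS, r$fit$intercept)
  expect_equal(gap_row$SPP, stats::plogis(r$fit$intercept))

  # alignment length mismatch is a hard error
  dir3 <- file.path(dir, "short")
  dir.create(dir3)
  for (g in fx$groups) {
    seqs <- substr(g$seqs, 1, nchar(g$seqs[[1]]) - 1)
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                                file.path(dir3, paste0(g$name, ".fasta")))
  }
  expect_error(apply_saved_model(mp, dir3), "length mismatch")
})
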