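# Independent oracles and small builders shared across the suite.

make_group <- function(name, seqs) {
  structure(list(name = name, seqs = seqs), class = "alignment_group")
}

# central-difference gradient: keeps the optimality check independent of the
# package's analytic gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# max-norm subgradient optimality residual of the sparse group lasso logistic
# objective at a fitted (beta, intercept)
kkt_residual <- function(fit, X, y, w) {
  w <- w / sum(w)
  b <- fit$beta; c0 <- fit$intercept
  f <- function(th) logistic_loss(th[-length(th)], th[length(th)], X, y, w)
  g <- num_grad(f, c(b, c0))
  gc <- g[length(g)]; g <- g[-length(g)]
  l1 <- fit$lambda1_abs; l2 <- fit$lambda2_abs; gs <- fit$groups
  r <- abs(gc)
  for (k in seq_len(nrow(gs))) {
    ix <- gs$start[k]:gs$end[k]
    bg <- b[ix]; gg <- g[ix]; wk <- gs$weight[k]
    if (all(bg == 0)) {
      sft <- sign(gg) * pmax(abs(gg) - l1, 0)
      r <- max(r, max(0, sqrt(sum(sft^2)) - l2 * wk))
    } else {
      nrm <- sqrt(sum(bg^2))
      for (i in seq_along(ix)) {
        ri <- if (bg[i] != 0) {
          abs(gg[i] + l1 * sign(bg[i]) + l2 * wk * bg[i] / nrm)
        } else {
          max(0, abs(gg[i]) - l1)
        }
        r <- max(r, ri)
      }
    }
  }
  r
}

prox_objective <- function(x, v, l1, l2, w) {
  0.5 * sum((x - v)^2) + l1 * sum(abs(x)) + l2 * w * sqrt(sum(x^2))
}

# fine-grid numerical minimizer of the prox objective (grid seed + simplex
# polish; golden-section in 1-D)
num_prox <- function(v, l1, l2, w) {
  d <- length(v)
  f <- function(x) prox_objective(x, v, l1, l2, w)
  if (d == 1L) {
    return(stats::optimize(f, lower = -abs(v) - 1, upper = abs(v) + 1,
                           tol = 1e-12)$minimum)
  }
  gpts <- seq(-max(abs(v)) - 0.5, max(abs(v)) + 0.5,
              length.out = if (d == 2L) 41 else 15)
  grid <- as.matrix(expand.grid(rep(list(gpts), d)))
  best <- grid[which.min(apply(grid, 1, f)), ]
  res <- lapply(list(best, v, numeric(d)), function(s) {
    stats::optim(s, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-16, maxit = 5000))
  })
  res[[which.min(vapply(res, `[[`, numeric(1), "value"))]]$par
}

single_group_structure <- function(d, w = 1) {
  structure(data.frame(name = "g", start = 1L, end = as.integer(d),
                       weight = w, stringsAsFactors = FALSE),
            class = c("group_structure", "data.frame"))
}

# independent generic convex minimizer of the L1-logistic objective:
# beta = bp - bm with bp, bm >= 0 turns the L1 term linear, so box-constrained
# L-BFGS-B applies
l1_logistic_oracle <- function(X, y, w, l1) {
  p <- ncol(X)
  w <- w / sum(w)
  fobj <- function(th) {
    b <- th[1:p] - th[(p + 1):(2 * p)]
    m <- as.numeric(X %*% b) + th[2 * p + 1]
    z <- -y * m
    sum(w * ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))) +
      l1 * sum(th[1:(2 * p)])
  }
  fgr <- function(th) {
    b <- th[1:p] - th[(p + 1):(2 * p)]
    m <- as.numeric(X %*% b) + th[2 * p + 1]
    r <- w * y * stats::plogis(-y * m)
    gb <- -as.numeric(crossprod(X, r))
    c(gb + l1, -gb + l1, -sum(r))
  }
  o <- stats::optim(rep(0, 2 * p + 1), fobj, fgr, method = "L-BFGS-B",
                    lower = c(rep(0, 2 * p), -Inf),
                    control = list(factr = 1e1, maxit = 5000))
  list(value = o$value,
       beta = o$par[1:p] - o$par[(p + 1):(2 * p)],
       intercept = o$par[2 * p + 1])
}

# encoded + filtered matrix and class map for a planted-signal fixture
fixture_dataset <- function(seed = 1, spec = NULL) {
  fx <- make_fixture(spec %||% fixture_spec(seed = seed))
  h <- clades_from_tree(fx$tree)[[1]]
  cm <- h$class_map
  m <- one_hot_encode(fx$groups, cm$taxon, data_type_policy("nucleotide"))
  list(fixture = fx, hypothesis = h, cm = cm, m = m,
       mf = filter_bits(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
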