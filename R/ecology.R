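## Self-contained community statistics: Shannon diversity, Bray-Curtis,
## nonmetric multidimensional scaling (Kruskal stress-1, isotonic
## regression + majorization updates), PERMANOVA, Mantel, two-way ANOVA
## with Tukey HSD, and a REML random-intercept mixed model. External
## packages (vegan, lme4) are used only as oracles in the test suite.

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with `p_i > 0`, where `p` is the profile
#' normalised to sum 1.
#'
#' @param abundance_profile Non-negative numeric vector (one sample's
#'   abundances).
#' @return `H`, or `NA` with a warning for an all-zero profile.
#' @export
shannon_diversity <- function(abundance_profile) {
  assert_that(all(abundance_profile >= 0), "abundances must be non-negative")
  s <- sum(abundance_profile)
  if (s == 0) {
    warning("all-zero profile: Shannon H undefined", call. = FALSE)
    return(NA_real_)
  }
  p <- abundance_profile[abundance_profile > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(s, t) = sum|x - y| / sum(x + y)` on (optionally square-root
#' transformed) profiles. Sample pairs whose profiles are both all-zero
#' get `d = 0` with a warning.
#'
#' @param x sample x taxon non-negative matrix.
#' @param transform `"sqrt"` (default, the convention for CPM profiles) or
#'   `"none"`.
#' @return Symmetric sample x sample matrix with zero diagonal and entries
#'   in `[0, 1]`; the transform is recorded in attribute `"transform"`.
#' @export
bray_curtis <- function(x, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  assert_that(all(x >= 0), "Bray-Curtis input must be non-negative")
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[i, ] + x[j, ])
      if (denom == 0) {
        if (!warned) {
          warning("sample pair(s) with both profiles all-zero: d set to 0",
                  call. = FALSE)
          warned <- TRUE
        }
        val <- 0
      } else {
        val <- sum(abs(x[i, ] - x[j, ])) / denom
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  attr(d, "transform") <- transform
  d
}

## Pool-adjacent-violators: least-squares isotonic fit to y in given order.
pava <- function(y) {
  n <- length(y)
  level <- y
  weight <- rep(1, n)
  idx <- integer(n)  # block bookkeeping via stack
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    level[nb] <- y[i]
    weight[nb] <- 1
    idx[nb] <- i
    while (nb > 1L && level[nb - 1L] > level[nb]) {
      w <- weight[nb - 1L] + weight[nb]
      level[nb - 1L] <- (weight[nb - 1L] * level[nb - 1L] +
                           weight[nb] * level[nb]) / w
      weight[nb - 1L] <- w
      nb <- nb - 1L
    }
  }
  out <- numeric(n)
  start <- 1L
  for (b in seq_len(nb)) {
    end <- if (b < nb) idx[b + 1L] - 1L else n
    out[start:end] <- level[b]
    start <- end + 1L
  }
  out
}

upper_tri <- function(d) d[upper.tri(d)]

config_dist <- function(X) {
  as.matrix(dist(X))
}

nmds_stress <- function(dc, dhat) {
  sqrt(sum((dc - dhat)^2) / sum(dc^2))
}

## One isotonic fit: disparities dhat for configuration distances dc given
## target dissimilarities d (Kruskal's primary approach to ties: within
## tie blocks of d, order by dc).
nmds_disparities <- function(d, dc) {
  ord <- order(d, dc)
  dhat <- numeric(length(d))
  dhat[ord] <- pava(dc[ord])
  dhat
}

#' Nonmetric multidimensional scaling
#'
#' Minimises Kruskal stress-1 of a `k`-dimensional configuration against
#' the rank order of the supplied dissimilarities. Disparities are fitted
#' by monotone (pool-adjacent-violators) regression of configuration
#' distances on the dissimilarity order; the configuration is updated by
#' SMACOF-style majorization (Guttman transform) with a step-halving
#' safeguard so stress is non-increasing within a start. The best of
#' `n_starts` initialisations is returned (the first start is seeded from
#' classical metric scaling, the rest are random).
#'
#' @param distance Symmetric dissimilarity matrix.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of initialisations (default 20).
#' @param max_iter Maximum iterations per start (default 200).
#' @param tol Stress-decrease convergence tolerance (default 1e-6).
#' @param seed RNG seed.
#' @return `ordination_result` list: `points` (sample x k), `stress`,
#'   `n_starts`, `seed`, `converged`, and `stress_trajectory` of the best
#'   start.
#' @export
nmds <- function(distance, k = 2, n_starts = 20, max_iter = 200,
                 tol = 1e-6, seed = 1) {
  D <- as.matrix(distance)
  n <- nrow(D)
  assert_that(n >= k + 1, "need at least k + 1 samples")
  d <- upper_tri(D)
  run_start <- function(X) {
    dcm <- config_dist(X)
    dc <- upper_tri(dcm)
    dhat <- nmds_disparities(d, dc)
    stress <- nmds_stress(dc, dhat)
    traj <- stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ## Guttman transform toward current disparities
      Dhat <- matrix(0, n, n)
      Dhat[upper.tri(Dhat)] <- dhat
      Dhat <- Dhat + t(Dhat)
      ratio <- ifelse(dcm > 0, Dhat / dcm, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      Xn <- B %*% X / n
      ## step-halving safeguard: accept only non-increasing stress
      accepted <- FALSE
      for (h in 0:10) {
        Xc <- X + (Xn - X) * (0.5^h)
        dcmc <- config_dist(Xc)
        dcc <- upper_tri(dcmc)
        dhc <- nmds_disparities(d, dcc)
        sc <- nmds_stress(dcc, dhc)
        if (sc <= stress + 1e-15) {
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        converged <- TRUE
        break
      }
      delta <- stress - sc
      X <- Xc; dcm <- dcmc; dc <- dcc; dhat <- dhc; stress <- sc
      traj <- c(traj, stress)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    list(X = X, stress = stress, traj = traj, converged = converged)
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      X0 <- if (s == 1) {
        cm <- suppressWarnings(cmdscale(D, k = k))
        if (ncol(cm) < k) {
          cm <- cbind(cm, matrix(rnorm(n * (k - ncol(cm)), sd = 1e-3),
                                 n, k - ncol(cm)))
        }
        cm + matrix(rnorm(n * k, sd = 1e-6), n, k)
      } else {
        matrix(runif(n * k, -1, 1), n, k) * max(d)
      }
      res <- run_start(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
  })
  dimnames(best$X) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  structure(list(points = best$X, stress = best$stress, n_starts = n_starts,
                 seed = seed, converged = best$converged,
                 stress_trajectory = best$traj),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples in", ncol(x$points),
      "dimensions; stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

## Permutation machinery -----------------------------------------------------

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

perm_set <- function(n, n_permutations, seed) {
  if (identical(n_permutations, "exhaustive")) {
    p <- all_perms(n)
    p[-1, , drop = FALSE]  # drop identity; observed plays that role
  } else {
    with_seed(seed, t(replicate(n_permutations, sample.int(n))))
  }
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

proj_mat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix (via the
#' Gower-centred inner-product matrix `G = -1/2 J D^2 J`) sequentially
#' among model terms in the declared order. Per term, `pseudo-F =
#' (SS_term/df_term) / (SS_resid/df_resid)` and `R^2 = SS_term/SS_total`.
#' P-values come from free permutation of sample labels with the add-one
#' rule `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`.
#'
#' @param distance Symmetric sample x sample dissimilarity matrix.
#' @param design data.frame of factors, rows aligned with `distance`.
#' @param terms Character vector of design columns, in testing order
#'   (default `c("compartment", "rotation")`).
#' @param n_permutations Number of permutations (default 9999), or
#'   `"exhaustive"` to enumerate all `n!` relabelings (small `n` only).
#' @param seed RNG seed.
#' @param interaction If `TRUE`, add the interaction of the first two
#'   terms after the main effects.
#' @return data.frame with one row per term plus a `Residual` row:
#'   `term, df, ss, r2, f, p`.
#' @export
permanova <- function(distance, design, terms = c("compartment", "rotation"),
                      n_permutations = 9999, seed = 1, interaction = FALSE) {
  D <- as.matrix(distance)
  n <- nrow(D)
  assert_that(nrow(design) == n, "design and distance must align")
  fac <- lapply(terms, function(tm) {
    f <- factor(design[[tm]])
    if (nlevels(f) < 2) stop2("term '", tm, "' has a single level")
    f
  })
  names(fac) <- terms
  if (interaction) {
    assert_that(length(terms) >= 2, "interaction needs two terms")
    fac[[paste(terms[1], terms[2], sep = ":")]] <-
      interaction(fac[[1]], fac[[2]], drop = TRUE)
  }
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  ## cumulative projections for sequential sums of squares
  X <- matrix(1, n, 1)
  H_prev <- proj_mat(X)
  Hs <- list(); dfs <- numeric(0)
  rank_prev <- 1
  for (nm in names(fac)) {
    X <- cbind(X, stats::model.matrix(~ f - 1, data.frame(f = fac[[nm]])))
    H <- proj_mat(X)
    rank <- qr(X)$rank
    Hs[[nm]] <- H - H_prev
    dfs[nm] <- rank - rank_prev
    H_prev <- H; rank_prev <- rank
  }
  df_res <- n - rank_prev
  assert_that(df_res > 0, "no residual degrees of freedom")
  stat <- function(Gp) {
    ss <- vapply(Hs, function(H) sum(H * Gp), numeric(1))
    ss_res <- sum(diag(Gp)) - sum(ss)
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat(G)
  perms <- perm_set(n, n_permutations, seed)
  n_perm <- nrow(perms)
  exceed <- numeric(length(Hs))
  for (i in seq_len(n_perm)) {
    p <- perms[i, ]
    fp <- stat(G[p, p])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    term = c(names(Hs), "Residual"),
    df = c(dfs, df_res),
    ss = c(obs$ss, obs$ss_res),
    r2 = c(obs$ss, obs$ss_res) / ss_total,
    f = c(obs$f, NA_real_),
    p = c(pvals, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Mantel test (Pearson correlation of distance matrices)
#'
#' `r` is the Pearson correlation of the upper-triangle entries; the null
#' distribution comes from simultaneous row/column permutation of the
#' second matrix (one-sided, greater), with the add-one p-value rule.
#'
#' @param d1,d2 Symmetric dissimilarity matrices over the same samples.
#' @param n_permutations Number of permutations (default 9999), or
#'   `"exhaustive"`.
#' @param seed RNG seed.
#' @return List: `r`, `p`, `n_permutations`, `seed`.
#' @export
mantel <- function(d1, d2, n_permutations = 9999, seed = 1) {
  D1 <- as.matrix(d1); D2 <- as.matrix(d2)
  assert_that(all(dim(D1) == dim(D2)), "distance matrices must align")
  v1 <- upper_tri(D1)
  if (sd(v1) == 0 || sd(upper_tri(D2)) == 0) {
    warning("constant upper triangle: Mantel r undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_,
                n_permutations = 0, seed = seed))
  }
  r_obs <- cor(v1, upper_tri(D2))
  perms <- perm_set(nrow(D1), n_permutations, seed)
  n_perm <- nrow(perms)
  exceed <- 0
  for (i in seq_len(n_perm)) {
    p <- perms[i, ]
    exceed <- exceed + (cor(v1, upper_tri(D2[p, p])) >= r_obs - 1e-12)
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
       n_permutations = n_perm, seed = seed)
}

#' Two-way ANOVA with Tukey HSD
#'
#' Sequential (type-I) decomposition with factors in the given order,
#' optionally with their interaction; p-values from the F distribution.
#' Tukey honestly-significant-difference tables use studentized-range
#' quantiles on group means with the full-model residual mean square. A
#' constant response yields `F = 0, p = 1` per factor; a single-level
#' factor contributes 0 df (one-way collapse).
#'
#' @param response Numeric response.
#' @param factorA,factorB Factors (coerced), aligned with `response`.
#' @param interaction Include A:B (default `FALSE`).
#' @return List: `anova` (term, df, ss, ms, f, p) and `tukey` (named list
#'   of pairwise tables: contrast, diff, lwr, upr, p_adj).
#' @export
two_way_anova <- function(response, factorA, factorB, interaction = FALSE) {
  y <- as.numeric(response)
  fA <- factor(factorA); fB <- factor(factorB)
  n <- length(y)
  if (interaction) {
    tab <- table(fA, fB)
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)[1, ]
      stop2("empty design cell: ", levels(fA)[empty[1]], " x ",
            levels(fB)[empty[2]])
    }
  }
  fac <- list(A = fA, B = fB)
  if (interaction) fac$`A:B` <- interaction(fA, fB, drop = TRUE)
  X <- matrix(1, n, 1)
  H_prev <- proj_mat(X); rank_prev <- 1
  ss <- numeric(0); dfs <- numeric(0)
  for (nm in names(fac)) {
    if (nlevels(fac[[nm]]) < 2) {
      ss[nm] <- 0; dfs[nm] <- 0
      next
    }
    X <- cbind(X, stats::model.matrix(~ f - 1, data.frame(f = fac[[nm]])))
    H <- proj_mat(X)
    rank <- qr(X)$rank
    ss[nm] <- sum((H - H_prev) %*% y * y)
    dfs[nm] <- rank - rank_prev
    H_prev <- H; rank_prev <- rank
  }
  ss_total <- sum((y - mean(y))^2)
  ss_res <- ss_total - sum(ss)
  df_res <- n - rank_prev
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  fstat <- pval <- numeric(length(ss))
  for (i in seq_along(ss)) {
    if (dfs[i] == 0 || ss_total < 1e-12) {
      fstat[i] <- 0; pval[i] <- 1
    } else if (ss_res < 1e-12 * ss_total) {
      fstat[i] <- Inf; pval[i] <- 0
    } else {
      fstat[i] <- (ss[i] / dfs[i]) / ms_res
      pval[i] <- pf(fstat[i], dfs[i], df_res, lower.tail = FALSE)
    }
  }
  anova_tab <- data.frame(
    term = c(names(ss), "Residual"),
    df = c(dfs, df_res),
    ss = c(unname(ss), ss_res),
    ms = c(unname(ss) / pmax(dfs, 1), ms_res),
    f = c(fstat, NA_real_),
    p = c(pval, NA_real_),
    stringsAsFactors = FALSE
  )
  tukey <- lapply(fac[c("A", "B")], function(f) {
    if (nlevels(f) < 2 || is.na(ms_res) || ss_total < 1e-12) {
      return(NULL)
    }
    lv <- levels(f)
    means <- tapply(y, f, mean)
    ns <- tapply(y, f, length)
    pairs <- utils::combn(lv, 2)
    res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      pr <- pairs[, j]
      d <- unname(means[pr[2]] - means[pr[1]])
      se <- sqrt(ms_res / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
      crit <- unname(qtukey(0.95, length(lv), df_res) * se)
      data.frame(contrast = paste(pr[2], pr[1], sep = "-"),
                 diff = d, lwr = d - crit, upr = d + crit,
                 p_adj = unname(ptukey(abs(d) / se, length(lv), df_res,
                                       lower.tail = FALSE)),
                 stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res
  })
  list(anova = anova_tab, tukey = tukey)
}

## Random-intercept linear mixed model, REML ---------------------------------

## -2 * REML log-likelihood, profiled over beta and sigma^2, as a function
## of the variance ratio theta = sigma_u^2 / sigma^2. Blockwise inversion:
## per group of size n_i, V_i = I + theta * J, V_i^{-1} = I - theta/(1 +
## theta n_i) J, log|V_i| = log(1 + theta n_i).
lmm_profile <- function(theta, y, X, gidx) {
  n <- length(y); p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0; logdet <- 0
  for (ix in gidx) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
    c1 <- theta / (1 + theta * ni)
    sX <- colSums(Xi); sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) - c1 * tcrossprod(sX)
    XtVy <- XtVy + crossprod(Xi, yi)[, 1] - c1 * sX * sy
    ytVy <- ytVy + sum(yi^2) - c1 * sy^2
    logdet <- logdet + log(1 + theta * ni)
  }
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - sum(beta * XtVy)
  crit <- (n - p) * log(rss) + logdet + determinant(XtVX)$modulus[1]
  list(crit = crit, beta = beta, rss = rss, XtVX = XtVX)
}

## -2 REML loglik in the original (sigma_u^2, sigma^2) parameterisation,
## used for the numeric Hessian behind the Satterthwaite step.
lmm_m2reml <- function(su2, s2, y, X, gidx) {
  n <- length(y); p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0; logdet <- 0
  for (ix in gidx) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
    c1 <- su2 / (s2 * (s2 + su2 * ni))
    sX <- colSums(Xi); sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) / s2 - c1 * tcrossprod(sX)
    XtVy <- XtVy + crossprod(Xi, yi)[, 1] / s2 - c1 * sX * sy
    ytVy <- ytVy + sum(yi^2) / s2 - c1 * sy^2
    logdet <- logdet + (ni - 1) * log(s2) + log(s2 + su2 * ni)
  }
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - sum(beta * XtVy)
  logdet + determinant(XtVX)$modulus[1] + rss
}

#' Random-intercept linear mixed model by REML
#'
#' Fits `y = b0 + b1 x + u_group + e`, `u_group ~ N(0, s_u^2)`,
#' `e ~ N(0, s^2)`, by REML with the variance ratio profiled out (1-D
#' optimisation). The slope test uses Satterthwaite-approximate degrees of
#' freedom (numeric gradient/Hessian). A degenerate fit (`s_u^2 -> 0`)
#' collapses to ordinary least squares with `n - p` df.
#'
#' @param y Numeric response.
#' @param x Numeric covariate, or `NULL` for an intercept-only fixed part.
#' @param group Grouping factor (>= 2 levels).
#' @return `mixed_model_result` list: `intercept`, `slope`, `slope_se`,
#'   `slope_df`, `slope_p`, `sigma2_group`, `sigma2_resid`, `theta`,
#'   `group_label`.
#' @export
fit_random_intercept_lmm <- function(y, x = NULL, group) {
  y <- as.numeric(y)
  g <- factor(group)
  assert_that(nlevels(g) >= 2, "need at least 2 groups")
  assert_that(length(y) >= 3, "need at least 3 observations")
  X <- if (is.null(x)) matrix(1, length(y), 1) else cbind(1, as.numeric(x))
  if (qr(X)$rank < ncol(X)) stop2("singular fixed-effect design")
  gidx <- split(seq_along(y), g)
  crit_fun <- function(lt) lmm_profile(expm1(lt), y, X, gidx)$crit
  opt <- optimize(crit_fun, interval = c(log1p(0), log1p(1e6)), tol = 1e-10)
  theta <- expm1(opt$minimum)
  if (crit_fun(log1p(0)) <= opt$objective + 1e-8) theta <- 0
  fit <- lmm_profile(theta, y, X, gidx)
  n <- length(y); p <- ncol(X)
  s2 <- fit$rss / (n - p)
  su2 <- theta * s2
  vcov_beta <- s2 * solve(fit$XtVX)
  beta <- fit$beta
  slope_i <- if (p == 2) 2L else 1L
  se <- sqrt(vcov_beta[slope_i, slope_i])
  if (theta <= 1e-10) {
    df <- n - p
  } else {
    ## Satterthwaite: df = 2 f^2 / (g' A g), f = Var(b1) as a function of
    ## (su2, s2), A = asymptotic REML covariance (2 * H^{-1}).
    fvar <- function(su2_, s2_) {
      XtVX <- matrix(0, p, p)
      for (ix in gidx) {
        ni <- length(ix)
        Xi <- X[ix, , drop = FALSE]
        c1 <- su2_ / (s2_ * (s2_ + su2_ * ni))
        XtVX <- XtVX + crossprod(Xi) / s2_ - c1 * tcrossprod(colSums(Xi))
      }
      solve(XtVX)[slope_i, slope_i]
    }
    h1 <- su2 * 1e-4 + 1e-10; h2 <- s2 * 1e-4
    grad <- c((fvar(su2 + h1, s2) - fvar(max(su2 - h1, 0), s2)) /
                (su2 + h1 - max(su2 - h1, 0)),
              (fvar(su2, s2 + h2) - fvar(su2, s2 - h2)) / (2 * h2))
    m2 <- function(a, b) lmm_m2reml(a, b, y, X, gidx)
    ha <- max(su2 * 1e-3, 1e-8); hb <- s2 * 1e-3
    H <- matrix(0, 2, 2)
    H[1, 1] <- (m2(su2 + ha, s2) - 2 * m2(su2, s2) +
                  m2(max(su2 - ha, 1e-12), s2)) / (ha^2)
    H[2, 2] <- (m2(su2, s2 + hb) - 2 * m2(su2, s2) + m2(su2, s2 - hb)) /
      (hb^2)
    H[1, 2] <- H[2, 1] <-
      (m2(su2 + ha, s2 + hb) - m2(su2 + ha, s2 - hb) -
         m2(max(su2 - ha, 1e-12), s2 + hb) +
         m2(max(su2 - ha, 1e-12), s2 - hb)) / (4 * ha * hb)
    A <- tryCatch(2 * solve(H), error = function(e) NULL)
    df <- if (is.null(A)) n - p else {
      denom <- drop(t(grad) %*% A %*% grad)
      if (denom <= 0) n - p else {
        min(max(2 * fvar(su2, s2)^2 / denom, 1), n - p)
      }
    }
  }
  tstat <- beta[slope_i] / se
  structure(list(
    intercept = beta[1],
    slope = if (p == 2) beta[2] else NA_real_,
    slope_se = se,
    slope_df = df,
    slope_p = 2 * pt(-abs(tstat), df),
    sigma2_group = su2,
    sigma2_resid = s2,
    theta = theta,
    group_label = deparse(substitute(group))
  ), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("random-intercept LMM (REML): slope =", signif(x$slope, 4),
      "(se", paste0(signif(x$slope_se, 3), ","), "df",
      paste0(signif(x$slope_df, 4), ","), "p",
      paste0(signif(x$slope_p, 3), ");"),
      "var(group) =", signif(x$sigma2_group, 4),
      "var(resid) =", signif(x$sigma2_resid, 4), "\n")
  invisible(x)
}
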