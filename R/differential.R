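## Simplified negative-binomial differential-activity test: median-of-ratios
## size factors, method-of-moments dispersion, per-group NB means fitted by
## Newton iteration with library-size offsets, Wald test on the condition
## contrast, Benjamini-Hochberg adjustment. Deliberately omits dispersion
## shrinkage, outlier replacement and independent filtering.

#' Median-of-ratios size factors
#'
#' `factor_s = median over reference genes of count(g, s) / geomean_g`,
#' where the reference genes are those with a positive geometric mean
#' across samples. If no gene is positive in all samples, each sample
#' falls back to the ratios over the genes positive in that sample
#' (logged via warning). Factors are rescaled to geometric mean 1.
#'
#' @param raw_gene_counts gene x sample integer matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(raw_gene_counts) {
  m <- as_count_matrix(raw_gene_counts, "raw_gene_counts")
  log_gm <- rowMeans(log(m))
  ref <- is.finite(log_gm)
  if (any(ref)) {
    f <- apply(m[ref, , drop = FALSE], 2, function(col) {
      median(exp(log(col) - log_gm[ref]))
    })
  } else {
    warning("no gene expressed in all samples: falling back to per-sample ",
            "positive genes", call. = FALSE)
    # geometric mean over the positive observations of each gene
    log_gm2 <- apply(m, 1, function(r) {
      if (any(r > 0)) mean(log(r[r > 0])) else NA_real_
    })
    f <- apply(m, 2, function(col) {
      ok <- col > 0 & is.finite(log_gm2)
      if (!any(ok)) return(NA_real_)
      median(exp(log(col[ok]) - log_gm2[ok]))
    })
  }
  assert_that(all(is.finite(f) & f > 0), "could not compute size factors")
  f / exp(mean(log(f)))
}

## Per-group NB mean fit with fixed dispersion alpha and offsets s:
## mu_j = s_j * exp(beta); score sum_j (y_j - mu_j) / (1 + alpha mu_j) = 0.
## Returns beta-hat and the Fisher information sum_j mu_j/(1 + alpha mu_j).
nb_group_fit <- function(y, s, alpha) {
  tot <- sum(y)
  if (tot == 0) {
    ## continuity correction: keep the Wald statistic finite
    y <- y + 0.5 / length(y)
    tot <- sum(y)
  }
  beta <- log(tot / sum(s))
  for (it in 1:50) {
    mu <- s * exp(beta)
    w <- 1 + alpha * mu
    score <- sum((y - mu) / w)
    info <- sum(mu / w^2 * (1 + alpha * y))
    info <- max(info, 1e-12)
    step <- score / info
    beta <- beta + max(min(step, 5), -5)
    if (abs(step) < 1e-10) break
  }
  mu <- s * exp(beta)
  list(beta = beta, info = sum(mu / (1 + alpha * mu)))
}

## Method-of-moments dispersion on normalized counts, pooled within
## condition: alpha = (var - mean) / mean^2, floored.
mom_dispersion <- function(q, cond, floor = 1e-8) {
  lv <- levels(cond)
  num <- 0; den <- 0; mbar <- 0; ntot <- 0
  for (l in lv) {
    x <- q[cond == l]
    n <- length(x)
    if (n >= 2) {
      num <- num + (n - 1) * var(x)
      den <- den + (n - 1)
      mbar <- mbar + sum(x)
      ntot <- ntot + n
    }
  }
  m <- mbar / max(ntot, 1)
  v <- if (den > 0) num / den else 0
  if (m <= 0) return(floor)
  max((v - m) / m^2, floor)
}

#' Negative-binomial Wald test for differential gene activity
#'
#' Two-condition contrast (by convention rhizosphere vs bulk soil). Per
#' gene: dispersion by method of moments on size-factor-normalised counts
#' (floored at 1e-8), per-condition NB means fitted by Newton iteration
#' with `log(size factor)` offsets, a Wald statistic on the log2 fold
#' change (second condition level vs first) referred to a t distribution
#' with `n - 2` degrees of freedom (the normal reference is visibly
#' anti-conservative at the replication levels this test is used at), and
#' Benjamini-Hochberg adjustment across tested genes. Genes with all-zero counts are excluded from testing and
#' from the BH denominator. A condition whose counts sum to zero for a
#' gene receives a 0.5 continuity correction so the statistic stays
#' finite.
#'
#' @param raw_gene_counts gene x sample integer matrix (raw counts).
#' @param sf Per-sample size factors from [size_factors()] (or `NULL` to
#'   compute them here).
#' @param condition Factor of length `ncol(counts)` with exactly two
#'   levels, each with >= 2 samples. The fold change is level 2 vs
#'   level 1.
#' @param alpha BH significance threshold for enrichment labels
#'   (default 0.05).
#' @return data.frame: `gene_id, base_mean, log2fc, se, p, padj,
#'   enriched` where `enriched` is the second level (log2fc > 0), the
#'   first level (log2fc < 0) or `"none"`.
#' @export
nb_wald_test <- function(raw_gene_counts, sf = NULL, condition,
                         alpha = 0.05) {
  m <- as_count_matrix(raw_gene_counts, "raw_gene_counts")
  cond <- factor(condition)
  assert_that(nlevels(cond) == 2, "exactly two conditions are required")
  assert_that(all(table(cond) >= 2), "each condition needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(m)
  sf <- sf[colnames(m)] %||% sf
  tested <- rowSums(m) > 0
  lv <- levels(cond)
  i1 <- cond == lv[1]; i2 <- cond == lv[2]
  res <- data.frame(gene_id = rownames(m), base_mean = NA_real_,
                    log2fc = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, enriched = "none",
                    stringsAsFactors = FALSE)
  q <- sweep(m, 2, sf, "/")
  for (g in which(tested)) {
    a <- mom_dispersion(q[g, ], cond)
    f1 <- nb_group_fit(m[g, i1], sf[i1], a)
    f2 <- nb_group_fit(m[g, i2], sf[i2], a)
    delta <- f2$beta - f1$beta
    se <- sqrt(1 / f1$info + 1 / f2$info)
    z <- delta / se
    res$base_mean[g] <- mean(q[g, ])
    res$log2fc[g] <- delta / log(2)
    res$se[g] <- se / log(2)
    res$p[g] <- 2 * pt(-abs(z), df = ncol(m) - 2)
  }
  res$padj[tested] <- p.adjust(res$p[tested], method = "BH")
  sig <- tested & !is.na(res$padj) & res$padj < alpha
  res$enriched[sig & res$log2fc > 0] <- lv[2]
  res$enriched[sig & res$log2fc < 0] <- lv[1]
  attr(res, "conditions") <- lv
  attr(res, "alpha") <- alpha
  res
}

#' Compartment-enriched activity fractions and spatial gradient
#'
#' Per sample, the fraction of total gene activity (summed TPM) carried by
#' bulk-enriched, rhizosphere-enriched and unclassified genes (the three
#' sum to 1). Compartment group means are reported, along with the
#' spatial-gradient check: whether the mean rhizosphere-enriched fraction
#' is ordered root >= rhizosphere >= bulk.
#'
#' @param gene_tpm gene x sample TPM matrix (all samples, including
#'   roots).
#' @param differential_results Output of [nb_wald_test()], or any
#'   data.frame with `gene_id` and `enriched` columns (external label
#'   tables are accepted as drop-in input).
#' @param design [sample_design()] covering the TPM columns.
#' @return List: `per_sample` (sample_id, compartment, frac_bulk,
#'   frac_rhizosphere, frac_none), `compartment_means`, and `gradient`
#'   (logical plus the three rhizosphere-enriched means).
#' @export
enrichment_summary <- function(gene_tpm, differential_results, design) {
  lab <- setNames(differential_results$enriched,
                  differential_results$gene_id)
  gl <- lab[rownames(gene_tpm)]
  gl[is.na(gl)] <- "none"
  total <- colSums(gene_tpm)
  zero <- total == 0
  if (any(zero)) {
    warning("zero total activity in sample(s): ",
            paste(colnames(gene_tpm)[zero], collapse = ", "), call. = FALSE)
  }
  frac_for <- function(which_lab) {
    rows <- gl == which_lab
    s <- if (any(rows)) colSums(gene_tpm[rows, , drop = FALSE]) else
      numeric(ncol(gene_tpm))
    ifelse(total > 0, s / total, NA_real_)
  }
  per_sample <- data.frame(
    sample_id = colnames(gene_tpm),
    compartment = design$compartment[match(colnames(gene_tpm),
                                           design$sample_id)],
    frac_bulk = frac_for("bulk"),
    frac_rhizosphere = frac_for("rhizosphere"),
    stringsAsFactors = FALSE
  )
  per_sample$frac_none <- ifelse(total > 0,
                                 1 - per_sample$frac_bulk -
                                   per_sample$frac_rhizosphere, NA_real_)
  means <- aggregate(cbind(frac_bulk, frac_rhizosphere, frac_none) ~
                       compartment, data = per_sample, FUN = mean)
  gm <- setNames(means$frac_rhizosphere, means$compartment)
  ordered_gradient <-
    !anyNA(gm[c("root", "rhizosphere", "bulk")]) &&
    gm["root"] >= gm["rhizosphere"] && gm["rhizosphere"] >= gm["bulk"]
  list(per_sample = per_sample,
       compartment_means = means,
       gradient = list(ordered = isTRUE(ordered_gradient),
                       rhizosphere_enriched_means = gm))
}
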