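# Size factors, the simplified NB test, enrichment fractions.

test_that("size factors match the median-of-ratios hand computation", {
  m <- matrix(c(10, 20, 30, 40, 50,
                20, 40, 60, 80, 100,
                10, 22, 28, 44, 48), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  f <- size_factors(m)
  # independent spreadsheet-style oracle
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  raw <- apply(m, 2, function(col) median(col / gm))
  expect_equal(unname(f), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)
  # identical samples: all factors 1
  mi <- matrix(rep(c(5, 9, 14), 4), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(mi)), rep(1, 4))
  # doubling one sample roughly doubles its factor
  md <- cbind(mi, s5 = 2 * mi[, 1])
  f2 <- size_factors(md)
  expect_equal(unname(f2["s5"] / f2["s1"]), 2, tolerance = 1e-9)
  # fallback when no gene is expressed everywhere
  mz <- rbind(g1 = c(10, 0), g2 = c(0, 10))
  colnames(mz) <- c("s1", "s2")
  expect_warning(fz <- size_factors(mz), "falling back")
  expect_length(fz, 2)
})

test_that("NB Wald test excludes all-zero genes and is antisymmetric", {
  set.seed(41)
  m <- matrix(rnbinom(50 * 8, mu = 30, size = 5), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  m[1, ] <- 0
  cond <- factor(rep(c("bulk", "rhizosphere"), each = 4))
  r <- nb_wald_test(m, condition = cond)
  expect_true(is.na(r$p[1]) && is.na(r$padj[1]))
  expect_equal(r$enriched[1], "none")
  # BH denominator counts tested genes only
  tested <- !is.na(r$p)
  expect_equal(r$padj[tested], p.adjust(r$p[tested], "BH"))

  # swapping condition labels flips fold changes and labels exactly
  r2 <- nb_wald_test(m, condition = factor(cond,
                                           levels = c("rhizosphere", "bulk")))
  expect_equal(r$log2fc[tested], -r2$log2fc[tested], tolerance = 1e-8)
  swapped <- c(bulk = "rhizosphere", rhizosphere = "bulk", none = "none")
  expect_equal(unname(swapped[r$enriched]), r2$enriched)

  expect_error(nb_wald_test(m, condition = factor(c("a", rep("b", 7)))),
               ">= 2 samples")
})

test_that("enrichment fractions sum to one and honour external labels", {
  d <- sample_design(data.frame(
    sample_id = paste0("s", 1:6),
    compartment = rep(c("bulk", "rhizosphere", "root"), each = 2),
    rotation = "continuous", growth_stage = "seedling",
    replicate = rep(1:2, 3), stringsAsFactors = FALSE))
  tpm <- matrix(c(2, 3, 5), 3, 6,
                dimnames = list(paste0("g", 1:3), d$sample_id))
  labels <- data.frame(gene_id = paste0("g", 1:3),
                       enriched = c("bulk", "rhizosphere", "none"))
  es <- enrichment_summary(tpm, labels, d)
  expect_equal(es$per_sample$frac_bulk, rep(0.2, 6))
  expect_equal(es$per_sample$frac_rhizosphere, rep(0.3, 6))
  expect_equal(es$per_sample$frac_bulk + es$per_sample$frac_rhizosphere +
                 es$per_sample$frac_none, rep(1, 6), tolerance = 1e-9)
  # all genes labelled -> enriched fraction 1
  lab_all <- data.frame(gene_id = paste0("g", 1:3), enriched = "bulk")
  expect_equal(enrichment_summary(tpm, lab_all, d)$per_sample$frac_bulk,
               rep(1, 6))
  # no labels -> all zero
  lab_none <- data.frame(gene_id = paste0("g", 1:3), enriched = "none")
  expect_equal(enrichment_summary(tpm, lab_none, d)$per_sample$frac_bulk,
               rep(0, 6))
})

test_that("planted enrichment labels are recovered with F1 >= 0.9", {
  cfg <- simulation_config(seed = 5, n_votus = 100, n_ssrna_votus = 0,
                           replicates = 4, enriched_fold = 16,
                           always_active_fraction = 0.25)
  ca <- simulate_catalog(cfg)
  d <- simulate_design(cfg)
  sim <- simulate_counts(ca$catalog, ca$annotations, d, cfg)
  soils <- d$sample_id[d$compartment %in% c("bulk", "rhizosphere")]
  cond <- factor(d$compartment[match(soils, d$sample_id)],
                 levels = c("bulk", "rhizosphere"))
  cnt <- sim$bundle$rna_gene_counts[, soils]
  r <- nb_wald_test(cnt[rowSums(cnt) > 0, ], condition = cond)
  # evaluate on the compartment-symmetric pool carrying the planted
  # labels (genes of priming vOTUs are genuinely rhizosphere-biased by
  # construction, so calls there are not label errors)
  pool <- ca$annotations$gene_id[ca$annotations$votu_id %in%
                                   sim$truth$always_active]
  rp <- r[r$gene_id %in% pool, ]
  truthlab <- sim$truth$enriched_gene_labels[rp$gene_id]
  tp <- sum(rp$enriched == truthlab & truthlab != "none")
  fp <- sum(rp$enriched != truthlab & rp$enriched != "none")
  fn <- sum(rp$enriched != truthlab & truthlab != "none")
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.9)

  # planted labels produce the root >= rhizosphere >= bulk gradient
  filt <- filter_gene_counts(sim$bundle$rna_gene_counts, d)
  tpm <- compute_gene_tpm(filt,
                          setNames(ca$annotations$gene_length_bp,
                                   ca$annotations$gene_id),
                          sim$bundle$library_sizes$metatranscriptome)
  planted <- data.frame(gene_id = names(sim$truth$enriched_gene_labels),
                        enriched = unname(sim$truth$enriched_gene_labels))
  es <- suppressWarnings(enrichment_summary(tpm, planted, d))
  expect_true(es$gradient$ordered)
})
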