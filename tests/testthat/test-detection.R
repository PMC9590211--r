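# Presence calling, CPM, aggregation, accumulation curves, greedy dedup.

test_that("presence threshold is inclusive and validated", {
  b <- matrix(c(0.75, 0.7499, 0, 1), 2, 2,
              dimnames = list(c("v1", "v2"), c("s1", "s2")))
  p <- suppressWarnings(call_presence(b))
  expect_true(p["v1", "s1"])    # 0.75 is present (inclusive)
  expect_false(p["v2", "s1"])   # 0.7499 is absent
  expect_error(call_presence(b, threshold = 1.01), "threshold")
  expect_error(call_presence(matrix(1.2, 1, 1)), "breadth")
  bz <- matrix(0, 2, 1, dimnames = list(c("v1", "v2"), "s1"))
  expect_warning(call_presence(bz), "all-zero")
  # merged presence is the OR over library types
  pl <- suppressWarnings(call_presence(list(a = b, b = b * 0)))
  expect_identical(pl$merged, pl$a | pl$b)
})

test_that("CPM matches the arithmetic oracle and its scaling laws", {
  cnt <- matrix(c(100, 0), 2, 1, dimnames = list(c("v1", "v2"), "s1"))
  cpm <- compute_cpm(cnt, c(v1 = 10000, v2 = 5000), c(s1 = 1e6))
  expect_equal(cpm["v1", "s1"], 10.0)
  expect_equal(cpm["v2", "s1"], 0)

  set.seed(2)
  m <- matrix(rpois(12, 30), 4, 3,
              dimnames = list(paste0("v", 1:4), paste0("s", 1:3)))
  L <- setNames(c(12000, 20000, 15000, 30000), rownames(m))
  N <- setNames(c(2e6, 1e6, 3e6), colnames(m))
  base <- compute_cpm(m, L, N)
  # linear in counts, inverse-linear in library size
  expect_equal(compute_cpm(3 * m, L, N), 3 * base)
  expect_equal(compute_cpm(m, L, 2 * N), base / 2)
  # doubling counts and depth together leaves CPM unchanged
  expect_equal(compute_cpm(2 * m, L, 2 * N), base)
  expect_error(compute_cpm(m, L, setNames(c(0, 1e6, 1e6), colnames(m))),
               "zero library size")
})

test_that("DNA library aggregation takes the median of available values", {
  a <- matrix(4, 1, 1, dimnames = list("v", "s"))
  b <- matrix(6, 1, 1, dimnames = list("v", "s"))
  expect_equal(aggregate_dna_libraries(a, b)[1, 1], 5)
  # one library missing entirely: its values are used as-is
  expect_equal(aggregate_dna_libraries(a, NULL)[1, 1], 4)
  # masking by presence comes after aggregation
  pres <- matrix(FALSE, 1, 1, dimnames = list("v", "s"))
  expect_equal(aggregate_dna_libraries(a, b, presence = pres)[1, 1], 0)
  # (0, 0) with presence stays 0
  z <- a * 0
  expect_equal(aggregate_dna_libraries(z, z, presence = !pres)[1, 1], 0)
})

test_that("abundance support never exceeds presence support", {
  sim <- small_sim()
  gl <- setNames(sim$catalog$genome_length_bp, sim$catalog$votu_id)
  pres <- suppressWarnings(call_presence(sim$bundle$coverage_breadth))
  cpms <- lapply(names(sim$bundle$dna_counts), function(lib) {
    compute_cpm(sim$bundle$dna_counts[[lib]], gl,
                sim$bundle$library_sizes[[lib]])
  })
  agg <- aggregate_dna_libraries(cpms[[1]], cpms[[2]],
                                 presence = pres$merged)
  expect_true(all(agg[!pres$merged] == 0))
})

test_that("exact accumulation curve matches brute-force enumeration", {
  set.seed(7)
  pres <- matrix(runif(25) < 0.4, 5, 5,
                 dimnames = list(paste0("v", 1:5), paste0("s", 1:5)))
  got <- accumulation_curve(pres)
  # independent oracle: average over all 5! sample orderings
  perms <- rhizovir:::all_perms(5)
  acc <- matrix(0, nrow(perms), 5)
  for (i in seq_len(nrow(perms))) {
    seen <- rep(FALSE, 5)
    for (k in 1:5) {
      seen <- seen | pres[, perms[i, k]]
      acc[i, k] <- sum(seen)
    }
  }
  expect_equal(got$richness, colMeans(acc), tolerance = 1e-12)
  # degenerate shapes
  one <- matrix(TRUE, 1, 4, dimnames = list("v", paste0("s", 1:4)))
  expect_equal(accumulation_curve(one)$richness, rep(1, 4))
  singletons <- diag(4) > 0
  dimnames(singletons) <- list(paste0("v", 1:4), paste0("s", 1:4))
  expect_equal(accumulation_curve(singletons)$richness, 1:4)
  # Monte-Carlo mode converges to the exact curve
  mc <- accumulation_curve(pres, n_permutations = 2000, seed = 1,
                           method = "permute")
  expect_equal(mc$richness, got$richness, tolerance = 0.05)
  expect_true(all(diff(got$richness) >= 0))
})

test_that("greedy dedup is length-sorted and not single-linkage", {
  lens <- c(A = 30000, B = 20000, C = 15000)
  # chain: A~B and B~C above threshold, A~C below -> C must not chain in
  pt <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                   identity = c(0.97, 0.97, 0.80),
                   aligned_fraction = c(0.99, 0.99, 0.99))
  cl <- greedy_dedup(pt, lens)
  expect_equal(cl$representative[cl$id == "A"], "A")
  expect_equal(cl$representative[cl$id == "B"], "A")
  expect_equal(cl$representative[cl$id == "C"], "C")

  # identical pair: one cluster, longer is representative
  cl2 <- greedy_dedup(data.frame(a = "A", b = "B", identity = 1,
                                 aligned_fraction = 1),
                      c(A = 10000, B = 25000))
  expect_equal(unique(cl2$representative), "B")
  # identity 0.94 stays below the 0.95 threshold
  cl3 <- greedy_dedup(data.frame(a = "A", b = "B", identity = 0.94,
                                 aligned_fraction = 1),
                      c(A = 10000, B = 25000))
  expect_equal(sort(unique(cl3$representative)), c("A", "B"))
  # coverage gate: high identity but low aligned fraction stays apart
  cl4 <- greedy_dedup(data.frame(a = "A", b = "B", identity = 0.99,
                                 aligned_fraction = 0.5),
                      c(A = 10000, B = 25000))
  expect_equal(sort(unique(cl4$representative)), c("A", "B"))
  # ties in length break lexicographically, deterministically
  cl5 <- greedy_dedup(data.frame(a = "x", b = "y", identity = 1,
                                 aligned_fraction = 1),
                      c(y = 10000, x = 10000))
  expect_equal(unique(cl5$representative), "x")
})
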