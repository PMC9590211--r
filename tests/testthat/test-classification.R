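# Lifestyle rules, host filtering, ssRNA completeness, RdRp clustering.

test_that("lifestyle calls are exhaustive, exclusive and evidence-tagged", {
  cat <- votu_catalog(data.frame(
    votu_id = c("v1", "v2", "v3", "v4"),
    genome_length_bp = c(12000, 15000, 6000, 20000),
    nucleic_type = "dsDNA", source_library = "dna_virome",
    is_provirus = c(FALSE, FALSE, TRUE, FALSE),
    vc_with_known_temperate = c(FALSE, FALSE, FALSE, TRUE),
    known_species_match = FALSE, stringsAsFactors = FALSE))
  ann <- gene_annotation(data.frame(
    gene_id = c("v1_g1", "v2_g1"), votu_id = c("v1", "v2"),
    start_bp = 0, end_bp = 900, cog_letter = "",
    pfam_domains = c("PF00589", "PF99999"), core_gene_role = "",
    full_length = TRUE, stringsAsFactors = FALSE), catalog = cat)
  ls <- call_lifestyle(cat, ann)
  expect_equal(ls$lifestyle, c("temperate", "lytic", "temperate",
                               "temperate"))
  expect_equal(ls$evidence, c("lysogeny_domain", "", "provirus",
                              "temperate_vc"))
  # exactly one call per vOTU; temperate iff evidence nonempty
  expect_setequal(ls$votu_id, cat$votu_id)
  expect_identical(ls$lifestyle == "temperate", nzchar(ls$evidence))
  expect_length(lysogeny_pfams(), 29)
})

test_that("host filtering is strict at p = 0.05 and deduplicates", {
  hp <- data.frame(votu_id = c("v1", "v2", "v3", "v3"),
                   host_genus = c("Bacillus", "Streptomyces",
                                  "Bacillus", "Bacillus"),
                   p_value = c(0.05, 0.049, 0.03, 0.01))
  fh <- suppressMessages(
    filter_hosts(hp, detected_genera = c("Bacillus")))
  expect_false("v1" %in% fh$predictions$votu_id)   # p = 0.05 removed
  expect_true("v2" %in% fh$predictions$votu_id)    # p = 0.049 kept
  # duplicate rows resolved to minimum p, one prediction per vOTU
  expect_equal(fh$predictions$p_value[fh$predictions$votu_id == "v3"], 0.01)
  expect_equal(fh$n_predicted_genera, 2)
  expect_equal(fh$n_detected_genera, 1)
  expect_equal(fh$detected_fraction_percent, 50.0)

  # 68 detected of 85 predicted genera -> 80.0%
  hp85 <- data.frame(votu_id = paste0("v", 1:85),
                     host_genus = paste0("g", 1:85), p_value = 0.01)
  fh85 <- filter_hosts(hp85, detected_genera = paste0("g", 1:68))
  expect_equal(fh85$detected_fraction_percent, 80.0)
})

test_that("ssRNA completeness distinguishes has-cores from near-complete", {
  mk <- function(votu, roles, full) {
    data.frame(gene_id = paste0(votu, "_g", seq_along(roles)),
               votu_id = votu, start_bp = (seq_along(roles) - 1) * 1000,
               end_bp = seq_along(roles) * 1000, cog_letter = "",
               pfam_domains = "", core_gene_role = roles,
               full_length = full, stringsAsFactors = FALSE)
  }
  ann <- gene_annotation(rbind(
    mk("r1", c("MP", "CP", "RdRp"), c(TRUE, TRUE, TRUE)),
    mk("r2", c("MP", "RdRp"), c(TRUE, TRUE)),
    mk("r3", c("MP", "CP", "RdRp"), c(TRUE, TRUE, FALSE)),
    mk("r4", c("MP", "CP", "RdRp", "RdRp"),
       c(TRUE, TRUE, FALSE, TRUE))))
  res <- assess_ssrna_completeness(ann)
  expect_equal(res$has_cores, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(res$near_complete, c(TRUE, FALSE, FALSE, TRUE))
  # near_complete implies has_cores
  expect_true(all(!res$near_complete | res$has_cores))
})

test_that("RdRp clustering nests species within genera", {
  lens <- c(a = 900, b = 800, c = 700, d = 600)
  pt <- data.frame(a = c("a", "a", "a", "b", "b", "c"),
                   b = c("b", "c", "d", "c", "d", "d"),
                   identity = c(0.99, 0.60, 0.10, 0.60, 0.10, 0.10))
  cl <- cluster_rdrp(pt, lens, genus_threshold = 0.5,
                     species_threshold = 0.9)
  gi <- setNames(cl$genus_id, cl$votu_id)
  si <- setNames(cl$species_id, cl$votu_id)
  # identity 0.99: same genus and species
  expect_equal(gi[["a"]], gi[["b"]]); expect_equal(si[["a"]], si[["b"]])
  # identity between thresholds: same genus, different species
  expect_equal(gi[["a"]], gi[["c"]])
  expect_false(si[["a"]] == si[["c"]])
  # below genus threshold: separate genus
  expect_false(gi[["a"]] == gi[["d"]])

  # property: same species => same genus over random fixtures
  set.seed(51)
  for (rep in 1:10) {
    ids <- letters[1:8]
    lens8 <- setNames(sample(500:1000, 8), ids)
    pairs <- t(combn(ids, 2))
    pt8 <- data.frame(a = pairs[, 1], b = pairs[, 2],
                      identity = runif(nrow(pairs)))
    cl8 <- cluster_rdrp(pt8, lens8, genus_threshold = 0.5,
                        species_threshold = 0.8)
    agg <- tapply(cl8$genus_id, cl8$species_id,
                  function(x) length(unique(x)))
    expect_true(all(agg == 1))
  }
  expect_error(cluster_rdrp(pt, lens), "mandatory")
  expect_error(cluster_rdrp(pt, lens, 0.9, 0.5), "exceed")
})

test_that("known-species matching uses the inclusive 0.95 ANI bound", {
  ani <- data.frame(votu_id = c("v1", "v2", "v2"),
                    reference_id = c("p1", "p1", "p2"),
                    ani = c(0.95, 0.949, 0.90))
  got <- match_known_species(ani, c("v1", "v2", "v3"))
  expect_identical(unname(got), c(TRUE, FALSE, FALSE))
  expect_warning(all_false <- match_known_species(NULL, "v1"), "empty")
  expect_false(all_false[["v1"]])
})
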