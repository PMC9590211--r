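# Domain types, readers, round trips, pipeline plumbing.

test_that("sample design validates, canonicalises and groups", {
  d <- tiny_design(reps = 2)
  expect_equal(nrow(d), 36)
  expect_equal(length(unique(d$group)), 18)
  expect_true(all(table(d$group) == 2))

  # trailing space / case are canonicalised
  raw <- data.frame(sample_id = "a", compartment = "Rhizosphere ",
                    rotation = "CONTINUOUS", growth_stage = "seedling",
                    replicate = 1)
  expect_equal(sample_design(raw)$compartment, "rhizosphere")

  dup <- data.frame(sample_id = c("a", "a"), compartment = "bulk",
                    rotation = "virgin", growth_stage = "seedling",
                    replicate = 1:2)
  expect_error(sample_design(dup), "duplicate sample_id")
  expect_error(sample_design(raw[, -2]), "compartment")
  raw$compartment <- "loam"
  expect_error(sample_design(raw), "unknown compartment")
})

test_that("catalog enforces length floors and uniqueness", {
  expect_s3_class(tiny_catalog(), "votu_catalog")
  expect_error(tiny_catalog(lengths = c(v1 = 9000), provirus = FALSE),
               "10 kb")
  # proviral sequences may be short
  expect_silent(tiny_catalog(lengths = c(v1 = 6000), provirus = TRUE))
  df <- as.data.frame(tiny_catalog())
  df$votu_id <- rep("x", 3)
  expect_error(votu_catalog(df), "duplicate votu_id")
})

test_that("GFF3 + function table reading converts coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "v1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
               "v1\tsrc\tgene\t301\t900\t.\t-\t.\tID=g2",
               "v2\tsrc\tgene\t10\t400\t.\t+\t.\tID=g3"), gff)
  fun <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcog_letter\tpfam_domains",
               "g1\tC\tPF00589;PF01609",
               "g2\t\t",
               "g_absent\tE\tPF00001"), fun)
  expect_warning(ann <- read_gene_annotations(gff, fun),
                 "1 function row")
  # 1-based inclusive -> 0-based half-open
  expect_equal(ann$start_bp[ann$gene_id == "g1"], 0L)
  expect_equal(ann$end_bp[ann$gene_id == "g1"], 300L)
  expect_equal(ann$gene_length_bp[ann$gene_id == "g1"], 300L)
  expect_equal(ann$start_bp[ann$gene_id == "g3"], 9L)
  # empty pfam field is an empty set, not a parse error
  psets <- rhizovir:::pfam_sets(ann)
  expect_length(psets[[which(ann$gene_id == "g2")]], 0)
  expect_equal(psets[[which(ann$gene_id == "g1")]],
               c("PF00589", "PF01609"))
  # unknown vOTU reference is a hard error
  cat3 <- tiny_catalog(lengths = c(v1 = 12000), provirus = FALSE)
  expect_error(suppressWarnings(
    read_gene_annotations(gff, fun, catalog = cat3)), "v2")
  # end < start rejected
  bad <- as.data.frame(ann)
  bad$end_bp[1] <- bad$start_bp[1]
  expect_error(gene_annotation(bad), "end <= start")
})

test_that("matrix and table TSV round trips preserve values", {
  set.seed(1)
  m <- matrix(c(rpois(20, 50), runif(20) * 1e-3), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  m2 <- read_matrix_tsv(p)
  expect_equal(m2, m, tolerance = 1e-12)
  # integers survive exactly
  expect_identical(m2[1:4, 1], m[1:4, 1])
  df <- data.frame(id = c("a", "b"), x = c(1L, 2L),
                   y = c(pi, exp(1)), stringsAsFactors = FALSE)
  write_table_tsv(df, p)
  df2 <- read_table_tsv(p)
  expect_equal(df2$y, df$y, tolerance = 1e-12)
  expect_identical(df2$x, df$x)
})

test_that("count bundle round trips through a directory", {
  sim <- small_sim()
  dir <- tempfile()
  write_count_bundle(sim$bundle, dir)
  b2 <- read_count_bundle(dir)
  expect_equal(b2$dna_counts, sim$bundle$dna_counts, tolerance = 1e-12)
  expect_equal(b2$rna_gene_counts, sim$bundle$rna_gene_counts)
  expect_equal(b2$library_sizes$metatranscriptome,
               sim$bundle$library_sizes$metatranscriptome)
  expect_equal(b2$coverage_breadth$dna_virome,
               sim$bundle$coverage_breadth$dna_virome, tolerance = 1e-12)
})

test_that("pipeline validates config before running and is deterministic", {
  expect_error(pipeline_config("in", "out", breadth_threshold = 1.01),
               "breadth_threshold")

  cfg <- simulation_config(seed = 5, n_votus = 40, n_ssrna_votus = 5,
                           replicates = 2)
  dir <- tempfile("bundle")
  simulate_bundle(cfg, dir)
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  run_pipeline(pipeline_config(dir, out1, seed = 3, n_permutations = 49,
                               nmds_starts = 2))
  run_pipeline(pipeline_config(dir, out2, seed = 3, n_permutations = 49,
                               nmds_starts = 2))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(names(man$stages), rhizovir:::.pipeline_stages)
  expect_true(all(vapply(man$stages, `[[`, "", "status") == "completed"))
  # byte-identical reruns under the same seed
  for (f in c("manifest.json", "abundance_cpm.tsv", "permanova.tsv",
              "nmds_coords.tsv", "summaries.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("CLI parses commands and simulates a bundle", {
  expect_output(rhizovir_cli(character()), "usage")
  cfgf <- tempfile(fileext = ".json")
  out <- tempfile("cli_bundle")
  jsonlite::write_json(list(output_dir = out, seed = 2, n_votus = 30,
                            n_ssrna_votus = 4, replicates = 2),
                       cfgf, auto_unbox = TRUE)
  suppressMessages(rhizovir_cli(c("simulate", "--config", cfgf)))
  expect_true(file.exists(file.path(out, "catalog.tsv")))
  expect_error(rhizovir_cli(c("simulate", "--config")), "needs a value")
})
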