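# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

tiny_design <- function(compartments = c("bulk", "rhizosphere", "root"),
                        rotations = c("continuous", "virgin"),
                        stages = c("seedling", "stem_extension",
                                   "pre_harvest"),
                        reps = 2) {
  g <- expand.grid(replicate = seq_len(reps), growth_stage = stages,
                   rotation = rotations, compartment = compartments,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("s%02d", seq_len(nrow(g)))
  sample_design(g)
}

tiny_catalog <- function(lengths = c(v1 = 12000, v2 = 23000, v3 = 9500),
                         provirus = c(FALSE, FALSE, TRUE)) {
  votu_catalog(data.frame(
    votu_id = names(lengths), genome_length_bp = unname(lengths),
    nucleic_type = "dsDNA", source_library = "dna_virome",
    is_provirus = provirus, vc_with_known_temperate = FALSE,
    known_species_match = FALSE, stringsAsFactors = FALSE))
}

tiny_annotations <- function(catalog, genes_per_votu = 4) {
  do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    L <- catalog$genome_length_bp[i]
    b <- round(seq_len(genes_per_votu) / genes_per_votu * L)
    data.frame(gene_id = sprintf("%s_g%d", catalog$votu_id[i],
                                 seq_len(genes_per_votu)),
               votu_id = catalog$votu_id[i],
               start_bp = c(0L, b[-genes_per_votu]), end_bp = b,
               cog_letter = "", pfam_domains = "", core_gene_role = "",
               full_length = TRUE, stringsAsFactors = FALSE)
  })) |> gene_annotation(catalog = catalog)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# One small simulated bundle reused by several files (moderate noise,
# generator defaults apart from size).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 101, n_votus = 60, n_ssrna_votus = 8,
                               replicates = 2)
      ca <- simulate_catalog(cfg)
      d <- simulate_design(cfg)
      sim <- simulate_counts(ca$catalog, ca$annotations, d, cfg)
      cache <<- c(ca, list(design = d, cfg = cfg), sim)
    }
    cache
  }
})
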