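## Pipeline orchestration: a validated configuration, fixed stage order
## (detect -> quantify -> activity -> ecology -> differential -> classify
## -> priming -> report), one run directory with per-stage TSV outputs,
## plain-text stage logs, and a machine-readable JSON manifest recording
## every threshold used. Raw files are read once, up front; stages pass
## validated objects in memory.

.pipeline_stages <- c("detect", "quantify", "activity", "ecology",
                      "differential", "classify", "priming", "report")

#' Build a validated pipeline configuration
#'
#' All rule thresholds default to the published values (0.75 breadth,
#' 4-read group filter, 1 gene / 10 kb activity density, p < 0.05 host
#' filter) and are recorded in the run manifest. Validation happens here,
#' before any stage runs.
#'
#' @param input_dir Directory holding the input bundle (layout of
#'   [simulate_bundle()]).
#' @param output_dir Run directory for outputs, logs and the manifest.
#' @param seed RNG seed for all stochastic stages.
#' @param breadth_threshold Presence breadth threshold in `[0, 1]`.
#' @param min_group_reads Metatranscriptome group-filter threshold.
#' @param activity_per_replicate Use the per-replicate filter reading.
#' @param host_p_threshold Strict host-prediction p cutoff.
#' @param n_permutations Permutations for PERMANOVA/Mantel.
#' @param nmds_starts NMDS random starts in the ecology stage.
#' @param diff_alpha BH threshold for enrichment labels.
#' @param diff_stage Restrict differential testing to one growth stage
#'   (`NULL` = pool all stages).
#' @param rdrp_genus_threshold,rdrp_species_threshold RdRp clustering
#'   thresholds; mandatory if an `rdrp_identity.tsv` table is present
#'   (no silent defaults).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1,
                            breadth_threshold = 0.75,
                            min_group_reads = 4,
                            activity_per_replicate = FALSE,
                            host_p_threshold = 0.05,
                            n_permutations = 999,
                            nmds_starts = 5,
                            diff_alpha = 0.05,
                            diff_stage = NULL,
                            rdrp_genus_threshold = NULL,
                            rdrp_species_threshold = NULL) {
  assert_that(is.numeric(breadth_threshold) &&
                breadth_threshold >= 0 && breadth_threshold <= 1,
              "breadth_threshold must be in [0, 1]")
  assert_that(min_group_reads >= 0, "min_group_reads must be >= 0")
  assert_that(host_p_threshold > 0 && host_p_threshold <= 1,
              "host_p_threshold must be in (0, 1]")
  assert_that(diff_alpha > 0 && diff_alpha < 1,
              "diff_alpha must be in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_inputs <- function(cfg) {
  dirp <- cfg$input_dir
  design <- read_sample_design(file.path(dirp, "design.tsv"))
  catalog <- read_votu_catalog(file.path(dirp, "catalog.tsv"))
  annotations <- read_gene_annotations(file.path(dirp, "genes.gff3"),
                                       file.path(dirp, "gene_functions.tsv"),
                                       catalog = catalog)
  bundle <- read_count_bundle(dirp)
  hosts_path <- file.path(dirp, "host_predictions.tsv")
  otu_path <- file.path(dirp, "otu_16s.tsv")
  rdrp_path <- file.path(dirp, "rdrp_identity.tsv")
  list(design = design, catalog = catalog, annotations = annotations,
       bundle = bundle,
       host_predictions = if (file.exists(hosts_path))
         read_table_tsv(hosts_path),
       otu16s = if (file.exists(otu_path)) read_matrix_tsv(otu_path),
       rdrp_identity = if (file.exists(rdrp_path))
         read_table_tsv(rdrp_path))
}

#' Run the analysis pipeline
#'
#' Executes the stages in fixed order, writing all outputs under the run
#' directory together with per-stage logs and a JSON manifest of the
#' parameters used. Any stage failure aborts with the stage name and
#' cause; stages already completed are flagged in the manifest. With a
#' fixed seed, reruns are byte-identical (no timestamps are written).
#'
#' @param config [pipeline_config()].
#' @param stages Subset of stages to run (in order, always starting from
#'   `detect`; prerequisites of a requested stage are computed in
#'   memory). Default: all eight.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, stages = .pipeline_stages) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  last <- max(match(stages, .pipeline_stages))
  todo <- .pipeline_stages[seq_len(last)]
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    parameters = config[setdiff(names(config), c("input_dir", "output_dir"))],
    input_dir = config$input_dir,
    stages = list()
  )
  env <- new.env(parent = emptyenv())
  env$inputs <- read_pipeline_inputs(config)
  results <- list()
  for (stage in todo) {
    log <- new_log(stage)
    res <- tryCatch(
      do.call(paste0("stage_", stage),
              list(env = env, cfg = config, out_dir = out_dir, log = log)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest(manifest, out_dir)
      stop2("stage '", stage, "' failed: ", conditionMessage(res))
    }
    write_log(log, file.path(out_dir, paste0("log_", stage, ".txt")))
    manifest$stages[[stage]] <- c(list(status = "completed"),
                                  res$manifest %||% list())
    results[[stage]] <- res
  }
  write_manifest(manifest, out_dir)
  invisible(results)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

## --- stages ----------------------------------------------------------------

stage_detect <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  pres <- suppressWarnings(
    call_presence(inp$bundle$coverage_breadth,
                  threshold = cfg$breadth_threshold, log = log))
  env$presence <- pres
  write_matrix_tsv(pres$merged + 0, file.path(out_dir, "presence.tsv"))
  acc <- accumulation_curve(pres$merged)
  write_table_tsv(acc, file.path(out_dir, "accumulation.tsv"))
  list(manifest = list(n_votus_detected = sum(rowSums(pres$merged) > 0)))
}

stage_quantify <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  gl <- genome_lengths(inp$catalog)
  cpms <- lapply(names(inp$bundle$dna_counts), function(lib) {
    compute_cpm(inp$bundle$dna_counts[[lib]], gl,
                inp$bundle$library_sizes[[lib]])
  })
  names(cpms) <- names(inp$bundle$dna_counts)
  agg <- aggregate_dna_libraries(cpms$dna_virome, cpms$total_metagenome,
                                 presence = env$presence$merged, log = log)
  env$cpm <- agg
  write_matrix_tsv(agg, file.path(out_dir, "abundance_cpm.tsv"))
  list(manifest = list(aggregation = "median_of_available_libraries"))
}

stage_activity <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  filt <- filter_gene_counts(inp$bundle$rna_gene_counts, inp$design,
                             min_group_reads = cfg$min_group_reads,
                             per_replicate = cfg$activity_per_replicate,
                             log = log)
  tpm <- compute_gene_tpm(filt, gene_lengths(inp$annotations),
                          inp$bundle$library_sizes$metatranscriptome)
  act <- suppressWarnings(
    call_active_votus(filt, inp$catalog, inp$annotations, log = log))
  env$filtered <- filt; env$tpm <- tpm; env$active <- act
  write_matrix_tsv(filt, file.path(out_dir, "filtered_gene_counts.tsv"))
  write_matrix_tsv(tpm, file.path(out_dir, "gene_tpm.tsv"))
  long <- data.frame(
    votu_id = rep(rownames(act$active), ncol(act$active)),
    sample_id = rep(colnames(act$active), each = nrow(act$active)),
    k = as.vector(act$active_gene_count),
    active = as.integer(as.vector(act$active))
  )
  write_table_tsv(long, file.path(out_dir, "active_votus.tsv"))
  list(manifest = list(n_active_votus = sum(rowSums(act$active) > 0)))
}

stage_ecology <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  soils <- design_samples(inp$design, c("bulk", "rhizosphere"))
  soils <- intersect(soils, colnames(env$cpm))
  H <- apply(env$cpm, 2, function(p) suppressWarnings(shannon_diversity(p)))
  write_table_tsv(data.frame(sample_id = names(H), shannon_h = unname(H)),
                  file.path(out_dir, "ecology.tsv"))
  d <- bray_curtis(t(env$cpm[, soils, drop = FALSE]), transform = "sqrt")
  write_matrix_tsv(d, file.path(out_dir, "distances.tsv"))
  sub <- inp$design[match(soils, inp$design$sample_id), ]
  ord <- nmds(d, k = 2, n_starts = cfg$nmds_starts,
              seed = derive_seed(cfg$seed, "nmds"))
  write_matrix_tsv(ord$points, file.path(out_dir, "nmds_coords.tsv"))
  pmv <- permanova(d, sub, terms = c("compartment", "rotation"),
                   n_permutations = cfg$n_permutations,
                   seed = derive_seed(cfg$seed, "permanova"))
  write_table_tsv(pmv, file.path(out_dir, "permanova.tsv"))
  man <- list(nmds_stress = ord$stress)
  if (!is.null(inp$otu16s)) {
    db <- bray_curtis(t(inp$otu16s[, soils, drop = FALSE]),
                      transform = "sqrt")
    mt <- mantel(d, db, n_permutations = cfg$n_permutations,
                 seed = derive_seed(cfg$seed, "mantel"))
    write_table_tsv(data.frame(r = mt$r, p = mt$p,
                               n_permutations = mt$n_permutations),
                    file.path(out_dir, "mantel.tsv"))
    man$mantel_r <- mt$r
  }
  ## KtW mixed model: host log10 abundance vs co-occurring active vOTUs
  ## predicted (p < 0.05) to infect the host, compartment random effect.
  if (!is.null(inp$otu16s) && !is.null(inp$host_predictions)) {
    fh <- filter_hosts(inp$host_predictions,
                       p_threshold = cfg$host_p_threshold)
    pred <- fh$predictions
    act <- env$active$active
    long <- do.call(rbind, lapply(rownames(inp$otu16s), function(h) {
      vh <- pred$votu_id[pred$host_genus == h]
      x <- if (length(vh)) {
        colSums(act[intersect(vh, rownames(act)), , drop = FALSE])
      } else {
        numeric(ncol(act))
      }
      data.frame(host = h, sample_id = colnames(inp$otu16s),
                 y = log10(1 + inp$otu16s[h, ]), x = as.numeric(x),
                 stringsAsFactors = FALSE)
    }))
    long$compartment <- inp$design$compartment[
      match(long$sample_id, inp$design$sample_id)]
    fit <- fit_random_intercept_lmm(long$y, long$x, long$compartment)
    write_table_tsv(data.frame(slope = fit$slope, se = fit$slope_se,
                               df = fit$slope_df, p = fit$slope_p,
                               var_group = fit$sigma2_group,
                               var_resid = fit$sigma2_resid),
                    file.path(out_dir, "lmm.tsv"))
    man$ktw_slope <- fit$slope
  }
  log_add(log, nmds_stress = signif(man$nmds_stress, 6))
  list(manifest = man)
}

stage_differential <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  soils <- design_samples(inp$design, c("bulk", "rhizosphere"),
                          growth_stage = cfg$diff_stage)
  soils <- intersect(soils, colnames(inp$bundle$rna_gene_counts))
  comp <- inp$design$compartment[match(soils, inp$design$sample_id)]
  cond <- factor(comp, levels = c("bulk", "rhizosphere"))
  counts <- inp$bundle$rna_gene_counts[, soils, drop = FALSE]
  keep <- rowSums(counts) > 0
  diff <- nb_wald_test(counts[keep, , drop = FALSE], condition = cond,
                       alpha = cfg$diff_alpha)
  env$differential <- diff
  write_table_tsv(diff, file.path(out_dir, "differential.tsv"))
  enr <- suppressWarnings(enrichment_summary(env$tpm, diff, inp$design))
  env$enrichment <- enr
  write_table_tsv(enr$per_sample,
                  file.path(out_dir, "enrichment_fractions.tsv"))
  log_add(log, n_bulk = sum(diff$enriched == "bulk"),
          n_rhizosphere = sum(diff$enriched == "rhizosphere"))
  list(manifest = list(
    method = "simplified_nb_wald_approximation",
    n_bulk_enriched = sum(diff$enriched == "bulk"),
    n_rhizosphere_enriched = sum(diff$enriched == "rhizosphere")))
}

stage_classify <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  ls <- call_lifestyle(inp$catalog, inp$annotations)
  env$lifestyle <- ls
  write_table_tsv(ls, file.path(out_dir, "lifestyle.tsv"))
  man <- list(n_temperate = sum(ls$lifestyle == "temperate"))
  if (!is.null(inp$host_predictions)) {
    detected <- if (!is.null(inp$otu16s)) {
      rownames(inp$otu16s)[rowSums(inp$otu16s) > 0]
    } else {
      character()
    }
    fh <- suppressMessages(
      filter_hosts(inp$host_predictions, p_threshold = cfg$host_p_threshold,
                   detected_genera = detected))
    env$hosts <- fh
    write_table_tsv(fh$predictions, file.path(out_dir, "hosts_filtered.tsv"))
    man$host_detected_percent <- fh$detected_fraction_percent
  }
  ss_ids <- inp$catalog$votu_id[inp$catalog$nucleic_type == "ssRNA"]
  if (length(ss_ids)) {
    comp <- assess_ssrna_completeness(inp$annotations, votu_ids = ss_ids)
    if (!is.null(inp$rdrp_identity)) {
      if (is.null(cfg$rdrp_genus_threshold) ||
          is.null(cfg$rdrp_species_threshold)) {
        stop2("rdrp_identity table present but RdRp clustering thresholds ",
              "are not configured (they have no defaults)")
      }
      lens <- genome_lengths(inp$catalog)[ss_ids]
      cl <- cluster_rdrp(inp$rdrp_identity, lens,
                         genus_threshold = cfg$rdrp_genus_threshold,
                         species_threshold = cfg$rdrp_species_threshold)
      comp <- merge(comp, cl, by = "votu_id", all.x = TRUE)
    }
    env$ssrna <- comp
    write_table_tsv(comp, file.path(out_dir, "ssrna_taxonomy.tsv"))
    man$n_near_complete <- sum(comp$near_complete)
  }
  list(manifest = man)
}

stage_priming <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  ps <- identify_priming_votus(env$active$active, inp$design)
  env$priming <- ps
  write_table_tsv(
    data.frame(votu_id = ps$votu_ids,
               first_active_stage = unname(ps$first_active_stage)),
    file.path(out_dir, "priming_set.tsv"))
  traj <- suppressWarnings(
    priming_activity_trajectory(ps, env$tpm, inp$annotations, inp$design))
  write_table_tsv(traj$trajectory, file.path(out_dir,
                                             "priming_trajectory.tsv"))
  cnt <- count_active_votus(env$active$active, inp$design)
  write_table_tsv(cnt$per_sample, file.path(out_dir, "active_counts.tsv"))
  log_add(log, n_priming = length(ps$votu_ids))
  list(manifest = list(n_priming = length(ps$votu_ids)))
}

stage_report <- function(env, cfg, out_dir, log) {
  inp <- env$inputs
  summ <- suppressWarnings(
    standard_summaries(inp$catalog, env$lifestyle, env$presence$merged,
                       env$active$active, hosts = env$hosts,
                       differential = env$differential))
  write_table_tsv(summ, file.path(out_dir, "summaries.tsv"))
  list(manifest = list(n_summaries = nrow(summ)))
}
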