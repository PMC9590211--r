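## Synthetic input bundles with planted ground truth. The generator states
## a world: a factorial field design (2 rotations x 3 compartments x 3
## growth stages x 4 replicate plots), log-normal genome lengths and
## library depths, Dirichlet compositional structure with deterministic
## compartment/rotation displacement of group centers, negative-binomial
## read counts, a saturating breadth model 1 - exp(-depth/delta), planted
## active/priming/enriched-gene sets, and a Kill-the-Winner coupling that
## depresses host log-abundance per co-occurring active vOTU.

#' Build a simulation configuration
#'
#' Defaults mirror the study scale where feasible and are scaled down for
#' desk-size runs where not (documented in the methods vignette): the
#' active fraction (0.78), priming fraction (0.185 of vOTUs), temperate
#' evidence rates (~10%), the Kill-the-Winner slope (-0.039 in log10
#' abundance per active vOTU) and the 4-replicate factorial design follow
#' the study; vOTU counts default to 150 (not 1059) for runtime.
#'
#' @param seed RNG seed (mandatory; all outputs are reproducible from
#'   `(config, seed)`).
#' @param n_votus Number of dsDNA vOTUs.
#' @param n_ssrna_votus Number of ssRNA phage vOTUs.
#' @param genome_length_meanlog,genome_length_sdlog Log-normal genome
#'   length law (bp), truncated at the catalog floors.
#' @param provirus_fraction Fraction of dsDNA vOTUs flagged proviral.
#' @param genes_per_kb Gene density used to tile genomes.
#' @param compartments,rotations,growth_stages,replicates Design factors.
#' @param library_size_meanlog,library_size_sdlog Log-normal target depth
#'   law (reads).
#' @param compartment_effect,rotation_effect Non-negative scalings of the
#'   compositional displacement of group centers.
#' @param dirichlet_concentration Sample-level Dirichlet concentration
#'   around the group center.
#' @param active_fraction Fraction of vOTUs in the ever-active set.
#' @param active_sample_prob Per-sample activity probability for
#'   active-set members.
#' @param always_active_fraction Fraction of the active set active in
#'   every sample (carriers of planted enriched genes).
#' @param priming_set_size Planted priming-set size (default
#'   `round(0.185 * n_votus)`).
#' @param priming_stage_boost Multiplier of priming-vOTU expression per
#'   growth stage (default doubles per stage).
#' @param ktw_slope Planted change in log10 host abundance per active
#'   vOTU.
#' @param nb_dispersion NB dispersion for all counts (0 = deterministic
#'   `round(mean)` limit, the noiseless regime).
#' @param breadth_delta Saturation scale of `1 - exp(-depth/delta)`
#'   (0 = step function).
#' @param read_length_bp Read length used to convert counts to coverage
#'   depth.
#' @param unmapped_fraction Fraction of each library not mapping to the
#'   catalog (library size = column sum / (1 - unmapped_fraction)).
#' @param leak_rate Probability that a silent gene x sample cell receives
#'   spurious transcripts.
#' @param rna_gene_mean Mean reads per expressed gene and sample.
#' @param expressed_gene_fraction Fraction of an active vOTU's genes that
#'   are transcribed (never below the activity-rule minimum + 1).
#' @param enriched_bulk_fraction,enriched_rhizo_fraction Fractions of
#'   always-active vOTUs' genes planted as bulk-/rhizosphere-enriched.
#'   Defaults keep bulk >> rhizosphere while leaving the majority of the
#'   ubiquitously expressed pool non-differential, as the median-of-ratios
#'   normalisation assumes.
#' @param enriched_fold Expression fold change of enriched genes in their
#'   compartment.
#' @param metabolic_cog_fraction Fraction of genes given a metabolic COG
#'   letter (C, E, F, G, H, I, P or Q).
#' @param lysogeny_domain_fraction Fraction of dsDNA vOTUs given a
#'   lysogeny-associated Pfam domain on one gene.
#' @param temperate_vc_fraction Fraction flagged as clustering with a
#'   known temperate phage.
#' @param known_species_fraction Fraction matching a known species.
#' @param ssrna_near_complete_fraction Fraction of ssRNA vOTUs with all
#'   three core genes full length.
#' @param n_hosts Number of bacterial host genera in the 16S table.
#' @param host_base_log10 Baseline log10 host abundance.
#' @param host_noise_sd Residual sd of log10 host abundance.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_votus = 150,
                              n_ssrna_votus = 30,
                              genome_length_meanlog = log(30000),
                              genome_length_sdlog = 0.35,
                              provirus_fraction = 0.1,
                              genes_per_kb = 1.0,
                              compartments = c("bulk", "rhizosphere", "root"),
                              rotations = c("continuous", "virgin"),
                              growth_stages = c("seedling", "stem_extension",
                                                "pre_harvest"),
                              replicates = 4,
                              library_size_meanlog = log(2e6),
                              library_size_sdlog = 0.3,
                              compartment_effect = 0.8,
                              rotation_effect = 0.8,
                              dirichlet_concentration = 300,
                              active_fraction = 0.78,
                              active_sample_prob = 0.6,
                              always_active_fraction = 0.12,
                              priming_set_size = round(0.185 * n_votus),
                              priming_stage_boost = NULL,
                              ktw_slope = -0.039,
                              nb_dispersion = 0.5,
                              breadth_delta = 1,
                              read_length_bp = 150,
                              unmapped_fraction = 0.3,
                              leak_rate = 0.01,
                              rna_gene_mean = 20,
                              expressed_gene_fraction = 0.5,
                              enriched_bulk_fraction = 0.10,
                              enriched_rhizo_fraction = 0.025,
                              enriched_fold = 8,
                              metabolic_cog_fraction = 0.15,
                              lysogeny_domain_fraction = 0.05,
                              temperate_vc_fraction = 0.03,
                              known_species_fraction = 0.005,
                              ssrna_near_complete_fraction = 0.68,
                              n_hosts = 40,
                              host_base_log10 = 3,
                              host_noise_sd = 0.05) {
  assert_that(!missing(seed), "seed is mandatory")
  cfg <- as.list(environment())
  if (is.null(cfg$priming_stage_boost)) {
    # doubling per stage: priming activity increases over the season
    cfg$priming_stage_boost <- 2^(seq_along(cfg$growth_stages) - 1)
  }
  assert_that(cfg$n_votus >= 1, "n_votus must be >= 1")
  assert_that(cfg$active_fraction >= 0 && cfg$active_fraction <= 1,
              "active_fraction must be in [0, 1]")
  assert_that(cfg$priming_set_size <= cfg$n_votus * cfg$active_fraction,
              "priming_set_size must be <= n_votus * active_fraction")
  assert_that(cfg$compartment_effect >= 0 && cfg$rotation_effect >= 0,
              "effect parameters must be non-negative")
  assert_that(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  assert_that(cfg$leak_rate >= 0 && cfg$leak_rate <= 1,
              "leak_rate must be in [0, 1]")
  assert_that(length(cfg$priming_stage_boost) == length(cfg$growth_stages),
              "priming_stage_boost must match growth_stages")
  class(cfg) <- "simulation_config"
  cfg
}

## NB sampler honouring the deterministic (dispersion 0) limit.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(round(mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

rlnorm_trunc <- function(n, meanlog, sdlog, min) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- x < min
  while (any(bad)) {
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- x < min
  }
  x
}

#' Simulate the factorial sample design
#'
#' @param sim_config [simulation_config()].
#' @return A [sample_design()] covering the full factorial.
#' @export
simulate_design <- function(sim_config) {
  g <- expand.grid(replicate = seq_len(sim_config$replicates),
                   growth_stage = sim_config$growth_stages,
                   rotation = sim_config$rotations,
                   compartment = sim_config$compartments,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("s_%s_%s_%s_r%d",
                         substr(g$compartment, 1, 4),
                         substr(g$rotation, 1, 4),
                         substr(g$growth_stage, 1, 4), g$replicate)
  sample_design(g)
}

#' Simulate the vOTU catalog and gene annotations
#'
#' dsDNA genome lengths are log-normal, truncated at 10 kb (proviruses at
#' 5 kb); genes tile each genome without overlap at about `genes_per_kb`
#' density (every genome gets at least one gene); a fraction of genes
#' receives metabolic COG letters; designated vOTUs carry a
#' lysogeny-associated Pfam domain; ssRNA vOTUs get the three core genes
#' (MP, CP, RdRp) in random order with configurable full-length flags.
#'
#' @param sim_config [simulation_config()].
#' @return List: `catalog` ([votu_catalog()]) and `annotations`
#'   ([gene_annotation()]).
#' @export
simulate_catalog <- function(sim_config) {
  cfg <- sim_config
  with_seed(derive_seed(cfg$seed, "catalog"), {
    n <- cfg$n_votus
    ids <- sprintf("vOTU_%04d", seq_len(n))
    provirus <- runif(n) < cfg$provirus_fraction
    len <- integer(n)
    len[!provirus] <- round(rlnorm_trunc(sum(!provirus),
                                         cfg$genome_length_meanlog,
                                         cfg$genome_length_sdlog, 10000))
    if (any(provirus)) {
      len[provirus] <- round(rlnorm_trunc(sum(provirus),
                                          cfg$genome_length_meanlog - 0.7,
                                          cfg$genome_length_sdlog, 5001))
    }
    src <- sample(.source_libraries, n, replace = TRUE,
                  prob = c(0.39, 0.12, 0.49))
    cat_ds <- data.frame(
      votu_id = ids, genome_length_bp = len, nucleic_type = "dsDNA",
      source_library = src, is_provirus = provirus,
      vc_with_known_temperate = runif(n) < cfg$temperate_vc_fraction,
      known_species_match = runif(n) < cfg$known_species_fraction,
      stringsAsFactors = FALSE
    )
    ss_n <- cfg$n_ssrna_votus
    cat_ss <- NULL
    if (ss_n > 0) {
      cat_ss <- data.frame(
        votu_id = sprintf("rOTU_%04d", seq_len(ss_n)),
        genome_length_bp = round(rlnorm_trunc(ss_n, log(3800), 0.1, 3000)),
        nucleic_type = "ssRNA",
        source_library = "metatranscriptome",
        is_provirus = FALSE, vc_with_known_temperate = FALSE,
        known_species_match = FALSE, stringsAsFactors = FALSE
      )
    }
    catalog <- votu_catalog(rbind(cat_ds, cat_ss))
    ## dsDNA genes: non-overlapping tiling at ~genes_per_kb
    metabolic <- c("C", "E", "F", "G", "H", "I", "P", "Q")
    other_cogs <- c("S", "L", "K", "J", "")
    lys <- lysogeny_pfams()
    lys_votus <- ids[runif(n) < cfg$lysogeny_domain_fraction]
    ann <- vector("list", n)
    for (i in seq_len(n)) {
      L <- len[i]
      ng <- max(1L, round(L / 1000 * cfg$genes_per_kb))
      w <- rgamma(ng, shape = 8, rate = 1)
      bounds <- round(cumsum(w) / sum(w) * L)
      starts <- c(0L, bounds[-ng])
      ends <- bounds
      keep <- ends > starts
      starts <- starts[keep]; ends <- ends[keep]
      ng <- length(starts)
      cogs <- ifelse(runif(ng) < cfg$metabolic_cog_fraction,
                     sample(metabolic, ng, replace = TRUE),
                     sample(other_cogs, ng, replace = TRUE))
      pf <- rep("", ng)
      if (ids[i] %in% lys_votus) pf[sample.int(ng, 1)] <- sample(lys, 1)
      ann[[i]] <- data.frame(
        gene_id = sprintf("%s_g%03d", ids[i], seq_len(ng)),
        votu_id = ids[i], start_bp = starts, end_bp = ends,
        cog_letter = cogs, pfam_domains = pf, core_gene_role = "",
        full_length = TRUE, stringsAsFactors = FALSE
      )
    }
    ## ssRNA core genes
    if (ss_n > 0) {
      ann_ss <- lapply(seq_len(ss_n), function(j) {
        v <- cat_ss$votu_id[j]
        L <- cat_ss$genome_length_bp[j]
        roles <- sample(.core_roles)
        bounds <- round(seq_len(3) / 3 * L)
        starts <- c(0L, bounds[-3])
        full <- rep(TRUE, 3)
        if (runif(1) >= cfg$ssrna_near_complete_fraction) {
          full[sample.int(3, 1)] <- FALSE
        }
        data.frame(
          gene_id = sprintf("%s_g%03d", v, 1:3), votu_id = v,
          start_bp = starts, end_bp = bounds, cog_letter = "",
          pfam_domains = "", core_gene_role = roles, full_length = full,
          stringsAsFactors = FALSE
        )
      })
      ann <- c(ann, ann_ss)
    }
    annotations <- gene_annotation(do.call(rbind, ann), catalog = catalog)
    list(catalog = catalog, annotations = annotations)
  })
}

## Planted activity matrix honouring the priming invariant.
plant_activity <- function(catalog, design, cfg) {
  ds <- catalog$votu_id[catalog$nucleic_type == "dsDNA"]
  n <- length(ds)
  n_active <- round(cfg$active_fraction * n)
  active_set <- sort(sample(ds, n_active))
  priming <- sort(sample(active_set, cfg$priming_set_size))
  pool <- setdiff(active_set, priming)
  n_always <- min(length(pool), round(cfg$always_active_fraction * n_active))
  always <- sort(sample(pool, n_always))
  A <- matrix(FALSE, n, nrow(design), dimnames = list(ds, design$sample_id))
  A[active_set, ] <- matrix(runif(length(active_set) * nrow(design)) <
                              cfg$active_sample_prob,
                            length(active_set), nrow(design))
  A[always, ] <- TRUE
  cont_seed <- design_samples(design, "rhizosphere", "continuous", "seedling")
  virg_seed <- design_samples(design, "rhizosphere", "virgin", "seedling")
  A[priming, cont_seed] <- TRUE
  A[priming, virg_seed] <- FALSE
  ## The priming set is DEFINED by the activity pattern, so the ground
  ## truth is the membership rule applied to the planted matrix: the
  ## forced core (priming_set_size strong) plus any active-set vOTU whose
  ## random activity happens to satisfy the rule.
  satisfies <- rowSums(A[, cont_seed, drop = FALSE]) >= 1 &
    rowSums(A[, virg_seed, drop = FALSE]) == 0
  list(active = A, active_set = active_set,
       priming = rownames(A)[satisfies], priming_core = priming,
       always = always)
}

#' Simulate count matrices, breadth, hosts and ground truth
#'
#' See the package vignette for the full generative model. Per treatment
#' group, the vOTU composition is the global center displaced on the log
#' scale by compartment/rotation effect vectors; per-sample compositions
#' are Dirichlet draws around the group center (with zero effects all
#' samples are i.i.d., so permutation nulls are exact); DNA counts are
#' negative-binomial around composition x depth; breadth follows
#' `1 - exp(-depth/delta)`; RNA gene counts are nonzero only for genes of
#' planted-active vOTUs (plus a leak rate); host 16S abundance is
#' depressed by `ktw_slope` per co-occurring active vOTU assigned to the
#' host.
#'
#' @param catalog,annotations Output of [simulate_catalog()].
#' @param design Output of [simulate_design()].
#' @param sim_config [simulation_config()].
#' @return List: `bundle` ([count_bundle()]), `truth` (active matrix,
#'   priming set, enriched gene labels, planted slope, group centers,
#'   host tables), `host_predictions`, `otu16s` (host x sample counts).
#' @export
simulate_counts <- function(catalog, annotations, design, sim_config) {
  cfg <- sim_config
  ds_ids <- catalog$votu_id[catalog$nucleic_type == "dsDNA"]
  nv <- length(ds_ids)
  ns <- nrow(design)
  L <- genome_lengths(catalog)[ds_ids]

  ## --- compositional structure -------------------------------------------
  comp_truth <- with_seed(derive_seed(cfg$seed, "composition"), {
    p0 <- stats::rlnorm(nv, 0, 1)
    p0 <- p0 / sum(p0)
    e_comp <- lapply(setNames(nm = cfg$compartments),
                     function(x) rnorm(nv))
    e_rot <- lapply(setNames(nm = cfg$rotations), function(x) rnorm(nv))
    centers <- list()
    for (co in cfg$compartments) {
      for (ro in cfg$rotations) {
        lc <- log(p0) + cfg$compartment_effect * e_comp[[co]] +
          cfg$rotation_effect * e_rot[[ro]]
        c_g <- exp(lc - max(lc))
        centers[[paste(co, ro, sep = ".")]] <- c_g / sum(c_g)
      }
    }
    list(p0 = p0, centers = centers)
  })

  ## --- DNA counts + breadth ----------------------------------------------
  dna <- with_seed(derive_seed(cfg$seed, "dna"), {
    out <- list()
    for (lib in c("dna_virome", "total_metagenome")) {
      depth <- stats::rlnorm(ns, cfg$library_size_meanlog,
                             cfg$library_size_sdlog)
      cnt <- matrix(0, nv, ns, dimnames = list(ds_ids, design$sample_id))
      for (s in seq_len(ns)) {
        key <- paste(design$compartment[s], design$rotation[s], sep = ".")
        q <- rdirichlet1(cfg$dirichlet_concentration *
                           comp_truth$centers[[key]])
        mu <- q * depth[s] * (1 - cfg$unmapped_fraction)
        cnt[, s] <- rcounts(nv, mu, cfg$nb_dispersion)
      }
      cover <- cnt * cfg$read_length_bp / L
      breadth <- if (cfg$breadth_delta <= 0) {
        (cover > 0) + 0
      } else {
        1 - exp(-cover / cfg$breadth_delta)
      }
      colsum <- colSums(cnt)
      libsize <- colsum + round(colsum * cfg$unmapped_fraction /
                                  (1 - cfg$unmapped_fraction))
      libsize[libsize == 0] <- 1
      out[[lib]] <- list(counts = cnt, breadth = breadth,
                         library_size = setNames(libsize, design$sample_id))
    }
    out
  })

  ## --- planted activity / priming / enrichment ---------------------------
  act <- with_seed(derive_seed(cfg$seed, "activity"), {
    plant_activity(catalog, design, cfg)
  })
  ds_ann <- annotations[annotations$votu_id %in% ds_ids, , drop = FALSE]
  rna <- with_seed(derive_seed(cfg$seed, "rna"), {
    genes <- ds_ann$gene_id
    gene_votu <- ds_ann$votu_id
    ## per-vOTU expressed gene set: at least the activity-rule minimum + 1
    expressed <- lapply(setNames(nm = ds_ids), function(v) {
      gv <- genes[gene_votu == v]
      need <- min(length(gv), ceiling(L[v] / 1e4) + 1)
      k <- max(need, round(cfg$expressed_gene_fraction * length(gv)))
      sort(sample(gv, min(k, length(gv))))
    })
    ## enriched labels on always-active vOTUs' expressed genes
    pool <- unlist(expressed[act$always], use.names = FALSE)
    labels <- setNames(rep("none", length(genes)), genes)
    if (length(pool)) {
      n_b <- round(cfg$enriched_bulk_fraction * length(pool))
      n_r <- round(cfg$enriched_rhizo_fraction * length(pool))
      pick <- sample(pool, min(length(pool), n_b + n_r))
      labels[pick[seq_len(min(n_b, length(pick)))]] <- "bulk"
      if (n_r > 0 && length(pick) > n_b) {
        labels[pick[(n_b + 1):length(pick)]] <- "rhizosphere"
      }
    }
    stage_idx <- match(design$growth_stage, cfg$growth_stages)
    cnt <- matrix(0, length(genes), ns,
                  dimnames = list(genes, design$sample_id))
    for (s in seq_len(ns)) {
      comp <- design$compartment[s]
      active_here <- ds_ids[act$active[, s]]
      for (v in active_here) {
        gv <- expressed[[v]]
        mu <- rep(cfg$rna_gene_mean, length(gv))
        if (v %in% act$priming) {
          mu <- mu * cfg$priming_stage_boost[stage_idx[s]]
        }
        lb <- labels[gv]
        mu[lb == "bulk" & comp == "bulk"] <-
          mu[lb == "bulk" & comp == "bulk"] * cfg$enriched_fold
        mu[lb == "rhizosphere" & comp == "rhizosphere"] <-
          mu[lb == "rhizosphere" & comp == "rhizosphere"] * cfg$enriched_fold
        mu[lb == "rhizosphere" & comp == "root"] <-
          mu[lb == "rhizosphere" & comp == "root"] * 2 * cfg$enriched_fold
        cnt[gv, s] <- rcounts(length(gv), mu, cfg$nb_dispersion)
      }
    }
    if (cfg$leak_rate > 0) {
      silent <- cnt == 0
      leak <- silent & matrix(runif(length(cnt)) < cfg$leak_rate,
                              nrow(cnt), ncol(cnt))
      cnt[leak] <- 1 + rpois(sum(leak), 1)
    }
    list(counts = cnt, labels = labels)
  })
  rna_colsum <- colSums(rna$counts)
  rna_libsize <- rna_colsum + round(rna_colsum * cfg$unmapped_fraction /
                                      (1 - cfg$unmapped_fraction))
  rna_libsize[rna_libsize == 0] <- 1

  ## --- hosts: predictions + KtW-coupled 16S table ------------------------
  hosts <- with_seed(derive_seed(cfg$seed, "hosts"), {
    genera <- sprintf("g_Host%02d", seq_len(cfg$n_hosts))
    assigned <- setNames(sample(genera, length(act$active_set),
                                replace = TRUE), act$active_set)
    hp <- data.frame(votu_id = act$active_set,
                     host_genus = unname(assigned),
                     p_value = stats::rbeta(length(assigned), 0.3, 4),
                     stringsAsFactors = FALSE)
    n_active_per_host <- matrix(0, cfg$n_hosts, ns,
                                dimnames = list(genera, design$sample_id))
    for (h in genera) {
      vh <- names(assigned)[assigned == h]
      if (length(vh)) {
        n_active_per_host[h, ] <-
          colSums(act$active[vh, , drop = FALSE])
      }
    }
    log10_ab <- cfg$host_base_log10 + cfg$ktw_slope * n_active_per_host +
      matrix(rnorm(length(n_active_per_host), 0, cfg$host_noise_sd),
             cfg$n_hosts, ns)
    otu <- matrix(rcounts(length(log10_ab), as.vector(10^log10_ab),
                          cfg$nb_dispersion),
                  cfg$n_hosts, ns, dimnames = dimnames(n_active_per_host))
    list(predictions = hp, otu = otu, assigned = assigned)
  })

  bundle <- count_bundle(
    dna_counts = list(dna_virome = dna$dna_virome$counts,
                      total_metagenome = dna$total_metagenome$counts),
    rna_gene_counts = rna$counts,
    library_sizes = list(
      dna_virome = dna$dna_virome$library_size,
      total_metagenome = dna$total_metagenome$library_size,
      metatranscriptome = setNames(rna_libsize, design$sample_id)
    ),
    coverage_breadth = list(dna_virome = dna$dna_virome$breadth,
                            total_metagenome = dna$total_metagenome$breadth)
  )
  truth <- list(
    active_matrix = act$active,
    priming_set = act$priming,
    priming_core = act$priming_core,
    always_active = act$always,
    enriched_gene_labels = rna$labels,
    planted_ktw_slope = cfg$ktw_slope,
    group_composition_centers = comp_truth$centers,
    host_assignment = hosts$assigned
  )
  list(bundle = bundle, truth = truth,
       host_predictions = hosts$predictions, otu16s = hosts$otu)
}

#' Simulate Kill-the-Winner host-abundance data
#'
#' Generates `(y, x, compartment)` with `y = intercept + slope * x +
#' u_compartment + e`: log10 host relative abundance against the number
#' of co-occurring active vOTUs, with a compartment random intercept.
#'
#' @param n Number of observations.
#' @param slope Planted slope (default -0.039).
#' @param seed RNG seed.
#' @param intercept Baseline log10 abundance (default 3).
#' @param group_sd Random-intercept sd (default 0.2).
#' @param resid_sd Residual sd (default 0.1).
#' @param x_max Active-count range (x uniform on 0..x_max, default 30).
#' @param n_groups Number of compartments (default 3).
#' @return data.frame: `y, x, compartment`.
#' @export
simulate_ktw <- function(n, slope = -0.039, seed = 1, intercept = 3,
                         group_sd = 0.2, resid_sd = 0.1, x_max = 30,
                         n_groups = 3) {
  with_seed(seed, {
    g <- rep_len(seq_len(n_groups), n)
    u <- rnorm(n_groups, 0, group_sd)
    x <- sample.int(x_max + 1, n, replace = TRUE) - 1
    y <- intercept + slope * x + u[g] + rnorm(n, 0, resid_sd)
    data.frame(y = y, x = x, compartment = paste0("c", g))
  })
}

write_gff3 <- function(annotations, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\trhizovir_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     annotations$votu_id, annotations$start_bp + 1L,
                     annotations$end_bp, annotations$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate and write a complete input bundle
#'
#' Generates the catalog, design, counts, breadth, annotations, host
#' tables and ground truth, and writes them in the exact formats the
#' readers consume: `design.tsv`, `catalog.tsv`, `genes.gff3`,
#' `gene_functions.tsv`, `counts_*.tsv`, `breadth_*.tsv`,
#' `rna_gene_counts.tsv`, `library_sizes.tsv`, `host_predictions.tsv`,
#' `otu_16s.tsv`, `ground_truth_active.tsv`, `ground_truth_sets.tsv`.
#'
#' @param sim_config [simulation_config()].
#' @param dir Output directory.
#' @return Invisibly, the in-memory objects (catalog, annotations, design,
#'   bundle, truth, host_predictions, otu16s).
#' @export
simulate_bundle <- function(sim_config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_ann <- simulate_catalog(sim_config)
  design <- simulate_design(sim_config)
  sim <- simulate_counts(cat_ann$catalog, cat_ann$annotations, design,
                         sim_config)
  write_table_tsv(as.data.frame(design)[
    c("sample_id", "compartment", "rotation", "growth_stage", "replicate")],
    file.path(dir, "design.tsv"))
  write_table_tsv(as.data.frame(cat_ann$catalog),
                  file.path(dir, "catalog.tsv"))
  write_gff3(cat_ann$annotations, file.path(dir, "genes.gff3"))
  write_table_tsv(as.data.frame(cat_ann$annotations)[
    c("gene_id", "cog_letter", "pfam_domains", "core_gene_role",
      "full_length")],
    file.path(dir, "gene_functions.tsv"))
  write_count_bundle(sim$bundle, dir)
  write_table_tsv(sim$host_predictions,
                  file.path(dir, "host_predictions.tsv"))
  write_matrix_tsv(sim$otu16s, file.path(dir, "otu_16s.tsv"))
  write_matrix_tsv(sim$truth$active_matrix + 0,
                   file.path(dir, "ground_truth_active.tsv"))
  write_table_tsv(
    data.frame(votu_id = names(sim$truth$host_assignment),
               set = ifelse(names(sim$truth$host_assignment) %in%
                              sim$truth$priming_set, "priming", "active"),
               host_genus = unname(sim$truth$host_assignment),
               stringsAsFactors = FALSE),
    file.path(dir, "ground_truth_sets.tsv"))
  invisible(c(cat_ann, list(design = design), sim))
}
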