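## Rhizosphere "viral priming": vOTUs actively infecting in the seedling
## rhizosphere under continuous cropping while absent from the seedling
## rhizosphere under virgin rotation — candidate locally-adapted viruses
## persisting from the previous season of the same crop. Plus the
## headline proportion summaries.

#' Identify rhizosphere priming vOTUs
#'
#' Membership rule: active in at least `min_active_continuous` replicate
#' samples of (continuous, rhizosphere, seedling) AND active in at most
#' `max_active_virgin` (default 0, i.e. absent from all) replicates of
#' (virgin, rhizosphere, seedling).
#'
#' @param active_votu Logical vOTU x sample matrix from
#'   [call_active_votus()].
#' @param design [sample_design()] covering the columns.
#' @param min_active_continuous Minimum active continuous replicates
#'   (default 1).
#' @param max_active_virgin Maximum active virgin replicates (default 0).
#' @return List: `votu_ids` (the priming set), `first_active_stage`
#'   (named, per member: earliest growth stage with any active sample),
#'   `criteria` record.
#' @export
identify_priming_votus <- function(active_votu, design,
                                   min_active_continuous = 1,
                                   max_active_virgin = 0) {
  cont <- design_samples(design, "rhizosphere", "continuous", "seedling")
  virg <- design_samples(design, "rhizosphere", "virgin", "seedling")
  if (!length(cont) || !length(virg)) {
    stop2("design must contain seedling rhizosphere samples for both ",
          "rotations")
  }
  cont <- intersect(cont, colnames(active_votu))
  virg <- intersect(virg, colnames(active_votu))
  assert_that(length(cont) > 0 && length(virg) > 0,
              "active matrix is missing seedling rhizosphere samples")
  n_cont <- rowSums(active_votu[, cont, drop = FALSE])
  n_virg <- rowSums(active_votu[, virg, drop = FALSE])
  members <- rownames(active_votu)[n_cont >= min_active_continuous &
                                     n_virg <= max_active_virgin]
  stage_order <- .stages
  first_stage <- vapply(members, function(v) {
    act <- active_votu[v, ]
    st <- design$growth_stage[match(names(act)[act], design$sample_id)]
    stage_order[min(match(st, stage_order))]
  }, character(1))
  list(votu_ids = members,
       first_active_stage = first_stage,
       criteria = list(min_active_continuous = min_active_continuous,
                       max_active_virgin = max_active_virgin))
}

#' Relative-activity trajectory of the priming set
#'
#' Sums the gene TPM of priming-set members per sample, then reports group
#' means with 95% confidence intervals per (growth stage, rotation,
#' compartment).
#'
#' @param priming_set Output of [identify_priming_votus()] (or a character
#'   vector of vOTU ids).
#' @param gene_tpm gene x sample TPM matrix.
#' @param annotations [gene_annotation()] linking genes to vOTUs.
#' @param design [sample_design()].
#' @return List: `per_sample` (sample_id, summed_tpm) and `trajectory`
#'   (growth_stage, rotation, compartment, mean, ci_lo, ci_hi).
#' @export
priming_activity_trajectory <- function(priming_set, gene_tpm, annotations,
                                        design) {
  ids <- if (is.list(priming_set)) priming_set$votu_ids else priming_set
  if (!length(ids)) {
    warning("empty priming set: trajectory is all zero", call. = FALSE)
  }
  genes <- annotations$gene_id[annotations$votu_id %in% ids]
  genes <- intersect(genes, rownames(gene_tpm))
  s <- if (length(genes)) colSums(gene_tpm[genes, , drop = FALSE]) else
    setNames(numeric(ncol(gene_tpm)), colnames(gene_tpm))
  per_sample <- data.frame(sample_id = names(s), summed_tpm = unname(s),
                           stringsAsFactors = FALSE)
  idx <- match(per_sample$sample_id, design$sample_id)
  per_sample$growth_stage <- design$growth_stage[idx]
  per_sample$rotation <- design$rotation[idx]
  per_sample$compartment <- design$compartment[idx]
  traj <- do.call(rbind, lapply(
    split(per_sample,
          list(per_sample$growth_stage, per_sample$rotation,
               per_sample$compartment), drop = TRUE),
    function(d) {
      n <- nrow(d)
      m <- mean(d$summed_tpm)
      half <- if (n > 1) qt(0.975, n - 1) * sd(d$summed_tpm) / sqrt(n) else 0
      data.frame(growth_stage = d$growth_stage[1], rotation = d$rotation[1],
                 compartment = d$compartment[1], mean = m,
                 ci_lo = m - half, ci_hi = m + half,
                 stringsAsFactors = FALSE)
    }))
  rownames(traj) <- NULL
  list(per_sample = per_sample, trajectory = traj)
}

#' Count active vOTUs per sample and per group
#'
#' @param active_votu Logical vOTU x sample matrix.
#' @param design [sample_design()].
#' @return List: `per_sample` (sample_id, n_active, plus design factors)
#'   and `per_group` (group, mean, ci_lo, ci_hi).
#' @export
count_active_votus <- function(active_votu, design) {
  cnt <- colSums(active_votu)
  per_sample <- data.frame(sample_id = names(cnt), n_active = unname(cnt),
                           stringsAsFactors = FALSE)
  idx <- match(per_sample$sample_id, design$sample_id)
  per_sample$compartment <- design$compartment[idx]
  per_sample$rotation <- design$rotation[idx]
  per_sample$growth_stage <- design$growth_stage[idx]
  per_sample$group <- design$group[idx]
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                     function(d) {
    n <- nrow(d)
    m <- mean(d$n_active)
    half <- if (n > 1) qt(0.975, n - 1) * sd(d$n_active) / sqrt(n) else 0
    data.frame(group = d$group[1], mean = m, ci_lo = m - half,
               ci_hi = m + half, stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

#' Proportion summaries over classification, detection and activity
#'
#' Pure arithmetic on numerator/denominator counts: each summary is
#' `percent = round_half_up(100 * num / den, 1)`. Summaries with a zero
#' denominator are omitted with a warning.
#'
#' @param counts Named list; each element is `c(num, den)` (or a list
#'   with `num`/`den`).
#' @return data.frame: `label, num, den, percent`.
#' @export
proportion_summaries <- function(counts) {
  rows <- lapply(names(counts), function(nm) {
    x <- counts[[nm]]
    num <- if (is.list(x)) x$num else x[[1]]
    den <- if (is.list(x)) x$den else x[[2]]
    if (den == 0) {
      warning("zero denominator for '", nm, "': summary omitted",
              call. = FALSE)
      return(NULL)
    }
    assert_that(num >= 0 && num <= den, paste0("need 0 <= num <= den (", nm, ")"))
    data.frame(label = nm, num = num, den = den,
               percent = percent_half_up(num, den),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(label = character(), num = numeric(),
                      den = numeric(), percent = numeric())
  }
  out
}

#' Standard proportion summaries from pipeline stage outputs
#'
#' Assembles the headline counts from upstream stage outputs: temperate
#' fraction of dsDNA vOTUs, detected-in->=1-sample fractions per source
#' library and overall, active fractions per source library and overall,
#' host-assignment and detected-host-genus fractions, and the ratio of
#' bulk- to rhizosphere-enriched differential genes.
#'
#' @param catalog [votu_catalog()].
#' @param lifestyle Output of [call_lifestyle()].
#' @param presence Merged logical presence matrix (dsDNA vOTUs).
#' @param active Logical active matrix.
#' @param hosts Output of [filter_hosts()] (optional).
#' @param differential Output of [nb_wald_test()] (optional).
#' @return data.frame as [proportion_summaries()], plus attribute
#'   `bulk_to_rhizosphere_gene_ratio` when differential results are given.
#' @export
standard_summaries <- function(catalog, lifestyle, presence, active,
                               hosts = NULL, differential = NULL) {
  ds <- catalog[catalog$nucleic_type == "dsDNA", ]
  counts <- list()
  counts[["temperate_dsDNA"]] <-
    c(sum(lifestyle$lifestyle[match(ds$votu_id, lifestyle$votu_id)] ==
            "temperate"), nrow(ds))
  det <- rownames(presence)[rowSums(presence) > 0]
  counts[["detected_overall"]] <- c(sum(ds$votu_id %in% det), nrow(ds))
  act <- rownames(active)[rowSums(active) > 0]
  counts[["active_overall"]] <- c(sum(ds$votu_id %in% act), nrow(ds))
  for (lib in unique(ds$source_library)) {
    sub <- ds$votu_id[ds$source_library == lib]
    counts[[paste0("detected_", lib)]] <- c(sum(sub %in% det), length(sub))
    counts[[paste0("active_", lib)]] <- c(sum(sub %in% act), length(sub))
  }
  if (!is.null(hosts)) {
    counts[["host_assigned_dsDNA"]] <-
      c(sum(ds$votu_id %in% hosts$predictions$votu_id), nrow(ds))
    counts[["host_genera_detected"]] <-
      c(hosts$n_detected_genera, hosts$n_predicted_genera)
  }
  out <- proportion_summaries(counts)
  if (!is.null(differential)) {
    n_bulk <- sum(differential$enriched == "bulk")
    n_rhizo <- sum(differential$enriched == "rhizosphere")
    attr(out, "bulk_to_rhizosphere_gene_ratio") <-
      if (n_rhizo > 0) n_bulk / n_rhizo else NA_real_
  }
  out
}
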