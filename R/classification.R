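## Rule-based vOTU characterisation: temperate/lytic lifestyle calling,
## host-prediction filtering and 16S cross-referencing, ssRNA phage
## (Leviviricetes) core-gene completeness, and RdRp identity clustering
## into genera and species.

#' The packaged list of lysogeny-associated Pfam domains
#'
#' 29 Pfam accessions covering transposases, integrases, excisionases,
#' resolvases and recombinases; a gene hit against any of them marks its
#' vOTU as putatively temperate.
#'
#' @return Character vector of Pfam accessions.
#' @export
lysogeny_pfams <- function() {
  readLines(system.file("extdata", "lysogeny_pfam_list.txt",
                        package = "rhizovir"))
}

#' Call temperate vs lytic lifestyle
#'
#' A vOTU is temperate iff any of its genes carries a lysogeny-associated
#' Pfam domain, OR it clustered with a known temperate phage, OR it is a
#' proviral sequence; otherwise lytic. Every vOTU receives exactly one
#' call; evidence is recorded per vOTU.
#'
#' @param catalog [votu_catalog()].
#' @param annotations [gene_annotation()].
#' @param lysogeny_domain_list Pfam accessions (default the packaged
#'   list, [lysogeny_pfams()]).
#' @return data.frame: `votu_id, lifestyle, evidence` (comma-joined subset
#'   of `lysogeny_domain`, `temperate_vc`, `provirus`).
#' @export
call_lifestyle <- function(catalog, annotations,
                           lysogeny_domain_list = lysogeny_pfams()) {
  psets <- pfam_sets(annotations)
  hit_gene <- vapply(psets, function(p) any(p %in% lysogeny_domain_list),
                     logical(1))
  hit_votu <- unique(annotations$votu_id[hit_gene])
  out <- data.frame(votu_id = catalog$votu_id, lifestyle = "lytic",
                    evidence = "", stringsAsFactors = FALSE)
  ev <- cbind(
    lysogeny_domain = catalog$votu_id %in% hit_votu,
    temperate_vc = catalog$vc_with_known_temperate,
    provirus = catalog$is_provirus
  )
  temperate <- rowSums(ev) > 0
  out$lifestyle[temperate] <- "temperate"
  out$evidence <- apply(ev, 1, function(r) {
    paste(colnames(ev)[r], collapse = ",")
  })
  out
}

#' Filter host predictions and cross-reference detected genera
#'
#' Keeps predictions with strictly `p < p_threshold` (so `p = 0.05` is
#' removed at the default threshold), resolves duplicate (vOTU, genus)
#' rows to the minimum p, retains the single best prediction per vOTU,
#' and flags each predicted host genus by membership in the set of genera
#' detected in the 16S data.
#'
#' @param host_predictions data.frame: `votu_id, host_genus, p_value`.
#' @param p_threshold Strict upper bound on p (default 0.05).
#' @param detected_genera Character vector of genera observed in the
#'   samples (default empty).
#' @return List: `predictions` (filtered, one row per vOTU, with
#'   `detected` flag), `n_predicted_genera`, `n_detected_genera`,
#'   `detected_fraction_percent` (half-up, 1 decimal).
#' @export
filter_hosts <- function(host_predictions, p_threshold = 0.05,
                         detected_genera = character()) {
  hp <- as.data.frame(host_predictions)
  assert_that(all(hp$p_value >= 0 & hp$p_value <= 1),
              "p_value must be in [0, 1]")
  dup <- duplicated(hp[c("votu_id", "host_genus")]) |
    duplicated(hp[c("votu_id", "host_genus")], fromLast = TRUE)
  if (any(dup)) {
    message(sum(dup), " duplicate (votu, genus) rows resolved to minimum p")
    hp <- do.call(rbind, lapply(
      split(hp, paste(hp$votu_id, hp$host_genus, sep = "\r")),
      function(d) d[which.min(d$p_value), , drop = FALSE]))
  }
  hp <- hp[hp$p_value < p_threshold, , drop = FALSE]
  ## one best prediction per vOTU
  hp <- hp[order(hp$votu_id, hp$p_value), ]
  hp <- hp[!duplicated(hp$votu_id), , drop = FALSE]
  rownames(hp) <- NULL
  hp$detected <- hp$host_genus %in% detected_genera
  genera <- unique(hp$host_genus)
  n_det <- sum(genera %in% detected_genera)
  list(predictions = hp,
       n_predicted_genera = length(genera),
       n_detected_genera = n_det,
       detected_fraction_percent =
         if (length(genera)) percent_half_up(n_det, length(genera))
         else NA_real_)
}

#' Assess ssRNA phage core-gene completeness
#'
#' A valid ssRNA phage vOTU carries all three core genes — maturation
#' protein (MP), coat protein (CP) and RNA-dependent RNA polymerase
#' (RdRp) — in any order; it is near-complete when each role is covered by
#' a full-length copy (any full-length copy counts if a role is
#' duplicated).
#'
#' @param annotations [gene_annotation()] rows for ssRNA vOTUs (roles in
#'   `core_gene_role`, `full_length` flags set).
#' @param votu_ids Optional vOTU ids to assess (default: all with
#'   annotated genes).
#' @return data.frame: `votu_id, has_cores, near_complete`
#'   (`near_complete` implies `has_cores`).
#' @export
assess_ssrna_completeness <- function(annotations, votu_ids = NULL) {
  ids <- votu_ids %||% unique(annotations$votu_id)
  res <- do.call(rbind, lapply(ids, function(v) {
    g <- annotations[annotations$votu_id == v, , drop = FALSE]
    roles_present <- vapply(.core_roles, function(r) {
      any(g$core_gene_role == r)
    }, logical(1))
    roles_full <- vapply(.core_roles, function(r) {
      any(g$core_gene_role == r & g$full_length)
    }, logical(1))
    data.frame(votu_id = v, has_cores = all(roles_present),
               near_complete = all(roles_full), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Cluster ssRNA vOTUs into genera and species from RdRp identities
#'
#' Greedy length-sorted clustering (as [greedy_dedup()]) on RdRp amino
#' acid identities: first at the genus threshold, then within each genus
#' at the (higher) species threshold. Species clusters nest within genus
#' clusters by construction. The thresholds are mandatory: the published
#' values live in an external reference, not in this package.
#'
#' @param pairwise_aa_identity data.frame: `a, b, identity` (aligned
#'   fraction optional; defaults to 1).
#' @param lengths Named vector of RdRp sequence lengths.
#' @param genus_threshold,species_threshold Identity thresholds in (0, 1)
#'   with `species_threshold > genus_threshold`. No defaults.
#' @return data.frame: `votu_id, genus_id, species_id`.
#' @export
cluster_rdrp <- function(pairwise_aa_identity, lengths, genus_threshold,
                         species_threshold) {
  assert_that(!missing(genus_threshold) && !missing(species_threshold),
              "genus and species thresholds are mandatory")
  assert_that(genus_threshold > 0 && genus_threshold < 1 &&
                species_threshold > 0 && species_threshold < 1,
              "thresholds must lie in (0, 1)")
  assert_that(species_threshold > genus_threshold,
              "species_threshold must exceed genus_threshold")
  pt <- as.data.frame(pairwise_aa_identity)
  if (!"aligned_fraction" %in% names(pt)) pt$aligned_fraction <- 1
  genus <- greedy_dedup(pt, lengths, id_threshold = genus_threshold,
                        cov_threshold = 0)
  gmap <- setNames(genus$representative, genus$id)
  species <- do.call(rbind, lapply(split(genus$id, gmap[genus$id]),
                                   function(members) {
    sub <- pt[pt$a %in% members & pt$b %in% members, , drop = FALSE]
    greedy_dedup(sub, lengths[members], id_threshold = species_threshold,
                 cov_threshold = 0)
  }))
  smap <- setNames(species$representative, species$id)
  ids <- names(lengths)
  data.frame(votu_id = ids,
             genus_id = paste0("g_", unname(gmap[ids])),
             species_id = paste0("s_", unname(smap[ids])),
             stringsAsFactors = FALSE)
}

#' Match vOTUs to known species by average nucleotide identity
#'
#' A vOTU matches a known species when its maximum ANI against the
#' reference genome set is `>= 0.95` (inclusive). vOTUs without any table
#' row do not match; an empty reference table yields all-FALSE with a
#' warning.
#'
#' @param pairwise_ani data.frame: `votu_id, reference_id, ani`.
#' @param votu_ids vOTU ids to report on.
#' @return Named logical vector over `votu_ids`.
#' @export
match_known_species <- function(pairwise_ani, votu_ids) {
  out <- setNames(rep(FALSE, length(votu_ids)), votu_ids)
  if (is.null(pairwise_ani) || nrow(pairwise_ani) == 0) {
    warning("empty reference ANI table: no known-species matches",
            call. = FALSE)
    return(out)
  }
  best <- tapply(pairwise_ani$ani, pairwise_ani$votu_id, max)
  hit <- names(best)[best >= 0.95]
  out[intersect(hit, votu_ids)] <- TRUE
  out
}
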