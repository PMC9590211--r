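## Sample design: the compartment x rotation x growth-stage x replicate
## factorial every grouping, filter and statistic keys on.

.compartments <- c("bulk", "rhizosphere", "root")
.rotations <- c("continuous", "virgin")
.stages <- c("seedling", "stem_extension", "pre_harvest")

canon_level <- function(x) tolower(trimws(as.character(x)))

#' Construct and validate a sample design
#'
#' A sample design records, for each sequencing sample, the soil/root
#' compartment (`bulk`, `rhizosphere`, `root`), the crop rotation practice
#' (`continuous` cropping vs `virgin` rotation), the crop growth stage
#' (`seedling`, `stem_extension`, `pre_harvest`) and the replicate field
#' plot. Factor levels are canonicalised (trimmed, lower-cased) on input.
#'
#' @param df data.frame with columns `sample_id`, `compartment`,
#'   `rotation`, `growth_stage`, `replicate`.
#' @return A validated `sample_design` data.frame with an added
#'   `group` column (`compartment.rotation.growth_stage`).
#' @seealso [read_sample_design()]
#' @export
sample_design <- function(df) {
  needed <- c("sample_id", "compartment", "rotation", "growth_stage",
              "replicate")
  for (col in needed) {
    if (!col %in% names(df)) stop2("design is missing column '", col, "'")
  }
  df <- as.data.frame(df)[needed]
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop2("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  for (col in c("compartment", "rotation", "growth_stage")) {
    df[[col]] <- canon_level(df[[col]])
  }
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad)) {
      stop2("unknown ", col, " value(s): ", paste(bad, collapse = ", "))
    }
  }
  check_levels("compartment", .compartments)
  check_levels("rotation", .rotations)
  check_levels("growth_stage", .stages)
  df$replicate <- as.integer(df$replicate)
  assert_that(all(df$replicate >= 1L), "replicate indices must be >= 1")
  df$group <- design_group_key(df)
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Deterministic group key from the three treatment factors
#'
#' @param design A `sample_design` (or data.frame with the factor columns).
#' @return Character vector `compartment.rotation.growth_stage`.
#' @export
design_group_key <- function(design) {
  paste(design$compartment, design$rotation, design$growth_stage, sep = ".")
}

#' Read a sample design table
#'
#' Reads a tab-separated design table with header columns `sample_id`,
#' `compartment`, `rotation`, `growth_stage`, `replicate` and validates it
#' (unique sample ids, known factor levels).
#'
#' @param path Path to a TSV file.
#' @return A `sample_design` data.frame.
#' @export
read_sample_design <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  sample_design(df)
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", nrow(x), "samples,",
      length(unique(x$group)), "treatment groups\n")
  NextMethod()
}

## Subset of samples belonging to one (compartment, rotation, stage) cell;
## used by the activity filter and priming rules.
design_samples <- function(design, compartment = NULL, rotation = NULL,
                           growth_stage = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(compartment)) keep <- keep & design$compartment %in% compartment
  if (!is.null(rotation)) keep <- keep & design$rotation %in% rotation
  if (!is.null(growth_stage)) keep <- keep & design$growth_stage %in% growth_stage
  design$sample_id[keep]
}
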