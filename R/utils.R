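## Shared internal helpers: argument checking, rounding, seeds, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop2(msg)
  invisible(TRUE)
}

## Percentages are reported to one decimal with half-up rounding (base
## round() rounds half to even, which would print 12.25 -> 12.2).

#' Round a percentage half-up
#'
#' Computes `100 * num / den` rounded half-up to one decimal place, the
#' convention used for all reported proportion summaries.
#'
#' @param num Numerator count (vectorised).
#' @param den Denominator count (vectorised, > 0).
#' @param digits Decimal places (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percent_half_up(105, 1059)  # 9.9
#' @export
percent_half_up <- function(num, den, digits = 1) {
  assert_that(all(den > 0), "percent denominator must be > 0")
  x <- 100 * num / den
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Deterministic sub-seed derivation: one user seed fans out to independent
## per-stage streams. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Minimal structured stage log: a character vector of "key=value" lines
## accumulated by each stage, written as plain text.
new_log <- function(stage) {
  env <- new.env(parent = emptyenv())
  env$stage <- stage
  env$lines <- character()
  env
}

log_add <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  kv <- c(...)
  log$lines <- c(log$lines, paste0(names(kv), "=", unname(kv)))
  invisible(NULL)
}

write_log <- function(log, path) {
  writeLines(c(paste0("stage=", log$stage), log$lines), path)
  invisible(path)
}

## Matrix helpers ------------------------------------------------------------

as_count_matrix <- function(x, what = "counts") {
  m <- as.matrix(x)
  assert_that(is.numeric(m), paste(what, "must be numeric"))
  assert_that(all(m >= 0), paste(what, "must be non-negative"))
  assert_that(all(abs(m - round(m)) < 1e-8), paste(what, "must be integer"))
  storage.mode(m) <- "double"
  m
}

check_aligned <- function(a, b, what) {
  assert_that(identical(rownames(a), rownames(b)) &&
                identical(colnames(a), colnames(b)),
              paste(what, "must share row and column names"))
}
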