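#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Round half up (x >= 0), as tables of integer percentages are usually
# printed (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Integer percentages, rounded half-up
#'
#' Formats a vector of counts as integer percentages of their total, rounding
#' halves away from zero. This is the rule used for all printed pangenome
#' partition percentages in the package.
#'
#' @param counts Numeric vector of non-negative counts.
#' @param total Denominator; defaults to `sum(counts)`.
#' @return Integer vector of the same length (and names) as `counts`.
#' @examples
#' percent_of_total(c(core = 1571, accessory = 2901, unique = 18058))
#' @export
percent_of_total <- function(counts, total = sum(counts)) {
  stopifnot(is.numeric(counts), all(counts >= 0), total > 0)
  p <- as.integer(floor(100 * counts / total + 0.5))
  names(p) <- names(counts)
  p
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this, so a seed in a config is the only source of randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable per-stage seed derived from a master seed: keeps every stage
# individually reproducible with a single user-facing knob. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Read a tab-separated table with a `#`-prefixed header
#'
#' All tabular outputs of the package use plain TSV whose header line starts
#' with `#`; this reads them (and plain-header TSVs) back.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_tsv_hash <- function(path) {
  first <- readLines(path, n = 1L)
  header <- sub("^#", "", first)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- cols
  df
}

#' Write a table as TSV with a `#`-prefixed header
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# The 25 one-letter COG functional class labels plus the bin for genes
# without an assignment.
cog_category_labels <- function() {
  c(strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]], "unassigned")
}
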