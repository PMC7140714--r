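#' Round half away from zero
#'
#' Nearest-integer rounding with halves rounded up (away from zero), the
#' convention used for reported overlap percentages. Base R's `round()` rounds
#' half to even, which would turn 42.5 into 42.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(41.5, 42.4, 42.5))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with call. = FALSE and sprintf-style formatting
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Normalize an identifier vector: character, whitespace-stripped, duplicates
# collapsed with a warning (IDs are compared case-sensitively).
.as_id_set <- function(x, what = "set") {
  x <- trimws(as.character(x))
  x <- x[!is.na(x) & nzchar(x)]
  if (anyDuplicated(x)) {
    warning(sprintf("%d duplicate ID(s) collapsed in %s", sum(duplicated(x)), what),
            call. = FALSE)
    x <- unique(x)
  }
  x
}

.check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    .err("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    .err("`%s` must be a single number in [0, 1]", name)
  as.numeric(x)
}

# write a data.frame as TSV, never quoting, never row names
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
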