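#' Two-way Venn partition
#'
#' Splits two identifier sets into the three disjoint Venn regions: elements
#' specific to A, specific to B, and common to both. Identifiers are
#' compared case-sensitively after whitespace stripping; duplicates within
#' one input collapse with a warning.
#'
#' @param a,b character vectors of identifiers.
#' @param labels length-2 character vector naming the inputs.
#' @return An object of class `two_way_partition` with fields `specific_a`,
#'   `specific_b`, `common` and `labels`.
#' @export
partition_two <- function(a, b, labels = c("A", "B")) {
  a <- .as_id_set(a, labels[1]); b <- .as_id_set(b, labels[2])
  structure(list(specific_a = sort(setdiff(a, b)),
                 specific_b = sort(setdiff(b, a)),
                 common = sort(intersect(a, b)),
                 labels = labels),
            class = "two_way_partition")
}

#' @export
print.two_way_partition <- function(x, ...) {
  cat(sprintf("two_way_partition (%s | %s)\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s-specific: %d\n", x$labels[1], length(x$specific_a)))
  cat(sprintf("  %s-specific: %d\n", x$labels[2], length(x$specific_b)))
  cat(sprintf("  common:      %d (%.3g%% of union)\n", length(x$common),
              if (length(x$common) + length(x$specific_a) + length(x$specific_b))
                common_fraction(x) else NA_real_))
  invisible(x)
}

#' Common fraction of a two-way partition
#'
#' The percentage of the union shared by both sets:
#' `100 * |common| / (|specific_a| + |specific_b| + |common|)`.
#' Use [round_half_up()] for the nearest-integer rendering used in reports.
#'
#' @param p a [partition_two()] result, or a list/vector with elements
#'   `specific_a`, `specific_b`, `common` giving sets or their sizes.
#' @return The exact percentage as a numeric scalar.
#' @export
#' @examples
#' common_fraction(list(specific_a = 1011, specific_b = 459, common = 1081))
common_fraction <- function(p) {
  sz <- function(x) if (is.numeric(x) && length(x) == 1L) x else length(x)
  na <- sz(p$specific_a); nb <- sz(p$specific_b); nc <- sz(p$common)
  tot <- na + nb + nc
  if (tot <= 0) .err("undefined fraction: the union is empty")
  100 * nc / tot
}

#' Three-way Venn partition
#'
#' Splits three identifier sets into the seven disjoint Venn regions and
#' reports the union size and the triple-intersection percentage
#' `100 * |A ∩ B ∩ C| / |A ∪ B ∪ C|`.
#'
#' @param a,b,c character vectors of identifiers.
#' @param labels length-3 character vector naming the inputs.
#' @return An object of class `three_way_partition` with the regions
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`, plus
#'   `union_size` and `triple_percent`.
#' @export
partition_three <- function(a, b, c, labels = c("A", "B", "C")) {
  a <- .as_id_set(a, labels[1])
  b <- .as_id_set(b, labels[2])
  c <- .as_id_set(c, labels[3])
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  reg <- list(
    a_only = u[in_a & !in_b & !in_c],
    b_only = u[!in_a & in_b & !in_c],
    c_only = u[!in_a & !in_b & in_c],
    ab     = u[in_a & in_b & !in_c],
    ac     = u[in_a & !in_b & in_c],
    bc     = u[!in_a & in_b & in_c],
    abc    = u[in_a & in_b & in_c])
  reg <- lapply(reg, sort)
  structure(c(reg, list(
    labels = labels,
    union_size = length(u),
    triple_percent = if (length(u)) 100 * length(reg$abc) / length(u) else NA_real_)),
    class = "three_way_partition")
}

#' @export
print.three_way_partition <- function(x, ...) {
  cat(sprintf("three_way_partition (%s | %s | %s), union %d\n",
              x$labels[1], x$labels[2], x$labels[3], x$union_size))
  for (r in c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc"))
    cat(sprintf("  %-6s %d\n", r, length(x[[r]])))
  cat(sprintf("  triple intersection: %.3g%% of union\n", x$triple_percent))
  invisible(x)
}

#' Residue intervals and their lengths
#'
#' Protein residue coordinates are 1-based and inclusive at both ends, so an
#' interval from residue `start` to residue `end` spans
#' `end - start + 1` amino acids (e.g. residues 92..405 span 314).
#'
#' @param start,end 1-based inclusive residue coordinates, `start <= end`.
#' @return `residue_interval()` returns a classed interval;
#'   `region_length()` returns the number of residues it spans.
#' @export
#' @examples
#' region_length(residue_interval(92, 405))  # 314
#' region_length(residue_interval(109, 195)) # 87
residue_interval <- function(start, end) {
  start <- .check_count(start, "start", min = 1L)
  end <- .check_count(end, "end", min = 1L)
  if (start > end)
    .err("invalid interval: start (%d) > end (%d)", start, end)
  structure(list(start = start, end = end), class = "residue_interval")
}

#' @rdname residue_interval
#' @param iv a `residue_interval`.
#' @export
region_length <- function(iv) {
  stopifnot(inherits(iv, "residue_interval"))
  iv$end - iv$start + 1L
}

#' @export
print.residue_interval <- function(x, ...) {
  cat(sprintf("residues %d..%d (%d aa)\n", x$start, x$end, region_length(x)))
  invisible(x)
}
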