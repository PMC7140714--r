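#' Score a TAP-MS intensity table
#'
#' Semiquantitative scoring of a bait purification against a negative
#' control, one protein per row:
#'
#' * **abundance** — mean signal intensity over the *detected* bait
#'   replicates (two or one), divided by the protein's molecular weight in
#'   kDa;
#' * **specificity** — mean detected bait intensity divided by the mean
#'   detected control intensity; for proteins not detected in any control
#'   replicate the background level is set to the arbitrary value 1, so the
#'   specificity equals the mean bait intensity numerically.
#'
#' "Not detected" must be encoded as `NA` in the intensity columns, never as
#' numeric 0. A control replicate recorded as detected with intensity
#' exactly 0 is floored to the smallest positive detected intensity in the
#' table (reported via message) to avoid dividing by zero without inventing
#' data. Rows with no detected bait replicate are not in the purification:
#' they are skipped with a message and do not appear in the result.
#'
#' @param tap_table data.frame with columns `protein_id`, `mw_kda`, one or
#'   more `bait_rep*` and `ctrl_rep*` intensity columns, and optionally
#'   `condition` and `tissue` labels (carried through).
#' @return A data.frame of class `tap_scores`: `protein_id`, (`condition`,
#'   `tissue`,) `abundance`, `specificity`, `detected_in_control`,
#'   `n_bait_detected`.
#' @export
score_tap <- function(tap_table) {
  tab <- if (inherits(tap_table, "planted_tap")) tap_table$table else tap_table
  need <- c("protein_id", "mw_kda")
  if (!all(need %in% names(tab)))
    .err("tap table needs columns: %s", paste(need, collapse = ", "))
  bait_cols <- grep("^bait_rep", names(tab), value = TRUE)
  ctrl_cols <- grep("^ctrl_rep", names(tab), value = TRUE)
  if (!length(bait_cols)) .err("tap table has no bait_rep* columns")
  if (any(!is.finite(tab$mw_kda) | tab$mw_kda <= 0))
    .err("molecular weight must be > 0 for every protein")

  bait <- as.matrix(tab[bait_cols])
  ctrl <- if (length(ctrl_cols)) as.matrix(tab[ctrl_cols]) else
    matrix(NA_real_, nrow(tab), 0)
  if (any(bait < 0, na.rm = TRUE) || any(ctrl < 0, na.rm = TRUE))
    .err("intensities must be non-negative")

  n_bait <- as.integer(rowSums(!is.na(bait)))
  skip <- n_bait == 0L
  if (any(skip))
    message(sprintf("skipping %d protein(s) with no detected bait replicate",
                    sum(skip)))

  # floor control intensities recorded as detected-at-0
  zero_ctrl <- !is.na(ctrl) & ctrl == 0
  if (any(zero_ctrl)) {
    floor_val <- min(c(bait[!is.na(bait) & bait > 0],
                       ctrl[!is.na(ctrl) & ctrl > 0]))
    message(sprintf("flooring %d control intensity value(s) of 0 to %g",
                    sum(zero_ctrl), floor_val))
    ctrl[zero_ctrl] <- floor_val
  }

  bait_mean <- rowMeans(bait, na.rm = TRUE)
  n_ctrl <- rowSums(!is.na(ctrl))
  ctrl_mean <- ifelse(n_ctrl > 0, rowMeans(ctrl, na.rm = TRUE), NA_real_)
  detected_in_control <- n_ctrl > 0
  # background level is 1 for proteins absent from the control
  specificity <- ifelse(detected_in_control, bait_mean / ctrl_mean, bait_mean / 1)

  out <- data.frame(protein_id = tab$protein_id, stringsAsFactors = FALSE)
  for (extra in c("condition", "tissue"))
    if (extra %in% names(tab)) out[[extra]] <- tab[[extra]]
  out$abundance <- bait_mean / tab$mw_kda
  out$specificity <- specificity
  out$detected_in_control <- detected_in_control
  out$n_bait_detected <- n_bait
  out <- out[!skip, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tap_scores", "data.frame")
  out
}

#' Call a condition-specific interactome from TAP scores
#'
#' Proteins pass iff their specificity is at least `min_specificity`;
#' additionally, with `control_absent_pass = TRUE` (default) proteins never
#' detected in the negative control pass on presence alone, since their
#' numeric specificity depends on the arbitrary background value of 1.
#' Results are split by (tissue, condition) when those columns are present.
#'
#' @param scores a [score_tap()] result.
#' @param min_specificity specificity threshold (>= 1), default 2.
#' @param control_absent_pass should control-absent proteins pass on
#'   presence alone?
#' @return A named list of sorted character vectors of protein IDs, one per
#'   `tissue.condition` combination (a single unnamed-group list element
#'   `"all"` when no labels are present).
#' @export
call_interactome <- function(scores, min_specificity = 2,
                             control_absent_pass = TRUE) {
  stopifnot(inherits(scores, "data.frame"))
  if (!is.finite(min_specificity) || min_specificity < 1)
    .err("`min_specificity` must be >= 1")
  pass <- scores$specificity >= min_specificity
  if (control_absent_pass) pass <- pass | !scores$detected_in_control
  called <- scores[pass, , drop = FALSE]
  if (all(c("tissue", "condition") %in% names(called))) {
    grp <- paste(called$tissue, called$condition, sep = ".")
    out <- lapply(split(called$protein_id, grp), function(x) sort(unique(x)))
  } else {
    out <- list(all = sort(unique(called$protein_id)))
  }
  out
}
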