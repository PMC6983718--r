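#' AP-MS filter parameters
#'
#' Evidence thresholds and the negative-control rule of the reference
#' filtering procedure: records with fewer than 3 unique peptides, under 20%
#' sequence coverage or an MS score under 50 are discarded (thresholds are
#' inclusive on the keep side), and a protein found in the negative-control
#' (false-positive) database is kept only when its bait-run score is at
#' least `control_fold` (1.5) times its control score. `abundance_ratio_min`
#' is the bait-relative abundance cut (1:100) applied by
#' [abundance_restrict()].
#'
#' @param min_unique_peptides,min_coverage_pct,min_ms_score,control_fold,abundance_ratio_min
#'   numeric thresholds, all > 0.
#' @return list of class `apms_filter_params`.
#' @export
apms_filter_params <- function(min_unique_peptides = 3,
                               min_coverage_pct = 20,
                               min_ms_score = 50,
                               control_fold = 1.5,
                               abundance_ratio_min = 0.01) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) stop("all filter thresholds must be > 0")
  structure(p, class = "apms_filter_params")
}

#' Filter one AP-MS bait run against a negative-control database
#'
#' Applies the four keep rules record by record: unique peptides, coverage,
#' MS score, and the negative-control rule (kept when absent from the
#' control database or when the bait-run score is >= `control_fold` times
#' the control score). The result lists every input record exactly once,
#' kept or rejected with its reasons, and is independent of input order.
#'
#' @param records data.frame with columns `protein_id`, `unique_peptides`,
#'   `coverage_pct`, `ms_score`, `is_bait` (exactly one TRUE; the bait must
#'   itself pass the evidence thresholds).
#' @param control_db data.frame `protein_id`, `control_score` (per-protein
#'   maximal score across control runs); attribute or column `n_runs`
#'   optional.
#' @param params an [apms_filter_params()].
#' @return object of class `filtered_interactome`: `records` (input plus
#'   `kept`, `reasons`, `rel_abundance` = ms_score / bait ms_score),
#'   `bait_id`, `params`.
#' @export
filter_records <- function(records, control_db, params = apms_filter_params()) {
  req <- c("protein_id", "unique_peptides", "coverage_pct", "ms_score", "is_bait")
  if (!all(req %in% names(records))) stop("records is missing required columns")
  if (anyDuplicated(records$protein_id)) stop("duplicate protein_ids in records")
  if (sum(records$is_bait) != 1) stop("records must contain exactly one bait")
  if (any(records$unique_peptides < 0) || any(records$ms_score < 0) ||
      any(records$coverage_pct < 0) || any(records$coverage_pct > 100))
    stop("invalid evidence values in records")
  bait <- records[records$is_bait, ]
  r <- records[order(records$protein_id), ]
  ctrl <- stats::setNames(control_db$control_score, control_db$protein_id)
  fail_up <- r$unique_peptides < params$min_unique_peptides
  fail_cov <- r$coverage_pct < params$min_coverage_pct
  fail_sc <- r$ms_score < params$min_ms_score
  in_ctrl <- r$protein_id %in% names(ctrl)
  fail_ctrl <- in_ctrl &
    r$ms_score < params$control_fold * unname(ctrl[r$protein_id])
  fail_ctrl[is.na(fail_ctrl)] <- FALSE
  if (fail_up[r$is_bait] || fail_cov[r$is_bait] || fail_sc[r$is_bait])
    stop("the bait itself fails the evidence thresholds")
  reasons <- mapply(function(a, b, c, d) {
    paste(c(if (a) "unique_peptides", if (b) "coverage",
            if (c) "score", if (d) "control_db"), collapse = ",")
  }, fail_up, fail_cov, fail_sc, fail_ctrl)
  r$kept <- !(fail_up | fail_cov | fail_sc | fail_ctrl)
  r$reasons <- reasons
  r$rel_abundance <- r$ms_score / bait$ms_score
  rownames(r) <- NULL
  structure(list(records = r, bait_id = bait$protein_id, params = params),
            class = "filtered_interactome")
}

#' @export
print.filtered_interactome <- function(x, ...) {
  cat(sprintf("filtered_interactome: %d/%d records kept (bait: %s)\n",
              sum(x$records$kept), nrow(x$records), x$bait_id))
  rej <- x$records$reasons[!x$records$kept]
  if (length(rej)) {
    tab <- sort(table(unlist(strsplit(rej, ","))), decreasing = TRUE)
    cat("  rejection reasons:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restrict a filtered interactome to bait-relative core interactors
#'
#' Keeps records whose bait-relative abundance (MS-score ratio) is at least
#' `abundance_ratio_min` (inclusive, the ~1:100 rule); the bait itself is
#' always retained.
#'
#' @param interactome a [filter_records()] result whose kept set contains
#'   the bait.
#' @param params an [apms_filter_params()].
#' @return a `filtered_interactome` whose `records` are the kept core set.
#' @export
abundance_restrict <- function(interactome, params = interactome$params) {
  stopifnot(inherits(interactome, "filtered_interactome"))
  r <- interactome$records
  if (!any(r$kept & r$is_bait))
    stop("bait was filtered out upstream; cannot restrict by abundance")
  core <- r[r$kept & (r$rel_abundance >= params$abundance_ratio_min | r$is_bait), ]
  rownames(core) <- NULL
  structure(list(records = core, bait_id = interactome$bait_id, params = params),
            class = "filtered_interactome")
}

#' Two-run reproducibility of filtered interactomes
#'
#' @param run1,run2 `filtered_interactome` objects filtered with identical
#'   parameters.
#' @return list of class `overlap_report`: `shared` (data.frame with per-
#'   protein abundance in each run), `only1`, `only2` (ids), `jaccard`.
#' @export
reproducibility_overlap <- function(run1, run2) {
  stopifnot(inherits(run1, "filtered_interactome"),
            inherits(run2, "filtered_interactome"))
  if (!identical(unclass(run1$params), unclass(run2$params)))
    stop("runs were filtered with different parameters")
  k1 <- run1$records[run1$records$kept, ]
  k2 <- run2$records[run2$records$kept, ]
  shared_ids <- intersect(k1$protein_id, k2$protein_id)
  uni <- union(k1$protein_id, k2$protein_id)
  shared <- data.frame(
    protein_id = shared_ids,
    rel_abundance_run1 = k1$rel_abundance[match(shared_ids, k1$protein_id)],
    rel_abundance_run2 = k2$rel_abundance[match(shared_ids, k2$protein_id)])
  structure(list(shared = shared,
                 only1 = setdiff(k1$protein_id, shared_ids),
                 only2 = setdiff(k2$protein_id, shared_ids),
                 jaccard = if (length(uni)) length(shared_ids) / length(uni) else 1),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d shared, %d/%d run-specific, Jaccard %.3f\n",
              nrow(x$shared), length(x$only1), length(x$only2), x$jaccard))
  invisible(x)
}
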