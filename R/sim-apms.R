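#' Configuration for synthetic AP-MS score tables
#'
#' Emulates a pair of bait pulldown runs plus a negative-control
#' (false-positive) database accumulated over `n_control_runs` control
#' pulldowns (reference design: eight). True interactors pass all evidence
#' thresholds, are shared between the two runs and either never appear in
#' the control database or appear there with scores low enough to survive
#' the fold rule; contaminants carry passable evidence but are present in
#' the controls with scores that violate the 1.5-fold rule; low-evidence
#' decoys fail at least one of the peptide/coverage/score thresholds.
#'
#' @param n_true_interactors,n_contaminants,n_low_evidence record counts per
#'   class.
#' @param bait_score bait MS score (score units).
#' @param true_score_range true-interactor scores as a fraction of the bait
#'   score (default 0.02-1.2, keeping all true interactors above the 1:100
#'   abundance cut).
#' @param contaminant_score_range contaminant bait-run scores, absolute.
#' @param frac_true_in_controls fraction of true interactors that do appear
#'   in the control database (with a weak score passing the fold rule).
#' @param n_control_runs number of control runs behind the database.
#' @return list of class `apms_sim_config`.
#' @export
apms_sim_config <- function(n_true_interactors = 15L,
                            n_contaminants = 60L,
                            n_low_evidence = 124L,
                            bait_score = 5000,
                            true_score_range = c(0.02, 1.2),
                            contaminant_score_range = c(60, 2000),
                            frac_true_in_controls = 0.3,
                            n_control_runs = 8L) {
  if (n_true_interactors < 0 || n_contaminants < 0 || n_low_evidence < 0)
    stop("counts must be >= 0")
  if (n_control_runs < 1) stop("n_control_runs must be >= 1")
  structure(as.list(environment()), class = "apms_sim_config")
}

#' Simulate AP-MS tables with planted ground truth
#'
#' @param config an [apms_sim_config()].
#' @param seed integer master seed.
#' @param params filter parameters the tables are constructed against
#'   (default [apms_filter_params()]).
#' @return list: `run1`, `run2` (record data.frames in the
#'   [filter_records()] schema), `control_db` (`protein_id`,
#'   `control_score`, per-protein maximum over the control runs; attribute
#'   `n_runs`), `labels` (`protein_id`, `role` in
#'   bait/true/contaminant/low_evidence).
#' @export
simulate_apms_tables <- function(config, seed, params = apms_filter_params()) {
  stopifnot(inherits(config, "apms_sim_config"))
  cfg <- config
  ids <- function(prefix, n) if (n) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
  true_ids <- ids("TRUE_", cfg$n_true_interactors)
  cont_ids <- ids("CONT_", cfg$n_contaminants)
  low_ids <- ids("LOW_", cfg$n_low_evidence)
  bait_id <- "BAIT_001"

  empty_rec <- data.frame(protein_id = character(0),
                          unique_peptides = integer(0),
                          coverage_pct = numeric(0), ms_score = numeric(0),
                          is_bait = logical(0))
  make_run <- function(run_tag) {
    with_seed(derive_seed(seed, paste0("apms-run-", run_tag)), {
      n_t <- cfg$n_true_interactors; n_c <- cfg$n_contaminants; n_l <- cfg$n_low_evidence
      bait <- data.frame(protein_id = bait_id,
                         unique_peptides = sample(20:60, 1),
                         coverage_pct = stats::runif(1, 40, 90),
                         ms_score = cfg$bait_score * stats::runif(1, 0.95, 1.05),
                         is_bait = TRUE)
      true <- if (n_t == 0) empty_rec else data.frame(protein_id = true_ids,
                         unique_peptides = sample(3:30, n_t, replace = TRUE),
                         coverage_pct = stats::runif(n_t, 20, 85),
                         ms_score = cfg$bait_score *
                           exp(stats::runif(n_t, log(cfg$true_score_range[1]),
                                            log(cfg$true_score_range[2]))),
                         is_bait = FALSE)
      cont <- if (n_c == 0) empty_rec else data.frame(protein_id = cont_ids,
                         unique_peptides = sample(3:25, n_c, replace = TRUE),
                         coverage_pct = stats::runif(n_c, 20, 70),
                         ms_score = exp(stats::runif(n_c, log(cfg$contaminant_score_range[1]),
                                                     log(cfg$contaminant_score_range[2]))),
                         is_bait = FALSE)
      # low-evidence decoys: fail >= 1 of the three evidence thresholds
      low <- if (n_l == 0) empty_rec else {
        fail_which <- sample(1:3, n_l, replace = TRUE)
        l <- data.frame(protein_id = low_ids,
                        unique_peptides = sample(3:20, n_l, replace = TRUE),
                        coverage_pct = stats::runif(n_l, 20, 60),
                        ms_score = stats::runif(n_l, 50, 500),
                        is_bait = FALSE)
        l$unique_peptides[fail_which == 1] <-
          sample(0:(params$min_unique_peptides - 1), sum(fail_which == 1),
                 replace = TRUE)
        l$coverage_pct[fail_which == 2] <-
          stats::runif(sum(fail_which == 2), 0, params$min_coverage_pct * 0.99)
        l$ms_score[fail_which == 3] <-
          stats::runif(sum(fail_which == 3), 1, params$min_ms_score * 0.99)
        l
      }
      rbind(bait, true, cont, low)
    })
  }
  run1 <- make_run("1")
  run2 <- make_run("2")

  control_db <- with_seed(derive_seed(seed, "apms-controls"), {
    # contaminants: present in controls with max score violating the fold
    # rule in BOTH bait runs (control > bait_score / fold)
    cont_min <- pmax(run1$ms_score[match(cont_ids, run1$protein_id)],
                     run2$ms_score[match(cont_ids, run2$protein_id)])
    per_run <- matrix(0, length(cont_ids), config$n_control_runs)
    cont_max <- cont_min / params$control_fold * stats::runif(length(cont_ids), 1.05, 2)
    for (j in seq_len(config$n_control_runs))
      per_run[, j] <- cont_max * stats::runif(length(cont_ids), 0.3, 1)
    # force the per-protein max to the constructed violating score
    if (length(cont_ids)) per_run[, 1] <- cont_max
    # a fraction of true interactors appears weakly in the controls
    n_weak <- round(config$frac_true_in_controls * length(true_ids))
    weak_ids <- if (n_weak) true_ids[seq_len(n_weak)] else character(0)
    weak_min <- pmin(run1$ms_score[match(weak_ids, run1$protein_id)],
                     run2$ms_score[match(weak_ids, run2$protein_id)])
    weak_score <- weak_min / params$control_fold * stats::runif(length(weak_ids), 0.2, 0.9)
    db <- data.frame(protein_id = c(cont_ids, weak_ids),
                     control_score = c(if (length(cont_ids)) apply(per_run, 1, max) else numeric(0),
                                       weak_score))
    attr(db, "n_runs") <- config$n_control_runs
    db
  })

  labels <- data.frame(
    protein_id = c(bait_id, true_ids, cont_ids, low_ids),
    role = c("bait", rep("true", length(true_ids)),
             rep("contaminant", length(cont_ids)),
             rep("low_evidence", length(low_ids))))
  list(run1 = run1, run2 = run2, control_db = control_db, labels = labels)
}
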