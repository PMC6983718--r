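make_records <- function(...) {
  rbind(data.frame(protein_id = "BAIT", unique_peptides = 40,
                   coverage_pct = 60, ms_score = 5000, is_bait = TRUE),
        ...)
}

ctrl_db <- function(ids, scores) data.frame(protein_id = ids, control_score = scores)

test_that("each evidence rule rejects with its named reason; boundaries are inclusive", {
  rec <- make_records(
    data.frame(protein_id = c("P1", "P2", "P3", "P4", "P5"),
               unique_peptides = c(2, 3, 10, 10, 3),
               coverage_pct = c(50, 19.9, 20, 50, 20),
               ms_score = c(500, 500, 50, 49.9, 50),
               is_bait = FALSE))
  f <- filter_records(rec, ctrl_db(character(0), numeric(0)))
  r <- f$records
  expect_false(r$kept[r$protein_id == "P1"])
  expect_equal(r$reasons[r$protein_id == "P1"], "unique_peptides")
  expect_false(r$kept[r$protein_id == "P2"])
  expect_equal(r$reasons[r$protein_id == "P2"], "coverage")
  expect_true(r$kept[r$protein_id == "P3"])   # all three exactly at threshold
  expect_false(r$kept[r$protein_id == "P4"])
  expect_equal(r$reasons[r$protein_id == "P4"], "score")
  expect_true(r$kept[r$protein_id == "P5"])
})

test_that("the negative-control rule keeps absentees and 1.5-fold enriched hits", {
  rec <- make_records(
    data.frame(protein_id = c("ABSENT", "ENRICHED", "BOUND", "CONTAM"),
               unique_peptides = 10, coverage_pct = 50,
               ms_score = c(300, 300, 300, 300), is_bait = FALSE))
  db <- ctrl_db(c("ENRICHED", "BOUND", "CONTAM"), c(100, 200, 201))
  f <- filter_records(rec, db)
  r <- f$records
  expect_true(r$kept[r$protein_id == "ABSENT"])
  expect_true(r$kept[r$protein_id == "ENRICHED"])   # 300 >= 1.5 * 100
  expect_true(r$kept[r$protein_id == "BOUND"])      # exactly 1.5-fold: kept
  expect_false(r$kept[r$protein_id == "CONTAM"])    # 300 < 1.5 * 201
  expect_equal(r$reasons[r$protein_id == "CONTAM"], "control_db")
})

test_that("malformed tables are rejected", {
  rec <- make_records(
    data.frame(protein_id = "P1", unique_peptides = 5, coverage_pct = 30,
               ms_score = 100, is_bait = FALSE))
  expect_error(filter_records(rbind(rec, rec[2, ]), ctrl_db(character(0), numeric(0))),
               "duplicate")
  no_bait <- rec; no_bait$is_bait <- FALSE
  expect_error(filter_records(no_bait, ctrl_db(character(0), numeric(0))),
               "bait")
  weak_bait <- rec; weak_bait$unique_peptides[1] <- 1
  expect_error(filter_records(weak_bait, ctrl_db(character(0), numeric(0))),
               "bait")
})

test_that("filtering equals brute-force rule evaluation and is order/threshold stable", {
  params <- apms_filter_params()
  for (s in 1:6) {
    tabs <- simulate_apms_tables(apms_sim_config(), s)
    f <- filter_records(tabs$run1, tabs$control_db, params)
    kept <- sort(f$records$protein_id[f$records$kept])
    expect_identical(kept,
                     brute_force_apms_keep(tabs$run1, tabs$control_db, params))
    # permutation invariance
    set.seed(s)
    shuf <- tabs$run1[sample(nrow(tabs$run1)), ]
    f2 <- filter_records(shuf, tabs$control_db, params)
    expect_identical(sort(f2$records$protein_id[f2$records$kept]), kept)
    # every record appears exactly once, kept or with >= 1 reason
    expect_equal(nrow(f$records), nrow(tabs$run1))
    expect_true(all(f$records$kept | nchar(f$records$reasons) > 0))
    # monotonicity: raising any threshold never adds a kept record
    for (fld in c("min_unique_peptides", "min_coverage_pct", "min_ms_score",
                  "control_fold")) {
      p2 <- params; p2[[fld]] <- p2[[fld]] * 1.5
      f3 <- tryCatch(filter_records(tabs$run1, tabs$control_db, p2),
                     error = function(e) NULL)  # bait itself may now fail
      if (!is.null(f3)) {
        kept3 <- f3$records$protein_id[f3$records$kept]
        expect_true(all(kept3 %in% kept))
      }
    }
  }
})

test_that("abundance restriction applies the inclusive 1:100 rule and keeps the bait", {
  rec <- make_records(
    data.frame(protein_id = c("AT_1PCT", "BELOW", "HIGH"),
               unique_peptides = 10, coverage_pct = 50,
               ms_score = c(50, 49.99, 4000), is_bait = FALSE))
  f <- filter_records(rec, ctrl_db(character(0), numeric(0)),
                      apms_filter_params(min_ms_score = 10))
  core <- abundance_restrict(f)
  ids <- core$records$protein_id
  expect_true(all(c("BAIT", "AT_1PCT", "HIGH") %in% ids))  # 50/5000 = 1% exactly
  expect_false("BELOW" %in% ids)
  bait_rel <- core$records$rel_abundance[core$records$is_bait]
  expect_equal(bait_rel, 1)
})

test_that("two-run overlap reports Jaccard and shared abundances", {
  tabs <- simulate_apms_tables(apms_sim_config(), 11)
  f1 <- abundance_restrict(filter_records(tabs$run1, tabs$control_db))
  f2 <- abundance_restrict(filter_records(tabs$run2, tabs$control_db))
  ov <- reproducibility_overlap(f1, f2)
  expect_equal(ov$jaccard, 1)
  expect_equal(sort(ov$shared$protein_id),
               sort(tabs$labels$protein_id[tabs$labels$role %in% c("bait", "true")]))
  same <- reproducibility_overlap(f1, f1)
  expect_equal(same$jaccard, 1)
  # disjoint: filter two unrelated tables and rename one side
  g2 <- f2
  g2$records$protein_id <- paste0("X_", g2$records$protein_id)
  ov0 <- reproducibility_overlap(f1, g2)
  expect_equal(ov0$jaccard, 0)
  expect_equal(nrow(ov0$shared), 0)
})
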