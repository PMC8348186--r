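test_that("detection holds out the intended rows and learns the task", {
  ds <- mid_table1_dataset()
  res <- run_detection(ds, families = c("LDA", "ESD"), seed = 3)
  expect_s3_class(res, "experiment_result")
  expect_setequal(names(res$reports), c("detect_L1", "detect_L2", "overall"))
  # holdouts reference the right rows
  meta <- ds$meta
  expect_true(all(meta$level[res$holdouts$detect_L1] == "L1"))
  expect_true(all(meta$level[res$holdouts$detect_L2] == "L2"))
  expect_equal(length(res$holdouts$detect_L1), 18)   # half of 36
  ov <- res$holdouts$overall
  expect_true(any(meta$status[ov] == "sound"))
  expect_true(all(meta$status[ov] == "sound" |
                    (meta$level[ov] %in% c("L1", "L2", "L3") &
                       meta$hours[ov] == 1)))
  # held-out early latent bruises are still detected reliably
  expect_gte(res$reports$detect_L2$ESD$test_accuracy, 90)
  expect_gte(res$reports$overall$ESD$test_accuracy, 90)
  # binary AUC is defined on the mixed overall block, not the
  # single-class level holdouts
  expect_gte(res$reports$overall$ESD$auc, 0.9)
  expect_true(is.na(res$reports$detect_L2$ESD$auc))
  # summary mirrors the reports
  expect_equal(nrow(res$summary), 6)
  expect_equal(res$summary$test_accuracy[res$summary$target == "detect_L2" &
                                           res$summary$family == "ESD"],
               res$reports$detect_L2$ESD$test_accuracy)
  # split is deterministic in the seed
  res2 <- run_detection(ds, families = "LDA", seed = 3)
  expect_identical(res2$holdouts, res$holdouts)
})

test_that("detection refuses datasets missing a level or sound rows", {
  ds <- mid_table1_dataset()
  drop_l4 <- ds
  keep <- ds$meta$level != "L4"
  drop_l4$spectra <- ds$spectra[keep, , drop = FALSE]
  drop_l4$meta <- ds$meta[keep, , drop = FALSE]
  expect_error(run_detection(drop_l4), "L4")
  no_sound <- ds
  keep <- ds$meta$status != "sound"
  no_sound$spectra <- ds$spectra[keep, , drop = FALSE]
  no_sound$meta <- ds$meta[keep, , drop = FALSE]
  expect_error(run_detection(no_sound), "sound")
})

test_that("temporal test sets pair bruised halves with equal sound halves", {
  ds <- mid_factorial_dataset()
  res <- run_temporal(ds, families = c("LDA", "ESD"), hours = c(1, 48),
                      seed = 2)
  expect_setequal(names(res$reports), c("h1", "h48"))
  s <- res$summary
  # each instant tests the same number of rows for every family
  for (h in c(1, 48))
    expect_length(unique(s$n_test[s$hours == h]), 1)
  # bruised and sound halves are balanced to within one row
  rep1 <- res$reports$h1$LDA
  cnt <- rowSums(rep1$confusion)
  expect_lte(abs(cnt[["bruised"]] - cnt[["sound"]]), 1)
  # normalised speed equals 1 for exactly the fastest family per instant
  for (h in c(1, 48)) {
    nsp <- s$normalized_speed[s$hours == h]
    expect_equal(max(nsp), 1)
    expect_true(all(nsp > 0 & nsp <= 1))
  }
  # accuracy stays high through the latent window
  expect_gte(res$reports$h1$ESD$test_accuracy, 85)
  expect_gte(res$reports$h48$ESD$test_accuracy, 90)
  expect_error(run_temporal(ds, hours = 7), "7 h")
})

test_that("severity class order starts at sound and tracks amplitude", {
  ord <- severity_class_order(all_class_codes())
  expect_equal(ord[1], "sound")
  expect_length(ord, 31)
  # the freshest weakest impact comes before the oldest strongest
  expect_lt(match("L11", ord), match("L672", ord))
  tbl <- severity_table()
  amps <- vapply(ord[-1], function(cd) {
    p <- parse_class_code(cd)
    bruise_amplitude(tbl$impact_energy_J[p$level], p$hours)
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))
})

test_that("quantitative experiment evaluates per-instant and global blocks", {
  ds <- mid_factorial_dataset()
  res <- run_quantitative(ds, families = "ESD", seed = 4)
  expect_setequal(names(res$reports), c("h1", "h6", "h18", "global"))
  # global block is the union of the per-instant holdouts
  expect_setequal(res$holdouts$global,
                  c(res$holdouts$h1, res$holdouts$h6, res$holdouts$h18))
  # only low levels at the test instants are ever held out
  meta <- ds$meta
  held <- res$holdouts$global
  expect_true(all(meta$level[held] %in% c("L1", "L2", "L3")))
  expect_true(all(meta$hours[held] %in% c(1, 6, 18)))
  # the 31-class problem beats chance by a wide margin
  expect_length(res$class_order, 31)
  expect_gt(res$reports$global$ESD$test_accuracy, 40)
  # errors concentrate near the severity diagonal
  adj <- confusion_adjacency(res$reports$global$ESD$confusion,
                             res$class_order)
  expect_gt(adj, 0.2)
})

test_that("grouping maps merge classes and must partition the codes", {
  ds <- mid_factorial_dataset()
  codes <- sort(unique(ds$meta$class_code))
  tbl <- severity_table()
  sev <- vapply(setdiff(codes, "sound"), function(cd) {
    p <- parse_class_code(cd)
    bruise_amplitude(tbl$impact_energy_J[p$level], p$hours)
  }, numeric(1))
  grouping <- list(sound = "sound",
                   latent = names(sev)[sev <= stats::median(sev)],
                   visible = names(sev)[sev > stats::median(sev)])
  res <- run_quantitative(ds, families = "LDA", grouping = grouping, seed = 4)
  expect_setequal(res$class_order, c("sound", "latent", "visible"))
  expect_setequal(rownames(res$reports$global$LDA$confusion),
                  c("sound", "latent", "visible"))
  # coarse problem is easier than the 31-class one
  fine <- run_quantitative(ds, families = "LDA", seed = 4)
  expect_gte(res$reports$global$LDA$test_accuracy,
             fine$reports$global$LDA$test_accuracy)
  # non-partitions are rejected
  expect_error(run_quantitative(ds, grouping = list(a = "sound")),
               "partition")
  expect_error(run_quantitative(ds, grouping = c(grouping,
                                                 list(dup = "sound"))),
               "partition")
})

test_that("identity grouping reproduces the ungrouped experiment", {
  ds <- mid_factorial_dataset()
  codes <- sort(unique(ds$meta$class_code))
  ident <- as.list(codes); names(ident) <- codes
  a <- run_quantitative(ds, families = "LDA", seed = 6)
  b <- run_quantitative(ds, families = "LDA", grouping = ident, seed = 6)
  expect_identical(a$holdouts, b$holdouts)
  expect_equal(a$reports$global$LDA$test_accuracy,
               b$reports$global$LDA$test_accuracy)
})
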