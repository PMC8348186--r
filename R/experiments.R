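# Orchestration of the three studies on simulator output: latent-bruise
# detection, temporal influence, and quantitative severity classification.

DEFAULT_FAMILIES <- c("QSVM", "FKNN", "LDA", "ESD")

# seeded half-split of an index vector (floor(n/2) held out)
.half <- function(idx, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sort(sample(idx, floor(length(idx) / 2)))
}

# stratified seeded half-split: half of each class cell
.half_stratified <- function(idx, strata, seed) {
  out <- integer(0)
  for (s in unique(strata)) {
    out <- c(out, .half(idx[strata == s], seed + sum(utf8ToInt(as.character(s)))))
  }
  sort(out)
}

.spec_for <- function(family, seed) classifier_spec(family = family, seed = seed)

.fit_and_eval <- function(family, X, y, train_idx, test_idx, seed,
                          n_folds = 10L, positive_class = NULL,
                          time_speed = FALSE) {
  spec <- .spec_for(family, seed)
  tr <- train_classifier(spec, X[train_idx, , drop = FALSE], y[train_idx],
                         n_folds = n_folds, seed = seed)
  rep <- evaluate_classifier(tr$model, X[test_idx, , drop = FALSE],
                             y[test_idx], positive_class = positive_class,
                             cv_accuracy = tr$cv_accuracy)
  if (time_speed)
    rep$prediction_speed <- prediction_speed(tr$model,
                                             X[test_idx, , drop = FALSE])
  rep
}

#' Latent-bruise detection experiment
#'
#' Binary bruised-vs-sound models. Three targets are evaluated:
#' `detect_L1` and `detect_L2` hold out a seeded half of the bruised rows
#' of that level and train on everything else; `overall` trains on all
#' rows and is tested on half the 1-h rows of levels L1-L3 together with
#' half of the sound rows.
#'
#' @param dataset A `spectra_table` from [assemble_dataset()] containing
#'   all six levels and sound rows.
#' @param families Classifier families to run.
#' @param seed Integer seed driving splits, folds and ensembles.
#' @param n_folds Cross-validation folds.
#' @return List of class `experiment_result`: `reports[[target]][[family]]`
#'   are [evaluate_classifier()] reports, `summary` a data.frame.
#' @export
run_detection <- function(dataset, families = DEFAULT_FAMILIES, seed = 1L,
                          n_folds = 10L) {
  meta <- dataset$meta; X <- dataset$spectra
  y <- meta$status
  for (lv in paste0("L", 1:6))
    if (!lv %in% meta$level) stop("dataset lacks severity level ", lv)
  if (!any(y == "sound")) stop("dataset lacks sound rows")
  all_idx <- seq_len(nrow(X))
  targets <- list(
    detect_L1 = .half(which(meta$level == "L1"), seed * 13L + 1L),
    detect_L2 = .half(which(meta$level == "L2"), seed * 13L + 2L),
    overall = sort(c(
      .half(which(meta$level %in% c("L1", "L2", "L3") & meta$hours == 1),
            seed * 13L + 3L),
      .half(which(y == "sound"), seed * 13L + 4L)))
  )
  reports <- list(); rows <- list()
  for (tname in names(targets)) {
    test_idx <- targets[[tname]]
    train_idx <- setdiff(all_idx, test_idx)
    reports[[tname]] <- list()
    for (fam in families) {
      rep <- .fit_and_eval(fam, X, y, train_idx, test_idx, seed,
                           n_folds = n_folds, positive_class = "bruised")
      reports[[tname]][[fam]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        target = tname, family = fam, cv_accuracy = rep$cv_accuracy,
        test_accuracy = rep$test_accuracy, auc = rep$auc,
        n_test = rep$n_test)
    }
  }
  structure(list(reports = reports, summary = do.call(rbind, rows),
                 holdouts = targets, seed = seed),
            class = "experiment_result")
}

#' Temporal-influence experiment
#'
#' For each scan instant, half the L1/L2 rows at that instant plus an
#' equally sized held-out sound sample form the test set; training uses
#' all remaining L1/L2 rows across every instant plus the remaining sound
#' rows. Prediction speeds are reported normalised per instant.
#'
#' @param dataset A `spectra_table` with L1 and L2 rows at all requested
#'   instants.
#' @param hours Scan instants to evaluate.
#' @inheritParams run_detection
#' @return `experiment_result` with `reports[[hour]][[family]]` and a
#'   summary including `normalized_speed`.
#' @export
run_temporal <- function(dataset, families = DEFAULT_FAMILIES,
                         hours = c(1, 6, 18, 48), seed = 1L, n_folds = 10L) {
  meta <- dataset$meta
  keep <- meta$level %in% c("L1", "L2") | meta$status == "sound"
  X <- dataset$spectra[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  y <- meta$status
  for (h in hours)
    if (!any(meta$level %in% c("L1", "L2") & meta$hours == h))
      stop("dataset lacks L1/L2 rows at ", h, " h")
  all_idx <- seq_len(nrow(X))
  reports <- list(); rows <- list()
  for (h in hours) {
    bru_h <- which(meta$level %in% c("L1", "L2") & meta$hours == h)
    snd <- which(y == "sound")
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed * 29L + h)
    snd_sub <- sample(snd, min(length(bru_h), length(snd)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    test_idx <- sort(c(.half(bru_h, seed * 29L + h + 1L),
                       .half(snd_sub, seed * 29L + h + 2L)))
    train_idx <- setdiff(all_idx, test_idx)
    hname <- paste0("h", h)
    reports[[hname]] <- list()
    speeds <- numeric(0)
    for (fam in families) {
      rep <- .fit_and_eval(fam, X, y, train_idx, test_idx, seed,
                           n_folds = n_folds, positive_class = "bruised",
                           time_speed = TRUE)
      reports[[hname]][[fam]] <- rep
      speeds[fam] <- rep$prediction_speed
      rows[[length(rows) + 1]] <- data.frame(
        hours = h, family = fam, cv_accuracy = rep$cv_accuracy,
        test_accuracy = rep$test_accuracy, auc = rep$auc,
        prediction_speed = rep$prediction_speed, n_test = rep$n_test)
    }
    nsp <- normalize_speeds(speeds)
    for (fam in families)
      reports[[hname]][[fam]]$normalized_speed <- nsp[[fam]]
  }
  summary <- do.call(rbind, rows)
  summary$normalized_speed <- stats::ave(summary$prediction_speed,
                                         summary$hours,
                                         FUN = function(v) v / max(v))
  structure(list(reports = reports, summary = summary, seed = seed),
            class = "experiment_result")
}

#' Severity-ordered class ordering
#'
#' Orders class codes by the expected bruise amplitude of their
#' (level, hours) cell — the model's notion of severity — with `"sound"`
#' first. Used to read confusion matrices along a severity axis.
#'
#' @param codes Character class codes (may include `"sound"`).
#' @return The codes reordered by increasing expected amplitude.
#' @export
severity_class_order <- function(codes) {
  tbl <- severity_table()
  amp <- vapply(codes, function(cd) {
    if (cd == "sound") return(-1)
    p <- parse_class_code(cd)
    bruise_amplitude(tbl$impact_energy_J[p$level], p$hours)
  }, numeric(1))
  codes[order(amp)]
}

#' Quantitative severity-classification experiment
#'
#' Multiclass problem over the severity/time class codes plus `"sound"`
#' (31 classes for six levels at five instants). For each test instant
#' (1, 6, 18 h) a stratified half of the low-level (L1-L3) rows at that
#' instant is held out; one model per family is trained on everything
#' else with cross-validation and evaluated on each per-instant block and
#' on their union (the global block).
#'
#' @param dataset A `spectra_table`, typically from the factorial
#'   manifest so every level has every instant.
#' @param grouping Optional named list mapping group labels to class-code
#'   vectors; must partition the observed codes. Classes are merged
#'   before training (e.g. to latent/visible/severe).
#' @param test_hours Instants whose L1-L3 halves form the test blocks.
#' @inheritParams run_detection
#' @return `experiment_result` with `reports[[block]][[family]]`,
#'   a summary data.frame and the severity `class_order` used for
#'   confusion-matrix reading.
#' @export
run_quantitative <- function(dataset, families = DEFAULT_FAMILIES,
                             grouping = NULL, test_hours = c(1, 6, 18),
                             seed = 1L, n_folds = 10L) {
  meta <- dataset$meta; X <- dataset$spectra
  y <- meta$class_code
  if (!is.null(grouping)) {
    flat <- unlist(grouping, use.names = FALSE)
    if (anyDuplicated(flat) || !setequal(flat, unique(y)))
      stop("grouping map is not a partition of the observed class codes")
    key <- rep(names(grouping), lengths(grouping))
    names(key) <- flat
    y <- unname(key[y])
  }
  all_idx <- seq_len(nrow(X))
  blocks <- list()
  for (h in test_hours) {
    idx <- which(meta$level %in% c("L1", "L2", "L3") & meta$hours == h)
    if (length(idx) == 0) stop("dataset lacks L1-L3 rows at ", h, " h")
    blocks[[paste0("h", h)]] <- .half_stratified(idx, y[idx], seed * 37L + h)
  }
  held <- sort(unique(unlist(blocks)))
  blocks$global <- held
  train_idx <- setdiff(all_idx, held)
  reports <- list(); rows <- list()
  models <- list()
  for (fam in families) {
    spec <- .spec_for(fam, seed)
    tr <- train_classifier(spec, X[train_idx, , drop = FALSE], y[train_idx],
                           n_folds = n_folds, seed = seed)
    models[[fam]] <- tr
  }
  for (bname in names(blocks)) {
    test_idx <- blocks[[bname]]
    reports[[bname]] <- list()
    for (fam in families) {
      tr <- models[[fam]]
      rep <- evaluate_classifier(tr$model, X[test_idx, , drop = FALSE],
                                 y[test_idx], cv_accuracy = tr$cv_accuracy)
      reports[[bname]][[fam]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        block = bname, family = fam, cv_accuracy = rep$cv_accuracy,
        test_accuracy = rep$test_accuracy, auc = rep$auc, n_test = rep$n_test)
    }
  }
  class_order <- if (is.null(grouping)) severity_class_order(sort(unique(y)))
                 else names(grouping)
  structure(list(reports = reports, summary = do.call(rbind, rows),
                 class_order = class_order, holdouts = blocks, seed = seed),
            class = "experiment_result")
}

#' Run the full study across several seeds
#'
#' For each seed, assembles a bookkeeping-faithful dataset (for the
#' detection experiment) and a factorial dataset (for the temporal and
#' quantitative experiments), runs the three experiments, and aggregates
#' test accuracies over seeds. The seed drives cube generation, holdout
#' splits, fold assignment and ensemble subspace draws.
#'
#' @param seeds Integer vector of seeds (one full replicate per seed).
#' @param config A [simulation_config()].
#' @param families Classifier families to run.
#' @param sound_total Sound ROIs per dataset.
#' @return List with `detection`, `temporal`, `quantitative` (data.frames
#'   of per-seed summaries) and `means` (test accuracy averaged over
#'   seeds per experiment cell).
#' @export
run_study <- function(seeds = 1:5, config = simulation_config(),
                      families = DEFAULT_FAMILIES, sound_total = 287L) {
  det_rows <- list(); tem_rows <- list(); qua_rows <- list()
  for (s in seeds) {
    ds <- assemble_dataset(experiment_manifest("table1", seed = s),
                           config, sound_total = sound_total)
    dsf <- assemble_dataset(experiment_manifest("factorial", seed = s + 5000L),
                            config, sound_total = sound_total)
    d <- run_detection(ds, families = families, seed = s)
    t <- run_temporal(dsf, families = families, seed = s)
    q <- run_quantitative(dsf, families = families, seed = s)
    d$summary$seed <- s; t$summary$seed <- s; q$summary$seed <- s
    q$summary$adjacency <- NA_real_
    for (fam in families) {
      conf <- q$reports$global[[fam]]$confusion
      q$summary$adjacency[q$summary$block == "global" &
                            q$summary$family == fam] <-
        confusion_adjacency(conf, q$class_order)
    }
    det_rows[[length(det_rows) + 1]] <- d$summary
    tem_rows[[length(tem_rows) + 1]] <- t$summary
    qua_rows[[length(qua_rows) + 1]] <- q$summary
  }
  detection <- do.call(rbind, det_rows)
  temporal <- do.call(rbind, tem_rows)
  quantitative <- do.call(rbind, qua_rows)
  agg <- function(df, keys) stats::aggregate(
    df["test_accuracy"], df[keys], FUN = mean)
  list(detection = detection, temporal = temporal,
       quantitative = quantitative,
       means = list(detection = agg(detection, c("target", "family")),
                    temporal = agg(temporal, c("hours", "family")),
                    quantitative = agg(quantitative, c("block", "family"))))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$summary, digits = 4)
  invisible(x)
}
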