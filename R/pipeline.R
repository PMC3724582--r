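# Experiment orchestration: normalization, stratified shuffled splits,
# training/evaluation per feature and per combination, report assembly.

#' Min-max normalize train/test feature sets
#'
#' Each column is mapped by `(v - min_train) / (max_train - min_train)`
#' using training-set extrema, so training values land in `[0, 1]` — the
#' scale on which the VEBF initial radius of 0.5 is meaningful. Test values
#' may fall outside `[0, 1]` (no clipping). A constant training column maps
#' to 0 everywhere, with a warning.
#'
#' @param train,test `emg_feature_set`s with matching columns.
#' @return List with normalized `train`, `test`, and `scaler`
#'   (per-column min/range).
#' @export
minmax_normalize <- function(train, test) {
  if (nrow(train$matrix) == 0) stop("empty training set")
  if (!identical(colnames(train$matrix), colnames(test$matrix))) {
    stop("train/test columns do not match")
  }
  mins <- apply(train$matrix, 2, min)
  maxs <- apply(train$matrix, 2, max)
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning("constant training column(s) mapped to 0: ",
            paste(colnames(train$matrix)[rng == 0], collapse = ", "))
  }
  scale_mat <- function(m) {
    out <- sweep(m, 2, mins, "-")
    out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
    out[, rng == 0] <- 0
    out
  }
  train$matrix <- scale_mat(train$matrix)
  test$matrix <- scale_mat(test$matrix)
  list(train = train, test = test,
       scaler = list(min = mins, range = rng))
}

# Largest-remainder proportional allocation of n_take over class counts.
allocate_per_class <- function(class_counts, n_take) {
  exact <- n_take * class_counts / sum(class_counts)
  base <- floor(exact)
  rem <- n_take - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base), names(class_counts))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Seeded (stratified) train/test split
#'
#' Rows are shuffled with the given seed; under stratification each class
#' contributes train/test rows proportional to its size (within one row).
#'
#' @param features An `emg_feature_set`.
#' @param n_train,n_test Row counts for the two partitions.
#' @param stratified Preserve class proportions (default `TRUE`).
#' @param seed Integer seed for the shuffle.
#' @return List of `emg_feature_set`s `train` and `test` (disjoint).
#' @export
stratified_split <- function(features, n_train = 300, n_test = 90,
                             stratified = TRUE, seed = 1L) {
  n <- nrow(features$matrix)
  if (n_train + n_test > n) stop("n_train + n_test exceeds available rows")
  old <- .Random.seed_save()
  set.seed(seed)
  perm <- sample.int(n)
  .Random.seed_restore(old)
  if (stratified) {
    labels <- features$row_labels
    classes <- sort(unique(labels))
    if (n_train < length(classes)) {
      stop("stratified split needs n_train >= number of classes")
    }
    counts <- vapply(classes, function(cl) sum(labels == cl), 1L)
    names(counts) <- classes
    a <- allocate_per_class(counts, n_train)
    b <- allocate_per_class(counts, n_test)
    tr_idx <- integer(0); te_idx <- integer(0)
    for (cl in classes) {
      rows <- perm[labels[perm] == cl]
      if (a[cl] + b[cl] > length(rows)) {
        stop("class ", cl, " has too few rows for the requested split")
      }
      tr_idx <- c(tr_idx, rows[seq_len(a[cl])])
      te_idx <- c(te_idx, rows[a[cl] + seq_len(b[cl])])
    }
  } else {
    tr_idx <- perm[seq_len(n_train)]
    te_idx <- perm[n_train + seq_len(n_test)]
  }
  subset_fs <- function(idx) {
    out <- features
    out$matrix <- features$matrix[idx, , drop = FALSE]
    out$row_labels <- features$row_labels[idx]
    out$segment_index <- features$segment_index[idx]
    out
  }
  list(train = subset_fs(tr_idx), test = subset_fs(te_idx))
}

# Row-stochastic confusion matrix in %, rows = true classes present.
confusion_matrix <- function(truth, predicted, classes) {
  truth_classes <- sort(unique(truth))
  cm <- matrix(0, length(truth_classes), length(classes),
               dimnames = list(truth_classes, classes))
  for (g in truth_classes) {
    preds <- predicted[truth == g]
    tab <- table(factor(preds, levels = classes))
    cm[g, ] <- 100 * as.numeric(tab) / length(preds)
  }
  cm
}

#' Evaluate a trained network on a labelled feature set
#'
#' @param network A `vebf_network` whose classes cover the test labels.
#' @param test An `emg_feature_set`.
#' @return List with `accuracy` (%), `confusion` (row-% matrix),
#'   `per_gesture_accuracy` (confusion diagonal).
#' @export
evaluate_network <- function(network, test) {
  if (nrow(test$matrix) == 0) stop("empty test set")
  if (!all(test$row_labels %in% network$classes)) {
    stop("network classes do not cover the test labels")
  }
  pred <- predict(network, test$matrix)
  acc <- 100 * mean(pred == test$row_labels)
  cm <- confusion_matrix(test$row_labels, pred, network$classes)
  diag_acc <- stats::setNames(cm[cbind(rownames(cm), rownames(cm))],
                              rownames(cm))
  list(accuracy = acc, confusion = cm, per_gesture_accuracy = diag_acc)
}

#' Train on a split and produce a full evaluation report
#'
#' @param split List with `train` and `test` `emg_feature_set`s (already
#'   normalized).
#' @param config A [vebf_config()].
#' @param feature_label Report label.
#' @return An `emg_eval_report`: train/test accuracy (%), mean absolute
#'   error (`100 - test_accuracy`), per-gesture accuracy, row-% confusion
#'   matrix (test), training time in seconds (informational only).
#' @export
train_and_evaluate <- function(split, config = vebf_config(),
                               feature_label = split$train$feature) {
  t0 <- proc.time()[["elapsed"]]
  net <- vebf_train(split$train$matrix, split$train$row_labels, config)
  elapsed <- proc.time()[["elapsed"]] - t0
  train_ev <- evaluate_network(net, split$train)
  test_ev <- evaluate_network(net, split$test)
  structure(list(feature_label = feature_label,
                 train_accuracy = train_ev$accuracy,
                 test_accuracy = test_ev$accuracy,
                 mean_absolute_error = 100 - test_ev$accuracy,
                 per_gesture_accuracy = test_ev$per_gesture_accuracy,
                 confusion = test_ev$confusion,
                 n_neurons = length(net$neurons),
                 training_time = elapsed,
                 network = net),
            class = "emg_eval_report")
}

#' @export
print.emg_eval_report <- function(x, ...) {
  cat(sprintf("<emg_eval_report> %s: train %.1f%%, test %.1f%% (MAE %.1f%%), %d neurons, %.3fs\n",
              x$feature_label, x$train_accuracy, x$test_accuracy,
              x$mean_absolute_error, x$n_neurons, x$training_time))
  invisible(x)
}

#' Average evaluation reports across subjects
#'
#' @param reports List of `emg_eval_report`s for the same feature.
#' @return List with mean/sd train and test accuracy, mean absolute error
#'   (`100 - mean test accuracy`), averaged per-gesture accuracies and
#'   averaged confusion matrix, and mean training time.
#' @export
average_reports <- function(reports) {
  tr <- vapply(reports, function(r) r$train_accuracy, 1)
  te <- vapply(reports, function(r) r$test_accuracy, 1)
  cms <- lapply(reports, function(r) r$confusion)
  cm <- Reduce(`+`, cms) / length(cms)
  list(feature_label = reports[[1]]$feature_label,
       n_subjects = length(reports),
       train_mean = mean(tr), train_sd = stats::sd(tr),
       test_mean = mean(te), test_sd = stats::sd(te),
       mean_absolute_error = 100 - mean(te),
       per_gesture_accuracy = stats::setNames(
         cm[cbind(rownames(cm), rownames(cm))], rownames(cm)),
       confusion = cm,
       training_time_mean = mean(vapply(reports,
                                        function(r) r$training_time, 1)))
}

#' Experiment configuration
#'
#' Defaults reproduce the study geometry: 10 subjects, 10 gestures x 5 x 2-s
#' trials x 3 channels at 1000 Hz, 30-450 Hz band, 256-ms windows, 300/90
#' stratified split, spherical initial width 0.5.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param features Feature names to evaluate.
#' @param criteria Ranking criteria for combinations (`"MRMR"`, `"RA"`).
#' @param k_range Combination sizes to build (clipped to the feature count).
#' @param run_combinations Evaluate multi-feature combinations.
#' @param bins MI histogram bin count.
#' @param band Band-pass edges in Hz.
#' @param window_ms Window length in ms.
#' @param n_train,n_test,stratified Split specification.
#' @param feature_cfg A [feature_config()].
#' @param vebf A [vebf_config()].
#' @param sim An [emg_sim_config()]; its seed is re-derived per subject from
#'   `seed`.
#' @param seed Master seed for dataset generation and splits.
#' @return List of class `emg_experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10, features = emg_features(),
                              criteria = c("MRMR", "RA"), k_range = 2:10,
                              run_combinations = TRUE, bins = 10,
                              band = c(30, 450), window_ms = 256,
                              n_train = 300, n_test = 90, stratified = TRUE,
                              feature_cfg = feature_config(),
                              vebf = vebf_config(),
                              sim = emg_sim_config(), seed = 1L) {
  features <- vapply(features, match_feature, "")
  criteria <- match.arg(criteria, several.ok = TRUE)
  structure(list(n_subjects = n_subjects, features = unname(features),
                 criteria = criteria, k_range = k_range,
                 run_combinations = isTRUE(run_combinations), bins = bins,
                 band = band, window_ms = window_ms, n_train = n_train,
                 n_test = n_test, stratified = stratified,
                 feature_cfg = feature_cfg, vebf = vebf, sim = sim,
                 seed = as.integer(seed)),
            class = "emg_experiment_config")
}

# Split + normalize + train + evaluate one feature set.
run_one <- function(fset, cfg, split_seed) {
  sp <- stratified_split(fset, cfg$n_train, cfg$n_test, cfg$stratified,
                         split_seed)
  norm <- minmax_normalize(sp$train, sp$test)
  train_and_evaluate(list(train = norm$train, test = norm$test), cfg$vebf,
                     feature_label = fset$feature)
}

#' Run the full recognition experiment
#'
#' For every subject a seeded synthetic dataset is generated, band-pass
#' filtered and segmented; every configured single feature is split,
#' normalized, trained and evaluated. Features are then ranked by
#' recognition accuracy (RA) and by greedy mRMR (raw MI relevance /
#' redundancy), and the k-feature combinations prescribed by each ranking
#' are evaluated the same way. Everything is a deterministic function of the
#' configuration (timing fields aside).
#'
#' @param cfg An [experiment_config()].
#' @param profiles Gesture profiles (default [default_gesture_profiles()]).
#' @return An `emg_report_bundle`: per-subject and averaged single-feature
#'   reports, rankings, the normalized MI matrix and class-relevance vector,
#'   combination reports per criterion, and the configuration.
#' @export
run_experiment <- function(cfg = experiment_config(),
                           profiles = default_gesture_profiles()) {
  stopifnot(inherits(cfg, "emg_experiment_config"))
  subjects <- paste0("S", seq_len(cfg$n_subjects))
  subject_sets <- list()
  for (s in subjects) {
    sim <- cfg$sim
    sim$seed <- derive_seed(cfg$seed, "dataset", s)
    ds <- generate_dataset(profiles, sim, s)
    ds <- preprocess_dataset(ds, cfg$band[1], cfg$band[2])
    subject_sets[[s]] <- build_all_feature_sets(ds, cfg$features,
                                                cfg$feature_cfg,
                                                cfg$window_ms)
  }
  singles <- list()
  for (f in cfg$features) {
    reports <- lapply(subjects, function(s) {
      run_one(subject_sets[[s]][[f]], cfg,
              derive_seed(cfg$seed, "split", s, f))
    })
    names(reports) <- subjects
    singles[[f]] <- list(per_subject = reports,
                         averaged = average_reports(reports))
  }
  acc <- vapply(singles, function(x) x$averaged$test_mean, 1)
  rankings <- list(RA = ra_rank(acc))
  mi_norm <- NULL; relevance <- NULL
  if (length(cfg$features) >= 2) {
    mi_raw <- mi_matrix(subject_sets, bins = cfg$bins, normalized = FALSE)
    mi_norm <- mi_matrix(subject_sets, bins = cfg$bins, normalized = TRUE)
    relevance <- class_relevance(subject_sets, bins = cfg$bins)
    rankings$MRMR <- mrmr_rank(relevance, mi_raw)
  }
  combos <- list()
  if (cfg$run_combinations && length(cfg$features) >= 2) {
    ks <- cfg$k_range[cfg$k_range <= length(cfg$features) & cfg$k_range >= 2]
    for (crit in cfg$criteria) {
      if (is.null(rankings[[crit]])) next
      ord <- rankings[[crit]]$order
      combos[[crit]] <- list()
      for (k in ks) {
        reports <- lapply(subjects, function(s) {
          cset <- combine_feature_sets(subject_sets[[s]], ord, k)
          run_one(cset, cfg, derive_seed(cfg$seed, "split", s, crit, k))
        })
        names(reports) <- subjects
        combos[[crit]][[paste0("C", k)]] <-
          list(per_subject = reports, averaged = average_reports(reports))
      }
    }
  }
  structure(list(singles = singles, rankings = rankings,
                 mi = list(normalized = mi_norm, relevance = relevance),
                 combinations = combos, config = cfg),
            class = "emg_report_bundle")
}

#' @export
print.emg_report_bundle <- function(x, ...) {
  cat(sprintf("<emg_report_bundle> %d subjects, %d single features, %d combination set(s)\n",
              x$config$n_subjects, length(x$singles),
              sum(lengths(x$combinations))))
  for (f in names(x$singles)) {
    a <- x$singles[[f]]$averaged
    cat(sprintf("  %-5s test %5.1f +- %4.1f %%  (MAE %5.1f %%)\n",
                f, a$test_mean, a$test_sd, a$mean_absolute_error))
  }
  invisible(x)
}

# Strip hardware-dependent timing fields for deterministic serialization.
strip_timing <- function(x) {
  if (is.list(x)) {
    x$training_time <- NULL
    x$training_time_mean <- NULL
    x$network <- NULL
    lapply(x, strip_timing)
  } else {
    x
  }
}

#' Serialize a report bundle to JSON
#'
#' Timing fields (and trained network objects) are excluded, so identical
#' configurations produce byte-identical JSON.
#'
#' @param bundle An `emg_report_bundle`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(bundle, path = NULL) {
  payload <- strip_timing(unclass(bundle))
  payload$config <- lapply(unclass(payload$config), function(v) {
    if (is.list(v)) unclass(v) else v
  })
  if (!is.null(payload$mi$normalized)) {
    payload$mi$normalized <- unclass(payload$mi$normalized)
  }
  payload$rankings <- lapply(payload$rankings, unclass)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Write confusion matrices of averaged reports as CSV
#'
#' @param bundle An `emg_report_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_confusions <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (f in names(bundle$singles)) {
    p <- file.path(dir, paste0("confusion_", f, ".csv"))
    utils::write.csv(round(bundle$singles[[f]]$averaged$confusion, 2), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
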