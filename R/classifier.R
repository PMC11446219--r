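#' Assemble the genotype-classification feature table
#'
#' One row per animal: the total number of occurrences of each catalog
#' behavior during the dark and the light phase separately, plus the total
#' distance traveled over housing, labeled with the animal's genotype.
#' With the default 18-behavior catalog this gives 37 features. Animals
#' without any RFID detections cannot contribute a distance and are
#' excluded with a warning.
#'
#' @param datasets A list of [group_dataset()] objects.
#' @param grid A [reader_grid()] for the distance computation.
#' @param catalog Behavior catalog.
#' @return A tibble with id columns `animal`, `group`, `genotype` followed
#'   by feature columns `<behavior>_dark`, `<behavior>_light`,
#'   `distance_m`; attribute `features` names the feature columns in
#'   their deterministic order.
#' @export
assemble_features <- function(datasets, grid = reader_grid(),
                              catalog = default_catalog()) {
  catalog <- behavior_catalog(catalog)
  rows <- list()
  for (ds in datasets) {
    totals <- behavior_totals(ds$events, ds$schedule, catalog,
                              animals = ds$animals)
    totals$col <- paste(totals$behavior, totals$phase, sep = "_")
    wide <- tidyr::pivot_wider(
      totals[, c("animal", "col", "n")],
      names_from = "col", values_from = "n"
    )
    dist <- distance_per_hour(ds$rfid, grid, ds$schedule)
    dist_tot <- dplyr::summarise(
      dplyr::group_by(dist, .data$animal),
      distance_m = sum(.data$distance_m), .groups = "drop"
    )
    missing <- setdiff(ds$animals, unique(ds$rfid$animal))
    if (length(missing) > 0) {
      warning("no RFID data for ", paste(missing, collapse = ", "),
              " in group ", ds$group_id, "; excluded from features")
      wide <- wide[!(wide$animal %in% missing), ]
    }
    w <- dplyr::inner_join(wide, dist_tot, by = "animal")
    w$group <- ds$group_id
    w$genotype <- ds$genotype
    rows[[length(rows) + 1]] <- w
  }
  out <- dplyr::bind_rows(rows)
  feature_cols <- c(
    as.vector(t(outer(catalog$behavior, c("dark", "light"), paste, sep = "_"))),
    "distance_m"
  )
  out <- out[, c("animal", "group", "genotype", feature_cols)]
  structure(out, features = feature_cols)
}

#' Leave-one-out random-forest genotype classification
#'
#' Repeatedly evaluates how well genotype can be predicted from the
#' feature table. In each of `runs` repetitions, every animal is held out
#' once, a random forest is trained on the remaining animals, and the
#' held-out animal is labeled; run accuracy is the fraction of correctly
#' labeled animals. Gini importances (mean decrease in node impurity,
#' averaged over the forest's trees, as reported by the randomForest
#' implementation) are averaged over folds within a run; features whose
#' mean importance over runs reaches `gini_threshold` form the key-feature
#' set — the behaviors that carry the genotype signal.
#'
#' Forest hyperparameters are the implementation defaults unless
#' overridden; they are echoed into the report for reproducibility. A
#' fixed seed makes the whole report reproducible.
#'
#' @param features A feature table from [assemble_features()] (or any
#'   tibble with a binary `genotype` column and numeric features).
#' @param runs Number of repetitions (default 100).
#' @param seed Integer seed.
#' @param ntree,mtry Forest hyperparameters (`NULL` = implementation
#'   default).
#' @param gini_threshold Mean-importance cutoff for the key-feature set
#'   (default 1).
#' @return An object of class `rf_report`: list with `accuracy` (per run),
#'   `accuracy_mean`, `accuracy_sd`, `gini` (runs x features matrix),
#'   `gini_mean`, `gini_sd`, `key_features`, and `config` (hyperparameters
#'   and the importance-scale note).
#' @export
loocv_rf <- function(features, runs = 100, seed = 1, ntree = 500,
                     mtry = NULL, gini_threshold = 1) {
  feat_cols <- attr(features, "features") %||%
    setdiff(names(features)[vapply(features, is.numeric, logical(1))],
            "genotype")
  x <- as.data.frame(features[, feat_cols])
  y <- factor(features$genotype)
  if (nlevels(y) < 2) stop("feature table contains a single class")
  if (min(table(y)) < 2) stop("need at least 2 animals per class")
  n <- nrow(x)
  mtry <- mtry %||% floor(sqrt(ncol(x)))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  accuracy <- numeric(runs)
  gini <- matrix(0, runs, length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (r in seq_len(runs)) {
    set.seed(run_seeds[r])
    correct <- 0L
    imp <- numeric(length(feat_cols))
    for (i in seq_len(n)) {
      fit <- randomForest::randomForest(
        x = x[-i, , drop = FALSE], y = y[-i],
        ntree = ntree, mtry = mtry
      )
      pred <- stats::predict(fit, x[i, , drop = FALSE])
      correct <- correct + as.integer(pred == y[i])
      imp <- imp + fit$importance[feat_cols, "MeanDecreaseGini"]
    }
    accuracy[r] <- correct / n
    gini[r, ] <- imp / n
  }
  gini_mean <- colMeans(gini)
  structure(
    list(
      accuracy = accuracy,
      accuracy_mean = mean(accuracy),
      accuracy_sd = stats::sd(accuracy),
      gini = gini,
      gini_mean = gini_mean,
      gini_sd = apply(gini, 2, stats::sd),
      key_features = feat_cols[gini_mean >= gini_threshold],
      config = list(
        runs = runs, seed = seed, ntree = ntree, mtry = mtry,
        gini_threshold = gini_threshold,
        importance_scale = "MeanDecreaseGini (impurity decrease averaged over trees), averaged over LOOCV folds"
      )
    ),
    class = "rf_report"
  )
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("LOOCV accuracy over %d runs: %.3f (SD %.3f)\n",
              length(x$accuracy), x$accuracy_mean, x$accuracy_sd))
  top <- sort(x$gini_mean, decreasing = TRUE)[seq_len(min(5, length(x$gini_mean)))]
  cat("Top features by mean Gini importance:\n")
  for (nm in names(top)) cat(sprintf("  %-28s %.3f\n", nm, top[nm]))
  cat("Key features (mean Gini >= ", x$config$gini_threshold, "): ",
      paste(x$key_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}
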