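#' Run the full VBS analysis pipeline
#'
#' Executes every stage of the home-cage analysis on a list of group
#' datasets and writes a report bundle: validation -> phase assignment ->
#' activity -> place preference -> behavior totals -> aggression profiles
#' -> social networks -> Glicko dominance -> genotype classifier. A stage
#' failure stops only its downstream dependents; the manifest records the
#' status of every stage and a digest of every file written.
#'
#' @param datasets A list of [group_dataset()] objects (e.g. from
#'   [simulate_experiment()] or assembled from CSV inputs).
#' @param out_dir Output directory for the report bundle.
#' @param grid A [reader_grid()].
#' @param plan A [sampling_plan()].
#' @param catalog Behavior catalog.
#' @param network_behaviors Behaviors to build daily networks for.
#' @param glicko_behavior Agonistic behavior feeding the rating engine.
#' @param classifier_runs Repetitions for the random-forest stage.
#' @param seed Seed for the classifier stage.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(datasets, out_dir, grid = reader_grid(),
                         plan = sampling_plan(),
                         catalog = default_catalog(),
                         network_behaviors = c("struggle_at_feeder",
                                               "allogrooming"),
                         glicko_behavior = "struggle_at_feeder",
                         classifier_runs = 100, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  outputs <- character(0)
  note_output <- function(path) outputs <<- c(outputs, path)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    note_output(path)
    path
  }
  stage <- function(name, deps, expr) {
    failed_deps <- deps[!vapply(deps, function(d) {
      identical(status[[d]], "ok")
    }, logical(1))]
    if (length(failed_deps) > 0) {
      status[[name]] <<- paste0("skipped (needs ",
                                paste(failed_deps, collapse = ", "), ")")
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste0("error: ", conditionMessage(res))
      NULL
    } else {
      status[[name]] <<- "ok"
      res
    }
  }

  validated <- stage("validate", character(0), {
    for (ds in datasets) {
      v <- validate_events(ds$events, catalog)
      if (!v$valid) {
        stop("group ", ds$group_id, ": ", nrow(v$report),
             " invalid event(s)")
      }
    }
    TRUE
  })

  stage("activity", "validate", {
    act <- dplyr::bind_rows(lapply(datasets, function(ds) {
      a <- distance_per_hour(ds$rfid, grid, ds$schedule)
      a$group <- ds$group_id
      a$genotype <- ds$genotype
      a
    }))
    emit(act, "activity_hourly.csv")
  })

  stage("preference", "validate", {
    for (ph in c("dark", "light")) {
      for (geno in unique(vapply(datasets, `[[`, "", "genotype"))) {
        sel <- datasets[vapply(datasets, `[[`, "", "genotype") == geno]
        rfid <- dplyr::bind_rows(lapply(sel, `[[`, "rfid"))
        map <- place_preference(rfid, grid, sel[[1]]$schedule, phase = ph)
        emit(tibble::as_tibble(map), sprintf("preference_%s_%s.csv", geno, ph))
      }
    }
    TRUE
  })

  totals_tbl <- stage("totals", "validate", {
    tt <- dplyr::bind_rows(lapply(datasets, function(ds) {
      t <- behavior_totals(ds$events, ds$schedule, catalog,
                           animals = ds$animals)
      t$group <- ds$group_id
      t$genotype <- ds$genotype
      t
    }))
    emit(tt, "behavior_totals.csv")
    tt
  })

  stage("aggression", "validate", {
    prof <- dplyr::bind_rows(lapply(datasets, function(ds) {
      p <- aggression_profile(ds$events, ds$schedule, plan,
                              animals = ds$animals)
      p$group <- ds$group_id
      p$genotype <- ds$genotype
      p
    }))
    emit(prof, "aggression_profiles.csv")
  })

  stage("network", "validate", {
    for (beh in network_behaviors) {
      ss <- strength_series(datasets, beh, catalog = catalog)
      emit(ss$series, sprintf("strength_%s.csv", beh))
      if (!is.null(ss$tests)) emit(ss$tests, sprintf("strength_tests_%s.csv", beh))
    }
    TRUE
  })

  glicko_res <- stage("glicko", "validate", {
    rows <- list()
    for (ds in datasets) {
      ev <- ds$events[ds$events$behavior == glicko_behavior, ]
      ev <- ev[!is.na(ev$target), ]
      ev <- dplyr::arrange(ev, .data$start)
      if (nrow(ev) < 2) next
      hist <- rate_history(
        tibble::tibble(winner = ev$actor, loser = ev$target),
        ds$animals
      )
      summ <- dominance_summary(hist)
      rows[[ds$group_id]] <- list(
        group = ds$group_id, genotype = ds$genotype,
        dominant = summ$dominant,
        total_interactions = summ$total_interactions,
        emergence_engaged = summ$emergence_engaged,
        emergence_all = summ$emergence_all,
        normalized_emergence = summ$normalized_emergence,
        despotism_ratio = summ$despotism$ratio,
        despotic = summ$despotism$despotic,
        final_ratings = as.list(stats::setNames(hist$final$rating,
                                                hist$final$animal))
      )
    }
    path <- file.path(out_dir, "dominance.json")
    jsonlite::write_json(unname(rows), path, auto_unbox = TRUE, digits = NA)
    note_output(path)
    rows
  })

  stage("glicko_summary", "glicko", {
    by_geno <- split(glicko_res, vapply(glicko_res, `[[`, "", "genotype"))
    summ <- dplyr::bind_rows(lapply(names(by_geno), function(g) {
      cnt <- vapply(by_geno[[g]], `[[`, numeric(1), "emergence_engaged")
      s <- emergence_summary(cnt)
      s$genotype <- g
      s
    }))
    emit(summ, "emergence_summary.csv")
  })

  stage("classifier", c("validate", "totals"), {
    feats <- assemble_features(datasets, grid, catalog)
    emit(feats, "features.csv")
    rep <- loocv_rf(feats, runs = classifier_runs, seed = seed)
    path <- file.path(out_dir, "classifier_report.json")
    jsonlite::write_json(
      list(
        accuracy_mean = rep$accuracy_mean, accuracy_sd = rep$accuracy_sd,
        gini_mean = as.list(rep$gini_mean),
        gini_sd = as.list(rep$gini_sd),
        key_features = rep$key_features, config = rep$config
      ),
      path, auto_unbox = TRUE, digits = NA
    )
    note_output(path)
    TRUE
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    n_groups = length(datasets),
    stages = status,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
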