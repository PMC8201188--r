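# Orchestration of the full study design: 12 slots (season x day type x
# hour), per-slot model fitting, cross-validation, mapping, and the
# between-hour comparison tests, behind one configuration object.

#' Pipeline run configuration
#'
#' Every modelling threshold is surfaced as a named key with its standard
#' default: Spearman screening floor 0, stepwise p_enter/p_remove 0.05,
#' VIF ceiling 5, 10 CV folds, 3 km mapping grid.
#'
#' @param city_config a [city_config()] (synthetic mode).
#' @param truth a [synthetic_truth()]; defaults to [default_truth()].
#' @param spec a [buffer_spec()].
#' @param slots character vector of slot ids to run (default all 12).
#' @param missing_rate fraction of stations marked missing per slot.
#' @param min_abs_rho screening floor on |Spearman rho|.
#' @param p_enter,p_remove,vif_max stepwise thresholds.
#' @param cv_folds number of cross-validation folds.
#' @param cv_reselect re-run selection within each CV fold.
#' @param variogram_model kriging family for meteorology and surfaces.
#' @param met_aggregation "slot" (hour-specific meteorology, the
#'   self-consistent choice for hourly models) or "annual" (one pooled
#'   meteorological field shared by all slots).
#' @param grid_spacing_m regression-mapping grid spacing.
#' @param fine_resolution_m kriged-surface cell size.
#' @param map_surfaces logical: krige the mapped surface per slot.
#' @param output_dir optional directory for artifacts (created on demand).
#' @param seed global run seed; all stage seeds are derived substreams.
#' @return list of class `run_config`.
#' @export
run_config <- function(city_config = pmlur::city_config(),
                       truth = default_truth(),
                       spec = buffer_spec(),
                       slots = slot_table()$slot_id,
                       missing_rate = 0.05,
                       min_abs_rho = 0,
                       p_enter = 0.05, p_remove = 0.05, vif_max = 5,
                       cv_folds = 10L, cv_reselect = FALSE,
                       variogram_model = "spherical",
                       met_aggregation = c("slot", "annual"),
                       grid_spacing_m = 3000,
                       fine_resolution_m = 2000,
                       map_surfaces = TRUE,
                       output_dir = NULL,
                       seed = 1L) {
  met_aggregation <- match.arg(met_aggregation)
  bad <- setdiff(slots, slot_table()$slot_id)
  if (length(bad)) stop("unknown slots: ", paste(bad, collapse = ", "))
  if (length(slots) == 0L) stop("slot list must be non-empty")
  structure(list(city_config = city_config, truth = truth, spec = spec,
                 slots = slots, missing_rate = missing_rate,
                 min_abs_rho = min_abs_rho, p_enter = p_enter,
                 p_remove = p_remove, vif_max = vif_max,
                 cv_folds = as.integer(cv_folds), cv_reselect = cv_reselect,
                 variogram_model = variogram_model,
                 met_aggregation = met_aggregation,
                 grid_spacing_m = grid_spacing_m,
                 fine_resolution_m = fine_resolution_m,
                 map_surfaces = map_surfaces,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(log, slot_id, stage, t0, ...) {
  extra <- list(...)
  detail <- if (length(extra)) {
    paste(names(extra), unlist(extra), sep = "=", collapse = " ")
  } else ""
  entry <- data.frame(slot = slot_id, stage = stage,
                      seconds = round(as.numeric(Sys.time()) - t0, 3),
                      detail = detail, stringsAsFactors = FALSE)
  rbind(log, entry)
}

# meteorology table for a slot honouring the met_aggregation setting:
# "annual" pools the four season x hour corner cases into one mean field
slot_met <- function(city, slot, config) {
  if (config$met_aggregation == "slot") return(generate_meteorology(city, slot))
  tab <- slot_table()
  mets <- lapply(tab$slot_id, function(id) generate_meteorology(city, id))
  out <- mets[[1]]
  for (v in MET_VARIABLES) {
    out[[v]] <- rowMeans(vapply(mets, function(m) m[[v]], numeric(nrow(out))))
  }
  out
}

#' Fit, validate and map one slot
#'
#' Stages: observations (drop missing-response stations), meteorology
#' kriging, predictor matrix, Spearman screening, stepwise fit, k-fold CV,
#' regression mapping. Any stage failure marks the slot failed with the
#' stage name; other slots are unaffected.
#'
#' @param config a [run_config()].
#' @param slot slot or slot id.
#' @param city optional pre-generated `synthetic_city` (one city is shared
#'   across slots in [run_all()]).
#' @param geo_predictors optional pre-computed station predictor matrix of
#'   the non-meteorological columns (shared across slots).
#' @return list: slot_id, ok, stage (on failure), model, screen, cv,
#'   observations, surface, station_scatter, relative_error_pct, log.
#' @export
run_slot <- function(config, slot, city = NULL, geo_predictors = NULL) {
  slot <- as_slot(slot)
  log <- NULL
  result <- list(slot_id = slot$slot_id, ok = FALSE, stage = NA_character_)
  stage <- "city"
  out <- tryCatch({
    t0 <- as.numeric(Sys.time())
    if (is.null(city)) city <- generate_city(config$city_config)
    log <- stage_log(log, slot$slot_id, "city", t0)

    stage <- "observations"
    t0 <- as.numeric(Sys.time())
    obs <- generate_observations(city, config$truth, slot,
                                 missing_rate = config$missing_rate)
    keep <- !is.na(obs$pm25)
    if (!any(keep)) stop("all responses missing")
    log <- stage_log(log, slot$slot_id, "observations", t0, n_obs = sum(keep))

    stage <- "meteorology"
    t0 <- as.numeric(Sys.time())
    met <- slot_met(city, slot, config)
    met_at_stations <- krige_met(met, city$stations,
                                 model = "exponential")
    log <- stage_log(log, slot$slot_id, "meteorology", t0)

    stage <- "predictors"
    t0 <- as.numeric(Sys.time())
    if (is.null(geo_predictors)) {
      geo_predictors <- build_predictor_matrix(city$layers, city$stations,
                                               config$spec)
    }
    X <- cbind(geo_predictors, met_at_stations)
    class(X) <- "data.frame"
    Xk <- X[keep, , drop = FALSE]
    yk <- obs$pm25[keep]
    log <- stage_log(log, slot$slot_id, "predictors", t0,
                     n_candidates = ncol(X))

    stage <- "screening"
    t0 <- as.numeric(Sys.time())
    screen <- screen_predictors(Xk, yk, min_abs_rho = config$min_abs_rho)
    log <- stage_log(log, slot$slot_id, "screening", t0,
                     n_screened = length(screen$retained))

    stage <- "stepwise"
    t0 <- as.numeric(Sys.time())
    model <- stepwise_regress(Xk[screen$retained], yk,
                              p_enter = config$p_enter,
                              p_remove = config$p_remove,
                              vif_max = config$vif_max)
    log <- stage_log(log, slot$slot_id, "stepwise", t0,
                     n_selected = nrow(model$terms))

    stage <- "cv"
    t0 <- as.numeric(Sys.time())
    cv_seed <- substream_seed(config$seed, paste0("cv/", slot$slot_id))
    cv <- if (config$cv_reselect) {
      kfold_cv(Xk[screen$retained], yk, k = config$cv_folds, seed = cv_seed,
               reselect = TRUE, p_enter = config$p_enter,
               p_remove = config$p_remove, vif_max = config$vif_max)
    } else {
      kfold_cv(Xk[model$terms$name], yk, k = config$cv_folds, seed = cv_seed)
    }
    log <- stage_log(log, slot$slot_id, "cv", t0)

    stage <- "mapping"
    t0 <- as.numeric(Sys.time())
    grid <- make_grid(city$layers$extent, config$grid_spacing_m)
    grid_pred <- predict_surface(model, city$layers, grid, met = met)
    surface <- if (config$map_surfaces) {
      krige_surface(grid_pred, city$layers$extent,
                    fine_resolution_m = config$fine_resolution_m,
                    model = config$variogram_model)
    } else NULL
    station_pred <- predict(model, Xk)
    rel_err <- station_relative_error(station_pred, yk)
    log <- stage_log(log, slot$slot_id, "mapping", t0,
                     n_clamped = attr(grid_pred, "n_clamped"))

    list(slot_id = slot$slot_id, ok = TRUE, stage = NA_character_,
         model = model, screen = screen, cv = cv, observations = obs,
         grid_predictions = grid_pred, surface = surface,
         station_scatter = data.frame(station_id = obs$station_id[keep],
                                      observed = yk, predicted = station_pred),
         relative_error_pct = rel_err, log = log)
  }, error = function(e) {
    list(slot_id = slot$slot_id, ok = FALSE, stage = stage,
         error = conditionMessage(e), log = log)
  })
  out
}

#' Run the full study design
#'
#' Generates (or reuses) the synthetic city, computes the station
#' geo-predictor matrix once, fits every requested slot, runs the
#' between-hour comparison tests (0:00 vs 8:00, 8:00 vs 18:00, 0:00 vs
#' 18:00 within each season x day type), and assembles a model-summary
#' table (R2, adjusted R2, CV adjusted R2, RMSE, CV RMSE per slot).
#'
#' @param config a [run_config()].
#' @param city optional pre-generated city.
#' @return list of class `run_report`: slots (per-slot results), summary
#'   (data frame), comparisons (data frame), provenance.
#' @export
run_all <- function(config, city = NULL) {
  if (is.null(city)) city <- generate_city(config$city_config)
  geo_predictors <- build_predictor_matrix(city$layers, city$stations,
                                           config$spec)
  slots <- lapply(config$slots, function(id)
    run_slot(config, id, city = city, geo_predictors = geo_predictors))
  names(slots) <- config$slots

  summary <- do.call(rbind, lapply(slots, function(s) {
    if (!isTRUE(s$ok)) {
      return(data.frame(slot = s$slot_id, ok = FALSE, n_obs = NA, n_terms = NA,
                        r2 = NA, adjusted_r2 = NA, cv_adjusted_r2 = NA,
                        rmse = NA, cv_rmse = NA, stringsAsFactors = FALSE))
    }
    data.frame(slot = s$slot_id, ok = TRUE, n_obs = s$model$n_obs,
               n_terms = nrow(s$model$terms), r2 = s$model$r2,
               adjusted_r2 = s$model$adjusted_r2,
               cv_adjusted_r2 = s$cv$cv_adjusted_r2,
               rmse = s$model$rmse, cv_rmse = s$cv$cv_rmse,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  comparisons <- compare_all_slots(slots)

  report <- list(slots = slots, summary = summary, comparisons = comparisons,
                 provenance = list(seed = config$seed,
                                   n_stations = config$city_config$n_stations,
                                   package_version =
                                     as.character(utils::packageVersion("pmlur")),
                                   timestamp = format(Sys.time(), tz = "UTC")))
  class(report) <- "run_report"
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

# hour-pair comparison tests within each season x day type group
compare_all_slots <- function(slots) {
  tab <- slot_table()
  groups <- unique(tab[, c("season", "day_type")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    season <- groups$season[g]; day_type <- groups$day_type[g]
    hours <- c(0L, 8L, 18L)
    pairs <- list(c(0L, 8L), c(8L, 18L), c(0L, 18L))
    for (pr in pairs) {
      ida <- paste(season, day_type, pr[1], sep = "_")
      idb <- paste(season, day_type, pr[2], sep = "_")
      sa <- slots[[ida]]; sb <- slots[[idb]]
      if (is.null(sa) || is.null(sb) || !isTRUE(sa$ok) || !isTRUE(sb$ok)) next
      cmp <- tryCatch(
        compare_slots(sa$observations$pm25, sb$observations$pm25),
        error = function(e) NULL)
      if (is.null(cmp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        season = season, day_type = day_type,
        slot_a = ida, slot_b = idb, test = cmp$test_used,
        statistic = cmp$statistic, p = cmp$p, significant = cmp$significant,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", sum(x$summary$ok), "of", nrow(x$summary),
      "slot models fitted\n")
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 3)
  print(s, row.names = FALSE)
  invisible(x)
}
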