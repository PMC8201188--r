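#!/usr/bin/env Rscript
# Thin command-line front end over the pmlur package.
#
#   Rscript scripts/lur.R <verb> [options]
#
# Verbs:
#   synth    --seed S --out DIR          generate a synthetic city + per-slot
#                                        observations + ground truth
#   features --city DIR --out FILE.csv   predictor matrix at the stations
#   fit      --seed S --slot ID --out DIR   fit one slot (synthetic mode)
#   run      --seed S --out DIR          full 12-slot study + artifacts
#   map      --seed S --slot ID --out DIR   fit + kriged surface for one slot
#   report   --run DIR                   print the model-summary table of a run
#
# Exit status is nonzero if any requested slot fails.

suppressMessages(library(pmlur))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L) {
  cat("usage: lur.R <synth|features|fit|run|map|report> [--seed S] [--out DIR]",
      "[--slot ID] [--city DIR] [--run DIR]\n")
  quit(status = 1L)
}
verb <- args[[1]]

opt <- list(seed = 1L, out = "lur_output", slot = "heating_working_0",
            city = NULL, run = NULL)
i <- 2L
while (i <= length(args)) {
  key <- sub("^--", "", args[[i]])
  if (!key %in% names(opt)) stop("unknown option --", key)
  opt[[key]] <- args[[i + 1L]]
  i <- i + 2L
}
opt$seed <- as.integer(opt$seed)

base_config <- function() {
  run_config(city_config = city_config(rng_seed = opt$seed), seed = opt$seed)
}

status <- 0L
if (verb == "synth") {
  city <- generate_city(city_config(rng_seed = opt$seed))
  write_city(city, opt$out)
  truth <- default_truth()
  write_truth(truth, file.path(opt$out, "truth.json"))
  obs <- do.call(rbind, lapply(slot_table()$slot_id, function(id)
    generate_observations(city, truth, id, missing_rate = 0.05)))
  utils::write.csv(obs, file.path(opt$out, "observations.csv"),
                   row.names = FALSE)
  cat("city written to", opt$out, "\n")
} else if (verb == "features") {
  if (is.null(opt$city)) stop("features needs --city DIR")
  city <- read_city(opt$city)
  X <- build_predictor_matrix(city$layers, city$stations)
  write_predictor_matrix(X, opt$out)
  cat("predictor matrix (", nrow(X), "x", ncol(X), ") written to",
      opt$out, "\n")
} else if (verb %in% c("fit", "map")) {
  cfg <- base_config()
  cfg$slots <- opt$slot
  cfg$map_surfaces <- identical(verb, "map")
  res <- run_slot(cfg, opt$slot)
  if (!isTRUE(res$ok)) {
    cat("slot", opt$slot, "failed at stage", res$stage, ":", res$error, "\n")
    status <- 1L
  } else {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_lur_model(res$model, file.path(opt$out, "model.json"))
    utils::write.csv(model_terms_table(res$model, opt$slot),
                     file.path(opt$out, "model_terms.csv"), row.names = FALSE)
    if (!is.null(res$surface)) {
      write_ascii_grid(res$surface$raster, file.path(opt$out, "surface.asc"))
    }
    print(res$model)
  }
} else if (verb == "run") {
  cfg <- base_config()
  cfg$output_dir <- opt$out
  rep <- run_all(cfg)
  print(rep)
  if (!all(rep$summary$ok)) status <- 1L
} else if (verb == "report") {
  if (is.null(opt$run)) stop("report needs --run DIR")
  path <- file.path(opt$run, "model_summary.csv")
  if (!file.exists(path)) stop("no model_summary.csv under ", opt$run)
  print(utils::read.csv(path), row.names = FALSE)
} else {
  stop("unknown verb '", verb, "'")
}
quit(status = status)
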