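#' Run the full profiling pipeline
#'
#' Orchestrates ingest -> per-plate robust-z normalization -> replicate
#' aggregation and induction -> induction-window selection ->
#' cross-similarity and MBP -> profile PCA -> fragment-dominance
#' classification -> report, writing every stage output plus a run
#' manifest (with MD5 content hashes, the full configuration echo, and
#' per-stage status) into the output directory. Reruns with the same
#' configuration and inputs reproduce the hashes; stage failures are
#' recorded in the manifest and earlier outputs are retained.
#'
#' The configuration is an R list or a YAML file with (all optional unless
#' stated):
#' \describe{
#'   \item{simulate}{name of a [preset_scenarios()] scenario, or a list of
#'     [sim_config()] arguments; mutually exclusive with `plate_csv`.}
#'   \item{plate_csv}{well-level CSV to analyze (required unless
#'     `simulate`).}
#'   \item{annotations_csv}{CSV with `compound_id`, `class_label`,
#'     `subclass_label`, `fragments` (semicolon-separated); required for
#'     the dominance stage when reading plates from file.}
#'   \item{z_star, biosim_threshold, activity_threshold, window,
#'     silhouette_cutoff, band, min_dmso}{analysis thresholds; defaults 3,
#'     75, 5, c(20, 40), 0.25, 1, 8.}
#'   \item{fragments}{fragment tags to classify; default: all tags shared
#'     by >= 2 subclasses.}
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{RNG seed for the simulation stage.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  defaults <- list(z_star = 3, biosim_threshold = 75, activity_threshold = 5,
                   window = c(20, 40), silhouette_cutoff = 0.25, band = 1,
                   min_dmso = 8L, seed = 1L)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list(), outputs = list())
  state <- new.env(parent = emptyenv())

  finish <- function() {
    files <- unlist(manifest$outputs)
    if (length(files)) {
      hashes <- tools::md5sum(file.path(out_dir, files))
      manifest$hashes <<- setNames(as.list(unname(hashes)), files)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
    manifest
  }

  run_stage <- function(name, fun) {
    res <- tryCatch({
      fun()
      manifest$stages[[name]] <<- "ok"
      TRUE
    }, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      FALSE
    })
    res
  }

  emit <- function(file) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<- file
  }

  ok <- run_stage("ingest", function() {
    if (!is.null(config$simulate)) {
      cfg <- if (is_string(config$simulate)) {
        presets <- preset_scenarios(seed = config$seed)
        if (!(config$simulate %in% names(presets))) {
          stopf("unknown preset '%s'", config$simulate)
        }
        presets[[config$simulate]]
      } else {
        do.call(sim_config, c(config$simulate, list(seed = config$seed)))
      }
      sim <- simulate_assay(cfg)
      state$plates <- sim$plates
      state$annotations <- sim$annotations
      write_plate_csv(sim$plates, file.path(out_dir, "plates.csv"))
      emit("plates.csv")
      write.csv(sim$annotations, file.path(out_dir, "annotations.csv"),
                row.names = FALSE)
      emit("annotations.csv")
    } else {
      if (is.null(config$plate_csv)) {
        stopf("config needs either 'simulate' or 'plate_csv'")
      }
      if (!file.exists(config$plate_csv)) {
        stopf("input file not found: %s", config$plate_csv)
      }
      state$plates <- read_plate_csv(config$plate_csv)
      if (!is.null(config$annotations_csv)) {
        if (!file.exists(config$annotations_csv)) {
          stopf("input file not found: %s", config$annotations_csv)
        }
        state$annotations <- read.csv(config$annotations_csv,
                                      stringsAsFactors = FALSE)
      }
    }
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("normalize", function() {
    state$norm <- lapply(state$plates, normalize_plate,
                         min_dmso = config$min_dmso)
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("aggregate", function() {
    state$profiles <- profiles_from_plates(state$norm, z_star = config$z_star)
    df <- cbind(state$profiles$meta, as.data.frame(state$profiles$values))
    write.csv(df, file.path(out_dir, "profiles.csv"), row.names = FALSE)
    emit("profiles.csv")
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("select", function() {
    state$selected <- select_profiles(state$profiles, window = config$window)
    write.csv(state$selected$meta, file.path(out_dir, "selected.csv"),
              row.names = FALSE)
    emit("selected.csv")
    excl <- attr(state$selected, "excluded")
    write.csv(excl, file.path(out_dir, "excluded.csv"), row.names = FALSE)
    emit("excluded.csv")
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("similarity", function() {
    m <- cross_similarity(state$selected)
    long <- data.frame(
      id_a = rep(rownames(m), times = ncol(m)),
      id_b = rep(colnames(m), each = nrow(m)),
      biosimilarity = as.vector(unclass(m)), stringsAsFactors = FALSE
    )
    write.csv(long, file.path(out_dir, "similarity.csv"), row.names = FALSE)
    emit("similarity.csv")
    state$similarity <- m
    summary <- list(
      n_profiles = nrow(state$profiles$meta),
      n_selected = nrow(state$selected$meta),
      active_fraction_pct = 100 * mean(
        state$profiles$meta$induction > config$activity_threshold),
      median_induction = median(state$profiles$meta$induction),
      library_mbp_within = mbp(m, mode = "within")
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("summary.json")
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("pca", function() {
    state$pca <- profile_pca(state$selected, k = 3L)
    df <- cbind(state$pca$meta, as.data.frame(state$pca$scores))
    write.csv(df, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    emit("pca_scores.csv")
  })
  if (!ok) return(invisible(finish()))

  ok <- run_stage("dominance", function() {
    ann <- state$annotations
    if (is.null(ann)) {
      manifest$stages$dominance <<- "skipped: no annotations"
      return(invisible(NULL))
    }
    sel <- state$selected
    idx <- match(sel$meta$compound_id, ann$compound_id)
    subclass <- ann$subclass_label[idx]
    frag_list <- lapply(ann$fragments[idx], split_tags)
    tags <- config$fragments %||% {
      all_tags <- unique(unlist(frag_list))
      keep <- vapply(all_tags, function(tg) {
        has <- vapply(frag_list, function(fl) tg %in% fl, logical(1))
        length(unique(subclass[has])) >= 2L
      }, logical(1))
      all_tags[keep]
    }
    calls <- list()
    for (tg in tags) {
      has <- vapply(frag_list, function(fl) tg %in% fl, logical(1))
      call <- tryCatch(
        classify_fragment_dominance(
          subset_profiles(sel, has), subclass[has], fragment = tg,
          threshold = config$biosim_threshold, band = config$band,
          silhouette_cutoff = config$silhouette_cutoff),
        error = function(e) list(fragment = tg,
                                 classification = paste("error:",
                                                        conditionMessage(e)))
      )
      calls[[tg]] <- list(
        fragment = tg, classification = call$classification,
        mbp = call$mbp %||% NA, silhouette = call$silhouette %||% NA,
        clustered = call$clustered %||% NA,
        subclasses = call$subclasses %||% character(0)
      )
    }
    state$dominance <- calls
    jsonlite::write_json(calls, file.path(out_dir, "dominance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("dominance.json")
  })
  if (!ok) return(invisible(finish()))

  run_stage("report", function() {
    report <- list(
      stages = names(manifest$stages),
      pc1_induction_r = state$pca$pc1_induction_r,
      explained_variance = state$pca$explained_variance,
      dominance = lapply(state$dominance %||% list(), function(x)
        x$classification)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("report.json")
  })

  invisible(finish())
}
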