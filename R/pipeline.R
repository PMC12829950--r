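# Pipeline orchestration: synth -> ingest -> cluster -> fit -> explain ->
# mediate -> reliability from one declarative config, with a manifest and
# deterministic per-stage seeds.

#' Build a pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Defaults follow the
#' published protocol (150 synthetic patients, k = 2, eGFR/BNP exposures,
#' PSD mediator, GWW/GWE outcomes); any field can be overridden, and all
#' randomness flows from `seed` via fixed per-stage offsets.
#'
#' @param stages Character vector of enabled stages, in any order; executed
#'   in dependency order. Subset of `synth`, `ingest`, `cluster`, `fit`,
#'   `explain`, `mediate`, `reliability`.
#' @param input Optional path to an existing raw CSV/XLSX (replaces the
#'   synth stage).
#' @param out Output directory.
#' @param seed Master seed.
#' @param ... Stage parameter overrides: `synth` (list passed to
#'   [synthetic_spec()] plus `dirty`), `cluster` (`k`, `n_boot`), `fit`
#'   (`targets`, `cv_spec`, `algorithms`, `grids`), `mediate` (`exposures`,
#'   `outcomes`, `n_boot`, `include_square`, `include_interaction`),
#'   `reliability` (`n_per_cluster`).
#' @return `pipeline_config` list, validated.
#' @export
pipeline_config <- function(stages = c("synth", "ingest", "cluster", "fit",
                                       "explain", "mediate", "reliability"),
                            input = NULL, out = tempfile("hfpef_run_"),
                            seed = 42L, ...) {
  cfg <- modifyList(list(
    stages = stages, input = input, out = out, seed = as.integer(seed),
    synth = list(n_patients = 150, dirty = 0),
    cluster = list(k = 2, n_boot = 100L),
    fit = list(targets = "GWW",
               cv_spec = list(outer_k = 5L, repeats = 2L, inner_k = 3L),
               algorithms = c("ridge", "lasso")),
    mediate = list(exposures = c("eGFR", "BNP"), outcomes = c("GWW", "GWE"),
                   mediator = "PSD", n_boot = 200L,
                   include_square = FALSE, include_interaction = FALSE),
    reliability = list(n_per_cluster = 20L)
  ), list(...))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("synth", "ingest", "cluster", "fit", "explain", "mediate",
             "reliability")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  has <- function(s) s %in% cfg$stages
  if (has("ingest") && !has("synth") && is.null(cfg$input))
    stopf("ingest enabled but no synth stage and no input path")
  if ((has("cluster") || has("fit")) && !has("ingest") && !has("synth") &&
      is.null(cfg$input))
    stopf("cluster/fit require an upstream data stage")
  if (has("mediate") && !has("cluster") && is.null(cfg$labels))
    stopf("mediate requires per-subtype labels: enable the cluster stage or supply a labels path")
  if (has("reliability") && !has("cluster") && is.null(cfg$pairs))
    stopf("reliability requires cluster labels or a pairs path")
  if (has("explain") && !has("fit"))
    stopf("explain requires the fit stage")
  invisible(cfg)
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writing every artifact
#' as UTF-8 CSV or JSON under `config$out` together with a manifest (seed,
#' package version, stage parameters, input hashes). A stage failure halts
#' the run naming the stage; artifacts already written are retained.
#'
#' @param config A [pipeline_config()] (or a YAML file path).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  has <- function(s) s %in% config$stages
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  raw_path <- config$input
  if (has("synth")) {
    res$synth <- stage("synth", {
      sp_args <- config$synth
      dirty <- sp_args$dirty %||% 0
      sp_args$dirty <- NULL
      sp_args$seed <- sp_args$seed %||% derive_seed(config$seed, 1L)
      spec <- do.call(synthetic_spec, sp_args)
      gen <- generate_cohort(spec)
      write_cohort(gen$cohort, gen$truth, out)
      spec2 <- spec; spec2$missing_rate <- dirty
      dj <- inject_dirty(gen$cohort, spec2)
      # expr evaluates in run_pipeline's frame, so this rebinds the local
      raw_path <- file.path(out, "raw.csv")
      write.csv(dj$raw, raw_path, row.names = FALSE)
      c(gen, list(spec = spec, dirty_positions = dj$positions))
    })
  }

  tbl <- NULL
  if (has("ingest")) {
    res$ingest <- stage("ingest", {
      q <- ingest_qc(raw_path)
      write.csv(q$table, file.path(out, "clean.csv"), row.names = FALSE)
      write_json_artifact(q$report, file.path(out, "qc_report.json"))
      q
    })
    tbl <- res$ingest$table
  } else if (has("synth")) {
    tbl <- res$synth$cohort
  } else if (!is.null(config$input)) {
    tbl <- parse_raw(config$input)$table
  }

  labels <- NULL
  if (has("cluster")) {
    res$cluster <- stage("cluster", {
      cl <- subtype_cohort(tbl, k = config$cluster$k,
                           n_boot = config$cluster$n_boot,
                           seed = derive_seed(config$seed, 2L))
      write.csv(data.frame(patient_id = tbl$patient_id, cluster = cl$labels),
                file.path(out, "labels.csv"), row.names = FALSE)
      write_json_artifact(list(k = cl$k, inertia = cl$inertia,
                               silhouette_by_k = as.list(cl$silhouette_by_k),
                               pca_variance_fractions = cl$pca_variance_fractions,
                               stability_ari_mean = mean(cl$stability_ari),
                               centroids = cl$centroids),
                          file.path(out, "cluster_result.json"))
      gc_tab <- compare_clusters(tbl, cl$labels)
      write.csv(gc_tab, file.path(out, "group_comparison.csv"), row.names = FALSE)
      cl$group_comparison <- gc_tab
      cl
    })
    labels <- res$cluster$labels
  }

  if (has("fit")) {
    res$fit <- stage("fit", {
      fits <- lapply(config$fit$targets, function(tg) {
        fm <- build_features(tbl, target = tg)
        args <- list(fm, cv_spec = config$fit$cv_spec,
                     seed = derive_seed(config$seed, 3L))
        if (!is.null(config$fit$algorithms)) args$algorithms <- config$fit$algorithms
        if (!is.null(config$fit$grids)) args$grids <- config$fit$grids
        rep <- do.call(fit_suite, args)
        write.csv(rep$summary,
                  file.path(out, sprintf("model_report_%s.csv", tg)),
                  row.names = FALSE)
        list(features = fm, report = rep)
      })
      names(fits) <- config$fit$targets
      fits
    })
  }

  if (has("explain")) {
    res$explain <- stage("explain", {
      lapply(res$fit, function(f) {
        attr_m <- shapley_exact_linear(f$report$final_model, f$features$X,
                                       f$features$X)
        tg <- f$features$target
        write.csv(as.data.frame(attr_m$values),
                  file.path(out, sprintf("attribution_%s.csv", tg)),
                  row.names = FALSE)
        write.csv(rank_features(attr_m),
                  file.path(out, sprintf("ranking_%s.csv", tg)),
                  row.names = FALSE)
        attr_m
      })
    })
  }

  if (has("mediate")) {
    res$mediate <- stage("mediate", {
      md <- config$mediate
      grid <- run_grid(tbl, labels, exposures = md$exposures,
                       outcomes = md$outcomes, mediator = md$mediator,
                       n_boot = md$n_boot,
                       include_square = isTRUE(md$include_square),
                       include_interaction = isTRUE(md$include_interaction),
                       seed = derive_seed(config$seed, 4L))
      write.csv(grid$results, file.path(out, "mediation_grid.csv"),
                row.names = FALSE)
      grid
    })
  }

  if (has("reliability")) {
    res$reliability <- stage("reliability", {
      tbl$cluster <- labels %||% tbl$cluster
      spec <- if (has("synth")) res$synth$spec else synthetic_spec()
      prs <- generate_replicates(tbl, config$reliability$n_per_cluster, spec)
      write.csv(prs, file.path(out, "reliability_pairs.csv"), row.names = FALSE)
      rel <- reliability_by_cluster(prs)
      write_json_artifact(rel, file.path(out, "reliability.json"))
      rel
    })
  }

  manifest <- list(
    seed = config$seed, stages = config$stages,
    package_version = as.character(packageVersion("hfpefmed")),
    r_version = R.version.string,
    input_hash = if (!is.null(raw_path) && file.exists(raw_path))
      unname(tools::md5sum(raw_path)) else NULL,
    parameters = config[setdiff(names(config), c("stages", "out"))])
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
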