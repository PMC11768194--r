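## End-to-end pipeline: per-sample crumb, curve and colour analysis,
## grouped lettered tables, colourmap renders and a JSON report bundle.
## Re-running with the same config and inputs is bit-identical except for
## the timestamp line in run.log.

#' Assemble a pipeline configuration
#'
#' @param samples data.frame with columns `sample` (unique id), `group`,
#'   and optional `image` / `curve` file paths (PNG/JPEG/PGM images; curve
#'   CSVs with header `time_min,torque_nm,temp_c`).
#' @param colors optional path to a colour-readings CSV
#'   (`group,replicate,L,a,b`).
#' @param reference_group group used as the Delta E reference (the 0%
#'   control); defaults to the first group.
#' @param out_dir output directory (created on run).
#' @param size_class,extraction named lists overriding
#'   [size_class_config()] / [extraction_config()] defaults.
#' @param alpha significance level for letter displays.
#' @param seed integer seed, recorded in every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, colors = NULL, reference_group = NULL,
                            out_dir = "crumblab_out", size_class = list(),
                            extraction = list(), alpha = 0.05, seed = 1L) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) abort("no samples in config", "crumblab_bad_config")
  if (!all(c("sample", "group") %in% names(samples))) {
    abort("samples need 'sample' and 'group' columns", "crumblab_bad_config")
  }
  if (anyDuplicated(samples$sample)) {
    abort("sample ids must be unique", "crumblab_bad_config")
  }
  structure(list(samples = samples, colors = colors,
                 reference_group = reference_group %||% samples$group[1L],
                 out_dir = out_dir, size_class = size_class,
                 extraction = extraction, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline configuration from JSON or YAML
#'
#' File paths in the config are resolved relative to the config file's
#' directory.
#'
#' @param path `.json` or `.yaml` config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- read_config_file(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(base, p))
  }
  samples <- as.data.frame(raw$samples)
  for (col in c("image", "curve")) {
    if (col %in% names(samples)) samples[[col]] <- resolve(samples[[col]])
  }
  pipeline_config(
    samples = samples,
    colors = if (!is.null(raw$colors)) resolve(raw$colors) else NULL,
    reference_group = raw$reference_group,
    out_dir = if (!is.null(raw$out_dir)) resolve(raw$out_dir) else
      file.path(base, "crumblab_out"),
    size_class = raw$size_class %||% list(),
    extraction = raw$extraction %||% list(),
    alpha = raw$alpha %||% 0.05,
    seed = raw$seed %||% 1L
  )
}

to_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  invisible(path)
}

## lettered tables for every numeric metric of a per-sample data.frame
family_tables <- function(df, metrics, alpha, dir, prefix) {
  ok <- character()
  for (m in metrics) {
    res <- tryCatch({
      gd <- group_data(df$group, df[[m]])
      tab <- lettered_table(gd, alpha = alpha)
      write.csv(tab, file.path(dir, paste0(prefix, "_", m, ".csv")),
                row.names = FALSE, quote = FALSE)
      m
    }, error = function(e) NA_character_, warning = function(w) m)
    if (!is.na(res)) ok <- c(ok, m)
  }
  ok
}

#' Run the full analysis pipeline
#'
#' For every sample: segments the crumb image (when present) into pore
#' statistics and a colourmap render, and extracts the MixoLab parameter
#' vector from the torque curve (when present). Colour readings are
#' averaged per group and classified against the reference group's mean
#' (CIE76). Per-group mean +/- SD tables with Tukey letters are written
#' for each measurement family, one per metric.
#'
#' Per-sample failures are isolated: the pipeline completes, reports them
#' in the bundle, and the CLI exits non-zero when any occurred.
#'
#' @param config a [pipeline_config()] or path to a JSON/YAML config.
#' @return (invisibly) the report bundle, a list with `samples`,
#'   `color_diffs`, `tables`, `errors`, `config_echo`; written to
#'   `out_dir` as JSON/CSV/PNG files plus `run.log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  for (d in file.path(out, c("samples", "tables", "colourmaps"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  scc <- do.call(size_class_config, config$size_class)
  exc <- do.call(extraction_config, config$extraction)
  errors <- list()
  per_sample <- list()

  for (i in seq_len(nrow(config$samples))) {
    row <- config$samples[i, ]
    id <- row$sample
    rec <- list(sample = id, group = row$group, seed = config$seed)
    res <- tryCatch({
      if (!is.null(row$image) && !is.na(row$image) && nzchar(row$image)) {
        img <- load_slice(row$image)
        an <- analyze_crumb(img, scc)
        rec$pore_statistics <- unclass(an$stats)
        cm <- render_colourmap(an$labels, an$regions)
        write_image(cm, file.path(out, "colourmaps", paste0(id, ".png")))
      }
      if (!is.null(row$curve) && !is.na(row$curve) && nzchar(row$curve)) {
        curve <- read_curve_csv(row$curve)
        rec$mixolab_parameters <- unclass(extract_parameters(curve, exc))
      }
      rec
    }, error = function(e) {
      errors[[id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) {
      per_sample[[id]] <- res
      to_json(res, file.path(out, "samples", paste0(id, ".json")))
    }
  }

  ## colour readings: group means and Delta E against the reference group
  color_diffs <- NULL
  color_tab <- NULL
  if (!is.null(config$colors)) {
    color_tab <- tryCatch(read_color_csv(config$colors), error = function(e) {
      errors[["colors"]] <<- conditionMessage(e)
      NULL
    })
  }
  if (!is.null(color_tab)) {
    grp_means <- lapply(split(color_tab, color_tab$group), average_readings)
    ref <- config$reference_group
    if (!ref %in% names(grp_means)) {
      errors[["colors"]] <- paste0("reference group not in readings: ", ref)
    } else {
      color_diffs <- lapply(names(grp_means), function(g) {
        de <- delta_e(grp_means[[ref]], grp_means[[g]])
        list(group = g, L = grp_means[[g]][["L"]], a = grp_means[[g]][["a"]],
             b = grp_means[[g]][["b"]], delta_e = de$delta_e,
             band = de$band_label)
      })
      names(color_diffs) <- names(grp_means)
    }
  }

  ## grouped lettered tables per measurement family
  tables <- list()
  pore_rows <- Filter(function(r) !is.null(r$pore_statistics), per_sample)
  if (length(pore_rows) > 0L) {
    df <- do.call(rbind, lapply(pore_rows, function(r) {
      data.frame(group = r$group, n_small = r$pore_statistics$n_small,
                 n_medium = r$pore_statistics$n_medium,
                 n_large = r$pore_statistics$n_large,
                 n_total = r$pore_statistics$n_total,
                 porosity = r$pore_statistics$porosity)
    }))
    tables$pores <- family_tables(df, c("n_small", "n_medium", "n_large",
                                        "n_total", "porosity"),
                                  config$alpha, file.path(out, "tables"), "pores")
  }
  mix_rows <- Filter(function(r) !is.null(r$mixolab_parameters), per_sample)
  if (length(mix_rows) > 0L) {
    metrics <- c("t_hydr", "t1", "c1", "amplitude", "stability", "c2", "c3",
                 "t3", "gelling_mid", "c4", "c5")
    df <- do.call(rbind, lapply(mix_rows, function(r) {
      cbind(data.frame(group = r$group),
            as.data.frame(r$mixolab_parameters[metrics]))
    }))
    tables$mixolab <- family_tables(df, metrics, config$alpha,
                                    file.path(out, "tables"), "mixolab")
  }
  if (!is.null(color_tab)) {
    tables$color <- family_tables(color_tab, c("L", "a", "b"), config$alpha,
                                  file.path(out, "tables"), "color")
  }

  config_echo <- list(
    seed = config$seed, alpha = config$alpha,
    reference_group = config$reference_group,
    size_class = unclass(scc), extraction = unclass(exc),
    samples = config$samples
  )
  bundle <- list(samples = per_sample, color_diffs = color_diffs,
                 tables = tables, errors = errors, config_echo = config_echo)
  to_json(bundle, file.path(out, "report.json"))
  writeLines(c(paste0("crumblab run at ", format(Sys.time(), usetz = TRUE)),
               paste0("seed: ", config$seed),
               paste0("alpha: ", config$alpha),
               paste0("samples: ", nrow(config$samples)),
               paste0("errors: ", length(errors)),
               jsonlite::toJSON(config_echo, auto_unbox = TRUE, digits = 12)),
             file.path(out, "run.log"))
  invisible(bundle)
}

#' Generate a complete synthetic fixture dataset on disk
#'
#' Builds a small study layout -- per sample a crumb image (PNG) and a
#' torque-curve CSV, plus one colour-readings CSV -- together with a JSON
#' pipeline config pointing at them. Group effects are injected so that
#' downstream lettered tables have real structure: pore counts, C3/C5
#' torques and colour means all shift with the group index.
#'
#' @param dir directory to create the dataset in.
#' @param n_groups number of groups (first group is the control /
#'   reference).
#' @param n_replicates samples per group.
#' @param seed integer master seed (per-file seeds are derived from it).
#' @return path to the written config file (`config.json`).
#' @export
simulate_dataset <- function(dir, n_groups = 3L, n_replicates = 3L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- reference_mixolab_params("control")
  groups <- c("control", paste0("banana_", seq_len(n_groups - 1L) * 10L))
  rows <- list()
  k <- 0L
  for (gi in seq_len(n_groups)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      id <- sprintf("%s_rep%d", groups[gi], r)
      sseed <- (seed * 131L + k) %% .Machine$integer.max
      spec <- crumb_scene_spec(n_pores = 30L + 12L * (gi - 1L),
                               noise_sd = 5, seed = sseed)
      scene <- generate_crumb_image(spec)
      img_rel <- paste0(id, ".png")
      write_image(scene$image$pixels, file.path(dir, img_rel))
      p <- base
      p$c3 <- base$c3 + 0.05 * (gi - 1L)
      p$c4 <- base$c4 + 0.04 * (gi - 1L)
      p$c5 <- base$c5 + 0.10 * (gi - 1L)
      p$stability <- base$stability + 0.10 * (gi - 1L)
      params <- do.call(mixolab_params, unclass(p)[names(formals(mixolab_params))])
      curve <- generate_torque_curve(params, noise_sd = 0.005, seed = sseed)
      curve_rel <- paste0(id, ".csv")
      write_curve_csv(curve, file.path(dir, curve_rel))
      rows[[k]] <- data.frame(sample = id, group = groups[gi],
                              image = img_rel, curve = curve_rel)
    }
  }
  means <- setNames(lapply(seq_len(n_groups), function(gi) {
    lab_color(L = 90 - 2.5 * (gi - 1L), a = 0.5 + 0.7 * (gi - 1L),
              b = 9 + 1.8 * (gi - 1L))
  }), groups)
  readings <- generate_color_readings(means, sd = 0.3,
                                      n_replicates = n_replicates,
                                      seed = (seed * 131L + 9999L) %% .Machine$integer.max)
  write_color_csv(readings, file.path(dir, "colors.csv"))
  cfg <- list(
    samples = do.call(rbind, rows), colors = "colors.csv",
    reference_group = "control", out_dir = "out",
    alpha = 0.05, seed = seed
  )
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  cfg_path
}
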