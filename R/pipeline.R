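# End-to-end pipeline surface: a round-trippable run configuration whose
# defaults are the protocol's stated values, plus file-level commands that the
# command-line script (inst/cli/moacascade) wraps one-to-one.

#' Run configuration
#'
#' All tunable parameters of the pipeline with their protocol defaults:
#' 10 uM activity threshold, Tc 0.4 sphere-exclusion cutoff, minimum 10
#' functional / 5 binding compounds, 100 trees (Arch1 depth 20, stages
#' unlimited), 3 calibration folds, 5 CV folds, k = 5 AD neighbors with 0.05
#' similarity bins. Round-trips losslessly through YAML.
#'
#' @param ... Overrides of individual fields.
#' @return A named list of class `moa_config`.
#' @export
moa_config <- function(...) {
  cfg <- list(
    threshold_um = 10, tc_cutoff = 0.4, inactive_multiple = 100,
    min_functional = 10L, min_binding = 5L,
    num_trees = 100L, arch1_max_depth = 20L, calibration_folds = 3L,
    use_instance_weights = TRUE,
    k_folds = 5L, ad_k = 5L, ad_bin_width = 0.05,
    n_bits = 2048L, fp_radius = 2L,
    seed = 1L, log_level = "info"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort_moa(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
              "moa_input_error")
  }
  structure(modifyList(cfg, overrides), class = "moa_config")
}

#' @rdname moa_config
#' @param path YAML file path.
#' @export
read_moa_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(moa_config, vals)
}

#' @rdname moa_config
#' @param config A `moa_config`.
#' @export
write_moa_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

read_annotation_csv <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("compound_id", "target_id", "protein_class", "endpoint_type",
                "value_um")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    abort_moa(paste0("annotation file lacks column(s): ",
                     paste(missing, collapse = ", ")), "moa_schema_error")
  }
  ann
}

#' Build per-target training sets from an annotation file
#'
#' Reads the annotation CSV (columns `compound_id`, `smiles` (optional when
#' `fp` is given), `target_id`, `protein_class`, `endpoint_type`, `value_um`,
#' `bao_term`), derives fingerprints (standardization, drug-likeness filter,
#' circular fingerprint) unless a precomputed matrix is supplied, assembles
#' the per-target sets, and optionally persists the universe (membership CSV,
#' hex-packed fingerprint CSV, JSON manifest with per-target counts and the
#' dropped-target report).
#'
#' @param annotations Path to a CSV or an annotation data frame.
#' @param fp Optional precomputed fingerprint 0/1 matrix.
#' @param out_dir Optional output directory.
#' @param config A [moa_config()].
#' @return The assembled [moa_universe()] (invisibly when writing).
#' @export
moa_build_data <- function(annotations, fp = NULL, out_dir = NULL,
                           config = moa_config()) {
  if (is.character(annotations)) annotations <- read_annotation_csv(annotations)
  check_columns(annotations, c("compound_id", "target_id", "protein_class",
                               "endpoint_type", "value_um"))
  if (is.null(fp)) {
    check_columns(annotations, "smiles")
    cmpds <- distinct(annotations, .data$compound_id, .data$smiles)
    recs <- standardize_compounds(cmpds) |>
      filter_druglike(drop = TRUE)
    dropped <- setdiff(cmpds$compound_id, recs$compound_id)
    if (length(dropped)) {
      warning(length(dropped), " compound(s) removed by standardization/filters.")
      annotations <- filter(annotations, !.data$compound_id %in% dropped)
    }
    fp <- fingerprint_smiles(recs$std_smiles, n_bits = config$n_bits,
                             radius = config$fp_radius)
    rownames(fp) <- recs$compound_id
  }
  u <- build_target_datasets(
    annotations, fp, threshold_um = config$threshold_um,
    tc_cutoff = config$tc_cutoff, inactive_multiple = config$inactive_multiple,
    min_functional = config$min_functional, min_binding = config$min_binding,
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    write_universe(u, out_dir)
    return(invisible(u))
  }
  u
}

#' Persist / load a universe as plain-text files
#'
#' @param universe A [moa_universe()].
#' @param dir Directory (created if needed).
#' @return `write_universe`: the directory, invisibly. `read_universe`: the
#'   restored universe.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(universe$membership, file.path(dir, "membership.csv"))
  readr::write_csv(universe$targets, file.path(dir, "targets.csv"))
  readr::write_csv(tibble(compound_id = rownames(universe$fp),
                          fp_hex = fp_to_hex(universe$fp)),
                   file.path(dir, "fingerprints.csv"))
  counts <- universe_counts(universe)
  manifest <- list(
    n_targets = nrow(universe$targets), n_bits = ncol(universe$fp),
    counts = counts,
    dropped = attr(universe, "dropped") %||% list()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_universe
#' @export
read_universe <- function(dir) {
  membership <- readr::read_csv(file.path(dir, "membership.csv"),
                                show_col_types = FALSE)
  targets <- readr::read_csv(file.path(dir, "targets.csv"), show_col_types = FALSE)
  fps <- readr::read_csv(file.path(dir, "fingerprints.csv"), show_col_types = FALSE)
  fp <- hex_to_fp(setNames(fps$fp_hex, fps$compound_id))
  moa_universe(targets, membership, fp)
}

#' Train an architecture and persist a model archive
#'
#' For the cascades, trains Stage 1 + Stage 2 per target (per-target failures
#' are collected, the run continues). For Arch1, the decision threshold is
#' first derived from a `config$k_folds`-fold cross-validation and the final
#' ensemble is refit on all functional data. The archive holds the serialized
#' models plus a JSON manifest (architecture, hyper-parameters, seed, training
#' counts, threshold, package version).
#'
#' @param universe A [moa_universe()] or a directory written by
#'   [write_universe()].
#' @param architecture `"arch1"`, `"arch2"` or `"arch3"`.
#' @param out_dir Optional archive directory.
#' @param config A [moa_config()].
#' @return The trained model (invisibly when writing).
#' @export
moa_train <- function(universe, architecture = c("arch1", "arch2", "arch3"),
                      out_dir = NULL, config = moa_config()) {
  architecture <- match.arg(architecture)
  if (is.character(universe)) universe <- read_universe(universe)
  model <- if (architecture == "arch1") {
    cv <- crossvalidate(universe, "arch1", k = config$k_folds, seed = config$seed,
                        num_trees = config$num_trees,
                        max_depth = config$arch1_max_depth)
    m <- train_arch1(universe, num_trees = config$num_trees,
                     max_depth = config$arch1_max_depth, seed = config$seed)
    m$theta <- cv$theta
    m
  } else {
    train_cascade(universe, architecture,
                  calibration_folds = config$calibration_folds,
                  num_trees = config$num_trees,
                  use_instance_weights = config$use_instance_weights,
                  seed = config$seed)
  }
  if (!is.null(out_dir)) {
    write_moa_model(model, out_dir)
    return(invisible(model))
  }
  model
}

#' Persist / load a trained model archive
#'
#' @param model An `arch1_model` or `cascade_model`.
#' @param dir Archive directory.
#' @return `write_moa_model`: the directory, invisibly; `read_moa_model`: the
#'   model.
#' @export
write_moa_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  manifest <- as.list(glance(model))
  manifest$package_version <- as.character(utils::packageVersion("moacascade"))
  manifest$failures <- attr(model, "failures") %||% list()
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_moa_model
#' @export
read_moa_model <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) abort_moa("model archive not found.", "moa_model_error")
  model <- tryCatch(readRDS(f), error = function(e) {
    abort_moa("corrupt model archive.", "moa_model_error")
  })
  if (!inherits(model, c("arch1_model", "cascade_model"))) {
    abort_moa("corrupt model archive.", "moa_model_error")
  }
  model
}

#' Predict functional effects for new compounds
#'
#' Accepts a SMILES/CSV file, a data frame with `compound_id` + `smiles`, or a
#' fingerprint matrix. Structures are standardized, filtered and
#' fingerprinted; unparsable or filtered rows are reported per row and valid
#' rows still processed.
#'
#' @param model A trained model or archive directory.
#' @param input `.smi`/`.csv` path, data frame, or fingerprint matrix.
#' @param out_file Optional CSV output path.
#' @param config A [moa_config()].
#' @return Tibble of predictions (`compound_id`, `target_id`, `p_bind`,
#'   `p_act`, `p_inh`, `final_label`); skipped input rows in the `"skipped"`
#'   attribute.
#' @export
moa_predict <- function(model, input, out_file = NULL, config = moa_config()) {
  if (is.character(model)) model <- read_moa_model(model)
  skipped <- tibble(compound_id = character(), reason = character())
  if (is.matrix(input)) {
    fp <- input
  } else {
    if (is.character(input)) {
      input <- if (grepl("\\.smi$", input)) read_smi(input)
      else readr::read_csv(input, show_col_types = FALSE)
    }
    if (nrow(input) == 0) {
      out <- tibble(compound_id = character(), target_id = character(),
                    p_bind = numeric(), p_act = numeric(), p_inh = numeric(),
                    final_label = character())
      if (!is.null(out_file)) readr::write_csv(out, out_file)
      return(out)
    }
    recs <- standardize_compounds(input)
    bad <- filter(recs, !.data$valid)
    if (nrow(bad)) {
      skipped <- bind_rows(skipped, tibble(compound_id = bad$compound_id,
                                           reason = "unparsable structure"))
    }
    recs <- filter_druglike(filter(recs, .data$valid), drop = TRUE)
    kept <- recs$compound_id
    filtered_out <- setdiff(input$compound_id, c(kept, skipped$compound_id))
    if (length(filtered_out)) {
      skipped <- bind_rows(skipped, tibble(compound_id = filtered_out,
                                           reason = "failed drug-likeness filter"))
    }
    fp <- fingerprint_smiles(recs$std_smiles, n_bits = config$n_bits,
                             radius = config$fp_radius)
    rownames(fp) <- kept
  }
  out <- predict(model, fp)
  if (nrow(skipped)) warning(nrow(skipped), " input row(s) skipped.")
  attr(out, "skipped") <- skipped
  if (!is.null(out_file)) {
    readr::write_csv(out, out_file)
    return(invisible(out))
  }
  out
}

#' Run an evaluation protocol and write reports
#'
#' `mode = "crossval"` cross-validates an architecture on the universe;
#' `"temporal"` evaluates a trained model on a later batch; `"adcurve"`
#' computes the applicability-domain curve of a model's predictions on a
#' batch. Reports are written as JSON (summary) and CSV (per-target table or
#' AD bins) when `out_dir` is given.
#'
#' @param universe A [moa_universe()] (crossval/adcurve reference data).
#' @param mode One of `"crossval"`, `"temporal"`, `"adcurve"`.
#' @param architecture Architecture id for `crossval`.
#' @param model Trained model for `temporal` / `adcurve`.
#' @param batch A `moa_temporal_batch` for `temporal` / `adcurve`.
#' @param out_dir Optional report directory.
#' @param config A [moa_config()].
#' @return The report object (`moa_metrics` or `moa_ad_curve`).
#' @export
moa_evaluate <- function(universe, mode = c("crossval", "temporal", "adcurve"),
                         architecture = "arch3", model = NULL, batch = NULL,
                         out_dir = NULL, config = moa_config()) {
  mode <- match.arg(mode)
  res <- switch(mode,
    crossval = crossvalidate(universe, architecture, k = config$k_folds,
                             seed = config$seed),
    temporal = {
      if (is.null(model) || is.null(batch)) {
        abort_moa("temporal mode needs `model` and `batch`.", "moa_input_error")
      }
      temporal_validate(model, batch)
    },
    adcurve = {
      if (is.null(model) || is.null(batch)) {
        abort_moa("adcurve mode needs `model` and `batch`.", "moa_input_error")
      }
      preds <- predict(model, batch$fp) |>
        inner_join(batch$annotations, by = c("compound_id", "target_id"))
      ad_curve(preds, universe, batch$fp, k = config$ad_k,
               bin_width = config$ad_bin_width)
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(res, "moa_metrics")) {
      readr::write_csv(res$per_target, file.path(out_dir, "per_target.csv"))
      jsonlite::write_json(metrics_summary(res),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      readr::write_csv(res$bins, file.path(out_dir, "ad_bins.csv"))
      jsonlite::write_json(list(ad_auc = res$ad_auc, k = res$k,
                                bin_width = res$bin_width),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  res
}

metrics_summary <- function(m) {
  list(
    n_predictions = m$n, architecture = m$architecture %||% NULL,
    theta = m$theta %||% NULL,
    target_averaged = as.list(m$target_averaged),
    class_averaged = if (!is.null(m$class_averaged)) as.list(m$class_averaged),
    conditional = if (!is.null(m$conditional)) {
      list(target_averaged = as.list(m$conditional$target_averaged),
           class_averaged = if (!is.null(m$conditional$class_averaged))
             as.list(m$conditional$class_averaged))
    }
  )
}

#' Generate a synthetic benchmark dataset on disk
#'
#' Writes the annotation CSV consumed by [moa_build_data()], the hex-packed
#' fingerprints and the ground-truth manifest for a synthetic universe.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return The generated universe, invisibly.
#' @export
moa_generate <- function(out_dir, spec = synthetic_spec(), seed = spec$seed) {
  u <- generate_universe(spec, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(synthetic_annotations(u, seed = seed),
                   file.path(out_dir, "annotations.csv"))
  readr::write_csv(tibble(compound_id = rownames(u$fp),
                          fp_hex = fp_to_hex(u$fp)),
                   file.path(out_dir, "fingerprints.csv"))
  jsonlite::write_json(
    list(spec = unclass(spec), seed = seed,
         assignments = u$truth$assignments),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(u)
}
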