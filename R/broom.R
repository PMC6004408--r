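# broom-style accessors for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname arch1_tidiers
#' @export
tidy.arch1_model <- function(x, ...) x$label_index

#' Tidiers for Arch1 models
#'
#' `tidy()` returns the (target, function) label index; `glance()` a one-row
#' summary of the ensemble and its decision threshold.
#'
#' @param x An `arch1_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name arch1_tidiers
#' @export
glance.arch1_model <- function(x, ...) {
  tibble(architecture = "arch1", n_labels = nrow(x$label_index),
         n_targets = length(unique(x$label_index$target_id)),
         n_training_compounds = length(x$training_ids),
         num_trees = x$hyper$num_trees, max_depth = x$hyper$max_depth,
         mtry = x$hyper$mtry, theta = x$theta, seed = x$hyper$seed)
}

#' Tidiers for cascade models
#'
#' `tidy()` returns one row per trained target with its training-set
#' composition; `glance()` a one-row model summary.
#'
#' @param x A `cascade_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name cascade_tidiers
#' @export
tidy.cascade_model <- function(x, ...) {
  list_rbind(lapply(names(x$models), function(tid) {
    cnt <- x$models[[tid]]$stage1$counts
    tibble(target_id = tid, activating = cnt[["activating"]],
           inhibiting = cnt[["inhibiting"]],
           binding_only = cnt[["binding_only"]], inactive = cnt[["inactive"]])
  }))
}

#' @rdname cascade_tidiers
#' @export
glance.cascade_model <- function(x, ...) {
  tibble(architecture = x$architecture, n_targets = length(x$models),
         n_failed = length(attr(x, "failures")),
         num_trees = x$hyper$num_trees,
         calibration_folds = x$hyper$calibration_folds, seed = x$hyper$seed)
}

#' Tidiers for metric reports
#'
#' `tidy()` returns the per-(target, label) metric cells; `glance()` the
#' target-averaged summary row.
#'
#' @param x A `moa_metrics` report.
#' @param ... Unused.
#' @return A tibble.
#' @name metrics_tidiers
#' @export
tidy.moa_metrics <- function(x, ...) x$per_target

#' @rdname metrics_tidiers
#' @export
glance.moa_metrics <- function(x, ...) {
  out <- x$target_averaged
  if (!is.null(x$architecture)) out$architecture <- x$architecture
  out
}

#' @rdname ad_tidiers
#' @export
tidy.moa_ad_curve <- function(x, ...) x$bins

#' Tidiers for applicability-domain curves
#'
#' `tidy()` returns the populated bins; `glance()` the AD-AUC summary.
#'
#' @param x A `moa_ad_curve`.
#' @param ... Unused.
#' @return A tibble.
#' @name ad_tidiers
#' @export
glance.moa_ad_curve <- function(x, ...) {
  tibble(ad_auc = x$ad_auc, k = x$k, bin_width = x$bin_width,
         n_bins = nrow(x$bins), n_compounds = sum(x$bins$n))
}
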