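# Benchmarking protocol: stratified 5-fold cross-validation, temporal-split
# validation with a leakage guard, per-label/target/protein-class metric
# aggregation (including the conditional "correct at Stage 1" variant), the
# Kolmogorov-Smirnov architecture comparison, nearest-neighbor chemical-space
# analysis, and the applicability-domain curve with AD-AUC.

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds preserving class proportions (per-fold
#' class counts differ from `n_class / k` only by rounding). Errors when any
#' class holds fewer than `k` members.
#'
#' @param labels Character/factor vector of class labels.
#' @param k Number of folds, default 5 (must be >= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per element of `labels`.
#' @export
stratified_kfold_split <- function(labels, k = 5, seed = 1) {
  if (k < 2) abort_moa("cross-validation needs k >= 2 folds.", "moa_input_error")
  counts <- table(labels)
  if (any(counts < k)) {
    abort_moa(sprintf("class '%s' has %d members, fewer than k = %d.",
                      names(counts)[which.min(counts)], min(counts), k),
              "moa_input_error")
  }
  folds <- withr::with_seed(derive_seed(seed, "kfold"),
                            caret::createFolds(factor(labels), k = k))
  out <- integer(length(labels))
  for (f in seq_along(folds)) out[folds[[f]]] <- f
  out
}

label_confusion <- function(pred, truth, label) {
  tp <- sum(pred == label & truth == label)
  tibble(
    label = label, tp = tp, n_pred = sum(pred == label),
    n_truth = sum(truth == label)
  )
}

metric_cells <- function(df) {
  df |>
    mutate(
      precision = if_else(.data$n_pred > 0, .data$tp / .data$n_pred, 0),
      recall = if_else(.data$n_truth > 0, .data$tp / .data$n_truth, NA_real_),
      f1 = if_else(!is.na(.data$recall) & (.data$precision + .data$recall) > 0,
                   2 * .data$precision * .data$recall /
                     (.data$precision + .data$recall), 0),
      # a label absent from both truth and predictions carries no information
      valid = .data$n_truth > 0
    )
}

#' Precision / recall / F1 report over predictions
#'
#' One-vs-rest precision, recall and F1 per (target, label), with
#' target-averaged and protein-class-averaged aggregates. Follows the
#' reporting conventions of large-scale target-prediction benchmarks: a label
#' present in the truth but never predicted scores precision = recall = 0; a
#' label absent from a target's truth is excluded from that target's averages
#' rather than scored 0. When predictions carry a logical `stage1_correct`
#' column, a conditional report restricted to Stage-1 true positives is
#' computed for the functional labels.
#'
#' @param predictions Tibble with `target_id`, `final_label`, `true_label`,
#'   optionally `protein_class` and `stage1_correct`.
#' @return A `moa_metrics` object: `per_target`, `target_averaged`,
#'   `class_averaged`, and `conditional` (or `NULL`) tibbles.
#' @export
compute_metrics <- function(predictions) {
  check_columns(predictions, c("target_id", "final_label", "true_label"))
  if (nrow(predictions) == 0) abort_moa("empty prediction table.", "moa_input_error")
  per_target <- predictions |>
    group_by(.data$target_id) |>
    summarise(cells = list(list_rbind(lapply(
      FINAL_LABELS, function(lb) label_confusion(.data$final_label,
                                                 .data$true_label, lb)))),
      .groups = "drop") |>
    unnest("cells") |>
    metric_cells()
  if ("protein_class" %in% names(predictions)) {
    per_target <- per_target |>
      left_join(distinct(predictions, .data$target_id, .data$protein_class),
                by = "target_id")
  }
  out <- structure(list(
    per_target = per_target,
    target_averaged = average_over(per_target, "target_id"),
    class_averaged = if ("protein_class" %in% names(per_target)) {
      average_over(per_target, "protein_class")
    },
    conditional = NULL,
    n = nrow(predictions)
  ), class = "moa_metrics")
  if ("stage1_correct" %in% names(predictions)) {
    cond <- predictions |>
      filter(.data$true_label %in% c("activating", "inhibiting"),
             .data$stage1_correct)
    if (nrow(cond)) {
      cm <- compute_metrics(select(cond, -all_of("stage1_correct")))
      out$conditional <- list(target_averaged = cm$target_averaged,
                              class_averaged = cm$class_averaged)
    }
  }
  out
}

# Mean of the valid per-label cells within each unit (target or protein
# class), then unweighted mean +/- sd across units.
average_over <- function(per_target, unit) {
  per_unit <- per_target |>
    filter(.data$valid) |>
    group_by(.data[[unit]]) |>
    summarise(precision = mean(.data$precision), recall = mean(.data$recall),
              f1 = mean(.data$f1), .groups = "drop")
  per_unit |>
    summarise(across(all_of(c("precision", "recall", "f1")),
                     list(mean = mean, sd = ~ if (length(.x) > 1) stats::sd(.x) else 0))) |>
    mutate(n_units = nrow(per_unit), unit = unit)
}

#' @export
print.moa_metrics <- function(x, ...) {
  cat("<moa_metrics> on", x$n, "predictions\n")
  cat("target-averaged:\n"); print(as.data.frame(x$target_averaged), digits = 3)
  if (!is.null(x$class_averaged)) {
    cat("class-averaged:\n"); print(as.data.frame(x$class_averaged), digits = 3)
  }
  invisible(x)
}

## ---------------------------------------------------------- cross-validation

#' Cross-validate an architecture
#'
#' Stratified k-fold evaluation of one architecture over an assembled
#' universe. For the cascades, folds stratify jointly over the four roles;
#' binding-only compounds enter Stage 1 training folds but are never tested.
#' For Arch1, out-of-fold scores from all folds are pooled to optimize the
#' decision threshold (never test-set-tuned per fold: the threshold search
#' only ever sees out-of-fold probabilities), after which fold predictions are
#' scored; the inactive truth at a target is every tested compound not
#' functionally annotated there.
#'
#' @param universe A [moa_universe()].
#' @param architecture `"arch1"`, `"arch2"` or `"arch3"`.
#' @param k Folds, default 5.
#' @param seed Integer seed.
#' @param ... Passed to the trainers ([train_arch1()] or [train_cascade()]).
#' @return A `moa_metrics` report; the Arch1 threshold and the raw per-fold
#'   predictions are attached as fields `theta` and `predictions`.
#' @export
crossvalidate <- function(universe, architecture = c("arch1", "arch2", "arch3"),
                          k = 5, seed = 1, ...) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(universe, "moa_universe"))
  preds <- if (architecture == "arch1") {
    cv_arch1(universe, k, seed, ...)
  } else {
    cv_cascade(universe, architecture, k, seed, ...)
  }
  m <- compute_metrics(preds$predictions)
  m$architecture <- architecture
  m$k <- k
  m$theta <- preds$theta
  m$predictions <- preds$predictions
  m
}

cv_arch1 <- function(universe, k, seed, ...) {
  rows <- universe$membership |>
    filter(.data$role %in% c("activating", "inhibiting"))
  strata <- paste(rows$target_id, rows$role)
  fold <- stratified_kfold_split(strata, k = k, seed = seed)
  oof <- vector("list", k)
  for (f in seq_len(k)) {
    train_u <- moa_universe(universe$targets, rows[fold != f, , drop = FALSE],
                            universe$fp)
    model <- train_arch1(train_u, seed = derive_seed(seed, paste0("a1fold", f)), ...)
    test_ids <- unique(rows$compound_id[fold == f])
    oof[[f]] <- arch1_scores(model, universe$fp[test_ids, , drop = FALSE]) |>
      mutate(fold = f)
  }
  scores <- list_rbind(oof)
  truth <- rows |>
    mutate(true_label = .data$role) |>
    select(all_of(c("compound_id", "target_id", "true_label")))
  thr <- optimize_arch1_threshold(scores, truth)
  predictions <- scores |>
    left_join(truth, by = c("compound_id", "target_id")) |>
    mutate(true_label = dplyr::coalesce(.data$true_label, "inactive"),
           final_label = arch1_rule(.data$p_act, .data$p_inh, thr$theta),
           p_bind = NA_real_) |>
    left_join(universe$targets, by = "target_id")
  list(predictions = predictions, theta = thr$theta)
}

cv_cascade <- function(universe, architecture, k, seed, ...) {
  out <- vector("list", nrow(universe$targets))
  for (i in seq_len(nrow(universe$targets))) {
    tid <- universe$targets$target_id[i]
    memb <- universe$membership |> filter(.data$target_id == tid)
    fold <- stratified_kfold_split(memb$role, k = k,
                                   seed = derive_seed(seed, paste0("cv", tid)))
    fold_preds <- vector("list", k)
    for (f in seq_len(k)) {
      train_u <- moa_universe(universe$targets[i, , drop = FALSE],
                              memb[fold != f, , drop = FALSE], universe$fp)
      s1 <- train_stage1(train_u, tid, seed = derive_seed(seed, paste0("f", f)))
      s2 <- if (architecture == "arch2") {
        train_stage2_arch2(train_u, tid, seed = derive_seed(seed, paste0("f", f)))
      } else {
        train_stage2_arch3(train_u, tid, seed = derive_seed(seed, paste0("f", f)))
      }
      test <- memb[fold == f & memb$role != "binding_only", , drop = FALSE]
      p <- cascade_predict(s1, s2, universe$fp[test$compound_id, , drop = FALSE])
      p$true_label <- if_else(test$role == "inactive", "inactive", test$role)
      p$fold <- f
      fold_preds[[f]] <- p
    }
    out[[i]] <- list_rbind(fold_preds)
  }
  predictions <- list_rbind(out) |>
    mutate(stage1_correct = .data$true_label %in% c("activating", "inhibiting") &
             .data$p_bind > 0.5) |>
    left_join(universe$targets, by = "target_id")
  list(predictions = predictions, theta = NULL)
}

#' Temporal (prospective) validation
#'
#' Evaluates trained models on a later-period batch. Training/test compound-id
#' overlap is a hard error (leakage guard). Only class-averaged metrics are
#' emphasized, since per-target test sets in a temporal batch can be very
#' small; the conditional Stage-1-correct variant is included for cascades.
#'
#' @param model A `cascade_model` or `arch1_model` (threshold set).
#' @param batch A `moa_temporal_batch` (or list with `annotations` containing
#'   `compound_id`, `target_id`, `true_label`, optionally `protein_class`, and
#'   a fingerprint matrix `fp`).
#' @return A `moa_metrics` report.
#' @export
temporal_validate <- function(model, batch) {
  ann <- batch$annotations
  check_columns(ann, c("compound_id", "target_id", "true_label"))
  leaked <- intersect(unique(ann$compound_id), model$training_ids)
  if (length(leaked)) {
    abort_moa(paste0(length(leaked), " test compound id(s) occur in training data."),
              "moa_leak_error")
  }
  preds <- if (inherits(model, "cascade_model")) {
    predict(model, batch$fp, targets = intersect(names(model$models),
                                                 unique(ann$target_id)))
  } else {
    predict(model, batch$fp)
  }
  preds <- preds |>
    inner_join(ann, by = c("compound_id", "target_id"))
  if (inherits(model, "cascade_model")) {
    preds$stage1_correct <- preds$true_label %in% c("activating", "inhibiting") &
      preds$p_bind > 0.5
  }
  m <- compute_metrics(preds)
  m$predictions <- preds
  m
}

#' Two-sample Kolmogorov-Smirnov comparison of metric distributions
#'
#' Compares per-target metric values (e.g. activating F1 under two
#' architectures); the statistic is the maximum ECDF gap, significance read at
#' the 0.05 level.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @return Tibble: `statistic`, `p_value`, `significant`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    abort_moa("both samples must be non-empty.", "moa_input_error")
  }
  kt <- suppressWarnings(ks.test(values_a, values_b))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         significant = kt$p.value < 0.05)
}

#' Nearest-neighbor similarity between compound sets
#'
#' For each target, computes per-compound nearest-neighbor (maximum) Tanimoto
#' similarity for the three pairings: activating into inhibiting (`A-I`),
#' binding-only into activating (`B-A`) and binding-only into inhibiting
#' (`B-I`). Pairings with an empty set are skipped with a warning.
#'
#' @param universe A [moa_universe()].
#' @return Tibble: `target_id`, `pairing`, `compound_id`, `nn_tc`.
#' @export
nn_similarity_analysis <- function(universe) {
  pairings <- list(`A-I` = c("activating", "inhibiting"),
                   `B-A` = c("binding_only", "activating"),
                   `B-I` = c("binding_only", "inhibiting"))
  out <- list()
  for (tid in universe$targets$target_id) {
    for (p in names(pairings)) {
      x <- role_fp(universe, tid, pairings[[p]][1])
      y <- role_fp(universe, tid, pairings[[p]][2])
      if (nrow(x) == 0 || nrow(y) == 0) {
        warning("pairing ", p, " skipped for target ", tid, " (empty set).")
        next
      }
      out[[paste(tid, p)]] <- tibble(
        target_id = tid, pairing = p, compound_id = rownames(x),
        nn_tc = unname(apply(tanimoto_matrix(x, y), 1, max))
      )
    }
  }
  list_rbind(out)
}

#' @rdname nn_similarity_analysis
#' @param nn Output of `nn_similarity_analysis()`.
#' @return `nn_similarity_medians`: overall median nearest-neighbor similarity
#'   per pairing.
#' @export
nn_similarity_medians <- function(nn) {
  nn |>
    group_by(.data$pairing) |>
    summarise(median_tc = median(.data$nn_tc), n = n(), .groups = "drop")
}

#' Applicability-domain curve and AD-AUC
#'
#' Assigns every functional test compound its mean k-nearest-neighbor
#' similarity to the training compounds of its true label at its target, bins
#' the similarities (width `bin_width`), and computes the per-bin true
#' positive rate (recall of the true functional label). The AD-AUC is the
#' trapezoidal area of TPR over the distance axis (1 - similarity), taken over
#' populated bins; since the distance axis spans \[0, 1\], the area is already
#' on that normalized scale.
#'
#' @param predictions Tibble with `compound_id`, `target_id`, `true_label` in
#'   `c("activating", "inhibiting")` and `final_label`.
#' @param universe The training [moa_universe()] providing per-label reference
#'   fingerprints.
#' @param fp Fingerprint matrix of the test compounds.
#' @param k Neighbors for the mean similarity, default 5 (reduced with a
#'   warning when a training set is smaller).
#' @param bin_width Similarity bin width, default 0.05.
#' @return A `moa_ad_curve`: `bins` tibble (`bin_low`, `bin_high`, `n`,
#'   `tpr`), `ad_auc`, `k`, `bin_width`.
#' @export
ad_curve <- function(predictions, universe, fp, k = 5, bin_width = 0.05) {
  check_columns(predictions, c("compound_id", "target_id", "true_label",
                               "final_label"))
  preds <- predictions |>
    filter(.data$true_label %in% c("activating", "inhibiting"))
  if (nrow(preds) == 0) abort_moa("no functional test compounds.", "moa_input_error")
  sim <- numeric(nrow(preds))
  for (grp in split(seq_len(nrow(preds)),
                    paste(preds$target_id, preds$true_label))) {
    ref <- role_fp(universe, preds$target_id[grp[1]], preds$true_label[grp[1]])
    sim[grp] <- knn_mean_similarity(fp[preds$compound_id[grp], , drop = FALSE],
                                    ref, k = min(k, nrow(ref)))
  }
  edges <- seq(0, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  idx <- pmin(findInterval(sim, edges, rightmost.closed = TRUE), length(edges) - 1)
  correct <- preds$final_label == preds$true_label
  bins <- tibble(bin = idx, correct = correct) |>
    group_by(.data$bin) |>
    summarise(n = n(), tpr = mean(.data$correct), .groups = "drop") |>
    mutate(bin_low = edges[.data$bin], bin_high = edges[.data$bin + 1],
           bin_mid = (.data$bin_low + .data$bin_high) / 2,
           distance = 1 - .data$bin_mid) |>
    arrange(.data$distance)
  ad_auc <- if (nrow(bins) > 1) pracma::trapz(bins$distance, bins$tpr) else 0
  structure(list(bins = select(bins, all_of(c("bin_low", "bin_high", "bin_mid",
                                              "distance", "n", "tpr"))),
                 ad_auc = ad_auc, k = k, bin_width = bin_width,
                 similarities = tibble(compound_id = preds$compound_id,
                                       target_id = preds$target_id,
                                       similarity = sim, correct = correct)),
            class = "moa_ad_curve")
}

#' @export
print.moa_ad_curve <- function(x, ...) {
  cat("<moa_ad_curve> ", nrow(x$bins), " populated bins (width ", x$bin_width,
      "), k = ", x$k, ", AD-AUC = ", round(x$ad_auc, 4), "\n", sep = "")
  print(as.data.frame(x$bins), digits = 3)
  invisible(x)
}
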