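# The three prediction architectures: a single multi-label random forest over
# all target-function effects (Arch1, with an F1-optimized decision threshold)
# and two cascaded designs sharing a per-target binding gate (Stage 1) but
# differing in Stage 2 - a single calibrated activator-vs-inhibitor forest
# (Arch2) or two independently calibrated one-vs-inactive forests (Arch3).

FINAL_LABELS <- c("inactive", "activating", "inhibiting")

rf_defaults <- function() list(num_trees = 100L, mtry_heuristic = "sqrt")

fit_rf <- function(x, y, num_trees = 100, max_depth = 0, case_weights = NULL,
                   seed = 1) {
  ranger::ranger(
    x = x, y = y, probability = TRUE, num.trees = num_trees,
    mtry = floor(sqrt(ncol(x))), max.depth = max_depth,
    case.weights = case_weights, seed = seed, num.threads = 1
  )
}

rf_prob <- function(forest, x, class) {
  p <- predict(forest, data = x, num.threads = 1)$predictions
  p[, class]
}

#' Fit a Platt scaling sigmoid
#'
#' Fits \eqn{\sigma(s) = 1/(1 + \exp(A s + B))} to raw classifier scores by
#' maximum likelihood (the minimizer of the calibration log-loss), via
#' unregularized logistic regression. Calibrated outputs are monotone in the
#' raw score.
#'
#' @param raw_scores Numeric vector of classifier scores.
#' @param binary_labels Logical/0-1 vector: `TRUE` for the positive class.
#'   Both classes must be present.
#' @return A `platt_scaling` object with elements `A` and `B`.
#' @export
platt_fit <- function(raw_scores, binary_labels) {
  y <- as.integer(as.logical(binary_labels))
  if (length(raw_scores) != length(y)) {
    abort_moa("scores and labels differ in length.", "moa_input_error")
  }
  if (length(unique(y)) < 2) {
    abort_moa("both classes must be present to fit a calibration sigmoid.",
              "moa_calibration_error")
  }
  fit <- suppressWarnings(glm(y ~ raw_scores, family = binomial()))
  co <- stats::coef(fit)
  structure(list(A = unname(-co[2]), B = unname(-co[1])), class = "platt_scaling")
}

#' @rdname platt_fit
#' @param fit A `platt_scaling` object.
#' @param scores Numeric scores to calibrate.
#' @return `platt_apply`: calibrated probabilities in (0, 1).
#' @export
platt_apply <- function(fit, scores) {
  stopifnot(inherits(fit, "platt_scaling"))
  1 / (1 + exp(fit$A * scores + fit$B))
}

#' @export
predict.platt_scaling <- function(object, scores, ...) platt_apply(object, scores)

# Out-of-fold scores from an internal stratified CV, used to fit one
# deterministic calibration sigmoid per stage-2 model.
oof_calibration <- function(x, y, positive, folds = 3, num_trees = 100, seed = 1) {
  counts <- table(y)
  if (any(counts < folds)) {
    abort_moa(sprintf(
      "calibration needs at least %d members per class (have: %s).", folds,
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
      "moa_calibration_error")
  }
  fold <- stratified_kfold_split(as.character(y), k = folds,
                                 seed = derive_seed(seed, "calibration"))
  oof <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- fit_rf(x[tr, , drop = FALSE], droplevels(y[tr]),
                  num_trees = num_trees, seed = derive_seed(seed, paste0("cal", f)))
    oof[!tr] <- rf_prob(fit, x[!tr, , drop = FALSE], positive)
  }
  platt_fit(oof, y == positive)
}

## ---------------------------------------------------------------- Arch1 ----

#' Train the single multi-label architecture (Arch1)
#'
#' One probability random forest (100 trees, depth 20, sqrt-feature sampling)
#' over every (target, functional label) effect. Each training row is one
#' compound-target-function annotation, so a promiscuous compound contributes
#' one row per annotation and the predicted probabilities over all effects sum
#' to 1 per compound. The decision threshold `theta` is unset until assigned
#' from cross-validated scores via [optimize_arch1_threshold()] and
#' [arch1_set_threshold()].
#'
#' @param universe A [moa_universe()]; only activating/inhibiting members are
#'   used (Arch1 ignores binding and inactive data).
#' @param num_trees,max_depth Forest size and depth (defaults 100 and 20).
#' @param seed Integer seed.
#' @return An `arch1_model`.
#' @export
train_arch1 <- function(universe, num_trees = 100, max_depth = 20, seed = 1) {
  stopifnot(inherits(universe, "moa_universe"))
  rows <- universe$membership |>
    filter(.data$role %in% c("activating", "inhibiting"))
  if (nrow(rows) == 0) abort_moa("no functional training data.", "moa_input_error")
  labels <- paste(rows$target_id, rows$role, sep = "::")
  if (length(unique(labels)) < 2) {
    abort_moa("at least two distinct (target, function) labels are required.",
              "moa_input_error")
  }
  x <- universe$fp[rows$compound_id, , drop = FALSE]
  y <- factor(labels)
  forest <- fit_rf(x, y, num_trees = num_trees,
                   max_depth = max_depth, seed = derive_seed(seed, "arch1"))
  parts <- strsplit(levels(y), "::", fixed = TRUE)
  label_index <- tibble(
    label = levels(y),
    target_id = vapply(parts, `[`, character(1), 1),
    role = vapply(parts, `[`, character(1), 2)
  )
  structure(list(
    forest = forest, label_index = label_index, theta = NA_real_,
    targets = universe$targets,
    training_ids = unique(rows$compound_id),
    hyper = list(num_trees = num_trees, max_depth = max_depth,
                 mtry = floor(sqrt(ncol(x))), seed = seed)
  ), class = "arch1_model")
}

# Raw per-label probability table for a fingerprint matrix: one row per
# compound x target with p_act / p_inh columns (0 for absent labels).
arch1_scores <- function(model, fp) {
  fp <- fp_matrix(fp)
  p <- predict(model$forest, data = fp, num.threads = 1)$predictions
  ids <- rownames(fp) %||% as.character(seq_len(nrow(fp)))
  idx <- model$label_index
  out <- vector("list", nrow(model$targets))
  for (i in seq_len(nrow(model$targets))) {
    tid <- model$targets$target_id[i]
    a <- idx$label[idx$target_id == tid & idx$role == "activating"]
    b <- idx$label[idx$target_id == tid & idx$role == "inhibiting"]
    out[[i]] <- tibble(
      compound_id = ids, target_id = tid,
      p_act = if (length(a)) p[, a] else 0,
      p_inh = if (length(b)) p[, b] else 0
    )
  }
  list_rbind(out)
}

#' Arch1 thresholded decision rule
#'
#' Functional labels with probability at or above `theta` are candidate calls;
#' when both functions pass, the larger probability wins (exact tie goes to
#' inhibiting); when neither passes, the call is inactive. With
#' `p_act = 0.15`, `p_inh = 0.05` and `theta = 0.092` the call is activating.
#'
#' @param p_act,p_inh Numeric probability vectors.
#' @param theta Decision threshold in \[0, 1\].
#' @return Character vector of final labels.
#' @export
arch1_rule <- function(p_act, p_inh, theta) {
  pass_a <- p_act >= theta
  pass_i <- p_inh >= theta
  dplyr::case_when(
    pass_a & pass_i & p_act > p_inh ~ "activating",
    pass_a & pass_i ~ "inhibiting",
    pass_a ~ "activating",
    pass_i ~ "inhibiting",
    TRUE ~ "inactive"
  )
}

#' Optimize the Arch1 decision threshold
#'
#' Exhaustive search over 100 candidate thresholds - the 1st..100th
#' percentiles of the pooled cross-validated score distribution - for the
#' threshold maximizing the mean F1-score over the inactive, activating and
#' inhibiting labels. Ties break toward the larger threshold. Scores must come
#' from out-of-fold (never training-set) predictions.
#'
#' @param scores Tibble from cross-validated Arch1 scoring with columns
#'   `compound_id`, `target_id`, `p_act`, `p_inh`.
#' @param truth Tibble `compound_id`, `target_id`, `true_label`; pairs absent
#'   from `truth` are treated as inactive.
#' @return An `arch1_threshold` object: `theta`, plus the full `grid` searched.
#' @export
optimize_arch1_threshold <- function(scores, truth) {
  check_columns(scores, c("compound_id", "target_id", "p_act", "p_inh"))
  check_columns(truth, c("compound_id", "target_id", "true_label"))
  if (nrow(scores) == 0) abort_moa("empty score table.", "moa_input_error")
  joined <- scores |>
    left_join(truth, by = c("compound_id", "target_id")) |>
    mutate(true_label = dplyr::coalesce(.data$true_label, "inactive"))
  pooled <- c(joined$p_act, joined$p_inh)
  grid <- unique(quantile(pooled, probs = seq(0.01, 1, by = 0.01), names = FALSE,
                          type = 7))
  f1s <- vapply(grid, function(th) {
    pred <- arch1_rule(joined$p_act, joined$p_inh, th)
    mean(vapply(FINAL_LABELS, function(lb) {
      tp <- sum(pred == lb & joined$true_label == lb)
      np <- sum(pred == lb); nt <- sum(joined$true_label == lb)
      pr <- if (np > 0) tp / np else 0
      rc <- if (nt > 0) tp / nt else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }, numeric(1)))
  }, numeric(1))
  best <- max(grid[f1s == max(f1s)])
  structure(list(theta = best, grid = tibble(theta = grid, mean_f1 = f1s)),
            class = "arch1_threshold")
}

#' Set the Arch1 decision threshold
#'
#' The threshold can only be assigned from an [optimize_arch1_threshold()]
#' result, which enforces that it was derived from cross-validated scores.
#'
#' @param model An `arch1_model`.
#' @param threshold An `arch1_threshold` object.
#' @return The model with `theta` set.
#' @export
arch1_set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "arch1_model"))
  if (!inherits(threshold, "arch1_threshold")) {
    abort_moa("`threshold` must come from optimize_arch1_threshold().",
              "moa_input_error")
  }
  model$theta <- threshold$theta
  model
}

#' Predict with Arch1
#'
#' Applies the thresholded decision rule per target: candidate labels are
#' those with probability at or above `theta`; when both functions pass the
#' larger probability wins (exact tie goes to inhibiting, the majority prior);
#' when none passes the compound is inactive at that target.
#'
#' @param object A trained `arch1_model` with `theta` set.
#' @param fp Fingerprint matrix (or tibble with `fingerprint` list-column).
#' @param theta Optional override; defaults to the model's threshold.
#' @param ... Unused.
#' @return Tibble: `compound_id`, `target_id`, `p_bind` (`NA`; Arch1 has no
#'   binding stage), `p_act`, `p_inh`, `final_label`.
#' @export
predict.arch1_model <- function(object, fp, theta = object$theta, ...) {
  if (is.na(theta)) {
    abort_moa("Arch1 threshold unset; run optimize_arch1_threshold() + arch1_set_threshold().",
              "moa_threshold_error")
  }
  arch1_scores(object, fp) |>
    mutate(p_bind = NA_real_,
           final_label = arch1_rule(.data$p_act, .data$p_inh, theta)) |>
    select(all_of(c("compound_id", "target_id", "p_bind", "p_act", "p_inh",
                    "final_label")))
}

## -------------------------------------------------------------- Cascades ----

#' Train a Stage 1 binding gate
#'
#' Per-target binary random forest (100 trees, unlimited depth) separating all
#' actives (activating, inhibiting and binding-only compounds) from the
#' inactive set. Class imbalance is countered twice, as prescribed: balanced
#' class weights (inverse class frequency) composed with per-instance weights
#' equal to the inactive:active ratio for actives; the instance component can
#' be disabled with `use_instance_weights = FALSE`.
#'
#' @param universe A [moa_universe()].
#' @param target_id Target to train.
#' @param num_trees Forest size, default 100.
#' @param use_instance_weights Apply the ratio-based instance weights on top of
#'   balanced class weights, default `TRUE`.
#' @param seed Integer seed.
#' @return A `stage1_model`.
#' @export
train_stage1 <- function(universe, target_id, num_trees = 100,
                         use_instance_weights = TRUE, seed = 1) {
  act_ids <- unlist(lapply(c("activating", "inhibiting", "binding_only"),
                           function(r) role_ids(universe, target_id, r)))
  ina_ids <- role_ids(universe, target_id, "inactive")
  if (!length(act_ids) || !length(ina_ids)) {
    abort_moa("Stage 1 needs both active and inactive compounds.",
              "moa_input_error")
  }
  ids <- c(act_ids, ina_ids)
  y <- factor(rep(c("active", "inactive"), c(length(act_ids), length(ina_ids))))
  x <- universe$fp[ids, , drop = FALSE]
  n <- length(y)
  w_bal <- n / (2 * table(y)[as.character(y)])
  w <- as.numeric(w_bal)
  if (use_instance_weights) {
    ratio <- length(ina_ids) / length(act_ids)
    w <- w * if_else(y == "active", ratio, 1)
  }
  forest <- fit_rf(x, y, num_trees = num_trees, case_weights = w,
                   seed = derive_seed(seed, paste0("stage1_", target_id)))
  structure(list(
    forest = forest, target_id = target_id,
    counts = c(activating = length(role_ids(universe, target_id, "activating")),
               inhibiting = length(role_ids(universe, target_id, "inhibiting")),
               binding_only = length(role_ids(universe, target_id, "binding_only")),
               inactive = length(ina_ids)),
    training_ids = ids,
    hyper = list(num_trees = num_trees, use_instance_weights = use_instance_weights,
                 seed = seed)
  ), class = "stage1_model")
}

#' @export
predict.stage1_model <- function(object, fp, ...) {
  rf_prob(object$forest, fp_matrix(fp), "active")
}

#' Train a Stage 2 activator-vs-inhibitor classifier (Arch2)
#'
#' Per-target random forest on the activating and inhibiting compounds,
#' Platt-calibrated with 3 internal stratified folds, so the two output
#' probabilities are complementary likelihoods (`p_act + p_inh = 1`).
#'
#' @inheritParams train_stage1
#' @param calibration_folds Internal calibration folds, default 3; each class
#'   must have at least this many members.
#' @return A `stage2_arch2` model.
#' @export
train_stage2_arch2 <- function(universe, target_id, calibration_folds = 3,
                               num_trees = 100, seed = 1) {
  a <- role_ids(universe, target_id, "activating")
  b <- role_ids(universe, target_id, "inhibiting")
  if (!length(a) || !length(b)) {
    abort_moa("both functional classes are required.", "moa_input_error")
  }
  ids <- c(a, b)
  y <- factor(rep(c("activator", "inhibitor"), c(length(a), length(b))))
  x <- universe$fp[ids, , drop = FALSE]
  cal <- oof_calibration(x, y, positive = "activator", folds = calibration_folds,
                         num_trees = num_trees,
                         seed = derive_seed(seed, paste0("s2a2_", target_id)))
  forest <- fit_rf(x, y, num_trees = num_trees,
                   seed = derive_seed(seed, paste0("s2a2f_", target_id)))
  structure(list(
    forest = forest, calibration = cal, target_id = target_id,
    counts = c(activating = length(a), inhibiting = length(b)),
    training_ids = ids,
    hyper = list(num_trees = num_trees, calibration_folds = calibration_folds,
                 seed = seed)
  ), class = "stage2_arch2")
}

#' @export
predict.stage2_arch2 <- function(object, fp, ...) {
  raw <- rf_prob(object$forest, fp_matrix(fp), "activator")
  p_act <- platt_apply(object$calibration, raw)
  tibble(p_act = p_act, p_inh = 1 - p_act)
}

#' Train Stage 2 one-vs-inactive classifiers (Arch3)
#'
#' Two independent per-target random forests - activator-vs-inactive and
#' inhibitor-vs-inactive - each Platt-calibrated with 3 internal folds so
#' their probabilities are directly comparable despite being distinct models.
#' The two outputs need not sum to 1.
#'
#' @inheritParams train_stage2_arch2
#' @return A `stage2_arch3` model.
#' @export
train_stage2_arch3 <- function(universe, target_id, calibration_folds = 3,
                               num_trees = 100, seed = 1) {
  a <- role_ids(universe, target_id, "activating")
  b <- role_ids(universe, target_id, "inhibiting")
  ina <- role_ids(universe, target_id, "inactive")
  if (!length(a) || !length(b)) {
    abort_moa("both functional classes are required.", "moa_input_error")
  }
  if (!length(ina)) abort_moa("Arch3 requires an inactive set.", "moa_input_error")
  fit_one <- function(pos_ids, pos_label, tag) {
    ids <- c(pos_ids, ina)
    y <- factor(rep(c(pos_label, "inactive"), c(length(pos_ids), length(ina))),
                levels = c(pos_label, "inactive"))
    x <- universe$fp[ids, , drop = FALSE]
    cal <- oof_calibration(x, y, positive = pos_label, folds = calibration_folds,
                           num_trees = num_trees,
                           seed = derive_seed(seed, paste0(tag, target_id)))
    forest <- fit_rf(x, y, num_trees = num_trees,
                     seed = derive_seed(seed, paste0(tag, "f", target_id)))
    list(forest = forest, calibration = cal, positive = pos_label)
  }
  structure(list(
    act_model = fit_one(a, "activator", "s2a3a_"),
    inh_model = fit_one(b, "inhibitor", "s2a3i_"),
    target_id = target_id,
    counts = c(activating = length(a), inhibiting = length(b),
               inactive = length(ina)),
    training_ids = unique(c(a, b, ina)),
    hyper = list(num_trees = num_trees, calibration_folds = calibration_folds,
                 seed = seed)
  ), class = "stage2_arch3")
}

#' @export
predict.stage2_arch3 <- function(object, fp, ...) {
  fp <- fp_matrix(fp)
  one <- function(m) platt_apply(m$calibration, rf_prob(m$forest, fp, m$positive))
  tibble(p_act = one(object$act_model), p_inh = one(object$inh_model))
}

#' Cascaded decision rule
#'
#' The gating and argmax logic shared by both cascades: `p_bind` at or below
#' 0.5 is inactive (strict greater-than gate) and Stage 2 probabilities are
#' ignored; past the gate a functional label is always forced - activating
#' when `p_act > p_inh`, inhibiting otherwise (exact ties go to inhibiting).
#'
#' @param p_bind,p_act,p_inh Numeric vectors (recycled to a common length);
#'   `p_act`/`p_inh` may be `NA` for gated-out compounds.
#' @return Character vector of final labels.
#' @export
cascade_rule <- function(p_bind, p_act, p_inh) {
  dplyr::case_when(
    p_bind <= 0.5 ~ "inactive",
    p_act > p_inh ~ "activating",
    TRUE ~ "inhibiting"
  )
}

#' Cascaded prediction for one target
#'
#' Stage 1 gates on `p_bind > 0.5` (a compound at exactly 0.5 is inactive, per
#' the strict greater-than rule); gated-out compounds are labeled inactive and
#' never reach Stage 2. Compounds passing the gate always receive a functional
#' label: activating when `p_act > p_inh`, inhibiting otherwise (exact ties go
#' to inhibiting, the majority prior).
#'
#' @param stage1 A `stage1_model`.
#' @param stage2 A `stage2_arch2` or `stage2_arch3` model for the same target.
#' @param fp Fingerprint matrix or tibble with a `fingerprint` list-column.
#' @return Tibble: `compound_id`, `target_id`, `p_bind`, `p_act`, `p_inh`,
#'   `final_label`.
#' @export
cascade_predict <- function(stage1, stage2, fp) {
  stopifnot(inherits(stage1, "stage1_model"),
            inherits(stage2, "stage2_arch2") || inherits(stage2, "stage2_arch3"))
  if (!identical(stage1$target_id, stage2$target_id)) {
    abort_moa("Stage 1 and Stage 2 models belong to different targets.",
              "moa_input_error")
  }
  fp <- fp_matrix(fp)
  ids <- rownames(fp) %||% as.character(seq_len(nrow(fp)))
  p_bind <- predict(stage1, fp)
  out <- tibble(compound_id = ids, target_id = stage1$target_id,
                p_bind = p_bind, p_act = NA_real_, p_inh = NA_real_,
                final_label = "inactive")
  pass <- p_bind > 0.5
  if (any(pass)) {
    s2 <- predict(stage2, fp[pass, , drop = FALSE])
    out$p_act[pass] <- s2$p_act
    out$p_inh[pass] <- s2$p_inh
  }
  out$final_label <- cascade_rule(out$p_bind, out$p_act, out$p_inh)
  out
}

#' Train a full cascaded architecture over a universe
#'
#' Trains the shared Stage 1 binding gate plus the architecture's Stage 2
#' model(s) for every target (or the subset given). Per-target failures are
#' collected, not fatal: failed targets appear in the `"failures"` attribute.
#'
#' @param universe A [moa_universe()].
#' @param architecture `"arch2"` or `"arch3"`.
#' @param targets Optional character vector of targets, default all.
#' @param calibration_folds,num_trees,seed Passed to the stage trainers.
#' @param use_instance_weights Stage 1 instance weighting switch.
#' @return A `cascade_model` holding per-target `stage1`/`stage2` pairs.
#' @export
train_cascade <- function(universe, architecture = c("arch2", "arch3"),
                          targets = NULL, calibration_folds = 3,
                          num_trees = 100, use_instance_weights = TRUE,
                          seed = 1) {
  architecture <- match.arg(architecture)
  targets <- targets %||% universe$targets$target_id
  models <- list(); failures <- list()
  for (tid in targets) {
    res <- tryCatch({
      s1 <- train_stage1(universe, tid, num_trees = num_trees,
                         use_instance_weights = use_instance_weights, seed = seed)
      s2 <- if (architecture == "arch2") {
        train_stage2_arch2(universe, tid, calibration_folds, num_trees, seed)
      } else {
        train_stage2_arch3(universe, tid, calibration_folds, num_trees, seed)
      }
      list(stage1 = s1, stage2 = s2)
    }, moacascade_error = function(e) e)
    if (inherits(res, "error")) failures[[tid]] <- conditionMessage(res)
    else models[[tid]] <- res
  }
  out <- structure(list(
    architecture = architecture, models = models, targets = universe$targets,
    training_ids = unique(unlist(lapply(models, function(m) m$stage1$training_ids))),
    hyper = list(num_trees = num_trees, calibration_folds = calibration_folds,
                 use_instance_weights = use_instance_weights, seed = seed)
  ), class = "cascade_model")
  attr(out, "failures") <- failures
  out
}

#' Predict with a cascaded architecture
#'
#' @param object A `cascade_model`.
#' @param fp Fingerprint matrix or tibble.
#' @param targets Optional subset of targets.
#' @param ... Unused.
#' @return Tibble with one row per compound x target.
#' @export
predict.cascade_model <- function(object, fp, targets = NULL, ...) {
  targets <- targets %||% names(object$models)
  list_rbind(lapply(targets, function(tid) {
    m <- object$models[[tid]]
    if (is.null(m)) abort_moa(paste0("no model for target ", tid), "moa_input_error")
    cascade_predict(m$stage1, m$stage2, fp)
  }))
}
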