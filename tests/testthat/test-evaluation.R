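# Folds, metrics, KS comparison, nearest-neighbor analysis, AD curves,
# cross-validation and temporal validation.

test_that("stratified folds preserve class ratios and partition exactly", {
  labels <- rep(c("act", "inh"), c(50, 250))
  fold <- stratified_kfold_split(labels, k = 5, seed = 3)
  for (f in 1:5) {
    expect_identical(sum(fold == f & labels == "act"), 10L)
    expect_identical(sum(fold == f & labels == "inh"), 50L)
  }
  # partition: disjoint and covering
  expect_identical(sort(unique(fold)), 1:5)
  expect_length(fold, 300)
  # non-divisible counts stay within one of n/k
  labels2 <- rep(c("a", "b"), c(11, 23))
  fold2 <- stratified_kfold_split(labels2, k = 5, seed = 3)
  cnt <- table(fold2, labels2)
  expect_true(all(abs(cnt[, "a"] - 11 / 5) < 1))
  expect_true(all(abs(cnt[, "b"] - 23 / 5) < 1))
  expect_error(stratified_kfold_split(rep(c("a", "b"), c(3, 50)), k = 5),
               class = "moa_input_error")
  expect_error(stratified_kfold_split(labels, k = 1), class = "moa_input_error")
})

test_that("metric cells match hand-computed confusion matrices", {
  all_right <- tibble::tibble(target_id = "T1",
                              true_label = rep(c("activating", "inhibiting",
                                                 "inactive"), each = 5),
                              final_label = rep(c("activating", "inhibiting",
                                                  "inactive"), each = 5))
  m <- compute_metrics(all_right)
  expect_true(all(m$per_target$precision == 1 & m$per_target$recall == 1 &
                    m$per_target$f1 == 1))
  # TP = 8, FP = 2, FN = 2 for the activating label
  tp8 <- tibble::tibble(
    target_id = "T1",
    true_label = c(rep("activating", 10), rep("inhibiting", 10)),
    final_label = c(rep("activating", 8), "inhibiting", "inhibiting",
                    "activating", "activating", rep("inhibiting", 8))
  )
  cell <- compute_metrics(tp8)$per_target
  act <- cell[cell$label == "activating", ]
  expect_equal(act$precision, 0.8)
  expect_equal(act$recall, 0.8)
  expect_equal(act$f1, 0.8)
  # 30-compound randomized oracle vs manual confusion matrices
  withr::with_seed(41, {
    toy <- tibble::tibble(
      target_id = rep(c("T1", "T2"), each = 15),
      true_label = sample(c("activating", "inhibiting", "inactive"), 30, TRUE),
      final_label = sample(c("activating", "inhibiting", "inactive"), 30, TRUE)
    )
  })
  rep_ <- compute_metrics(toy)$per_target
  for (i in seq_len(nrow(rep_))) {
    sub <- toy[toy$target_id == rep_$target_id[i], ]
    tp <- sum(sub$final_label == rep_$label[i] & sub$true_label == rep_$label[i])
    npred <- sum(sub$final_label == rep_$label[i])
    ntruth <- sum(sub$true_label == rep_$label[i])
    expect_equal(rep_$tp[i], tp)
    expect_equal(rep_$precision[i], if (npred) tp / npred else 0)
    if (ntruth) expect_equal(rep_$recall[i], tp / ntruth)
  }
  # F1 identity holds on every valid cell
  ok <- rep_[rep_$valid, ]
  expect_equal(ok$f1, ifelse(ok$precision + ok$recall > 0,
                             2 * ok$precision * ok$recall /
                               (ok$precision + ok$recall), 0))
  expect_error(compute_metrics(toy[0, ]), class = "moa_input_error")
})

test_that("KS comparison equals the maximum ECDF gap", {
  expect_equal(suppressWarnings(ks_compare(1:10, 1:10))$statistic, 0)
  disjoint <- ks_compare(rep(0.1, 8), rep(0.9, 8))
  expect_equal(disjoint$statistic, 1)
  withr::with_seed(5, { a <- runif(20); b <- runif(20)^2 })
  got <- ks_compare(a, b)
  # direct ECDF enumeration oracle
  pts <- sort(c(a, b))
  gap <- max(abs(sapply(pts, function(x) mean(a <= x) - mean(b <= x))))
  expect_equal(got$statistic, gap)
  expect_error(ks_compare(numeric(0), a), class = "moa_input_error")
})

test_that("nearest-neighbor analysis equals row maxima of the Tc matrix", {
  A <- rand_fp(5, seed = 1, prefix = "a")
  I <- rand_fp(5, seed = 2, prefix = "i")
  B <- rand_fp(5, seed = 3, prefix = "bo")
  u <- manual_universe(list(activating = A, inhibiting = I, binding_only = B,
                            inactive = rand_fp(5, seed = 4, prefix = "n")))
  nn <- nn_similarity_analysis(u)
  expect_equal(nn$nn_tc[nn$pairing == "A-I"],
               unname(apply(tanimoto_matrix(A, I), 1, max)))
  expect_equal(nn$nn_tc[nn$pairing == "B-I"],
               unname(apply(tanimoto_matrix(B, I), 1, max)))
  # activating set duplicating inhibitor structures: all A-I similarities are 1
  A2 <- I[1:3, , drop = FALSE]
  rownames(A2) <- paste0("adup", 1:3)
  u2 <- manual_universe(list(activating = A2, inhibiting = I))
  nn2 <- suppressWarnings(nn_similarity_analysis(u2))
  expect_true(all(nn2$nn_tc[nn2$pairing == "A-I"] == 1))
  # orthogonal sets: all zero
  X <- diag(10L)[1:3, ]; rownames(X) <- paste0("x", 1:3)
  Y <- diag(10L)[4:6, ]; rownames(Y) <- paste0("y", 1:3)
  colnames(X) <- colnames(Y) <- paste0("b", 1:10)
  u3 <- manual_universe(list(activating = X, inhibiting = Y))
  nn3 <- suppressWarnings(nn_similarity_analysis(u3))
  expect_true(all(nn3$nn_tc[nn3$pairing == "A-I"] == 0))
})

test_that("AD curve matches a hand-binned trapezoid on a 12-point toy set", {
  # training reference: one fingerprint per label with bits 1..20 on; a test
  # compound sharing j bits has similarity j / (40 - j)
  n_bits <- 60
  ref <- matrix(0L, 1, n_bits, dimnames = list("ref", paste0("b", 1:n_bits)))
  ref[1, 1:20] <- 1L
  shared <- c(20, 19, 18, 16, 14, 12, 10, 7, 6, 5, 4, 3)
  sims <- shared / (40 - shared)
  test_fp <- t(vapply(seq_along(shared), function(i) {
    v <- integer(n_bits)
    v[seq_len(shared[i])] <- 1L
    v[20 + seq_len(20 - shared[i])] <- 1L
    v
  }, integer(n_bits)))
  rownames(test_fp) <- sprintf("q%02d", seq_along(shared))
  colnames(test_fp) <- paste0("b", 1:n_bits)
  u <- manual_universe(list(activating = ref,
                            inhibiting = matrix(ref, 1, n_bits,
                                                dimnames = list("ref2",
                                                                colnames(ref)))))
  correct <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
               FALSE, FALSE, FALSE)
  preds <- tibble::tibble(
    compound_id = rownames(test_fp), target_id = "T01",
    true_label = "activating",
    final_label = ifelse(correct, "activating", "inhibiting")
  )
  got <- suppressWarnings(ad_curve(preds, u, test_fp, k = 1, bin_width = 0.05))
  # hand binning
  bin <- floor(sims / 0.05); bin[sims == 1] <- 19
  hand <- data.frame(bin = bin, correct = correct) |>
    (\(d) aggregate(correct ~ bin, d, mean))()
  hand$mid <- hand$bin * 0.05 + 0.025
  hand <- hand[order(1 - hand$mid), ]
  expect_equal(nrow(got$bins), nrow(hand))
  expect_equal(got$bins$tpr, hand$correct)
  expect_equal(got$ad_auc, pracma::trapz(1 - hand$mid, hand$correct))
  # all-correct and all-wrong degenerate cases
  all_right <- dplyr::mutate(preds, final_label = "activating")
  ar <- suppressWarnings(ad_curve(all_right, u, test_fp, k = 1))
  expect_true(all(ar$bins$tpr == 1))
  span <- max(ar$bins$distance) - min(ar$bins$distance)
  expect_equal(ar$ad_auc, span)
  all_wrong <- dplyr::mutate(preds, final_label = "inhibiting")
  expect_equal(suppressWarnings(ad_curve(all_wrong, u, test_fp, k = 1))$ad_auc, 0)
})

test_that("cross-validation is deterministic and validates its inputs", {
  u <- tiny_universe()
  r1 <- crossvalidate(u, "arch2", k = 5, seed = 14)
  r2 <- crossvalidate(u, "arch2", k = 5, seed = 14)
  expect_identical(r1$per_target, r2$per_target)
  expect_identical(r1$predictions, r2$predictions)
  expect_error(crossvalidate(u, "arch2", k = 1), class = "moa_input_error")
  # fold partitions: every tested functional compound appears exactly once
  folds <- r1$predictions |>
    dplyr::count(compound_id, target_id) |>
    dplyr::pull(n)
  expect_true(all(folds == 1))
})

test_that("temporal validation guards leaks and handles empty classes", {
  u <- tiny_universe()
  spec <- tiny_spec()
  m <- train_cascade(u, "arch3", seed = 2)
  b <- generate_temporal_batch(spec, u, novelty = 1, n_per_target = 15, seed = 8)
  tv <- temporal_validate(m, b)
  # duplicates of training compounds: near-training performance
  expect_gte(tv$target_averaged$f1_mean, 0.9)
  expect_false(is.null(tv$conditional))
  # leaked id is a hard error
  leaky <- b
  leaky$annotations$compound_id[1] <- rownames(u$fp)[1]
  expect_error(temporal_validate(m, leaky), class = "moa_leak_error")
  # a target with zero activators in the batch is excluded, not zeroed
  b2 <- b
  keep <- !(b2$annotations$target_id == "T01" &
              b2$annotations$true_label == "activating")
  b2$annotations <- b2$annotations[keep, ]
  tv2 <- temporal_validate(m, b2)
  act_t01 <- tv2$per_target[tv2$per_target$target_id == "T01" &
                              tv2$per_target$label == "activating", ]
  expect_false(act_t01$valid)
  expect_false(is.na(tv2$class_averaged$f1_mean))
})
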