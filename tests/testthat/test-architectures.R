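# Platt calibration, Arch1 (single multi-label forest + threshold), the
# cascaded stage models and the cascade decision rule.

test_that("Platt scaling is a monotone sigmoid minimizing log-loss", {
  fit <- platt_fit(c(0, 0.1, 0.9, 1), c(0, 0, 1, 1))
  s <- seq(0, 1, by = 0.1)
  p <- platt_apply(fit, s)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  # labels independent of scores: calibrated output ~ class prevalence
  withr::with_seed(99, {
    sc <- runif(4000); y <- rbinom(4000, 1, 0.3)
  })
  fit2 <- platt_fit(sc, y)
  expect_equal(unname(platt_apply(fit2, median(sc))), 0.3, tolerance = 0.1)
  expect_error(platt_fit(c(0.2, 0.8), c(1, 1)), class = "moa_calibration_error")
})

test_that("Arch1 probabilities sum to one and recover separable clusters", {
  u <- tiny_universe()
  m <- train_arch1(u, seed = 17)
  rows <- u$membership[u$membership$role %in% c("activating", "inhibiting"), ]
  sc <- moacascade:::arch1_scores(m, u$fp[rows$compound_id, ])
  sums <- sc |>
    dplyr::group_by(compound_id) |>
    dplyr::summarise(total = sum(p_act) + sum(p_inh))
  expect_true(all(abs(sums$total - 1) < 1e-9))
  # training-set top-1 label accuracy on well-separated clusters
  top1 <- sc |>
    tidyr::pivot_longer(c(p_act, p_inh), names_to = "fn", values_to = "p") |>
    dplyr::mutate(label = paste(target_id,
                                ifelse(fn == "p_act", "activating", "inhibiting"))) |>
    dplyr::group_by(compound_id) |>
    dplyr::slice_max(p, n = 1, with_ties = FALSE)
  truth <- paste(rows$target_id, rows$role)[match(top1$compound_id, rows$compound_id)]
  expect_gte(mean(top1$label == truth), 0.95)
  # single-label input cannot be trained
  single <- moa_universe(u$targets[1, ],
                         u$membership[u$membership$role == "activating" &
                                        u$membership$target_id == "T01", ],
                         u$fp)
  expect_error(train_arch1(single), class = "moa_input_error")
})

test_that("threshold optimization equals exhaustive percentile-grid search", {
  withr::with_seed(7, {
    scores <- tibble::tibble(
      compound_id = sprintf("c%02d", 1:20), target_id = "T1",
      p_act = runif(20), p_inh = runif(20)
    )
    truth <- tibble::tibble(
      compound_id = scores$compound_id, target_id = "T1",
      true_label = sample(c("activating", "inhibiting", "inactive"), 20, TRUE)
    )
  })
  got <- optimize_arch1_threshold(scores, truth)
  # independent brute-force oracle over the percentile grid
  grid <- unique(quantile(c(scores$p_act, scores$p_inh), seq(0.01, 1, 0.01),
                          names = FALSE))
  oracle_f1 <- sapply(grid, function(th) {
    pred <- mapply(function(pa, pi_) {
      if (pa >= th && pi_ >= th) if (pa > pi_) "activating" else "inhibiting"
      else if (pa >= th) "activating"
      else if (pi_ >= th) "inhibiting"
      else "inactive"
    }, scores$p_act, scores$p_inh)
    mean(sapply(c("inactive", "activating", "inhibiting"), function(lb) {
      tp <- sum(pred == lb & truth$true_label == lb)
      pr <- if (sum(pred == lb)) tp / sum(pred == lb) else 0
      rc <- if (sum(truth$true_label == lb)) tp / sum(truth$true_label == lb) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }))
  })
  expect_equal(got$theta, max(grid[oracle_f1 == max(oracle_f1)]))
  # degenerate distribution: a single candidate, returned as-is
  const <- dplyr::mutate(scores, p_act = 0.3, p_inh = 0.3)
  expect_equal(optimize_arch1_threshold(const, truth)$theta, 0.3)
  # perfectly separating scores attain F1 = 1
  sep <- dplyr::mutate(truth,
                       p_act = ifelse(true_label == "activating", 0.9, 0.01),
                       p_inh = ifelse(true_label == "inhibiting", 0.9, 0.01))
  res <- optimize_arch1_threshold(sep[, c("compound_id", "target_id", "p_act", "p_inh")],
                                  truth)
  expect_equal(max(res$grid$mean_f1), 1)
  expect_error(optimize_arch1_threshold(scores[0, ], truth),
               class = "moa_input_error")
})

test_that("the Arch1 decision rule reproduces the worked threshold example", {
  # score 0.15 passes theta = 0.092 while 0.05 does not -> activating
  expect_identical(arch1_rule(0.15, 0.05, 0.092), "activating")
  expect_identical(arch1_rule(0.05, 0.15, 0.092), "inhibiting")
  expect_identical(arch1_rule(0.05, 0.05, 0.092), "inactive")
  expect_identical(arch1_rule(0.3, 0.3, 0.092), "inhibiting")  # tie -> majority
  # randomized score table versus hand evaluation of the rule
  withr::with_seed(12, { pa <- runif(50); pi_ <- runif(50) })
  hand <- mapply(function(a, b) {
    if (a < 0.5 && b < 0.5) "inactive"
    else if (a >= 0.5 && (b < 0.5 || a > b)) "activating"
    else "inhibiting"
  }, pa, pi_)
  expect_identical(arch1_rule(pa, pi_, 0.5), unname(hand))
  # threshold unset is an error at prediction time
  u <- tiny_universe()
  m <- train_arch1(u, seed = 1)
  expect_error(predict(m, u$fp[1:2, ]), class = "moa_threshold_error")
  expect_error(arch1_set_threshold(m, 0.5), class = "moa_input_error")
})

test_that("Stage 1 separates actives from inactives and is seed-stable", {
  u <- tiny_universe()
  sp <- split_universe(u, seed = 4)
  s1 <- train_stage1(sp$train, "T01", seed = 13)
  test <- sp$test[sp$test$target_id == "T01", ]
  p <- predict(s1, u$fp[test$compound_id, ])
  expect_true(all(p >= 0 & p <= 1))
  acc <- mean((p > 0.5) == (test$role != "inactive"))
  expect_gte(acc, 0.95)
  s1b <- train_stage1(sp$train, "T01", seed = 13)
  expect_identical(predict(s1b, u$fp[test$compound_id, ]), p)
  # missing class errors
  no_inact <- moa_universe(u$targets,
                           u$membership[u$membership$role != "inactive", ], u$fp)
  expect_error(train_stage1(no_inact, "T01"), class = "moa_input_error")
})

test_that("Arch2 stage 2 yields complementary calibrated probabilities", {
  u <- tiny_universe()
  sp <- split_universe(u, seed = 6)
  s2 <- train_stage2_arch2(sp$train, "T01", seed = 19)
  test <- sp$test[sp$test$target_id == "T01" &
                    sp$test$role %in% c("activating", "inhibiting"), ]
  p <- predict(s2, u$fp[test$compound_id, ])
  expect_equal(p$p_act + p$p_inh, rep(1, nrow(p)))
  f1 <- sapply(c("activating", "inhibiting"), function(lb) {
    pred <- ifelse(p$p_act > p$p_inh, "activating", "inhibiting")
    tp <- sum(pred == lb & test$role == lb)
    2 * tp / (sum(pred == lb) + sum(test$role == lb))
  })
  expect_true(all(f1 >= 0.9))
  # fewer than 3 per class: calibration error surfaced
  small <- manual_universe(list(
    activating = rand_fp(2, 2048, 0.03, seed = 1, prefix = "a"),
    inhibiting = rand_fp(10, 2048, 0.03, seed = 2, prefix = "i")
  ))
  expect_error(train_stage2_arch2(small, "T01"), class = "moa_calibration_error")
})

test_that("Arch3 stage 2 probabilities are independent and well-calibrated", {
  u <- tiny_universe()
  sp <- split_universe(u, seed = 6)
  s3 <- train_stage2_arch3(sp$train, "T01", seed = 19)
  test <- sp$test[sp$test$target_id == "T01" &
                    sp$test$role %in% c("activating", "inhibiting"), ]
  p <- predict(s3, u$fp[test$compound_id, ])
  expect_true(all(p$p_act >= 0 & p$p_act <= 1))
  expect_true(all(p$p_inh >= 0 & p$p_inh <= 1))
  expect_false(isTRUE(all.equal(p$p_act + p$p_inh, rep(1, nrow(p)))))
  f1 <- sapply(c("activating", "inhibiting"), function(lb) {
    pred <- ifelse(p$p_act > p$p_inh, "activating", "inhibiting")
    tp <- sum(pred == lb & test$role == lb)
    2 * tp / (sum(pred == lb) + sum(test$role == lb))
  })
  expect_true(all(f1 >= 0.9))
  no_inact <- moa_universe(u$targets,
                           u$membership[u$membership$role != "inactive", ], u$fp)
  expect_error(train_stage2_arch3(no_inact, "T01"), class = "moa_input_error")
})

test_that("the cascade rule gates strictly and always forces a function", {
  grid <- expand.grid(p_bind = c(0.4, 0.5, 0.6), p_act = c(0.7, 0.2),
                      p_inh = c(0.2, 0.7))
  got <- cascade_rule(grid$p_bind, grid$p_act, grid$p_inh)
  hand <- apply(grid, 1, function(r) {
    if (r["p_bind"] <= 0.5) "inactive"
    else if (r["p_act"] > r["p_inh"]) "activating" else "inhibiting"
  })
  expect_identical(got, unname(hand))
  expect_identical(cascade_rule(0.9, 0.5, 0.5), "inhibiting")  # tie -> inhibiting
  expect_identical(cascade_rule(0.3, 0.99, 0.01), "inactive")  # gate wins
})

test_that("cascade models are reproducible and enforce gate invariants", {
  u <- tiny_universe()
  m1 <- train_cascade(u, "arch2", seed = 23)
  m2 <- train_cascade(u, "arch2", seed = 23)
  fp <- u$fp[sample(rownames(u$fp), 40), ]
  p1 <- predict(m1, fp); p2 <- predict(m2, fp)
  expect_identical(p1, p2)
  expect_true(all(p1$final_label[p1$p_bind <= 0.5] == "inactive"))
  expect_true(all(p1$final_label[p1$p_bind > 0.5] != "inactive"))
  # target mismatch across stages is an error
  s1 <- m1$models$T01$stage1
  s2 <- m1$models$T02$stage2
  expect_error(cascade_predict(s1, s2, fp), class = "moa_input_error")
})
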