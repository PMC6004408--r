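# Label mapping, activity thresholds, conflict removal, sphere exclusion,
# minimum-size filters and the full assembly pipeline.

test_that("the eight-term functional mapping schema is reproduced exactly", {
  expect_identical(
    map_functional_label(c("Activation", "Agonism", "Opening")),
    rep("activator", 3))
  expect_identical(
    map_functional_label(c("Antagonism", "Blocking", "Closing", "Inhibition",
                           "Inverse agonism")),
    rep("inhibitor", 5))
  expect_identical(map_functional_label("aGoNiSm"), "activator")
  err <- tryCatch(map_functional_label("Allosteric modulation"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "Allosteric modulation")
  expect_match(err, "agonism")  # error lists the accepted vocabulary
})

test_that("activity classes honor the inclusive 10 uM boundary", {
  ann <- tibble::tibble(
    endpoint_type = c("EC50", "Ki", "IC50", "IC50", "EC50", "Kd"),
    value_um = c(0.5, 2, 10, 10.01, 3, 50),
    bao_term = c(NA, NA, NA, NA, "Antagonism", NA)
  )
  out <- assign_activity_class(ann)
  expect_identical(out$activity_class,
                   c("functional_active", "binder", "functional_active",
                     "nonbinder", "functional_active", "nonbinder"))
  expect_identical(out$functional_label[1], "activator")  # EC50 unit rule
  expect_identical(out$functional_label[3], "inhibitor")  # IC50 unit rule
  expect_identical(out$functional_label[5], "inhibitor")  # BAO term wins over EC50
  expect_error(assign_activity_class(tibble::tibble(endpoint_type = "IC50",
                                                    value_um = -1)),
               class = "moa_input_error")
  expect_error(assign_activity_class(tibble::tibble(endpoint_type = "AC50",
                                                    value_um = 1)),
               class = "moa_vocabulary_error")
})

test_that("conflict removal drops per-target contradictions only", {
  ann <- assign_activity_class(tibble::tibble(
    compound_id = c("X", "X", "X", "Y", "Z", "Z"),
    target_id = c("T1", "T1", "T2", "T1", "T1", "T1"),
    endpoint_type = c("EC50", "IC50", "EC50", "IC50", "Ki", "IC50"),
    value_um = c(1, 1, 1, 1, 2, 50),
    bao_term = NA_character_
  ))
  out <- remove_conflicts(ann)
  # X conflicted at T1: both functional rows gone; kept at T2
  expect_false(any(out$compound_id == "X" & out$target_id == "T1"))
  expect_true(any(out$compound_id == "X" & out$target_id == "T2"))
  # Z has binder + nonbinder evidence: the nonbinder row is dropped
  expect_false(any(out$compound_id == "Z" & out$activity_class == "nonbinder"))
  expect_true(any(out$compound_id == "Z" & out$activity_class == "binder"))
  # brute-force count oracle: of 3 compounds at T1, only X loses functional rows
  expect_identical(sort(unique(out$compound_id[out$target_id == "T1"])),
                   c("Y", "Z"))
  # removal only: surviving rows are a subset with unchanged labels
  expect_true(nrow(dplyr::anti_join(out, ann, by = names(ann))) == 0)
  conf <- attr(out, "conflicts")
  expect_identical(conf$compound_id[conf$rule == "functional_conflict"], "X")
})

test_that("sphere exclusion equals a brute-force similarity filter", {
  # active: bits 1..10 on; pool compound i shares i of them -> Tc = i/(20-i)
  n_bits <- 40
  active <- matrix(0L, 1, n_bits, dimnames = list("act", paste0("b", 1:n_bits)))
  active[1, 1:10] <- 1L
  pool <- matrix(0L, 10, n_bits,
                 dimnames = list(sprintf("p%02d", 1:10), paste0("b", 1:n_bits)))
  for (i in 1:10) {
    pool[i, seq_len(i)] <- 1L
    if (i < 10) pool[i, 10 + seq_len(10 - i)] <- 1L
  }
  max_tc <- apply(tanimoto_matrix(pool, active), 1, max)
  oracle <- rownames(pool)[max_tc <= 0.4]
  got <- suppressWarnings(
    sphere_exclusion_sample(active, pool, n_required = 10, seed = 11))
  expect_setequal(got, oracle)
  # the compound identical to an active is never sampled
  pool2 <- rbind(pool, act_copy = active[1, ])
  got2 <- suppressWarnings(
    sphere_exclusion_sample(active, pool2, n_required = 11, seed = 11))
  expect_false("act_copy" %in% got2)
  # orthogonal pool: exactly n_required returned, seed-deterministic,
  # invariant to pool row order
  ortho <- matrix(0L, 8, n_bits,
                  dimnames = list(paste0("o", 1:8), paste0("b", 1:n_bits)))
  for (i in 1:8) ortho[i, 20 + i] <- 1L
  s1 <- sphere_exclusion_sample(active, ortho, n_required = 4, seed = 5)
  s2 <- sphere_exclusion_sample(active, ortho[sample(8), ], n_required = 4, seed = 5)
  expect_length(s1, 4)
  expect_identical(s1, s2)
  expect_warning(sphere_exclusion_sample(active, ortho, n_required = 20, seed = 1),
                 "exhausted")
  expect_error(sphere_exclusion_sample(active[0, , drop = FALSE], pool, 1),
               class = "moa_input_error")
})

test_that("minimum-size filters match hand enumeration on five toy targets", {
  counts <- list(
    T01 = c(act = 9, inh = 500, bnd = 10, ina = 20),   # dropped: <10 activating
    T02 = c(act = 10, inh = 10, bnd = 3, ina = 20),    # kept, binding emptied
    T03 = c(act = 30, inh = 40, bnd = 5, ina = 20),    # kept intact
    T04 = c(act = 12, inh = 9, bnd = 0, ina = 20),     # dropped: <10 inhibiting
    T05 = c(act = 10, inh = 10, bnd = 0, ina = 20)     # kept (no binding set)
  )
  memb <- purrr::imap(counts, function(ct, tid) {
    tibble::tibble(
      target_id = tid,
      compound_id = paste0(tid, "_", seq_len(sum(ct))),
      role = rep(c("activating", "inhibiting", "binding_only", "inactive"), ct)
    )
  }) |> purrr::list_rbind()
  fp <- rand_fp(nrow(memb), seed = 2)
  rownames(fp) <- memb$compound_id
  u <- moa_universe(
    tibble::tibble(target_id = names(counts),
                   protein_class = rep(c("GPCR", "NHR", "IonChannel",
                                         "Transporter", "GPCR"), 1)),
    memb, fp)
  out <- apply_minimum_size_filters(u)
  expect_setequal(out$targets$target_id, c("T02", "T03", "T05"))
  cnt <- universe_counts(out)
  expect_identical(cnt$binding_only[cnt$target_id == "T02"], 0L)
  expect_identical(cnt$binding_only[cnt$target_id == "T03"], 5L)
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$targets$target_id, c("T01", "T04"))
})

test_that("full assembly satisfies every dataset invariant", {
  u0 <- tiny_universe()
  ann <- synthetic_annotations(u0, seed = 4)
  u <- build_target_datasets(ann, u0$fp, inactive_multiple = 2, seed = 9)
  cnt <- universe_counts(u)
  expect_true(all(cnt$activating >= 10), info = "min activating")
  expect_true(all(cnt$inhibiting >= 10), info = "min inhibiting")
  expect_true(all(cnt$binding_only == 0 | cnt$binding_only >= 5))
  # functional sets disjoint per target
  overlap <- u$membership |>
    dplyr::filter(role %in% c("activating", "inhibiting")) |>
    dplyr::count(target_id, compound_id) |>
    dplyr::filter(n > 1)
  expect_identical(nrow(overlap), 0L)
  # every sphere-exclusion inactive sits at max Tc <= 0.4 from every active
  for (tid in u$targets$target_id) {
    se <- u$membership$compound_id[u$membership$target_id == tid &
                                     u$membership$role == "inactive" &
                                     u$membership$provenance == "sphere_exclusion"]
    if (!length(se)) next
    act <- u$membership$compound_id[u$membership$target_id == tid &
                                      u$membership$role != "inactive"]
    mx <- max(tanimoto_matrix(u$fp[se, , drop = FALSE],
                              u$fp[act, , drop = FALSE]))
    expect_lte(mx, 0.4)
  }
})
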