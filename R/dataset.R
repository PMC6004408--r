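# Assembly of per-target training sets from raw compound-target-assay
# annotations: BAO label mapping, the inclusive 10 uM activity thresholds,
# per-target conflict removal, sphere-exclusion sampling of putative
# inactives, and the minimum-size filters.

BAO_MAP <- c(
  "activation"      = "activator",
  "agonism"         = "activator",
  "antagonism"      = "inhibitor",
  "blocking"        = "inhibitor",
  "closing"         = "inhibitor",
  "inhibition"      = "inhibitor",
  "inverse agonism" = "inhibitor",
  "opening"         = "activator"
)

ENDPOINTS <- c("IC50", "EC50", "Ki", "Kd")

#' Map a BioAssay Ontology functional term to activator/inhibitor
#'
#' Implements the eight-term functional mapping schema: Activation, Agonism
#' and Opening map to `activator`; Antagonism, Blocking, Closing, Inhibition
#' and Inverse agonism map to `inhibitor`. Matching is case-insensitive.
#'
#' @param bao_term Character vector of BAO functional terms.
#' @return Character vector in `c("activator", "inhibitor")`.
#' @export
map_functional_label <- function(bao_term) {
  key <- tolower(trimws(bao_term))
  unknown <- unique(bao_term[!key %in% names(BAO_MAP) & !is.na(bao_term)])
  if (length(unknown) || anyNA(bao_term)) {
    abort_moa(paste0(
      "unknown functional term(s): ", paste(unknown, collapse = ", "),
      ". Accepted vocabulary: ", paste(names(BAO_MAP), collapse = ", "), "."),
      "moa_vocabulary_error")
  }
  unname(BAO_MAP[key])
}

#' Classify assay annotations by the 10 uM activity rule
#'
#' Functional endpoints (IC50/EC50) at values better than or equal to
#' `threshold_um` become `functional_active` with a label taken from the BAO
#' term when present (the term wins over the endpoint unit), otherwise from
#' the unit (EC50 to activator, IC50 to inhibitor). Binding endpoints (Ki/Kd)
#' at or below threshold become `binder`. Any endpoint above threshold is a
#' `nonbinder`.
#'
#' @param annotations Tibble with `endpoint_type`, `value_um` and optionally
#'   `bao_term` (`NA` allowed).
#' @param threshold_um Activity threshold in micromolar, default 10 (inclusive).
#' @return `annotations` with added `activity_class` in
#'   `c("functional_active","binder","nonbinder")` and `functional_label`
#'   (`NA` unless functionally active).
#' @export
assign_activity_class <- function(annotations, threshold_um = 10) {
  check_columns(annotations, c("endpoint_type", "value_um"))
  bad <- setdiff(unique(annotations$endpoint_type), ENDPOINTS)
  if (length(bad)) {
    abort_moa(paste0("unknown endpoint type(s): ", paste(bad, collapse = ", ")),
              "moa_vocabulary_error")
  }
  if (any(annotations$value_um <= 0 | !is.finite(annotations$value_um))) {
    abort_moa("`value_um` must be positive and finite.", "moa_input_error")
  }
  ann <- as_tibble(annotations)
  if (!"bao_term" %in% names(ann)) ann$bao_term <- NA_character_
  active <- ann$value_um <= threshold_um
  functional <- ann$endpoint_type %in% c("IC50", "EC50")
  ann$activity_class <- dplyr::case_when(
    !active ~ "nonbinder",
    functional ~ "functional_active",
    TRUE ~ "binder"
  )
  unit_label <- if_else(ann$endpoint_type == "EC50", "activator", "inhibitor")
  has_term <- !is.na(ann$bao_term) & nzchar(trimws(ann$bao_term))
  lab <- unit_label
  if (any(has_term)) lab[has_term] <- map_functional_label(ann$bao_term[has_term])
  ann$functional_label <- if_else(ann$activity_class == "functional_active",
                                  lab, NA_character_)
  ann
}

#' Remove per-target conflicting annotations
#'
#' Two rules, both applied per (compound, target): a compound carrying both
#' activator and inhibitor functional evidence is dropped from that target's
#' functional sets; a compound with both active (at or below threshold) and
#' non-binding (above threshold) evidence is dropped from that target's
#' inactive evidence. Conflicts are per target: labels at other targets are
#' untouched. Rows are only ever removed, never relabeled.
#'
#' @param annotations Output of [assign_activity_class()] with `compound_id`
#'   and `target_id`.
#' @return The cleaned annotation tibble; removed rows are reported in the
#'   `"conflicts"` attribute.
#' @export
remove_conflicts <- function(annotations) {
  check_columns(annotations, c("compound_id", "target_id", "activity_class",
                               "functional_label"))
  ann <- as_tibble(annotations)
  fun_conf <- ann |>
    filter(.data$activity_class == "functional_active") |>
    distinct(.data$compound_id, .data$target_id, .data$functional_label) |>
    count(.data$compound_id, .data$target_id) |>
    filter(.data$n > 1) |>
    select(-"n")
  act_pairs <- ann |>
    filter(.data$activity_class %in% c("functional_active", "binder")) |>
    distinct(.data$compound_id, .data$target_id)
  inact_conf <- ann |>
    filter(.data$activity_class == "nonbinder") |>
    distinct(.data$compound_id, .data$target_id) |>
    semi_join(act_pairs, by = c("compound_id", "target_id"))

  drop_fun <- ann |>
    mutate(.row = row_number()) |>
    filter(.data$activity_class == "functional_active") |>
    semi_join(fun_conf, by = c("compound_id", "target_id"))
  drop_inact <- ann |>
    mutate(.row = row_number()) |>
    filter(.data$activity_class == "nonbinder") |>
    semi_join(inact_conf, by = c("compound_id", "target_id"))
  drop_rows <- c(drop_fun$.row, drop_inact$.row)
  out <- if (length(drop_rows)) ann[-drop_rows, , drop = FALSE] else ann
  attr(out, "conflicts") <- bind_rows(
    mutate(fun_conf, rule = "functional_conflict"),
    mutate(inact_conf, rule = "nonbinding_conflict")
  )
  out
}

#' Sphere-exclusion sampling of putative inactives
#'
#' Samples up to `n_required` pool compounds whose maximum Tanimoto similarity
#' to every active is at most `tc_cutoff` (default 0.4), the standard
#' putative-inactive background construction. Candidates are visited in a
#' seed-shuffled order after sorting the pool by compound id, so the result is
#' invariant to pool row order. Returns fewer than requested, with a warning,
#' when the eligible pool is exhausted.
#'
#' @param actives 0/1 fingerprint matrix (or tibble with a `fingerprint`
#'   list-column) of the target's active compounds; must be non-empty.
#' @param pool Candidate fingerprint matrix with compound ids as rownames.
#' @param n_required Number of inactives wanted (>= 1).
#' @param tc_cutoff Maximum allowed similarity to any active, default 0.4.
#' @param seed Integer seed controlling the sampling order.
#' @return Character vector of sampled compound ids.
#' @export
sphere_exclusion_sample <- function(actives, pool, n_required, tc_cutoff = 0.4,
                                    seed = 1) {
  actives <- fp_matrix(actives); pool <- fp_matrix(pool)
  if (nrow(actives) == 0) abort_moa("active set is empty.", "moa_input_error")
  if (nrow(pool) == 0) abort_moa("pool is empty.", "moa_input_error")
  stopifnot(n_required >= 1)
  if (is.null(rownames(pool))) rownames(pool) <- as.character(seq_len(nrow(pool)))
  pool <- pool[order(rownames(pool)), , drop = FALSE]
  max_tc <- apply(tanimoto_matrix(pool, actives), 1, max)
  eligible <- rownames(pool)[max_tc <= tc_cutoff]
  perm <- withr::with_seed(derive_seed(seed, "sphere_exclusion"),
                           sample.int(length(eligible)))
  picked <- eligible[perm][seq_len(min(n_required, length(eligible)))]
  if (length(picked) < n_required) {
    warning("sphere-exclusion pool exhausted: ", length(picked), " of ",
            n_required, " requested inactives sampled.")
  }
  picked
}

#' Minimum-size filters on an assembled universe
#'
#' Drops targets with fewer than `min_functional` activating or inhibiting
#' compounds; within kept targets, empties the binding-only set when it holds
#' fewer than `min_binding` compounds (so that every retained class supports
#' the cross-validation fold count).
#'
#' @param universe A [moa_universe()].
#' @param min_functional Minimum activating and inhibiting set size, default 10.
#' @param min_binding Minimum binding-only set size, default 5.
#' @return Filtered universe; dropped targets and emptied binding sets are
#'   reported in the `"dropped"` attribute.
#' @export
apply_minimum_size_filters <- function(universe, min_functional = 10,
                                       min_binding = 5) {
  cnt <- universe_counts(universe)
  for (r in ROLES) if (!r %in% names(cnt)) cnt[[r]] <- 0L
  drop_targets <- cnt$target_id[cnt$activating < min_functional |
                                  cnt$inhibiting < min_functional]
  small_binding <- cnt$target_id[!cnt$target_id %in% drop_targets &
                                   cnt$binding_only > 0 &
                                   cnt$binding_only < min_binding]
  keep <- !universe$membership$target_id %in% drop_targets &
    !(universe$membership$target_id %in% small_binding &
        universe$membership$role == "binding_only")
  membership <- universe$membership[keep, , drop = FALSE]
  targets <- universe$targets[!universe$targets$target_id %in% drop_targets, , drop = FALSE]
  out <- moa_universe(targets, membership, universe$fp, truth = universe$truth)
  attr(out, "dropped") <- list(
    targets = cnt[cnt$target_id %in% drop_targets, , drop = FALSE],
    binding_only_emptied = small_binding
  )
  out
}

#' Assemble per-target training sets from annotations
#'
#' The full data-assembly pipeline: activity classification at the inclusive
#' `threshold_um` boundary, per-target conflict removal, role assignment
#' (functional evidence wins over binding-only; experimental non-binders
#' become inactives), sphere-exclusion sampling of additional putative
#' inactives from the remaining pool up to `inactive_multiple` times the
#' active-set size, and the minimum-size filters.
#'
#' @param annotations Tibble with columns `compound_id`, `target_id`,
#'   `protein_class`, `endpoint_type`, `value_um` and optionally `bao_term`.
#' @param fp Fingerprint 0/1 matrix for every annotated compound (rownames =
#'   compound ids), e.g. from [fingerprint_smiles()] or a synthetic generator.
#' @param threshold_um Activity threshold, default 10 uM.
#' @param tc_cutoff Sphere-exclusion similarity cutoff, default 0.4.
#' @param inactive_multiple Putative inactives sampled per target, as a
#'   multiple of its active-set size (capped by the pool); default 100.
#' @param min_functional,min_binding Minimum-size filters, defaults 10 and 5.
#' @param seed Integer seed for sphere-exclusion sampling.
#' @return A [moa_universe()]; dropped-target report in the `"dropped"`
#'   attribute, conflict report in the `"conflicts"` attribute.
#' @export
build_target_datasets <- function(annotations, fp, threshold_um = 10,
                                  tc_cutoff = 0.4, inactive_multiple = 100,
                                  min_functional = 10, min_binding = 5,
                                  seed = 1) {
  check_columns(annotations, c("compound_id", "target_id", "protein_class"))
  if (!"activity_class" %in% names(annotations)) {
    annotations <- assign_activity_class(annotations, threshold_um = threshold_um)
  }
  ann <- remove_conflicts(annotations)
  conflicts <- attr(ann, "conflicts")

  roles <- ann |>
    group_by(.data$target_id, .data$compound_id) |>
    summarise(
      fun_label = if (any(.data$activity_class == "functional_active")) {
        unique(.data$functional_label[.data$activity_class == "functional_active"])[1]
      } else NA_character_,
      has_binder = any(.data$activity_class == "binder"),
      has_nonbinder = any(.data$activity_class == "nonbinder"),
      .groups = "drop"
    ) |>
    mutate(role = dplyr::case_when(
      !is.na(.data$fun_label) & .data$fun_label == "activator" ~ "activating",
      !is.na(.data$fun_label) & .data$fun_label == "inhibitor" ~ "inhibiting",
      .data$has_binder ~ "binding_only",
      .data$has_nonbinder ~ "inactive"
    )) |>
    filter(!is.na(.data$role)) |>
    mutate(provenance = if_else(.data$role == "inactive", "experimental",
                                NA_character_)) |>
    select(all_of(c("target_id", "compound_id", "role", "provenance")))

  targets <- annotations |>
    distinct(.data$target_id, .data$protein_class)
  if (anyDuplicated(targets$target_id)) {
    abort_moa("inconsistent protein_class within a target.", "moa_schema_error")
  }

  # Sphere-exclusion putative inactives: pool = all annotated compounds not
  # active and not already inactive at the target.
  extra <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tid <- targets$target_id[i]
    here <- roles[roles$target_id == tid, , drop = FALSE]
    active_ids <- here$compound_id[here$role != "inactive"]
    n_actives <- length(active_ids)
    if (n_actives == 0) next
    pool_ids <- setdiff(rownames(fp), here$compound_id)
    if (!length(pool_ids)) next
    n_have <- sum(here$role == "inactive")
    n_want <- max(0L, n_actives * inactive_multiple - n_have)
    if (n_want == 0) next
    picked <- suppressWarnings(sphere_exclusion_sample(
      fp[active_ids, , drop = FALSE], fp[pool_ids, , drop = FALSE],
      n_required = n_want, tc_cutoff = tc_cutoff,
      seed = derive_seed(seed, tid)))
    if (length(picked)) {
      extra[[i]] <- tibble(target_id = tid, compound_id = picked,
                           role = "inactive", provenance = "sphere_exclusion")
    }
  }
  membership <- bind_rows(roles, list_rbind(extra[!vapply(extra, is.null, logical(1))]))

  u <- moa_universe(targets, membership, fp)
  u <- apply_minimum_size_filters(u, min_functional = min_functional,
                                  min_binding = min_binding)
  attr(u, "conflicts") <- conflicts
  u
}
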