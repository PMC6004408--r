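# The assembled training universe: per-target labeled compound sets over a
# shared fingerprint matrix. Kept deliberately flat (a long membership table +
# one bit matrix) so every downstream verb is ordinary dplyr.

PROTEIN_CLASSES <- c("GPCR", "NHR", "IonChannel", "Transporter")
ROLES <- c("activating", "inhibiting", "binding_only", "inactive")

#' Construct a modeling universe
#'
#' Bundles per-target compound sets with the shared fingerprint matrix. The
#' membership table is long: one row per (target, compound, role), where role
#' is one of `activating`, `inhibiting`, `binding_only`, `inactive`;
#' `provenance` distinguishes `experimental` from `sphere_exclusion`
#' inactives.
#'
#' @param targets Tibble with `target_id`, `protein_class` (GPCR, NHR,
#'   IonChannel or Transporter).
#' @param membership Tibble with `target_id`, `compound_id`, `role` and
#'   optionally `provenance`.
#' @param fp Integer 0/1 matrix, rownames = compound ids covering every
#'   compound in `membership`.
#' @param truth Optional ground-truth manifest (synthetic universes).
#' @return An object of class `moa_universe`.
#' @export
moa_universe <- function(targets, membership, fp, truth = NULL) {
  check_columns(targets, c("target_id", "protein_class"))
  check_columns(membership, c("target_id", "compound_id", "role"))
  bad_class <- setdiff(unique(targets$protein_class), PROTEIN_CLASSES)
  if (length(bad_class)) {
    abort_moa(paste0("unknown protein class(es): ", paste(bad_class, collapse = ", "),
                     "; allowed: ", paste(PROTEIN_CLASSES, collapse = ", ")),
              "moa_schema_error")
  }
  bad_role <- setdiff(unique(membership$role), ROLES)
  if (length(bad_role)) {
    abort_moa(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
              "moa_schema_error")
  }
  if (!"provenance" %in% names(membership)) {
    membership$provenance <- if_else(membership$role == "inactive",
                                     "experimental", NA_character_)
  }
  missing_fp <- setdiff(unique(membership$compound_id), rownames(fp))
  if (length(missing_fp)) {
    abort_moa(paste0(length(missing_fp), " compound(s) lack fingerprints."),
              "moa_schema_error")
  }
  conflict <- membership |>
    filter(.data$role %in% c("activating", "inhibiting")) |>
    distinct(.data$target_id, .data$compound_id, .data$role) |>
    count(.data$target_id, .data$compound_id) |>
    filter(.data$n > 1)
  if (nrow(conflict)) {
    abort_moa("activating and inhibiting sets overlap; run remove_conflicts() first.",
              "moa_invariant_error")
  }
  structure(
    list(targets = as_tibble(targets), membership = as_tibble(membership),
         fp = fp, truth = truth),
    class = "moa_universe"
  )
}

#' @export
print.moa_universe <- function(x, ...) {
  cnt <- universe_counts(x)
  cat("<moa_universe> ", nrow(x$targets), " targets, ",
      length(unique(x$membership$compound_id)), " compounds, ",
      ncol(x$fp), "-bit fingerprints\n", sep = "")
  print(cnt, n = 20)
  invisible(x)
}

#' Per-target role counts of a universe
#'
#' @param universe A [moa_universe()].
#' @return Tibble with one row per target and one column per role.
#' @export
universe_counts <- function(universe) {
  universe$membership |>
    count(.data$target_id, .data$role) |>
    pivot_wider(names_from = "role", values_from = "n", values_fill = 0L) |>
    left_join(universe$targets, by = "target_id") |>
    select(all_of(c("target_id", "protein_class")),
           any_of(c("activating", "inhibiting", "binding_only", "inactive")))
}

# Compound ids of one role at one target.
role_ids <- function(universe, target, role) {
  universe$membership$compound_id[
    universe$membership$target_id == target & universe$membership$role == role]
}

# Fingerprint rows for a set of compound ids.
role_fp <- function(universe, target, role) {
  universe$fp[role_ids(universe, target, role), , drop = FALSE]
}

#' @importFrom dplyr any_of
#' @noRd
NULL
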