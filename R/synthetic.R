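# Seeded generator of benchmark chemical universes. Fingerprints are drawn
# directly as bit vectors: each functional class at a target is a prototype
# bit pattern plus independent per-bit flip noise, and the prototype overlaps
# are calibrated numerically against the closed-form expected Tanimoto
# similarity so the realized nearest-neighbor separations match the requested
# knobs (activator-inhibitor ~0.835, binder-inhibitor ~0.958 by default, the
# medians observed in large proprietary functional screening collections).

#' Specification of a synthetic benchmark universe
#'
#' Defaults emulate the statistical structure of large corporate functional
#' screening data: a median inhibitor:activator imbalance of 5:1, activating
#' versus inhibiting nearest-neighbor Tanimoto separation of about 0.835,
#' binding-only compounds sitting much closer to inhibitors (about 0.958), and
#' a large diffuse inactive background far from all actives.
#'
#' @param n_targets Number of protein targets (protein classes are cycled over
#'   GPCR, NHR, IonChannel, Transporter).
#' @param n_activating Activating compounds per target.
#' @param n_inhibiting Inhibiting compounds per target; if `NULL`, derived as
#'   `n_activating * imbalance_ratio` so the realized ratio is exact.
#' @param imbalance_ratio Inhibitor:activator ratio, default 5.
#' @param n_binding Binding-only compounds per target.
#' @param n_inactive Inactive compounds per target.
#' @param target_function_separation Expected Tanimoto similarity between
#'   activator and inhibitor cluster members, default 0.835.
#' @param binder_inhibitor_overlap Expected binder-inhibitor member
#'   similarity, default 0.958.
#' @param inactive_similarity Expected similarity of inactives to active
#'   cluster members, default 0.10.
#' @param noise_rate Per-bit flip probability applied to every cluster member,
#'   default 5e-4 (with 2048 bits this yields intra-cluster similarity around
#'   0.97).
#' @param n_bits Fingerprint length, default 2048.
#' @param n_on_bits On-bits per prototype, default 64 (a typical circular
#'   fingerprint density for drug-like molecules).
#' @param seed Default integer seed for [generate_universe()].
#' @return A `moa_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_targets = 8, n_activating = 40,
                           n_inhibiting = NULL, imbalance_ratio = 5,
                           n_binding = 60, n_inactive = 400,
                           target_function_separation = 0.835,
                           binder_inhibitor_overlap = 0.958,
                           inactive_similarity = 0.10,
                           noise_rate = 5e-4, n_bits = 2048, n_on_bits = 64,
                           seed = 1) {
  if (is.null(n_inhibiting)) n_inhibiting <- round(n_activating * imbalance_ratio)
  spec <- list(
    n_targets = as.integer(n_targets), n_activating = as.integer(n_activating),
    n_inhibiting = as.integer(n_inhibiting),
    imbalance_ratio = n_inhibiting / n_activating,
    n_binding = as.integer(n_binding), n_inactive = as.integer(n_inactive),
    target_function_separation = target_function_separation,
    binder_inhibitor_overlap = binder_inhibitor_overlap,
    inactive_similarity = inactive_similarity,
    noise_rate = noise_rate, n_bits = as.integer(n_bits),
    n_on_bits = as.integer(n_on_bits), seed = as.integer(seed)
  )
  counts <- c(spec$n_targets, spec$n_activating, spec$n_inhibiting,
              spec$n_binding, spec$n_inactive)
  if (any(counts < 0)) abort_moa("counts must be non-negative.", "moa_input_error")
  knobs <- c(spec$target_function_separation, spec$binder_inhibitor_overlap,
             spec$inactive_similarity)
  if (any(knobs < 0 | knobs > 1)) {
    abort_moa("similarity knobs must lie in [0, 1].", "moa_input_error")
  }
  if (noise_rate < 0 || noise_rate >= 0.5) {
    abort_moa("noise_rate must lie in [0, 0.5).", "moa_input_error")
  }
  intra <- expected_member_tc(spec$n_on_bits, spec$n_on_bits, spec$n_on_bits,
                              spec$n_bits, noise_rate, noise_rate)
  infeasible <- knobs[1:2][knobs[1:2] > intra]
  if (length(infeasible)) {
    abort_moa(sprintf(
      paste0("separation knob(s) %s exceed the intra-cluster expectation %.3f ",
             "attainable at noise_rate %.4g; lower the knob or the noise."),
      paste(sprintf("%.3f", infeasible), collapse = ", "), intra, noise_rate),
      "moa_infeasible_error")
  }
  structure(spec, class = "moa_synthetic_spec")
}

# Closed-form expected Tanimoto between one member of a prototype with mA
# on-bits and one member of a prototype with mB on-bits sharing `o` on-bits,
# under independent per-bit flip noise ea / eb (ratio-of-expectations
# approximation, accurate for L >> m).
expected_member_tc <- function(o, mA, mB, L, ea, eb) {
  n <- c(o, mA - o, mB - o, L - mA - mB + o)
  pa <- c(1 - ea, 1 - ea, ea, ea)
  pb <- c(1 - eb, eb, 1 - eb, eb)
  sum(n * pa * pb) / sum(n * (1 - (1 - pa) * (1 - pb)))
}

# Calibrate the prototype overlap o (shared on-bits) so the expected member
# similarity equals `target_tc`; monotone in o, solved by bisection.
calibrate_overlap <- function(target_tc, m, L, ea, eb) {
  f <- function(o) expected_member_tc(o, m, m, L, ea, eb) - target_tc
  if (f(m) < 0) {
    abort_moa("requested similarity exceeds the noise-limited maximum.",
              "moa_infeasible_error")
  }
  if (f(0) >= 0) return(0L)
  lo <- 0; hi <- m
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  as.integer(round(hi))
}

# Calibrate a per-bit flip rate so a noisy copy of a prototype has expected
# similarity `target_tc` to members generated at base noise `eb`.
calibrate_noise <- function(target_tc, m, L, eb) {
  f <- function(e) expected_member_tc(m, m, m, L, e, eb) - target_tc
  if (f(0) <= 0) return(0)
  lo <- 0; hi <- 0.499
  if (f(hi) > 0) return(hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_prototype <- function(n_bits, n_on) {
  p <- integer(n_bits)
  p[sample.int(n_bits, n_on)] <- 1L
  p
}

# Derive a prototype from `base` keeping `o` of its on-bits and relocating the
# remainder to unused positions (constant on-bit density).
derived_prototype <- function(base, o) {
  on <- which(base == 1L)
  keep <- sample(on, o)
  moved <- length(on) - o
  free <- which(base == 0L)
  p <- integer(length(base))
  p[keep] <- 1L
  if (moved > 0) p[sample(free, moved)] <- 1L
  p
}

# n noisy copies of a prototype (per-bit flip probability eps).
noisy_members <- function(proto, n, eps) {
  if (n == 0) return(matrix(integer(0), 0, length(proto)))
  flips <- matrix(stats::runif(n * length(proto)) < eps, n, length(proto))
  m <- matrix(rep(proto, each = n), n, length(proto))
  storage.mode(m) <- "integer"
  (m + flips) %% 2L
}

#' Generate a synthetic modeling universe
#'
#' Draws, per target, an inhibitor prototype, an activator prototype and a
#' binding-only prototype at calibrated overlaps, populates each class by
#' bit-flip noise, and surrounds them with a diffuse inactive background whose
#' similarity to the actives is controlled by `inactive_similarity`. Class
#' counts equal the spec exactly and the generator is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A [moa_universe()] whose `truth` field holds the ground-truth
#'   manifest (spec echo, per-compound cluster assignment, prototypes).
#' @export
generate_universe <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "moa_synthetic_spec"))
  L <- spec$n_bits; m <- spec$n_on_bits; eps <- spec$noise_rate
  o_ai <- calibrate_overlap(spec$target_function_separation, m, L, eps, eps)
  o_bi <- calibrate_overlap(spec$binder_inhibitor_overlap, m, L, eps, eps)
  o_in <- calibrate_overlap(spec$inactive_similarity, m, L, 0, eps)

  withr::with_seed(derive_seed(seed, "universe"), {
    targets <- tibble(
      target_id = sprintf("T%02d", seq_len(spec$n_targets)),
      protein_class = rep(PROTEIN_CLASSES, length.out = spec$n_targets)
    )
    memb <- vector("list", spec$n_targets)
    fps <- vector("list", spec$n_targets)
    protos <- vector("list", spec$n_targets)
    next_id <- 1L
    for (t in seq_len(spec$n_targets)) {
      p_inh <- random_prototype(L, m)
      p_act <- derived_prototype(p_inh, o_ai)
      p_bind <- derived_prototype(p_inh, o_bi)
      act <- noisy_members(p_act, spec$n_activating, eps)
      inh <- noisy_members(p_inh, spec$n_inhibiting, eps)
      bnd <- noisy_members(p_bind, spec$n_binding, eps)
      # Each inactive gets its own prototype sharing o_in bits with the
      # inhibitor prototype: diffuse background at controlled similarity.
      ina <- matrix(0L, spec$n_inactive, L)
      for (i in seq_len(spec$n_inactive)) {
        q <- integer(L)
        on <- which(p_inh == 1L)
        keepn <- min(o_in, length(on))
        if (keepn > 0) q[sample(on, keepn)] <- 1L
        q[sample(which(q == 0L & p_inh == 0L), m - keepn)] <- 1L
        ina[i, ] <- q
      }
      fp_t <- rbind(act, inh, bnd, ina)
      n_t <- nrow(fp_t)
      ids <- sprintf("C%06d", seq.int(next_id, length.out = n_t))
      next_id <- next_id + n_t
      rownames(fp_t) <- ids
      colnames(fp_t) <- paste0("b", seq_len(L))
      roles <- rep(c("activating", "inhibiting", "binding_only", "inactive"),
                   times = c(spec$n_activating, spec$n_inhibiting,
                             spec$n_binding, spec$n_inactive))
      memb[[t]] <- tibble(
        target_id = targets$target_id[t], compound_id = ids, role = roles,
        provenance = if_else(roles == "inactive", "sphere_exclusion", NA_character_)
      )
      fps[[t]] <- fp_t
      protos[[t]] <- list(activator = p_act, inhibitor = p_inh, binder = p_bind)
    }
    membership <- list_rbind(memb)
    fp <- do.call(rbind, fps)
    names(protos) <- targets$target_id
    truth <- list(
      spec = spec, seed = seed,
      assignments = membership[, c("target_id", "compound_id", "role")],
      prototypes = protos
    )
    moa_universe(targets, membership, fp, truth = truth)
  })
}

#' Generate a later-period (temporal) validation batch
#'
#' Emulates a prospective validation set mined after the training data: new
#' activating/inhibiting compounds at controlled chemical distance from the
#' training clusters. Per compound, a desired similarity is drawn uniformly
#' from `novelty +/- novelty_spread` (clipped to feasibility) and the compound
#' is synthesized as a noisy copy of its label's prototype at a flip rate
#' calibrated to that similarity. With `novelty = 1` the batch duplicates
#' actual training compounds under new ids. When `error_gradient` is `TRUE`,
#' the recorded true label is flipped with probability increasing with
#' distance from the training space, so prediction errors grow with
#' dissimilarity (for applicability-domain testing).
#'
#' @param spec The [synthetic_spec()] used for the base universe.
#' @param base The training [moa_universe()] generated from `spec`.
#' @param novelty Expected Tanimoto similarity of new compounds to training
#'   compounds, in \[0, 1\].
#' @param novelty_spread Half-width of the per-compound similarity draw,
#'   default 0.25.
#' @param n_per_target New compounds per target, default 60.
#' @param error_gradient Flip true labels with probability increasing with
#'   distance, default `FALSE`.
#' @param id_prefix Prefix for new compound ids; generation refuses to emit an
#'   id already present in `base`.
#' @param seed Integer seed.
#' @return A `moa_temporal_batch`: list with `annotations` (tibble
#'   `compound_id`, `target_id`, `protein_class`, `true_label`) and `fp`.
#' @export
generate_temporal_batch <- function(spec, base, novelty, novelty_spread = 0.25,
                                    n_per_target = 60, error_gradient = FALSE,
                                    id_prefix = "V", seed = 1) {
  stopifnot(inherits(spec, "moa_synthetic_spec"), inherits(base, "moa_universe"))
  if (novelty < 0 || novelty > 1) {
    abort_moa("`novelty` must lie in [0, 1].", "moa_input_error")
  }
  L <- spec$n_bits; m <- spec$n_on_bits; eps <- spec$noise_rate
  protos <- base$truth$prototypes
  if (is.null(protos)) {
    abort_moa("`base` lacks a ground-truth manifest; generate it with generate_universe().",
              "moa_input_error")
  }
  intra <- expected_member_tc(m, m, m, L, 0, eps)
  p_act_share <- 1 / (1 + spec$imbalance_ratio)

  withr::with_seed(derive_seed(seed, "temporal"), {
    rows <- vector("list", length(protos))
    fps <- vector("list", length(protos))
    for (t in seq_along(protos)) {
      tid <- names(protos)[t]
      labels <- if_else(stats::runif(n_per_target) < p_act_share,
                        "activating", "inhibiting")
      fp_t <- matrix(0L, n_per_target, L)
      sims <- pmin(pmax(stats::runif(n_per_target, novelty - novelty_spread,
                                     novelty + novelty_spread), 0.02), 1)
      for (i in seq_len(n_per_target)) {
        proto <- if (labels[i] == "activating") protos[[t]]$activator else protos[[t]]$inhibitor
        if (novelty >= 1) {
          src <- role_ids(base, tid, labels[i])
          fp_t[i, ] <- base$fp[sample(src, 1), ]
          sims[i] <- 1
        } else {
          e_i <- calibrate_noise(min(sims[i], intra), m, L, eps)
          fp_t[i, ] <- noisy_members(proto, 1, e_i)[1, ]
        }
      }
      true_label <- labels
      if (error_gradient) {
        flip <- stats::runif(n_per_target) < pmin(0.9, 1.2 * (1 - sims))
        true_label[flip] <- if_else(labels[flip] == "activating",
                                    "inhibiting", "activating")
      }
      ids <- sprintf("%s%s_%04d", id_prefix, tid, seq_len(n_per_target))
      if (any(ids %in% rownames(base$fp))) {
        abort_moa("generated compound ids collide with the base universe.",
                  "moa_input_error")
      }
      rownames(fp_t) <- ids
      colnames(fp_t) <- paste0("b", seq_len(L))
      rows[[t]] <- tibble(
        compound_id = ids, target_id = tid,
        protein_class = base$targets$protein_class[base$targets$target_id == tid],
        true_label = true_label, target_similarity = sims
      )
      fps[[t]] <- fp_t
    }
    structure(list(annotations = list_rbind(rows), fp = do.call(rbind, fps)),
              class = "moa_temporal_batch")
  })
}

BAO_ACTIVATOR_TERMS <- c("Activation", "Agonism", "Opening")
BAO_INHIBITOR_TERMS <- c("Antagonism", "Blocking", "Closing", "Inhibition",
                         "Inverse agonism")

#' Emit the annotation table corresponding to a synthetic universe
#'
#' Produces the raw assay-annotation table (one row per compound-target
#' evidence item, with endpoint types, micromolar values and BAO terms) that
#' [build_target_datasets()] consumes, so the full assembly pipeline can be
#' exercised end to end against known ground truth. Inactive members are
#' emitted as high-concentration non-binding evidence.
#'
#' @param universe A synthetic [moa_universe()] (from [generate_universe()]).
#' @param seed Integer seed for the drawn assay values.
#' @return Tibble with columns `compound_id`, `target_id`, `protein_class`,
#'   `endpoint_type`, `value_um`, `bao_term`.
#' @export
synthetic_annotations <- function(universe, seed = 1) {
  stopifnot(inherits(universe, "moa_universe"))
  withr::with_seed(derive_seed(seed, "annotations"), {
    memb <- universe$membership |>
      left_join(universe$targets, by = "target_id")
    n <- nrow(memb)
    value <- stats::runif(n, 0.005, 9.9)
    endpoint <- character(n)
    bao <- rep(NA_character_, n)
    act <- memb$role == "activating"
    inh <- memb$role == "inhibiting"
    bnd <- memb$role == "binding_only"
    ina <- memb$role == "inactive"
    endpoint[act] <- "EC50"
    bao[act] <- sample(BAO_ACTIVATOR_TERMS, sum(act), replace = TRUE)
    endpoint[inh] <- "IC50"
    bao[inh] <- sample(BAO_INHIBITOR_TERMS, sum(inh), replace = TRUE)
    endpoint[bnd] <- sample(c("Ki", "Kd"), sum(bnd), replace = TRUE)
    endpoint[ina] <- sample(ENDPOINTS, sum(ina), replace = TRUE)
    value[ina] <- stats::runif(sum(ina), 10.01, 500)
    tibble(
      compound_id = memb$compound_id, target_id = memb$target_id,
      protein_class = memb$protein_class, endpoint_type = endpoint,
      value_um = round(value, 4), bao_term = bao
    )
  })
}

#' Generate random drug-like SMILES from a small fragment grammar
#'
#' Combines aromatic/aliphatic ring scaffolds with linkers and tails into
#' valid, drug-like SMILES strings. Intended for end-to-end tests of the
#' standardization, filtering and fingerprinting path; makes no claim of
#' medicinal-chemistry realism.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param salted Fraction of molecules emitted with a counter-ion fragment
#'   appended (exercises salt stripping), default 0.
#' @return Tibble with `compound_id` and `smiles`.
#' @export
generate_smiles <- function(n, seed = 1, salted = 0) {
  scaffolds <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCNCC1",
                 "C1CCOC1", "c1ccsc1", "C1CCCCC1", "c1cnc2ccccc2c1")
  linkers <- c("CC", "C(=O)N", "OC", "C(=O)O", "S(=O)(=O)N", "C(C)C", "N(C)C")
  tails <- c("", "C", "CC", "OC", "C(=O)O", "N", "Cl", "F", "C(F)(F)F")
  salts <- c(".[Na+].[Cl-]", ".Cl", ".C(=O)O")
  withr::with_seed(derive_seed(seed, "smiles"), {
    smi <- vapply(seq_len(n), function(i) {
      s <- paste0(sample(scaffolds, 1), sample(linkers, 1), sample(scaffolds, 1),
                  sample(tails, 1))
      if (stats::runif(1) < salted) s <- paste0(s, sample(salts, 1))
      s
    }, character(1))
    tibble(compound_id = sprintf("S%05d", seq_len(n)), smiles = smi)
  })
}
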