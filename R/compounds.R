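# Chemistry substrate: standardization, drug-likeness filters, circular
# fingerprints and Tanimoto similarity. Structure handling is delegated to
# OpenBabel via ChemmineOB; everything downstream operates on plain 0/1 bit
# matrices so the modeling modules never touch molecule objects.

# Symbol -> atomic number lookup for the element filter.
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18, K = 19,
  Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26, Co = 27,
  Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34, Br = 35,
  Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42, Tc = 43,
  Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50, Sb = 51,
  Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58, Pr = 59,
  Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66, Ho = 67,
  Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74, Re = 75,
  Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82, Bi = 83,
  Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90, Pa = 91,
  U = 92, Np = 93, Pu = 94, Am = 95, Cm = 96, Bk = 97, Cf = 98, Es = 99,
  Fm = 100
)

#' Atomic numbers excluded by the drug-likeness element rule
#'
#' Molecules containing any atom with atomic number in \eqn{[21,32] \cup
#' [36,52] \cup (53,\infty)} are rejected, retaining the typical organic
#' elements (H--Ca, As, Se, Br, I). The rule is exposed so alternative element
#' policies can be supplied to [filter_druglike()].
#'
#' @return Integer vector of excluded atomic numbers.
#' @export
druglike_excluded_elements <- function() {
  as.integer(c(21:32, 36:52, 54:100))
}

ob_convert <- function(smiles, opts = data.frame(names = character(), args = character())) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"), options = opts),
    error = function(e) ""
  )
  out <- sub("[ \t\r\n]+$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

#' Standardize SMILES strings
#'
#' Canonical standardization pipeline: keep the largest connected fragment
#' (salt/counter-ion stripping), neutralize charges where chemically valid,
#' and emit a canonical SMILES. Tautomers are not enumerated. Unparsable
#' input yields `NA`, never an error, so bulk imports survive bad rows.
#'
#' @param smiles Character vector of SMILES strings; empty strings are an error.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
standardize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0) {
    abort_moa("`smiles` must be a non-empty character vector.", "moa_input_error")
  }
  if (any(is.na(smiles)) || any(!nzchar(trimws(smiles)))) {
    abort_moa("empty SMILES string supplied.", "moa_input_error")
  }
  opts <- data.frame(names = c("r", "neutralize"), args = c("", ""))
  vapply(trimws(smiles), ob_convert, character(1), opts = opts, USE.NAMES = FALSE)
}

#' Standardize a compound table
#'
#' Data-frame-first wrapper around [standardize_smiles()]. Returns one record
#' per input row with the raw structure, its standardized canonical form and a
#' validity flag; `passed_filters` is `NA` until [filter_druglike()] runs.
#'
#' @param data Data frame with columns `compound_id` and `smiles`.
#' @return A tibble with columns `compound_id`, `raw_smiles`, `std_smiles`,
#'   `valid`, `passed_filters`.
#' @examples
#' \donttest{
#' standardize_compounds(data.frame(compound_id = "c1", smiles = "CCO.[Na+].[Cl-]"))
#' }
#' @export
standardize_compounds <- function(data) {
  check_columns(data, c("compound_id", "smiles"))
  if (anyDuplicated(data$compound_id)) {
    abort_moa("`compound_id` must be unique within a dataset.", "moa_input_error")
  }
  std <- standardize_smiles(data$smiles)
  tibble(
    compound_id = as.character(data$compound_id),
    raw_smiles = as.character(data$smiles),
    std_smiles = std,
    valid = !is.na(std),
    passed_filters = NA
  )
}

mol_properties <- function(smiles) {
  mol <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
  p <- ChemmineOB::prop_OB(mol)
  syms <- regmatches(p$formula, gregexpr("[A-Z][a-z]?", p$formula))[[1]]
  syms <- syms[syms %in% names(.element_z)]
  list(mw = p$MW, elements = unname(.element_z[syms]))
}

#' Drug-likeness filter
#'
#' Flags standardized compounds that contain at least one carbon atom, have a
#' molecular weight inside `mw_range` (inclusive), and contain no atom from
#' `excluded_z` (default [druglike_excluded_elements()]).
#'
#' @param records Tibble from [standardize_compounds()] (needs `std_smiles`,
#'   `valid`).
#' @param mw_range Numeric length-2 inclusive molecular weight window in Da.
#' @param excluded_z Integer atomic numbers whose presence rejects a molecule.
#' @param drop If `TRUE`, rows failing the filter (or invalid) are removed.
#' @return `records` with `passed_filters` filled in and an added `mw` column.
#' @export
filter_druglike <- function(records, mw_range = c(100, 1000),
                            excluded_z = druglike_excluded_elements(),
                            drop = FALSE) {
  check_columns(records, c("compound_id", "std_smiles", "valid"))
  if (any(!records$valid)) {
    if (!drop) {
      abort_moa("invalid records present; standardize first or use drop = TRUE.",
                "moa_filter_error")
    }
  }
  flags <- rep(NA, nrow(records))
  mws <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!records$valid[i]) next
    pr <- mol_properties(records$std_smiles[i])
    mws[i] <- pr$mw
    flags[i] <- any(pr$elements == 6L) &&
      pr$mw >= mw_range[1] && pr$mw <= mw_range[2] &&
      !any(pr$elements %in% excluded_z)
  }
  out <- records
  out$mw <- mws
  out$passed_filters <- flags
  if (drop) out <- out[!is.na(flags) & flags, , drop = FALSE]
  as_tibble(out)
}

fold_bits <- function(bits, n_bits) {
  if (length(bits) %% n_bits != 0) {
    abort_moa("`n_bits` must divide the native fingerprint length.", "moa_input_error")
  }
  as.integer(rowSums(matrix(bits, nrow = n_bits)) > 0)
}

#' Circular (Morgan-type) fingerprints from SMILES
#'
#' Computes hashed circular substructure fingerprints (ECFP family; `radius = 2`
#' corresponds to ECFP4) and folds them by bitwise OR to `n_bits`. Bit
#' positions are deterministic for a given molecular graph and invariant to
#' SMILES atom ordering.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @param n_bits Folded fingerprint length; default 2048.
#' @param radius Circular neighborhood radius; default 2.
#' @return Integer 0/1 matrix with one row per molecule, `n_bits` columns
#'   named `b1..bN`, and `smiles`-derived row order preserved.
#' @export
fingerprint_smiles <- function(smiles, n_bits = 2048, radius = 2) {
  stopifnot(n_bits >= 8, radius %in% 1:5)
  fptype <- paste0("ECFP", 2L * radius)
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits,
                dimnames = list(NULL, paste0("b", seq_len(n_bits))))
  for (i in seq_along(smiles)) {
    if (is.na(smiles[i])) {
      abort_moa("cannot fingerprint an invalid (NA) structure.", "moa_input_error")
    }
    mol <- ChemmineOB::forEachMol("SMILES", paste0(smiles[i], "\n"), identity)
    bits <- tryCatch(ChemmineOB::fingerprint_OB(mol, fptype),
                     error = function(e) NULL)
    if (is.null(bits) || length(bits) == 0) {
      abort_moa(paste0("fingerprint generation failed for: ", smiles[i]),
                "moa_input_error")
    }
    out[i, ] <- if (length(bits) == n_bits) as.integer(bits) else fold_bits(bits, n_bits)
  }
  out
}

#' Fingerprint a compound table
#'
#' @param records Tibble with `compound_id` and `std_smiles` where
#'   `passed_filters` is `TRUE` (rows failing filters are an error).
#' @inheritParams fingerprint_smiles
#' @return `records` with an added `fingerprint` list-column of integer 0/1
#'   vectors of length `n_bits`.
#' @export
morgan_fingerprint <- function(records, n_bits = 2048, radius = 2) {
  check_columns(records, c("compound_id", "std_smiles"))
  if ("passed_filters" %in% names(records) &&
      any(is.na(records$passed_filters) | !records$passed_filters)) {
    abort_moa("all records must be valid and pass filters before fingerprinting.",
              "moa_input_error")
  }
  m <- fingerprint_smiles(records$std_smiles, n_bits = n_bits, radius = radius)
  out <- as_tibble(records)
  out$fingerprint <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  out
}

#' Stack a fingerprint list-column into a bit matrix
#'
#' @param data Tibble with `compound_id` and a `fingerprint` list-column, or a
#'   bit matrix (returned unchanged).
#' @return Integer 0/1 matrix, rownames = compound ids.
#' @export
fp_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  check_columns(data, c("compound_id", "fingerprint"))
  m <- do.call(rbind, data$fingerprint)
  rownames(m) <- data$compound_id
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T_c = |a \cap b| / |a \cup b|} on bit vectors. Two all-zero
#' fingerprints are defined to have similarity 0 (the formula's 0/0 case).
#'
#' @param a,b Integer/logical 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort_moa("fingerprint lengths differ.", "moa_input_error")
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param a,b 0/1 matrices with the same number of columns (rows = compounds).
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b) {
  a <- fp_matrix(a); b <- fp_matrix(b)
  if (ncol(a) != ncol(b)) abort_moa("fingerprint lengths differ.", "moa_input_error")
  inter <- a %*% t(b)
  un <- outer(rowSums(a), rowSums(b), "+") - inter
  s <- ifelse(un == 0, 0, inter / un)
  dimnames(s) <- list(rownames(a), rownames(b))
  s
}

#' Mean similarity to the k nearest reference fingerprints
#'
#' The applicability-domain distance measure: for each query, the mean
#' Tanimoto similarity of its `k` most similar reference fingerprints (all of
#' them, with a warning, when the reference holds fewer than `k`). `k = 1`
#' gives the nearest-neighbor similarity.
#'
#' @param query A 0/1 vector or matrix of queries.
#' @param reference 0/1 matrix of reference fingerprints (non-empty).
#' @param k Number of neighbors, default 5.
#' @return Numeric vector (one value per query row) in \[0, 1\].
#' @export
knn_mean_similarity <- function(query, reference, k = 5) {
  if (is.null(dim(query))) query <- matrix(as.integer(query), nrow = 1)
  reference <- fp_matrix(reference)
  if (nrow(reference) == 0) abort_moa("reference set is empty.", "moa_input_error")
  stopifnot(k >= 1)
  if (k > nrow(reference)) {
    warning("k exceeds reference size; using all ", nrow(reference), " references.")
    k <- nrow(reference)
  }
  s <- tanimoto_matrix(query, reference)
  apply(s, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(k)]))
}

#' Read / write SMILES line files
#'
#' `.smi` format: one `SMILES<whitespace>id` record per line.
#'
#' @param path File path.
#' @return `read_smi`: tibble with `compound_id`, `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  tibble(
    compound_id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    smiles = vapply(parts, `[`, character(1), 1)
  )
}

#' @rdname read_smi
#' @param data Data frame with `compound_id` and `smiles`.
#' @export
write_smi <- function(data, path) {
  check_columns(data, c("compound_id", "smiles"))
  writeLines(paste(data$smiles, data$compound_id, sep = "\t"), path)
  invisible(path)
}

# Hex packing for plain-text fingerprint persistence (512 hex chars per 2048 bits).
fp_to_hex <- function(m) {
  m <- fp_matrix(m)
  apply(m, 1, function(v) {
    nyb <- colSums(matrix(v, nrow = 4) * c(8, 4, 2, 1))
    paste(format.hexmode(as.integer(nyb)), collapse = "")
  })
}

hex_to_fp <- function(hex, ids = names(hex)) {
  m <- t(vapply(hex, function(h) {
    nyb <- strtoi(strsplit(h, "")[[1]], base = 16L)
    as.integer(rbind(nyb %/% 8, nyb %/% 4 %% 2, nyb %/% 2 %% 2, nyb %% 2))
  }, integer(nchar(hex[1]) * 4L)))
  rownames(m) <- ids
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

check_columns <- function(data, cols) {
  if (!is.data.frame(data)) abort_moa("expected a data frame.", "moa_input_error")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort_moa(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
              "moa_schema_error")
  }
  invisible(data)
}
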