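#' Drug-target interaction dataset
#'
#' Container for the matrix collection a run consumes: the binary
#' interaction matrix `Y` (drugs x targets), the drug-drug and
#' target-target interaction networks, three binary association matrices
#' (drug-disease, drug-side effect, target-disease) and the two
#' precomputed real-valued similarity matrices (chemical structure for
#' drugs, amino-acid sequence for targets).
#'
#' @param drug_ids character vector of drug identifiers (length m).
#' @param target_ids character vector of target identifiers (length n).
#' @param Y binary m x n drug-target interaction matrix.
#' @param A_drug binary symmetric m x m drug-drug interaction matrix,
#'   zero diagonal.
#' @param A_target binary symmetric n x n target-target interaction
#'   matrix, zero diagonal.
#' @param B_drug_disease binary m x d drug-disease association matrix.
#' @param B_drug_sideeffect binary m x s drug-side effect association
#'   matrix.
#' @param B_target_disease binary n x d target-disease association
#'   matrix.
#' @param S_chemical real symmetric m x m drug chemical-structure
#'   similarity, entries in [0, 1], unit diagonal.
#' @param S_sequence real symmetric n x n target sequence similarity,
#'   entries in [0, 1], unit diagonal.
#' @param validate if `TRUE` (default) stop on invariant violations.
#'
#' @return An object of class `dti_dataset` (a named list of the above).
#' @seealso [load_dti_dataset()], [validate_dataset()],
#'   [synthetic_dti_dataset()]
#' @export
dti_dataset <- function(drug_ids, target_ids, Y, A_drug, A_target,
                        B_drug_disease, B_drug_sideeffect,
                        B_target_disease, S_chemical, S_sequence,
                        validate = TRUE) {
  as_dbl <- function(M) {
    M <- as.matrix(M)
    storage.mode(M) <- "double"   # uniform storage: text round-trips exactly
    dimnames(M) <- NULL
    M
  }
  ds <- structure(
    list(
      drug_ids = as.character(drug_ids),
      target_ids = as.character(target_ids),
      Y = as_dbl(Y),
      A_drug = as_dbl(A_drug),
      A_target = as_dbl(A_target),
      B_drug_disease = as_dbl(B_drug_disease),
      B_drug_sideeffect = as_dbl(B_drug_sideeffect),
      B_target_disease = as_dbl(B_target_disease),
      S_chemical = as_dbl(S_chemical),
      S_sequence = as_dbl(S_sequence)
    ),
    class = "dti_dataset"
  )
  if (validate) {
    v <- validate_dataset(ds)
    if (length(v) > 0L)
      stop("invalid dti_dataset:\n  ", paste(v, collapse = "\n  "))
  }
  ds
}

# File names follow the public DTINet-style dataset layout so the real
# matrices drop in unchanged.
.dti_files <- function() {
  c(
    drug_ids = "drug.txt",
    target_ids = "protein.txt",
    Y = "mat_drug_protein.txt",
    A_drug = "mat_drug_drug.txt",
    A_target = "mat_protein_protein.txt",
    B_drug_disease = "mat_drug_disease.txt",
    B_drug_sideeffect = "mat_drug_se.txt",
    B_target_disease = "mat_protein_disease.txt",
    S_chemical = "Similarity_Matrix_Drugs.txt",
    S_sequence = "Similarity_Matrix_Proteins.txt"
  )
}

.read_dense <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  len <- unique(vapply(rows, length, 1L))
  if (length(len) != 1L)
    stop("ragged matrix in ", basename(path), ": row lengths ",
         paste(len, collapse = ", "))
  matrix(unlist(rows), nrow = length(rows), ncol = len, byrow = TRUE)
}

.write_dense <- function(M, path) {
  # full double precision so save/load round-trips bit-for-bit
  txt <- apply(M, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(txt, path)
}

#' Load a drug-target dataset directory
#'
#' Reads the whitespace-delimited dense numeric text matrices and id
#' lists of a dataset directory (public DTINet-style layout:
#' `mat_drug_protein.txt`, `mat_drug_drug.txt`, `mat_protein_protein.txt`,
#' `mat_drug_disease.txt`, `mat_drug_se.txt`, `mat_protein_disease.txt`,
#' `Similarity_Matrix_Drugs.txt`, `Similarity_Matrix_Proteins.txt`,
#' `drug.txt`, `protein.txt`).
#'
#' @param dir path to the dataset directory.
#' @param validate stop on invariant violations (default `TRUE`).
#' @return A [dti_dataset()].
#' @export
load_dti_dataset <- function(dir, validate = TRUE) {
  files <- .dti_files()
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing dataset file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  names(paths) <- names(files)
  dti_dataset(
    drug_ids = readLines(paths[["drug_ids"]]),
    target_ids = readLines(paths[["target_ids"]]),
    Y = .read_dense(paths[["Y"]]),
    A_drug = .read_dense(paths[["A_drug"]]),
    A_target = .read_dense(paths[["A_target"]]),
    B_drug_disease = .read_dense(paths[["B_drug_disease"]]),
    B_drug_sideeffect = .read_dense(paths[["B_drug_sideeffect"]]),
    B_target_disease = .read_dense(paths[["B_target_disease"]]),
    S_chemical = .read_dense(paths[["S_chemical"]]),
    S_sequence = .read_dense(paths[["S_sequence"]]),
    validate = validate
  )
}

#' Save a drug-target dataset directory
#'
#' Writes a [dti_dataset()] in the layout read by [load_dti_dataset()].
#' Matrices are written at full double precision so that
#' `load_dti_dataset(save_dti_dataset(ds, dir))` reproduces `ds` exactly.
#'
#' @param ds a [dti_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_dti_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "dti_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- .dti_files()
  writeLines(ds$drug_ids, file.path(dir, files[["drug_ids"]]))
  writeLines(ds$target_ids, file.path(dir, files[["target_ids"]]))
  for (f in setdiff(names(files), c("drug_ids", "target_ids")))
    .write_dense(ds[[f]], file.path(dir, files[[f]]))
  invisible(dir)
}

.is_binary <- function(M) all(M == 0 | M == 1)

.first_bad_cell <- function(M, bad) {
  idx <- which(bad, arr.ind = TRUE)
  sprintf("[%d,%d]=%g", idx[1, 1], idx[1, 2], M[idx[1, 1], idx[1, 2]])
}

#' Validate a drug-target dataset
#'
#' Checks every structural invariant of [dti_dataset()]: consistent
#' dimensions, 0/1 entries in the binary matrices, symmetry and zero
#' diagonal of the interaction networks, and symmetry, unit diagonal and
#' [0, 1] range of the similarity matrices. Violations are returned (not
#' raised) as human-readable descriptions; an empty character vector
#' means the dataset is valid.
#'
#' @param ds a [dti_dataset()] (or plain list with its fields).
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_dataset <- function(ds) {
  v <- character(0)
  m <- length(ds$drug_ids)
  n <- length(ds$target_ids)
  dims <- list(
    Y = c(m, n), A_drug = c(m, m), A_target = c(n, n),
    B_drug_disease = c(m, NA), B_drug_sideeffect = c(m, NA),
    B_target_disease = c(n, NA), S_chemical = c(m, m),
    S_sequence = c(n, n)
  )
  for (nm in names(dims)) {
    d <- dim(ds[[nm]])
    want <- dims[[nm]]
    if (d[1] != want[1] || (!is.na(want[2]) && d[2] != want[2]))
      v <- c(v, sprintf("%s has dimensions %dx%d, expected %sx%s", nm,
                        d[1], d[2], want[1],
                        if (is.na(want[2])) "*" else want[2]))
  }
  # shared disease axis
  if (ncol(ds$B_drug_disease) != ncol(ds$B_target_disease))
    v <- c(v, sprintf(
      "B_drug_disease and B_target_disease disagree on disease count (%d vs %d)",
      ncol(ds$B_drug_disease), ncol(ds$B_target_disease)))
  for (nm in c("Y", "A_drug", "A_target", "B_drug_disease",
               "B_drug_sideeffect", "B_target_disease")) {
    bad <- !(ds[[nm]] == 0 | ds[[nm]] == 1)
    if (any(bad))
      v <- c(v, sprintf("%s has non-binary entry %s", nm,
                        .first_bad_cell(ds[[nm]], bad)))
  }
  for (nm in c("A_drug", "A_target")) {
    M <- ds[[nm]]
    if (nrow(M) == ncol(M)) {
      if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
        v <- c(v, sprintf("%s is not symmetric", nm))
      if (any(diag(M) != 0))
        v <- c(v, sprintf("%s has a nonzero diagonal entry", nm))
    }
  }
  for (nm in c("S_chemical", "S_sequence")) {
    M <- ds[[nm]]
    if (nrow(M) != ncol(M)) next
    if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
      v <- c(v, sprintf("%s is not symmetric", nm))
    if (any(abs(diag(M) - 1) > 1e-12))
      v <- c(v, sprintf("%s diagonal is not all 1", nm))
    bad <- M < 0 | M > 1
    if (any(bad))
      v <- c(v, sprintf("%s has entry outside [0,1]: %s", nm,
                        .first_bad_cell(M, bad)))
  }
  v
}

#' Count known and unknown drugs/targets
#'
#' A drug (target) is *known* if it has at least one recorded interaction
#' in `Y`, i.e. its row (column) is not all zero; otherwise it is
#' *unknown* and appears as an isolated node in the drug-target bipartite
#' graph.
#'
#' @param ds a [dti_dataset()], or a binary interaction matrix.
#' @return Named integer vector with elements `known_drugs`,
#'   `unknown_drugs`, `known_targets`, `unknown_targets`.
#' @export
count_known_entities <- function(ds) {
  Y <- if (inherits(ds, "dti_dataset")) ds$Y else as.matrix(ds)
  unknown_d <- sum(rowSums(Y) == 0)
  unknown_t <- sum(colSums(Y) == 0)
  c(known_drugs = nrow(Y) - unknown_d, unknown_drugs = unknown_d,
    known_targets = ncol(Y) - unknown_t, unknown_targets = unknown_t)
}

#' @export
print.dti_dataset <- function(x, ...) {
  m <- length(x$drug_ids); n <- length(x$target_ids)
  k <- count_known_entities(x)
  cat("Drug-target interaction dataset\n")
  cat(sprintf("  %d drugs x %d targets, %d known interactions (%.4f%%)\n",
              m, n, sum(x$Y), 100 * sum(x$Y) / (m * n)))
  cat(sprintf("  unknown drugs: %d, unknown targets: %d\n",
              k[["unknown_drugs"]], k[["unknown_targets"]]))
  cat(sprintf("  diseases: %d, side effects: %d\n",
              ncol(x$B_drug_disease), ncol(x$B_drug_sideeffect)))
  invisible(x)
}
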