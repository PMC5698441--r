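#' Atomic structure container
#'
#' A light container for macromolecular coordinates: a data frame of atoms
#' plus optional crystallographic metadata. All geometry operations in the
#' package consume this class.
#'
#' @param atoms data frame with columns `type` ("ATOM"/"HETATM"), `chain`,
#'   `resno` (author residue number), `insert` (insertion code, "" if none),
#'   `resid` (3-letter residue name), `elety` (atom name), `elesy` (element
#'   symbol), `x`, `y`, `z` (angstroms), `occ`, `b`. Missing `occ`/`b`
#'   default to 1 and 0.
#' @param cell optional numeric length-6 unit cell `(a, b, c, alpha, beta,
#'   gamma)` in angstroms / degrees.
#' @param spacegroup optional space-group symbol.
#'
#' @return An object of class `struct3d`.
#' @export
structure3d <- function(atoms, cell = NULL, spacegroup = NULL) {
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stopf("atoms is missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("atom coordinates must be finite")
  if (!is.null(cell)) {
    if (length(cell) != 6) stopf("cell must have 6 values")
    if (any(cell[1:3] <= 0)) stopf("unit cell lengths must be > 0")
  }
  out <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              cell = cell, spacegroup = spacegroup)
  class(out) <- "struct3d"
  out
}

#' @export
print.struct3d <- function(x, ...) {
  cat(sprintf("struct3d: %d atoms, chains: %s\n",
              nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = " ")))
  if (!is.null(x$cell))
    cat(sprintf("unit cell: %s\n", paste(format(x$cell), collapse = " ")))
  invisible(x)
}

#' Select atom indices in a structure
#'
#' @param struct a [structure3d()] object.
#' @param chain optional chain id(s).
#' @param resno optional residue number(s).
#' @param elety optional atom name(s), e.g. `"CA"`.
#' @param heavy drop hydrogens/deuteriums (default `TRUE`).
#' @param het include HETATM records (default `FALSE`); water is always
#'   excluded unless `water = TRUE`.
#' @param water include water molecules (default `FALSE`).
#'
#' @return Integer row indices into `struct$atoms`.
#' @export
select_atoms <- function(struct, chain = NULL, resno = NULL, elety = NULL,
                         heavy = TRUE, het = FALSE, water = FALSE) {
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy) keep <- keep & !(toupper(a$elesy) %in% c("H", "D"))
  if (!het) keep <- keep & a$type == "ATOM"
  if (!water) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  which(keep)
}

# xyz coordinate matrix for selected atoms
#' @noRd
atom_xyz <- function(struct, sel = NULL) {
  a <- struct$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# coordinates of one named atom; NULL if absent
#' @noRd
atom_coord <- function(struct, chain, resno, elety, insert = NULL) {
  a <- struct$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (!is.null(insert)) i <- i[a$insert[i] == insert]
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Apply a rigid transform to a structure
#'
#' @param struct a [structure3d()] object.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return Transformed `struct3d`.
#' @export
transform_structure <- function(struct, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- atom_xyz(struct)
  new <- t(rotation %*% t(xyz) + translation)
  struct$atoms$x <- new[, 1]
  struct$atoms$y <- new[, 2]
  struct$atoms$z <- new[, 3]
  struct
}
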