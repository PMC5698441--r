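# Solvent accessible surface area (Shrake-Rupley), interface burial, and
# least-squares superposition of structure copies.

#' Default van der Waals radius set
#'
#' NACCESS-style radii in angstroms, keyed by element symbol. Calcium is
#' included (1.74) so structural Ca2+ ions can be treated as part of a
#' protein component.
#'
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
    P = 1.80, SE = 1.90, CA = 1.74, ZN = 1.39, MG = 1.73, F = 1.47,
    CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75, FE = 1.40,
    MN = 1.40, CU = 1.40)
}

# deterministic, nearly uniform sphere points (golden-section spiral)
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @noRd
atom_radii <- function(struct, idx, radii, fallback_radius = NULL) {
  el <- toupper(struct$atoms$elesy[idx])
  r <- radii[el]
  if (any(is.na(r))) {
    if (is.null(fallback_radius))
      stopf("no van der Waals radius for element(s): %s",
            paste(unique(el[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- fallback_radius
  }
  as.numeric(r)
}

# Shrake-Rupley accessible area per atom of `sel`, occluded by `env`
#' @noRd
sr_area <- function(struct, sel, env, probe, n_points, radii,
                    fallback_radius) {
  pts <- sphere_points(n_points)
  xyz_sel <- atom_xyz(struct, sel)
  xyz_env <- atom_xyz(struct, env)
  r_sel <- atom_radii(struct, sel, radii, fallback_radius)
  r_env <- atom_radii(struct, env, radii, fallback_radius)
  env_in_sel <- match(env, sel)  # to skip self-occlusion
  areas <- numeric(length(sel))
  for (i in seq_along(sel)) {
    ri <- r_sel[i] + probe
    ci <- xyz_sel[i, ]
    d2 <- (xyz_env[, 1] - ci[1])^2 + (xyz_env[, 2] - ci[2])^2 +
      (xyz_env[, 3] - ci[3])^2
    rj <- r_env + probe
    nb <- which(d2 < (ri + rj)^2 & d2 > 1e-12)
    nb <- nb[is.na(env_in_sel[nb]) | env_in_sel[nb] != i]
    p <- pts * ri
    p <- sweep(p, 2, ci, `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      cj <- xyz_env[j, ]
      dj2 <- (p[, 1] - cj[1])^2 + (p[, 2] - cj[2])^2 + (p[, 3] - cj[3])^2
      acc <- acc & (dj2 > rj[j]^2)
    }
    areas[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  areas
}

#' Solvent accessible surface area of a selection
#'
#' Shrake-Rupley quadrature: for each heavy atom, `n_points` points are
#' distributed on the probe-expanded sphere and the accessible fraction
#' is the share of points outside every other probe-expanded atom sphere.
#' Waters and HETATM records are excluded from selections by default (use
#' [select_atoms()] with `het = TRUE` to include ions).
#'
#' @param struct a [structure3d()].
#' @param selection integer atom indices (from [select_atoms()]); default
#'   all protein heavy atoms.
#' @param probe probe radius in angstroms (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named radius set (default [default_vdw_radii()]).
#' @param fallback_radius optional radius for unknown elements; unknown
#'   elements are an error when NULL.
#' @param environment optional atom indices that occlude the selection
#'   (default: the selection itself, i.e. the component in isolation).
#' @return List (`surface_report`) with `total_area`, `per_residue`
#'   (data frame chain/resno/resid/area), `probe`, `n_points`.
#' @export
sasa <- function(struct, selection = NULL, probe = 1.4, n_points = 960,
                 radii = default_vdw_radii(), fallback_radius = NULL,
                 environment = NULL) {
  if (is.null(selection)) selection <- select_atoms(struct)
  if (length(selection) == 0) stopf("empty selection")
  env <- environment %||% selection
  areas <- sr_area(struct, selection, env, probe, n_points, radii,
                   fallback_radius)
  a <- struct$atoms[selection, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert)
  per <- stats::aggregate(areas, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  info <- data.frame(key = key[first], chain = a$chain[first],
                     resno = a$resno[first], resid = a$resid[first],
                     stringsAsFactors = FALSE)
  per <- merge(info, per, by = "key")
  per <- per[order(per$chain, per$resno), c("chain", "resno", "resid", "x")]
  names(per)[4] <- "area"
  rownames(per) <- NULL
  list(total_area = sum(areas), per_residue = per, probe = probe,
       n_points = n_points)
}

#' Interface area buried between two components
#'
#' `buried_A = sasa(A alone) - sasa(A in the A+B complex)`, and likewise
#' for B, with both components frozen in their complexed conformations.
#'
#' @param struct a [structure3d()].
#' @param selection_a,selection_b disjoint atom index sets.
#' @inheritParams sasa
#' @return List (`interface_report`) with `buried_a`, `buried_b`,
#'   `mean_interface`, and the isolated/complexed totals.
#' @export
buried_area <- function(struct, selection_a, selection_b, probe = 1.4,
                        n_points = 960, radii = default_vdw_radii(),
                        fallback_radius = NULL) {
  if (length(intersect(selection_a, selection_b)) > 0)
    stopf("selections overlap")
  both <- c(selection_a, selection_b)
  a_alone <- sasa(struct, selection_a, probe, n_points, radii,
                  fallback_radius)
  b_alone <- sasa(struct, selection_b, probe, n_points, radii,
                  fallback_radius)
  a_cplx <- sasa(struct, selection_a, probe, n_points, radii,
                 fallback_radius, environment = both)
  b_cplx <- sasa(struct, selection_b, probe, n_points, radii,
                 fallback_radius, environment = both)
  ba <- a_alone$total_area - a_cplx$total_area
  bb <- b_alone$total_area - b_cplx$total_area
  list(buried_a = ba, buried_b = bb, mean_interface = (ba + bb) / 2,
       area_a_alone = a_alone$total_area, area_b_alone = b_alone$total_area,
       area_a_complex = a_cplx$total_area, area_b_complex = b_cplx$total_area,
       probe = probe, n_points = n_points)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R %*% x_b + t` against `x_a` over paired atoms, with reflection
#' correction so that `det(R) = +1`.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices of paired atoms (row
#'   i of one pairs with row i of the other).
#' @return List (`superposition`) with `rotation`, `translation`, `rmsd`,
#'   `n_pairs`.
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stopf("coordinate sets differ in size")
  n <- nrow(coords_a)
  if (n < 3) stopf("need at least 3 paired atoms")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  aa <- sweep(coords_a, 2, ca)
  bb <- sweep(coords_b, 2, cb)
  h <- t(bb) %*% aa
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stopf("degenerate (collinear) geometry; rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$v %*% corr %*% t(sv$u)
  trans <- ca - as.numeric(rot %*% cb)
  fitted <- t(rot %*% t(coords_b) + trans)
  rmsd <- sqrt(mean(rowSums((fitted - coords_a)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, n_pairs = n)
}

#' RMSD between two copies of a complex over a residue region
#'
#' C-alpha atoms are paired by identical author residue numbers present
#' in both copies (per chain pair); residues unresolved in either copy
#' are skipped and counted. The region's atoms are superposed with
#' [superpose()] and the post-fit RMSD returned.
#'
#' @param struct a [structure3d()].
#' @param chains_a,chains_b chain id vectors of the two copies, in
#'   corresponding order (e.g. `c("A", "C")` vs `c("B", "D")`).
#' @param resno optional residue-number subset (applied to every chain
#'   pair), e.g. `80:145`.
#' @return List with `rmsd`, `n_pairs`, `n_skipped`, and the underlying
#'   `superposition`.
#' @export
region_rmsd <- function(struct, chains_a, chains_b, resno = NULL) {
  if (length(chains_a) != length(chains_b))
    stopf("copies must pair the same number of chains")
  xa <- NULL
  xb <- NULL
  skipped <- 0L
  a <- struct$atoms
  for (k in seq_along(chains_a)) {
    ra <- a[a$chain == chains_a[k] & a$elety == "CA" & a$type == "ATOM", ]
    rb <- a[a$chain == chains_b[k] & a$elety == "CA" & a$type == "ATOM", ]
    if (!is.null(resno)) {
      ra <- ra[ra$resno %in% resno, ]
      rb <- rb[rb$resno %in% resno, ]
    }
    common <- intersect(ra$resno, rb$resno)
    skipped <- skipped + length(setdiff(union(ra$resno, rb$resno), common))
    ia <- match(common, ra$resno)
    ib <- match(common, rb$resno)
    xa <- rbind(xa, as.matrix(ra[ia, c("x", "y", "z")]))
    xb <- rbind(xb, as.matrix(rb[ib, c("x", "y", "z")]))
  }
  if (is.null(xa) || nrow(xa) < 3)
    stopf("fewer than 3 matched residues between copies")
  fit <- superpose(xa, xb)
  list(rmsd = fit$rmsd, n_pairs = fit$n_pairs, n_skipped = skipped,
       superposition = fit)
}
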