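# Backbone characterization of bound peptide helices: dihedrals, alpha vs
# 3-10 classification, backbone hydrogen bonds, anchor spacing and
# hydrophobic-face coherence.

# ordered backbone table for one chain; one row per residue
#' @noRd
backbone_table <- function(struct, chain, resno = NULL) {
  a <- struct$atoms
  a <- a[a$chain == chain & a$type == "ATOM" &
           !(toupper(a$elesy) %in% c("H", "D")) &
           !(a$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  if (nrow(a) == 0) stopf("no atoms for chain '%s'", chain)
  res <- unique(a[, c("resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  get <- function(rn, ins, ety) {
    i <- which(a$resno == rn & a$insert == ins & a$elety == ety)
    if (length(i) == 0) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  res$N <- lapply(seq_len(nrow(res)),
                  function(i) get(res$resno[i], res$insert[i], "N"))
  res$CA <- lapply(seq_len(nrow(res)),
                   function(i) get(res$resno[i], res$insert[i], "CA"))
  res$C <- lapply(seq_len(nrow(res)),
                  function(i) get(res$resno[i], res$insert[i], "C"))
  res$O <- lapply(seq_len(nrow(res)),
                  function(i) get(res$resno[i], res$insert[i], "O"))
  res$CB <- lapply(seq_len(nrow(res)),
                   function(i) get(res$resno[i], res$insert[i], "CB"))
  rownames(res) <- NULL
  res
}

# peptide-bond continuity between consecutive residues (C-N distance)
#' @noRd
bonded_to_next <- function(bb, i, max_cn = 2.0) {
  if (i >= nrow(bb)) return(FALSE)
  c_i <- bb$C[[i]]
  n_j <- bb$N[[i + 1]]
  if (any(is.na(c_i)) || any(is.na(n_j))) return(FALSE)
  sqrt(sum((c_i - n_j)^2)) <= max_cn
}

#' Backbone dihedral angles of a chain
#'
#' Standard phi (C(i-1), N, CA, C) and psi (N, CA, C, N(i+1)) torsions in
#' degrees, in (-180, 180]. Angles are undefined (NA, with the
#' corresponding `*_defined` flag FALSE) at segment termini and across
#' chain breaks (peptide C-N distance > 2 angstroms), and whenever a
#' backbone atom is missing; such residues are flagged, not dropped.
#'
#' @param struct a [structure3d()].
#' @param chain chain id.
#' @param resno optional residue-number subset (e.g. `78:88`).
#' @return Data frame with `chain`, `resno`, `resid`, `phi`, `psi`,
#'   `phi_defined`, `psi_defined`, `backbone_complete`.
#' @export
compute_dihedrals <- function(struct, chain, resno = NULL) {
  bb <- backbone_table(struct, chain, resno)
  n <- nrow(bb)
  phi <- psi <- rep(NA_real_, n)
  complete <- vapply(seq_len(n), function(i) {
    !any(is.na(c(bb$N[[i]], bb$CA[[i]], bb$C[[i]])))
  }, logical(1))
  for (i in seq_len(n)) {
    if (!complete[i]) next
    if (i > 1 && complete[i - 1] && bonded_to_next(bb, i - 1)) {
      phi[i] <- torsion_angle(bb$C[[i - 1]], bb$N[[i]], bb$CA[[i]], bb$C[[i]])
    }
    if (i < n && complete[i + 1] && bonded_to_next(bb, i)) {
      psi[i] <- torsion_angle(bb$N[[i]], bb$CA[[i]], bb$C[[i]], bb$N[[i + 1]])
    }
  }
  data.frame(chain = chain, resno = bb$resno, resid = bb$resid,
             phi = phi, psi = psi,
             phi_defined = !is.na(phi), psi_defined = !is.na(psi),
             backbone_complete = complete,
             stringsAsFactors = FALSE)
}

#' Classify residues as alpha, 3-10, or non-helical
#'
#' A residue is right-handed helical when `phi` lies in `phi_range` and
#' `psi` in `psi_range`. Within that band, psi angles above `psi_310`
#' (default -37 degrees, midway between canonical alpha -47 and 3-10 -26)
#' are called `three10`, the rest `alpha`. The mirror-image band (phi and
#' psi negated) is reported as `other_helical` (left-handed); anything
#' else, or residues with undefined angles, is `nonhelical`.
#'
#' @param dihedrals output of [compute_dihedrals()].
#' @param psi_310 psi boundary between alpha and 3-10 (degrees).
#' @param phi_range,psi_range right-handed helical band (degrees).
#' @return `dihedrals` with an added factor column `class`.
#' @export
classify_helix <- function(dihedrals, psi_310 = -37,
                           phi_range = c(-100, -30),
                           psi_range = c(-80, 0)) {
  phi <- dihedrals$phi
  psi <- dihedrals$psi
  cls <- rep("nonhelical", nrow(dihedrals))
  ok <- !is.na(phi) & !is.na(psi)
  right <- ok & phi >= phi_range[1] & phi <= phi_range[2] &
    psi >= psi_range[1] & psi <= psi_range[2]
  left <- ok & phi >= -phi_range[2] & phi <= -phi_range[1] &
    psi >= -psi_range[2] & psi <= -psi_range[1]
  cls[left] <- "other_helical"
  cls[right & psi > psi_310] <- "three10"
  cls[right & psi <= psi_310] <- "alpha"
  dihedrals$class <- factor(cls, levels = c("alpha", "three10",
                                            "other_helical", "nonhelical"))
  dihedrals
}

#' Detect backbone hydrogen bonds within a chain
#'
#' Amide hydrogens are inferred geometrically when absent: H is placed in
#' the plane of C(i-1), N(i), CA(i), opposite the C/CA bisector at the N,
#' with an N-H bond of 1.01 angstroms. A bond N(d) -> O(a) is reported
#' when the N...O distance is at most `distance_cutoff`, the N-H...O
#' angle is at least `angle_cutoff`, and the donor-acceptor sequence
#' offset `donor_res - acceptor_res` is at least `min_offset` (alpha
#' helices give offset 4, 3-10 helices offset 3).
#'
#' @param struct a [structure3d()].
#' @param chain chain id.
#' @param distance_cutoff maximum N...O distance in angstroms (default 3.5).
#' @param angle_cutoff minimum N-H...O angle in degrees (default 120).
#' @param min_offset minimum sequence separation (default 2).
#' @param resno optional residue-number subset.
#' @return Data frame with `donor_resno`, `acceptor_resno`, `offset`,
#'   `dist`, `angle`.
#' @export
detect_backbone_hbonds <- function(struct, chain, distance_cutoff = 3.5,
                                   angle_cutoff = 120, min_offset = 2,
                                   resno = NULL) {
  bb <- backbone_table(struct, chain, resno)
  n <- nrow(bb)
  out <- data.frame(donor_resno = integer(), acceptor_resno = integer(),
                    offset = integer(), dist = numeric(), angle = numeric())
  for (d in seq_len(n)) {
    nd <- bb$N[[d]]
    if (any(is.na(nd))) next
    # inferred amide H (first residue of a segment has no defined H)
    if (d == 1 || any(is.na(bb$C[[d - 1]])) || !bonded_to_next(bb, d - 1))
      next
    cprev <- bb$C[[d - 1]]
    ca <- bb$CA[[d]]
    if (any(is.na(ca))) next
    hdir <- unit(-(unit(cprev - nd) + unit(ca - nd)))
    h <- nd + 1.01 * hdir
    for (acc in seq_len(n)) {
      off <- d - acc
      if (off < min_offset) next
      oa <- bb$O[[acc]]
      if (any(is.na(oa))) next
      dist <- sqrt(sum((nd - oa)^2))
      if (dist > distance_cutoff) next
      ang <- vec_angle(nd, h, oa)
      if (ang < angle_cutoff) next
      out <- rbind(out, data.frame(donor_resno = bb$resno[d],
                                   acceptor_resno = bb$resno[acc],
                                   offset = bb$resno[d] - bb$resno[acc],
                                   dist = dist, angle = ang))
    }
  }
  rownames(out) <- NULL
  out
}

#' Distance between the C-alpha atoms of two residues
#'
#' @param struct a [structure3d()].
#' @param chain chain id.
#' @param res_i,res_j residue numbers.
#' @return Euclidean distance in angstroms.
#' @export
anchor_spacing <- function(struct, chain, res_i, res_j) {
  ci <- atom_coord(struct, chain, res_i, "CA")
  cj <- atom_coord(struct, chain, res_j, "CA")
  if (is.null(ci)) stopf("residue %s %d has no CA atom", chain, res_i)
  if (is.null(cj)) stopf("residue %s %d has no CA atom", chain, res_j)
  sqrt(sum((ci - cj)^2))
}

#' Check whether hydrophobic anchors project from one helix face
#'
#' The local helix axis is the first principal axis of the chain's
#' C-alpha atoms (over the span of the anchors). Each anchor's CA->CB
#' vector is projected onto the plane normal to that axis; the anchors
#' are coherent when every pairwise projected angle is below `max_angle`.
#'
#' @param struct a [structure3d()].
#' @param chain chain id.
#' @param anchors residue numbers of the anchor positions (glycines,
#'   which lack CB, are skipped).
#' @param max_angle coherence threshold in degrees (default 120).
#' @return List with `coherent`, `max_pairwise_angle`, `n_anchors_used`.
#' @export
hydrophobic_face_check <- function(struct, chain, anchors, max_angle = 120) {
  if (length(anchors) < 2) stopf("need at least 2 anchor residues")
  span <- seq(min(anchors), max(anchors))
  a <- struct$atoms
  ca_rows <- a[a$chain == chain & a$elety == "CA" & a$resno %in% span &
                 a$type == "ATOM", , drop = FALSE]
  if (nrow(ca_rows) < 3)  # too short a span: use the whole chain for the axis
    ca_rows <- a[a$chain == chain & a$elety == "CA" & a$type == "ATOM", ,
                 drop = FALSE]
  if (nrow(ca_rows) < 3)
    stopf("need at least 3 CA atoms to define a helix axis")
  ca_xyz <- as.matrix(ca_rows[, c("x", "y", "z")])
  centered <- sweep(ca_xyz, 2, colMeans(ca_xyz))
  axis <- svd(centered)$v[, 1]
  vecs <- list()
  for (r in anchors) {
    ca <- atom_coord(struct, chain, r, "CA")
    cb <- atom_coord(struct, chain, r, "CB")
    if (is.null(ca) || is.null(cb)) next
    v <- cb - ca
    v <- v - sum(v * axis) * axis  # project off the axis component
    if (sqrt(sum(v^2)) < 1e-8) next
    vecs[[length(vecs) + 1]] <- unit(v)
  }
  if (length(vecs) < 2)
    stopf("fewer than 2 anchors with usable CA->CB vectors")
  maxang <- 0
  for (i in seq_along(vecs)) {
    for (j in seq_along(vecs)) {
      if (j <= i) next
      cosang <- max(-1, min(1, sum(vecs[[i]] * vecs[[j]])))
      maxang <- max(maxang, acos(cosang) * 180 / pi)
    }
  }
  list(coherent = maxang < max_angle, max_pairwise_angle = maxang,
       n_anchors_used = length(vecs))
}
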