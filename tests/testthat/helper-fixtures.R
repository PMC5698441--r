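# Fixtures are built in code at test time; nothing binary is stored.

# minimal PDB text with a CRYST1 record and a few atoms
write_mini_pdb <- function(path, atoms, cell = c(20, 25, 30, 90, 90, 90),
                           spacegroup = "P 1") {
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                   spacegroup)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$type, i, a$elety, a$alt %||% " ", a$resid, a$chain, a$resno, " ",
      a$x, a$y, a$z, a$occ, a$b, a$elesy))
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the same atoms as a minimal mmCIF atom_site loop
write_mini_cif <- function(path, atoms, cell = c(20, 25, 30, 90, 90, 90)) {
  head <- c("data_test",
            sprintf("_cell.length_a   %.3f", cell[1]),
            sprintf("_cell.length_b   %.3f", cell[2]),
            sprintf("_cell.length_c   %.3f", cell[3]),
            "_cell.angle_alpha   90.00",
            "_cell.angle_beta    90.00",
            "_cell.angle_gamma   90.00",
            "loop_",
            "_atom_site.group_PDB", "_atom_site.id",
            "_atom_site.type_symbol", "_atom_site.label_atom_id",
            "_atom_site.label_alt_id", "_atom_site.label_comp_id",
            "_atom_site.label_asym_id", "_atom_site.label_entity_id",
            "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
            "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
            "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
            "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
            "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            a$type, i, a$elesy, a$elety, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, a$b, a$resno, a$resid, a$chain, a$elety)
  }, character(1))
  writeLines(c(head, rows, "#"), path)
  path
}

# small atom table builder
mini_atoms <- function() {
  data.frame(
    type = "ATOM",
    chain = c("A", "A", "A", "B"),
    resno = c(1L, 1L, 2L, 5L),
    resid = c("GLY", "GLY", "ALA", "LEU"),
    elety = c("N", "CA", "CA", "CA"),
    elesy = c("N", "C", "C", "C"),
    x = c(0, 1.458, 4.1, 10),
    y = c(0, 0, 1.2, -3),
    z = c(0, 0, 0.4, 2.5),
    occ = 1, b = 10,
    stringsAsFactors = FALSE)
}

# crosslink record rows from compact arguments
xl_rec <- function(protein_a, pos_a, protein_b, pos_b, id_score = 30,
                   fdr = 0.01, replicate = 1L, charge = 3L,
                   peptide_a = NULL, peptide_b = NULL) {
  data.frame(protein_a = protein_a, pos_a = as.integer(pos_a),
             peptide_a = peptide_a %||% paste0("PEP", protein_a, pos_a),
             protein_b = protein_b, pos_b = as.integer(pos_b),
             peptide_b = peptide_b %||% paste0("PEP", protein_b, pos_b),
             id_score = id_score, fdr = fdr,
             replicate = as.integer(replicate),
             charge = as.integer(charge), stringsAsFactors = FALSE)
}

# random rigid transform (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, sd = 10))
}

# mixed alpha -> 3-10 plan mimicking the bound AKAP79 helix: alpha body,
# 3-10 turn before the C-terminal anchor
akap_mimic_plan <- function() {
  helix_plan("GAWASLKRLVTR",
             phi = c(rep(-57, 7), -49, -49, rep(-57, 3)),
             psi = c(rep(-47, 7), -26, -26, rep(-47, 3)))
}
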