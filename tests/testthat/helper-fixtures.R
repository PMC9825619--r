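# Hand-written text fixtures for the structure readers. Column layouts follow
# wwPDB format v3.3 / the mmCIF atom_site category.

pdb_atom_line <- function(serial, elety, res_name, chain, res_seq, x, y, z,
                          occ = 1.0, b = 90.0, alt = " ") {
  # elety must be pre-padded to 4 characters (" CA ", " N  ", ...)
  sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, res_name, chain, res_seq, x, y, z, occ, b)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# the canonical 3-residue fixture: CA at (0,0,0), (3.8,0,0), (7.6,0,0)
three_residue_pdb <- function(b = c(91.0, 65.5, 88.0)) {
  write_pdb_fixture(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0.0, 0, 0, b = b[1]),
    pdb_atom_line(2, " CA ", "GLY", "A", 2, 3.8, 0, 0, b = b[2]),
    pdb_atom_line(3, " CA ", "LEU", "A", 3, 7.6, 0, 0, b = b[3])
  ))
}

three_residue_cif <- function(b = c(91.0, 65.5, 88.0)) {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_asym_id", "pdbx_PDB_model_num")),
    sprintf("ATOM %d C CA . %s A 1 %d ? %.3f 0.000 0.000 1.00 %.2f %d A 1",
            1:3, c("ALA", "GLY", "LEU"), 1:3, c(0, 3.8, 7.6), b, 1:3),
    "#"
  ), path)
  path
}

# structure with given coordinates (matrix n x 3), for geometric toys
coords_structure <- function(coords, b = 90) {
  allokit:::new_calpha_structure(tibble::tibble(
    chain_id = "A", res_seq = seq_len(nrow(coords)), res_name = "ALA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    bfactor = rep_len(b, nrow(coords))
  ), source_path = "synthetic:test")
}

collinear3 <- function() {
  coords_structure(cbind(c(0, 3.8, 7.6), 0, 0))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
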