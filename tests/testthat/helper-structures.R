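# Synthetic structure fixtures, built in code (no deposited coordinates).

write_minimal_pdb <- function(atoms, path) {
  # atoms: data.frame(chain, resno, resid, elety, element, x, y, z, o, b)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    nm <- if (nchar(a$elety) >= 4) substr(a$elety, 1, 4) else paste0(" ", a$elety)
    # name cols 13-16, altLoc 17 (blank), resName 18-20, chain 22, resSeq 23-26
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm, a$resid, a$chain, a$resno, a$x, a$y, a$z, a$o, a$b,
            a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# active-site-like synthetic model: a serine hydroxyl 2.7 A from a
# non-bridging phosphate oxygen, a second serine 3.7 A away, a backbone
# N...O pair at 2.9 A and another at 3.3 A (weak band)
synthetic_site_atoms <- function() {
  data.frame(
    chain = "A",
    resno = c(210, 210, 211, 211, 301, 301, 301, 118, 120),
    resid = c("SER", "SER", "SER", "SER", "AMP", "AMP", "AMP", "VAL", "HIS"),
    elety = c("CB", "OG", "CB", "OG", "P", "O1P", "O2P", "N", "O"),
    element = c("C", "O", "C", "O", "P", "O", "O", "N", "O"),
    # OG210-O1P 2.7 (good H bond); OG211-O1P 3.7 (too long);
    # N118-O2P 3.3 (weak band); N118-O120 2.9 (good)
    x = c(0.0, 0.0, 7.4, 6.4, 2.0, 2.7, 2.7, 2.7, 2.7),
    y = c(-1.4, 0.0, 0.0, 0.0, 1.6, 0.0, 3.3, 6.6, 9.5),
    z = c(0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0),
    o = 1, b = 10, stringsAsFactors = FALSE)
}

synthetic_site_model <- function() {
  path <- tempfile(fileext = ".pdb")
  write_minimal_pdb(synthetic_site_atoms(), path)
  read_structure(path, source_id = "synthetic_active_site")
}

# nucleotide fragment with a prescribed glycosidic torsion chi
# (O4'-C1'-N9-C4 for the purine case)
chi_nucleotide_atoms <- function(chi_deg, purine = TRUE) {
  chi <- chi_deg * pi / 180
  p_o4 <- c(-0.7, 1.3, 0)      # O4'
  p_c1 <- c(0, 0, 0)           # C1'
  p_n  <- c(1.47, 0, 0)        # N9 (or N1)
  # C4 (or C2) placed so that the dihedral about C1'-N9 equals chi:
  # start in the O4' plane (chi = 0 -> cis) and rotate about the x axis
  r <- 1.37
  ang <- 125 * pi / 180        # C1'-N9-C4 angle
  base <- c(p_n[1] + r * cos(ang), r * sin(ang), 0)
  rot <- base
  rot[2] <- base[2] * cos(chi)
  rot[3] <- -base[2] * sin(chi) # sign chosen to match the IUPAC torsion sense
  nms <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  data.frame(
    chain = "B", resno = 5,
    resid = if (purine) "A" else "U",
    elety = nms,
    element = c("O", "C", "N", "C"),
    x = c(p_o4[1], p_c1[1], p_n[1], rot[1]),
    y = c(p_o4[2], p_c1[2], p_n[2], rot[2]),
    z = c(p_o4[3], p_c1[3], p_n[3], rot[3]),
    o = 1, b = 10, stringsAsFactors = FALSE)
}

chi_nucleotide_model <- function(chi_deg, purine = TRUE) {
  path <- tempfile(fileext = ".pdb")
  write_minimal_pdb(chi_nucleotide_atoms(chi_deg, purine), path)
  read_structure(path, source_id = sprintf("synthetic_chi_%g", chi_deg))
}
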