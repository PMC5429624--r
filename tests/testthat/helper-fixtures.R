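# A small hand-built PDB fixture: chain A = ALA, GLY, ARG; chain B = A, U;
# plus a water, a magnesium ion, and an altloc pair on ALA's CA.

pdb_line <- function(serial, name, alt, res, chain, resno, x, y, z, occ = 1,
                     elem = substr(name, 1, 1), rec = "ATOM") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, res, chain, resno, x, y, z, occ, 0, elem)
}

fixture_pdb <- function(alt_occ = c(0.7, 0.3)) {
  s <- 0
  nxt <- function() { s <<- s + 1; s }
  res_bb <- function(res, chain, resno, x0, extra = NULL) {
    ln <- c(pdb_line(nxt(), "N", " ", res, chain, resno, x0, 0.5, 0, elem = "N"),
            if (res == "ALA") c(
              pdb_line(nxt(), "CA", "A", res, chain, resno, x0 + 1.0, 0, 0,
                       occ = alt_occ[1], elem = "C"),
              pdb_line(nxt(), "CA", "B", res, chain, resno, 99, 99, 99,
                       occ = alt_occ[2], elem = "C"))
            else pdb_line(nxt(), "CA", " ", res, chain, resno, x0 + 1.0, 0, 0,
                          elem = "C"),
            pdb_line(nxt(), "C", " ", res, chain, resno, x0 + 2.0, 0.5, 0,
                     elem = "C"),
            pdb_line(nxt(), "O", " ", res, chain, resno, x0 + 2.0, 1.7, 0,
                     elem = "O"))
    c(ln, extra)
  }
  lines <- c(
    res_bb("ALA", "A", 1, 0),
    res_bb("GLY", "A", 2, 4),
    res_bb("ARG", "A", 3, 8,
           pdb_line(nxt(), "CB", " ", "ARG", "A", 3, 9.0, -1.3, 0.5,
                    elem = "C")),
    "TER",
    pdb_line(nxt(), "P", " ", "A", "B", 1, 0, 20, 0, elem = "P"),
    pdb_line(nxt(), "C1'", " ", "A", "B", 1, 1.2, 20.5, 0, elem = "C"),
    pdb_line(nxt(), "N1", " ", "A", "B", 1, 2.2, 20.2, 0, elem = "N"),
    pdb_line(nxt(), "P", " ", "U", "B", 2, 6, 20, 0, elem = "P"),
    pdb_line(nxt(), "C1'", " ", "U", "B", 2, 7.2, 20.5, 0, elem = "C"),
    pdb_line(nxt(), "N1", " ", "U", "B", 2, 8.2, 20.2, 0, elem = "N"),
    "TER",
    pdb_line(nxt(), "O", " ", "HOH", "B", 90, 50, 50, 50, rec = "HETATM",
             elem = "O"),
    pdb_line(nxt(), "MG", " ", "MG", "A", 91, 60, 60, 60, rec = "HETATM",
             elem = "MG"),
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}
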