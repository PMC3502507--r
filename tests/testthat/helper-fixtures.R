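# hand-written file fixtures, built in code at test time

pdbAtomLine <- function(serial, resno, x, y, z, alt = " ", occ = 1.00,
                        resname = "ALA", chain = "A", elety = " CA ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, resname, chain, resno, x, y, z, occ, 0.00)
}

writeTempPdb <- function(lines, name = "fix.pdb") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(c(lines, "TER", "END"), path)
  path
}

# three residues on a line-free path (non-collinear)
threeResidueLines <- function() {
  c(pdbAtomLine(1, 1, 1.234, 2.345, 3.456),
    pdbAtomLine(2, 2, 4.000, 5.000, 6.000, resname = "GLY"),
    pdbAtomLine(3, 3, 7.500, 8.000, 0.250, resname = "SER"))
}

writeTempText <- function(lines, fileext = ".txt") {
  path <- withr::local_tempfile(fileext = fileext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a domtblout row as 23 whitespace-separated fields
domtbloutRow <- function(pfam, eValue, from, to, tname = "target",
                         tlen = 200) {
  paste(tname, "-", tlen, pfam, pfam, to - from + 1,
        format(eValue, scientific = TRUE), "100.0", "0.1", 1, 1,
        format(eValue, scientific = TRUE), format(eValue, scientific = TRUE),
        "100.0", "0.1", 1, to - from + 1, from, to, from, to, "0.98",
        "test domain")
}
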