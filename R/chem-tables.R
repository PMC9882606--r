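# Fixed chemistry lookup tables: residue vocabularies, nucleobase ring
# topology, donor/acceptor capabilities, van der Waals radii.

# Bondi van der Waals radii (Angstrom); heavy atoms only, C fallback.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

.aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.water_res <- c("HOH", "WAT", "DOD", "H2O")

# Standard + common modified ribonucleotides, mapped to the parent base.
.rna_parent <- c(
  A = "A", G = "G", C = "C", U = "U",
  RA = "A", RG = "G", RC = "C", RU = "U",
  ADE = "A", GUA = "G", CYT = "C", URA = "U", URI = "U",
  `1MA` = "A", `2MA` = "A", `6MA` = "A", MIA = "A",
  `1MG` = "G", `2MG` = "G", `7MG` = "G", M2G = "G", OMG = "G", YG = "G",
  `5MC` = "C", OMC = "C", `4OC` = "C",
  PSU = "U", `5MU` = "U", H2U = "U", `4SU` = "U", OMU = "U", UR3 = "U"
)

rna_parent_base <- function(resname) {
  p <- .rna_parent[toupper(trimws(resname))]
  unname(p)
}

is_rna_resname <- function(resname) !is.na(rna_parent_base(resname))
is_protein_resname <- function(resname) toupper(trimws(resname)) %in% .aa3
is_water_resname <- function(resname) toupper(trimws(resname)) %in% .water_res

# RNA backbone atom names (ribose + phosphate); both prime and star dialects.
.rna_backbone <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'"
)

normalize_atom_name <- function(name) {
  gsub("\\*", "'", trimws(name))
}

is_rna_backbone_atom <- function(atom_name) {
  normalize_atom_name(atom_name) %in% .rna_backbone
}

# Aromatic ring atom names per parent base: purines carry two fused rings,
# pyrimidines one.
.base_rings <- list(
  A = list(
    ring5 = c("N9", "C8", "N7", "C5", "C4"),
    ring6 = c("C4", "C5", "C6", "N1", "C2", "N3")
  ),
  G = list(
    ring5 = c("N9", "C8", "N7", "C5", "C4"),
    ring6 = c("C4", "C5", "C6", "N1", "C2", "N3")
  ),
  C = list(ring6 = c("N1", "C2", "N3", "C4", "C5", "C6")),
  U = list(ring6 = c("N1", "C2", "N3", "C4", "C5", "C6"))
)

# Base polar N/O atoms with hydrogen-bond capabilities. The exocyclic amines
# are donors only; ring nitrogens without protons and carbonyl oxygens are
# acceptors.
.base_polar <- list(
  A = data.frame(
    atom = c("N6", "N1", "N3", "N7"),
    donor = c(TRUE, FALSE, FALSE, FALSE),
    acceptor = c(FALSE, TRUE, TRUE, TRUE)
  ),
  G = data.frame(
    atom = c("N1", "N2", "O6", "N3", "N7"),
    donor = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    acceptor = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  ),
  C = data.frame(
    atom = c("N4", "O2", "N3"),
    donor = c(TRUE, FALSE, FALSE),
    acceptor = c(FALSE, TRUE, TRUE)
  ),
  U = data.frame(
    atom = c("N3", "O2", "O4"),
    donor = c(TRUE, FALSE, FALSE),
    acceptor = c(FALSE, TRUE, TRUE)
  )
)

# RNA backbone polar atoms: 2'-OH donates and accepts; the rest accept.
.backbone_polar <- data.frame(
  atom = c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2", "OP3"),
  donor = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  acceptor = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
)

# Protein hydrogen-bonding heavy atoms. Backbone N donates, backbone O
# accepts; sidechain capabilities per residue.
.protein_polar <- list(
  backbone = data.frame(
    atom = c("N", "O", "OXT"),
    donor = c(TRUE, FALSE, FALSE),
    acceptor = c(FALSE, TRUE, TRUE)
  ),
  sidechain = list(
    ARG = data.frame(atom = c("NE", "NH1", "NH2"), donor = TRUE, acceptor = FALSE),
    ASN = data.frame(atom = c("OD1", "ND2"), donor = c(FALSE, TRUE), acceptor = c(TRUE, FALSE)),
    ASP = data.frame(atom = c("OD1", "OD2"), donor = FALSE, acceptor = TRUE),
    GLN = data.frame(atom = c("OE1", "NE2"), donor = c(FALSE, TRUE), acceptor = c(TRUE, FALSE)),
    GLU = data.frame(atom = c("OE1", "OE2"), donor = FALSE, acceptor = TRUE),
    HIS = data.frame(atom = c("ND1", "NE2"), donor = TRUE, acceptor = TRUE),
    LYS = data.frame(atom = "NZ", donor = TRUE, acceptor = FALSE),
    SER = data.frame(atom = "OG", donor = TRUE, acceptor = TRUE),
    THR = data.frame(atom = "OG1", donor = TRUE, acceptor = TRUE),
    TRP = data.frame(atom = "NE1", donor = TRUE, acceptor = FALSE),
    TYR = data.frame(atom = "OH", donor = TRUE, acceptor = TRUE)
  )
)

# Aromatic sidechain rings used for stacking annotation.
.protein_aromatic_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
)
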