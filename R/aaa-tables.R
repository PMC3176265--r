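# Embedded constant tables shared across modules.

#' @keywords internal
"_PACKAGE"

## Three-letter -> one-letter amino-acid codes, plus common modified-residue
## parents (MSE -> M etc.). Anything else maps to "X".
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  ## standard substitutions
  MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", HYP = "P", MLY = "K"
)

AA_ONE <- unname(AA_THREE_TO_ONE[1:20])

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE)[1:20], names = AA_ONE)

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

## Van der Waals radii (Angstrom), per element, NACCESS/Chothia-style values
## simplified to one radius per element.  Atom-name overrides may be supplied
## by the caller where the carbon aliphatic/aromatic split matters.
VDW_RADII <- c(
  C = 1.76, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

## Reference all-atom accessibilities (Angstrom^2) of residue X in an extended
## ALA-X-ALA tripeptide, used to normalise complex-state ASA into relASA.
TRIPEPTIDE_REF_ASA <- c(
  A = 107.95, R = 238.76, N = 143.94, D = 140.39, C = 134.28,
  Q = 178.50, E = 172.25, G = 80.10,  H = 182.88, I = 175.12,
  L = 178.63, K = 200.78, M = 194.15, F = 199.48, P = 136.13,
  S = 116.50, T = 139.27, W = 249.36, Y = 212.76, V = 151.44
)

## Six physicochemical scales per amino acid, pinned by AAindex accession:
##   hydrophobicity  KYTJ820101 (Kyte & Doolittle hydropathy)
##   hydrophilicity  HOPT810101 (Hopp & Woods)
##   polarity        GRAR740102 (Grantham)
##   polarizability  CHAM820101 (Charton)
##   propensity      CHOP780202 (Chou & Fasman beta-sheet propensity)
##   avg_asa         JANJ780101 (Janin average accessible surface area)
PHYSCHEM_TABLE <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- cbind(
    hydrophobicity = c( 1.8, -4.5, -3.5, -3.5,  2.5, -3.5, -3.5, -0.4, -3.2,  4.5,
                        3.8, -3.9,  1.9,  2.8, -1.6, -0.8, -0.7, -0.9, -1.3,  4.2),
    hydrophilicity = c(-0.5,  3.0,  0.2,  3.0, -1.0,  0.2,  3.0,  0.0, -0.5, -1.8,
                       -1.8,  3.0, -1.3, -2.5,  0.0,  0.3, -0.4, -3.4, -2.3, -1.5),
    polarity       = c( 8.1, 10.5, 11.6, 13.0,  5.5, 10.5, 12.3,  9.0, 10.4,  5.2,
                        4.9, 11.3,  5.7,  5.2,  8.0,  9.2,  8.6,  5.4,  6.2,  5.9),
    polarizability = c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000, 0.230, 0.186,
                       0.186, 0.219, 0.221, 0.290, 0.131, 0.062, 0.108, 0.409, 0.298, 0.140),
    propensity     = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
                       1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70),
    avg_asa        = c(27.8, 94.7, 60.1, 60.6, 15.5, 68.7, 68.2, 24.5, 50.7, 22.8,
                       27.6, 103.0, 33.5, 25.5, 51.5, 42.0, 45.0, 34.7, 55.2, 23.7)
  )
  rownames(m) <- aa
  m
})

PHYSCHEM_ACCESSIONS <- c(
  hydrophobicity = "KYTJ820101", hydrophilicity = "HOPT810101",
  polarity = "GRAR740102", polarizability = "CHAM820101",
  propensity = "CHOP780202", avg_asa = "JANJ780101"
)

## Charged side-chain atoms for salt-bridge detection.  Histidine is treated
## as positively charged by default (excludable via the include_his flag of
## salt_bridges()).
CHARGED_ATOMS_POSITIVE <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)
CHARGED_ATOMS_NEGATIVE <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

## Heavy-atom hydrogen-bond donors: (residue, atom) -> covalent antecedent
## used for the donor-angle test.  Backbone N (antecedent CA) is a donor for
## every residue except proline.
HB_DONORS <- list(
  SER = c(OG  = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH  = "CZ"),
  CYS = c(SG  = "CB"),
  ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"),
  LYS = c(NZ  = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  TRP = c(NE1 = "CD1")
)

## Heavy-atom hydrogen-bond acceptors per residue type; backbone O accepts in
## every residue.
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = "OD1",
  GLN = "OE1",
  SER = "OG",
  THR = "OG1",
  TYR = "OH",
  HIS = c("ND1", "NE2"),
  MET = "SD"
)

## Feature-group -> column-name mapping used when assembling model matrices.
FEATURE_GROUPS <- list(
  ASA  = c("asa_monomer", "asa_complex", "delta_asa", "delta_asa_pct", "rel_asa"),
  BC   = c("n_hbonds", "n_salt_bridges", "n_atomic_contacts"),
  Phy  = c("hydrophobicity", "hydrophilicity", "polarity", "polarizability",
           "propensity", "avg_asa"),
  PSSM = paste0("pssm_", c("A","R","N","D","C","Q","E","G","H","I",
                           "L","K","M","F","P","S","T","W","Y","V")),
  ECS  = "cons_grade",
  SE   = "seq_entropy"
)

BID_CATEGORIES <- c("Strong", "Intermediate", "Weak", "Insignificant",
                    "Negative-weak", "Negative-strong")
BID_HOTSPOT_CATEGORIES <- c("Strong", "Intermediate")

## One-letter code for a PDB residue name.
aa_one_letter <- function(resid) {
  out <- AA_THREE_TO_ONE[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

## Van der Waals radius per atom, from element table plus optional atom-name
## overrides; unknown elements error unless a fallback radius is supplied.
vdw_radius <- function(element, atom_name = NULL, radii = VDW_RADII,
                       overrides = NULL, fallback = NA_real_) {
  element <- toupper(element)
  r <- radii[element]
  if (!is.null(overrides) && !is.null(atom_name)) {
    hit <- match(atom_name, names(overrides))
    r[!is.na(hit)] <- overrides[hit[!is.na(hit)]]
  }
  if (anyNA(r)) {
    if (is.na(fallback)) {
      bad <- unique(element[is.na(r)])
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "),
           " (supply `fallback` or extend `radii`)", call. = FALSE)
    }
    r[is.na(r)] <- fallback
  }
  unname(r)
}
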