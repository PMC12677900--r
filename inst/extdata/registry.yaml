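# Registry of evolutionary classification tables used throughout the package.
#
# This file is data, not logic: the temporality, nucleotide-derivation and
# phosphate flags encode the prevailing view of the origins-of-life
# literature and can be edited (or refreshed from the PDBe cofactor
# endpoint) without touching code.  Ligand codes follow PDB chemical
# component dictionary conventions (<= 5 alphanumeric characters) and are a
# curated starting set, not an exhaustive mirror of the live dictionary.
#
# Amino acid chronology ranks follow the consensus order of alphabet
# expansion, arranged so that every early residue precedes every late one;
# ranks are used for report ordering only, never for statistics.

backbone_atoms: ["N", "C", "CA", "O"]

water_codes: [HOH, WAT, DOD, H2O]

metal_codes: [LI, "NA", K, RB, CS, MG, CA, SR, BA, MN, FE, FE2, CO, NI, CU,
              CU1, ZN, CD, HG, MO, W, AL, V, 3CO, 4MO]

# Raw contact-type vocabulary -> nine grouped interaction types.
contact_groups:
  covalent:      [covalent]
  electrostatic: [ionic, hbond, weak_hbond, polar, weak_polar, xbond, carbonyl]
  amide:         [AMIDEAMIDE, AMIDERING]
  vdw:           [vdw]
  hydrophobic:   [hydrophobic]
  aromatic:      [aromatic, FF, OF, EE, FT, OT, ET, FE, OE, EF]
  atom-pi:       [CARBONPI, CATIONPI, DONORPI, HALOGENPI, METSULPHURPI]
  metal:         [metal]
  clashes:       [clash, vdw_clash]

amino_acids:
  - {three: GLY, one: G, era: early, rank: 1,  sidechain_atoms: []}
  - {three: ALA, one: A, era: early, rank: 2,  sidechain_atoms: [CB]}
  - {three: ASP, one: D, era: early, rank: 3,  sidechain_atoms: [CB, CG, OD1, OD2]}
  - {three: VAL, one: V, era: early, rank: 4,  sidechain_atoms: [CB, CG1, CG2]}
  - {three: PRO, one: P, era: early, rank: 5,  sidechain_atoms: [CB, CG, CD]}
  - {three: SER, one: S, era: early, rank: 6,  sidechain_atoms: [CB, OG]}
  - {three: GLU, one: E, era: early, rank: 7,  sidechain_atoms: [CB, CG, CD, OE1, OE2]}
  - {three: LEU, one: L, era: early, rank: 8,  sidechain_atoms: [CB, CG, CD1, CD2]}
  - {three: THR, one: T, era: early, rank: 9,  sidechain_atoms: [CB, OG1, CG2]}
  - {three: ILE, one: I, era: early, rank: 10, sidechain_atoms: [CB, CG1, CG2, CD1]}
  - {three: ARG, one: R, era: late,  rank: 11, sidechain_atoms: [CB, CG, CD, NE, CZ, NH1, NH2]}
  - {three: GLN, one: Q, era: late,  rank: 12, sidechain_atoms: [CB, CG, CD, OE1, NE2]}
  - {three: ASN, one: "N", era: late,  rank: 13, sidechain_atoms: [CB, CG, OD1, ND2]}
  - {three: HIS, one: H, era: late,  rank: 14, sidechain_atoms: [CB, CG, ND1, CD2, CE1, NE2]}
  - {three: LYS, one: K, era: late,  rank: 15, sidechain_atoms: [CB, CG, CD, CE, NZ]}
  - {three: CYS, one: C, era: late,  rank: 16, sidechain_atoms: [CB, SG]}
  - {three: PHE, one: F, era: late,  rank: 17, sidechain_atoms: [CB, CG, CD1, CD2, CE1, CE2, CZ]}
  - {three: TYR, one: "Y", era: late,  rank: 18, sidechain_atoms: [CB, CG, CD1, CD2, CE1, CE2, CZ, OH]}
  - {three: MET, one: M, era: late,  rank: 19, sidechain_atoms: [CB, CG, SD, CE]}
  - {three: TRP, one: W, era: late,  rank: 20, sidechain_atoms: [CB, CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2]}

# 28 coenzyme classes: the 27 CoFactor-derived classes plus ATP.  MIO and
# Orthoquinone are stored but flagged excluded (no structural interaction
# data are available for them) and are skipped by analyses by default.
coenzyme_classes:
  - {name: ATP,                     temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [ATP, ADP, AMP, ANP, AGS]}
  - {name: NAD,                     temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [NAD, NAI, NAP, NDP]}
  - {name: FAD,                     temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [FAD, FDA]}
  - {name: FMN,                     temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [FMN, FNR]}
  - {name: SAM,                     temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: false, excluded: false, ligands: [SAM, SAH]}
  - {name: Coenzyme A,              temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [COA, ACO, PNS]}
  - {name: Adenosylcobalamin,       temporality: Ancient,  nucleotide_derived: true,  phosphate_containing: true,  excluded: false, ligands: [B12, COY]}
  - {name: Heme,                    temporality: Ancient,  nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [HEM, HEC, HEA, HEB]}
  - {name: Tetrahydrofolic acid,    temporality: Ancient,  nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [THG, FON, FOL]}
  - {name: Biopterin,               temporality: Ancient,  nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [H4B, BIO]}
  - {name: Pyridoxal 5-phosphate,   temporality: LUCA,     nucleotide_derived: false, phosphate_containing: true,  excluded: false, ligands: [PLP, PMP]}
  - {name: Biotin,                  temporality: LUCA,     nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [BTN, BTI]}
  - {name: Lipoic acid,             temporality: LUCA,     nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [LPA]}
  - {name: Pyrroloquinoline quinone, temporality: LUCA,    nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [PQQ]}
  - {name: Molybdopterin,           temporality: LUCA,     nucleotide_derived: false, phosphate_containing: true,  excluded: false, ligands: [MTE, MGD]}
  - {name: Menaquinone,             temporality: LUCA,     nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [MQ7]}
  - {name: Ascorbic acid,           temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [ASC]}
  - {name: Ubiquinone,              temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [U10]}
  - {name: Coenzyme B,              temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: true,  excluded: false, ligands: [TP7]}
  - {name: Coenzyme F420,           temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: true,  excluded: false, ligands: [F42]}
  - {name: Methanofuran,            temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [MFN]}
  - {name: Dipyrromethane,          temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [DPM]}
  - {name: Thiamine diphosphate,    temporality: Unclassified, nucleotide_derived: false, phosphate_containing: true,  excluded: false, ligands: [TPP, TDP]}
  - {name: Coenzyme M,              temporality: Unclassified, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [COM]}
  - {name: Factor F430,             temporality: Unclassified, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [F43]}
  - {name: Glutathione,             temporality: Unclassified, nucleotide_derived: false, phosphate_containing: false, excluded: false, ligands: [GSH, GDS]}
  - {name: MIO,                     temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: true,  ligands: [MDO]}
  - {name: Orthoquinone,            temporality: PostLUCA, nucleotide_derived: false, phosphate_containing: false, excluded: true,  ligands: [TRQ]}
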