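#' A tiny hand-written input bundle with hand-computed expected outputs
#'
#' Three proteins and three coenzyme classes, small enough that every
#' downstream quantity can be verified by hand:
#'
#' * `PA` — NAD (Ancient), 2 structures with different author numbering
#'   offsets; Gly12 (backbone atoms) and Asp40 (side chain) contact the
#'   coenzyme in both structures (ratio 1.0).  One structure carries a
#'   water contact (dropped) and an Mg ion in the bound environment, so
#'   the site is metal-mediated.  Both residues are early: the planted
#'   early-exclusive site.
#' * `PB` — ATP (Ancient), 1 structure; a single Gly7 contact (ratio
#'   1.0).  A one-residue site, excluded from exclusive-site detection by
#'   the >= 2 residue rule.
#' * `PC` — SAM (Ancient, phosphate-free), 4 structures; Gly12 contacts
#'   in 2/4 (ratio 0.5, kept under the inclusive threshold), Asp40 in 1/4
#'   (0.25, dropped), Arg60 in 4/4.  The called site {Gly12, Arg60} is
#'   mixed-era.  One structure carries a selenomethionine contact
#'   (non-standard, excluded).  The site spans two ECOD domains (X001,
#'   X002).
#'
#' Site residues overall: Gly, Asp, Gly, Gly, Arg — 4 early, 1 late
#' (80% / 20%).
#'
#' @param dir Optional directory; when given, the bundle is also written
#'   in the standard file formats.
#' @param registry A `coenz_registry`.
#' @return A `coenz_bundle` with an extra `expected` element holding the
#'   hand-computed residue table, site table and composition.
#' @export
make_minimal_fixture <- function(dir = NULL, registry = load_registry()) {
  row <- function(sid, chain, resnum, resname, atom, ligand, label,
                  icode = "", instance = "1") {
    data.table::data.table(structure_id = sid, chain = chain,
                           resnum = as.integer(resnum), icode = icode,
                           resname = resname, atom = atom, ligand = ligand,
                           instance = instance, labels = list(label))
  }
  raw <- data.table::rbindlist(list(
    ## PA, structure 1pa1 (author numbering = UniProt + 100)
    row("1pa1", "A", 112, "GLY", "CA", "NAD", "hbond"),
    row("1pa1", "A", 112, "GLY", "O", "NAD", "hbond"),
    row("1pa1", "A", 140, "ASP", "OD1", "NAD", "ionic"),
    row("1pa1", "W", 501, "HOH", "O", "NAD", "polar"),
    row("1pa1", "M", 901, "MG", "MG", "NAD", "metal"),
    ## PA, structure 1pa2 (author numbering = UniProt)
    row("1pa2", "A", 12, "GLY", "CA", "NAD", "hbond"),
    row("1pa2", "A", 40, "ASP", "OD2", "NAD", "ionic"),
    ## PB, one structure
    row("1pb1", "A", 7, "GLY", "N", "ATP", "hbond"),
    ## PC, four structures (author numbering = UniProt + 5)
    row("1pc1", "A", 17, "GLY", "N", "SAM", "hbond"),
    row("1pc1", "A", 45, "ASP", "OD1", "SAM", "ionic"),
    row("1pc1", "A", 65, "ARG", "NH1", "SAM", "ionic"),
    row("1pc1", "A", 75, "MSE", "SD", "SAM", "polar"),
    row("1pc2", "A", 17, "GLY", "N", "SAM", "hbond"),
    row("1pc2", "A", 65, "ARG", "NH1", "SAM", "ionic"),
    row("1pc3", "A", 65, "ARG", "NH1", "SAM", "ionic"),
    row("1pc4", "A", 65, "ARG", "NH2", "SAM", "vdw")
  ))

  ## distinct repeating fillers keep the three sequences well below any
  ## clustering threshold while fixing the site residues
  mkseq <- function(len, filler, at) {
    s <- strsplit(strrep(filler, ceiling(len / nchar(filler))), "")[[1]][1:len]
    for (nm in names(at)) s[as.integer(nm)] <- at[[nm]]
    paste(s, collapse = "")
  }
  seqs <- c(PA = mkseq(60, "LVKWE", list(`12` = "G", `40` = "D")),
            PB = mkseq(30, "HQNMY", list(`7` = "G")),
            PC = mkseq(80, "TRFCP", list(`12` = "G", `40` = "D", `60` = "R")))

  sifts_tab <- data.table::data.table(
    PDB = c("1pa1", "1pa2", "1pb1", "1pc1", "1pc2", "1pc3", "1pc4"),
    CHAIN = "A",
    SP_PRIMARY = c("PA", "PA", "PB", "PC", "PC", "PC", "PC"),
    RES_BEG = 1L, RES_END = c(60L, 60L, 30L, 80L, 80L, 80L, 80L),
    PDB_BEG = c(101L, 1L, 1L, 6L, 6L, 6L, 6L),
    PDB_END = c(160L, 60L, 30L, 85L, 85L, 85L, 85L),
    SP_BEG = 1L, SP_END = c(60L, 60L, 30L, 80L, 80L, 80L, 80L))

  ss_one <- function(sid, offset, len, at) {
    code <- rep("c", len)
    for (nm in names(at)) code[as.integer(nm)] <- at[[nm]]
    data.table::data.table(structure_id = sid, chain = "A",
                           reskey = as.character(seq_len(len) + offset),
                           code = code)
  }
  ss <- data.table::rbindlist(list(
    ss_one("1pa1", 100, 60, list(`12` = "h", `40` = "h")),
    ss_one("1pa2", 0, 60, list(`12` = "h", `40` = "c")),
    ss_one("1pb1", 0, 30, list()),
    ss_one("1pc1", 5, 80, list(`12` = "b", `60` = "h")),
    ss_one("1pc2", 5, 80, list(`12` = "b", `60` = "h")),
    ss_one("1pc3", 5, 80, list(`12` = "b", `60` = "h")),
    ss_one("1pc4", 5, 80, list(`12` = "b", `60` = "h"))))

  ecod <- data.table::rbindlist(list(
    data.table::data.table(domain_id = "dPA1", structure_id = c("1pa1", "1pa2"),
                           chain = "A", res_beg = c(101L, 1L),
                           res_end = c(160L, 60L), x_group = "X001"),
    data.table::data.table(domain_id = "dPB1", structure_id = "1pb1",
                           chain = "A", res_beg = 1L, res_end = 30L,
                           x_group = "X001"),
    data.table::data.table(domain_id = "dPC1",
                           structure_id = c("1pc1", "1pc2", "1pc3", "1pc4"),
                           chain = "A", res_beg = 6L, res_end = 40L,
                           x_group = "X001"),
    data.table::data.table(domain_id = "dPC2",
                           structure_id = c("1pc1", "1pc2", "1pc3", "1pc4"),
                           chain = "A", res_beg = 41L, res_end = 85L,
                           x_group = "X002")))

  conservation <- data.table::data.table(
    accession = c("PA", "PA", "PB", "PC", "PC"),
    position = c(12L, 40L, 7L, 12L, 60L),
    grade = c(9L, 7L, 2L, 8L, 3L),
    max_aa = c("G", "D", "S", "G", "K"))

  expected <- list(
    residues = data.table::data.table(
      accession = c("PA", "PA", "PB", "PC", "PC"),
      class_name = c("NAD", "NAD", "ATP", "SAM", "SAM"),
      position = c(12L, 40L, 7L, 12L, 60L),
      resname = c("GLY", "ASP", "GLY", "GLY", "ARG"),
      era = c("early", "early", "early", "early", "late"),
      ratio = c(1, 1, 1, 0.5, 1),
      mode = c("backbone_only", "sidechain_only", "backbone_only",
               "backbone_only", "sidechain_only")),
    sites = data.table::data.table(
      accession = c("PA", "PB", "PC"),
      class_name = c("NAD", "ATP", "SAM"),
      n_structures = c(2L, 1L, 4L),
      n_residues = c(2L, 1L, 2L),
      has_metal = c(TRUE, FALSE, FALSE)),
    composition = list(n_early = 4L, n_late = 1L,
                       early_pct = 80, late_pct = 20),
    early_exclusive = "PA",
    conservation = list(frac_conserved = 1, frac_max_aa = 1))

  contacts <- .finalize_contacts(raw, registry)
  bundle <- structure(list(sequences = seqs,
                           sifts = .expand_sifts_ranges(sifts_tab),
                           contacts = contacts, ss = ss, ecod = ecod,
                           conservation = conservation,
                           truth = NULL, dir = dir, expected = expected),
                      class = "coenz_bundle")
  if (!is.null(dir)) {
    bundle$files <- .write_bundle(bundle, sifts_tab, raw, dir)
  }
  bundle
}
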