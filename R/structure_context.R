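#' Read per-residue secondary-structure assignments
#'
#' Tab-separated columns `PDB CHAIN PDB_RES CODE`.  Codes are collapsed to
#' the three-letter vocabulary `h` (helix), `b` (strand) and `c` (coil);
#' richer DSSP-style letters are mapped (H/G/I to `h`, E/B to `b`,
#' everything else to `c`).
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with `structure_id`, `chain`, `reskey`, `code`.
#' @export
read_ss_table <- function(path) {
  tab <- data.table::as.data.table(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      colClasses = "character"))
  need <- c("PDB", "CHAIN", "PDB_RES", "CODE")
  if (!all(need %in% names(tab))) stop("secondary-structure table needs columns ",
                                       paste(need, collapse = " "))
  out <- data.table::data.table(
    structure_id = tab$PDB, chain = tab$CHAIN, reskey = tab$PDB_RES,
    code = collapse_ss_code(tab$CODE))
  out[]
}

#' Collapse secondary-structure codes to {h, b, c}
#'
#' @param code Character vector of codes (already `h`/`b`/`c`, or
#'   DSSP-style letters).
#' @return Character vector over `h`, `b`, `c`.
#' @export
collapse_ss_code <- function(code) {
  out <- ifelse(code %in% c("h", "b", "c"), code,
         ifelse(toupper(code) %in% c("H", "G", "I"), "h",
         ifelse(toupper(code) %in% c("E", "B"), "b", "c")))
  out
}

#' Lift secondary-structure assignments to UniProt coordinates
#'
#' @param ss Assignments from [read_ss_table()].
#' @param map Residue map from [read_sifts()].
#' @return A `data.table` of distinct (`accession`, `position`, `code`)
#'   triples: the per-residue profile with structural redundancy removed
#'   (a residue helical in every structure contributes `h` once; a residue
#'   seen as both helix and coil contributes both codes).
#' @export
lift_secondary_structure <- function(ss, map) {
  lifted <- map[ss, on = c("structure_id", "chain", "reskey"), nomatch = NULL]
  unique(lifted[, .(accession, position, code)])
}

#' Secondary-structure profile of one residue
#'
#' @param ss_lifted Lifted assignments from [lift_secondary_structure()].
#' @param accession UniProt accession.
#' @param position UniProt position.
#' @return Sorted character vector of the codes observed for that residue
#'   across all structures (empty if unobserved).
#' @export
residue_ss_profile <- function(ss_lifted, accession, position) {
  acc <- accession; pos <- position
  sort(unique(ss_lifted[accession == acc & position == pos]$code))
}

#' Secondary-structure content of binding sites
#'
#' Counts (residue, code) pairs over site residues per coenzyme
#' temporality — a residue observed in two conformations contributes to
#' both bins — plus a dataset-wide background over all mapped residues
#' (every position of every protein in the dataset, not only site
#' residues).  Site residues with no observed assignment are excluded and
#' counted.
#'
#' @param sites A `coenz_sites` object.
#' @param ss_lifted Lifted assignments from [lift_secondary_structure()].
#' @return A list: `by_temporality` (`data.table`: `temporality`, `code`,
#'   `n`, `pct`), `background` (`data.table`: `code`, `n`, `pct`), and
#'   `n_unobserved` site residues.
#' @export
ss_content <- function(sites, ss_lifted) {
  res <- sites$residues[, .(temporality, accession, position)]
  if (nrow(res) == 0L) stop("no site residues")
  joined <- ss_lifted[res, on = c("accession", "position"), allow.cartesian = TRUE]
  n_unobserved <- nrow(unique(joined[is.na(code),
                                     .(accession, position, temporality)]))
  joined <- joined[!is.na(code)]
  by_temp <- joined[, .(n = .N), by = .(temporality, code)]
  by_temp[, pct := 100 * n / sum(n), by = temporality]
  data.table::setorder(by_temp, temporality, code)
  bg <- ss_lifted[, .(n = .N), by = code]
  bg[, pct := 100 * n / sum(n)]
  data.table::setorder(bg, code)
  list(by_temporality = by_temp[], background = bg[], n_unobserved = n_unobserved)
}

#' Read ECOD-style domain assignments
#'
#' Flat tab-separated dialect with columns
#' `DOMAIN_ID PDB CHAIN RES_BEG RES_END X_GROUP` and optional `H_GROUP`,
#' `F_GROUP`.  Residue ranges are in structure (author) numbering.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with `domain_id`, `structure_id`, `chain`,
#'   `res_beg`, `res_end`, `x_group` (+ `h_group`/`f_group` if present).
#' @export
read_ecod <- function(path) {
  tab <- data.table::as.data.table(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      colClasses = "character"))
  need <- c("DOMAIN_ID", "PDB", "CHAIN", "RES_BEG", "RES_END", "X_GROUP")
  if (!all(need %in% names(tab))) stop("ECOD table needs columns ",
                                       paste(need, collapse = " "))
  out <- data.table::data.table(
    domain_id = tab$DOMAIN_ID, structure_id = tab$PDB, chain = tab$CHAIN,
    res_beg = as.integer(tab$RES_BEG), res_end = as.integer(tab$RES_END),
    x_group = tab$X_GROUP)
  if ("H_GROUP" %in% names(tab)) out[, h_group := tab$H_GROUP]
  if ("F_GROUP" %in% names(tab)) out[, f_group := tab$F_GROUP]
  if (any(!nzchar(out$x_group))) stop("empty X-group identifier(s)")
  out[]
}

#' ECOD fold diversity of coenzyme binding sites
#'
#' A site contributes an X-group when at least one of its residues falls
#' inside a domain of that group (residue-level assignment, so a site
#' spanning two domains contributes both).  Site residues are located in
#' each structure through the SIFTS map and compared against the domain's
#' author-numbered range.
#'
#' @param sites A `coenz_sites` object.
#' @param ecod Domain table from [read_ecod()].
#' @param map Residue map from [read_sifts()].
#' @return A `data.table` per coenzyme class: `class_name`, `temporality`,
#'   `n_xgroups` (distinct X-groups), `n_proteins` (distinct UniProt
#'   accessions), `x_groups` (list column).  Classes whose sites have no
#'   domain coverage report 0 with a warning.
#' @export
fold_diversity <- function(sites, ecod, map) {
  res <- sites$residues[, .(class_name, temporality, accession, position)]
  if (nrow(res) == 0L) stop("no site residues")
  locs <- map[res, on = c("accession", "position"), allow.cartesian = TRUE]
  locs <- locs[!is.na(structure_id)]
  locs[, resnum := suppressWarnings(as.integer(reskey))]
  locs <- locs[!is.na(resnum)]
  hits <- ecod[locs,
               on = .(structure_id, chain, res_beg <= resnum, res_end >= resnum),
               nomatch = NULL]
  per_class <- res[, .(n_proteins = length(unique(accession))), by = .(class_name, temporality)]
  xg <- hits[, .(x_groups = list(sort(unique(x_group)))), by = class_name]
  out <- xg[per_class, on = "class_name"]
  out[, n_xgroups := vapply(x_groups, length, integer(1))]
  uncovered <- out$class_name[out$n_xgroups == 0L]
  if (length(uncovered) > 0L) {
    warning("no ECOD coverage for class(es): ", paste(uncovered, collapse = ", "))
  }
  data.table::setorder(out, -n_xgroups, class_name)
  data.table::setcolorder(out, c("class_name", "temporality", "n_xgroups",
                                 "n_proteins", "x_groups"))
  out[]
}

#' Sites bound exclusively by early (or late) residues
#'
#' Filters to sites with at least two residues whose residues all belong
#' to the requested era.  The early- and late-exclusive sets are disjoint
#' by construction.
#'
#' @param sites A `coenz_sites` object.
#' @param registry A `coenz_registry`.
#' @param era `"early"` or `"late"`.
#' @return A `coenz_sites` object restricted to the exclusive sites.
#' @export
find_exclusive_sites <- function(sites, registry, era = c("early", "late")) {
  era_req <- match.arg(era)
  res <- sites$residues
  flag <- res[, .(excl = .N >= 2L && all(era == era_req)),
              by = .(accession, class_name)]
  keep <- flag[excl == TRUE, .(accession, class_name)]
  structure(list(
    residues = res[keep, on = c("accession", "class_name")],
    sites = sites$sites[keep, on = c("accession", "class_name")]
  ), class = "coenz_sites")
}

#' Read a per-position conservation table
#'
#' Tab-separated columns `ACCESSION POS GRADE MAX_AA`: the conservation
#' grade (1 = variable .. 9 = conserved) and the most frequent residue
#' (one-letter) in the homolog alignment at that position.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with `accession`, `position`, `grade`, `max_aa`.
#' @export
read_conservation <- function(path) {
  tab <- data.table::as.data.table(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      colClasses = "character"))
  need <- c("ACCESSION", "POS", "GRADE", "MAX_AA")
  if (!all(need %in% names(tab))) stop("conservation table needs columns ",
                                       paste(need, collapse = " "))
  out <- data.table::data.table(
    accession = tab$ACCESSION, position = as.integer(tab$POS),
    grade = as.integer(tab$GRADE), max_aa = toupper(tab$MAX_AA))
  if (any(!out$grade %in% 1:9)) stop("conservation grades must be in 1..9")
  out[]
}

#' Conservation summary of exclusive binding sites
#'
#' Two fractions over the covered residues of the supplied sites: the
#' fraction with conservation grade >= 7, and the fraction whose residue
#' equals the most frequent residue of the homolog alignment (MAX AA).
#'
#' @param sites A `coenz_sites` object (typically from
#'   [find_exclusive_sites()]).
#' @param conservation Table from [read_conservation()].
#' @param registry A `coenz_registry` (for three- to one-letter residue
#'   conversion).
#' @return A list: `frac_conserved`, `frac_max_aa`, and their
#'   numerators/denominators (`n_conserved`, `n_max_aa`, `n_covered`),
#'   plus `n_uncovered` residues without conservation data.
#' @export
conservation_summary <- function(sites, conservation, registry) {
  res <- sites$residues[, .(accession, position, resname)]
  if (nrow(res) == 0L) stop("no site residues")
  joined <- conservation[res, on = c("accession", "position")]
  n_uncovered <- sum(is.na(joined$grade))
  joined <- joined[!is.na(grade)]
  if (nrow(joined) == 0L) stop("no conservation coverage for any site residue")
  one <- stats::setNames(registry$amino_acids$one, registry$amino_acids$three)
  n_cons <- sum(joined$grade >= 7L)
  n_max <- sum(one[joined$resname] == joined$max_aa, na.rm = TRUE)
  list(frac_conserved = n_cons / nrow(joined),
       frac_max_aa = n_max / nrow(joined),
       n_conserved = n_cons, n_max_aa = n_max,
       n_covered = nrow(joined), n_uncovered = n_uncovered)
}
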