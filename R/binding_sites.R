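## Exact rational comparison of an interaction ratio against a threshold.
## The threshold (a double such as 0.5) is converted to a small fraction by
## continued-fraction approximation so that ties like 2/4 vs 0.5 are decided
## exactly by integer cross-multiplication.
.as_fraction <- function(x, max_den = 1000000L) {
  stopifnot(x >= 0, x <= 1)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps) break
    if (r - a < .Machine$double.eps) break
    r <- 1 / (r - a)
  }
  list(num = p1, den = q1)
}

.ratio_passes <- function(k, n, threshold, inclusive = TRUE) {
  fr <- .as_fraction(threshold)
  if (inclusive) k * fr$den >= fr$num * n else k * fr$den > fr$num * n
}

#' Interaction ratio of a residue across structures
#'
#' The interaction ratio is the fraction of a protein's structures in which
#' a given residue contacts the coenzyme; residues preserved in at least
#' half of the structures constitute the consensus binding site.
#'
#' @param presence Logical vector, one element per structure of the protein
#'   (`TRUE` when the residue contacts the coenzyme in that structure).
#' @return The ratio `sum(presence) / length(presence)`.
#' @examples
#' compute_interaction_ratio(c(TRUE, TRUE, FALSE))
#' @export
compute_interaction_ratio <- function(presence) {
  if (length(presence) == 0L) stop("presence vector must be non-empty")
  stopifnot(is.logical(presence), !anyNA(presence))
  sum(presence) / length(presence)
}

#' Backbone/side-chain classification of a residue's contacting atoms
#'
#' @param atom_names Character vector (or set) of atom names through which
#'   the residue contacts the coenzyme.
#' @param registry A `coenz_registry` (supplies the backbone atom set
#'   N, C, CA, O).
#' @return `"backbone_only"` if every atom is a backbone atom,
#'   `"sidechain_only"` if none is, `"both"` otherwise.
#' @examples
#' reg <- load_registry()
#' classify_contact_mode(c("CA", "O"), reg)
#' @export
classify_contact_mode <- function(atom_names, registry) {
  stopifnot(inherits(registry, "coenz_registry"), length(atom_names) > 0L)
  bb <- toupper(atom_names) %in% registry$backbone_atoms
  if (all(bb)) "backbone_only" else if (!any(bb)) "sidechain_only" else "both"
}

#' Annotate contacts with grouped interaction types
#'
#' Adds a `groups` list column (distinct grouped types per record) and a
#' `clash_only` flag.  Metal-partner records are given the `metal` group.
#'
#' @param contacts Contacts `data.table`.
#' @param registry A `coenz_registry`.
#' @param unknown Passed to [classify_contact_group()].
#' @return The contacts table, modified by reference and returned.
#' @export
annotate_contact_groups <- function(contacts, registry, unknown = "skip") {
  known <- registry$label_to_group
  grp <- lapply(contacts$labels, function(l) {
    g <- known[l]
    unique(unname(g[!is.na(g)]))
  })
  unk <- unique(unlist(contacts$labels)[!unlist(contacts$labels) %in% names(known)])
  if (length(unk) > 0L) {
    if (unknown == "reject") stop("unknown contact label(s): ", paste(unk, collapse = ", "))
    warning("skipping unknown contact label(s): ", paste(unk, collapse = ", "))
  }
  contacts[, groups := grp]
  contacts[, clash_only := vapply(groups, is_clash_only, logical(1))]
  invisible(contacts[])
}

#' Call consensus coenzyme binding sites at the UniProt level
#'
#' For each (UniProt accession, coenzyme class) pair, the number of bound
#' structures is the count of distinct structures of that protein with at
#' least one mapped residue contact to that class; each residue's
#' interaction ratio is the fraction of those structures in which it
#' contacts the class (presence is the OR over ligand copies).  Residues
#' whose ratio passes the threshold (exact rational comparison; inclusive
#' `>=` by default, matching the "at least 50%" site definition — set
#' `inclusive = FALSE` for a strict reading) form the site.
#'
#' Contact modes are classified from the union of contacting atom names
#' across all structures; grouped interaction types are the union over
#' structures, clashes excluded.  Clash-only contact records must already
#' have been removed (see [annotate_contact_groups()]); records flagged
#' `nonstandard` are excluded and counted.  A site is metal-mediated when a
#' metal-ion partner record shares a (structure, ligand, instance) bound
#' environment with the site's residue contacts.
#'
#' @param lifted Lifted, group-annotated contacts (see [lift_to_uniprot()]
#'   and [annotate_contact_groups()]) with clash-only records removed.
#' @param registry A `coenz_registry`.
#' @param threshold Site-calling ratio threshold (default 0.5).
#' @param inclusive Include residues exactly at the threshold (default TRUE).
#' @return An object of class `coenz_sites`: a list with `residues` (one
#'   row per site residue: `accession`, `class_name`, `temporality`,
#'   `position`, `resname`, `era`, `ratio`, `n_present`, `n_structures`,
#'   `mode`, `groups`) and `sites` (one row per site: `accession`,
#'   `class_name`, `temporality`, `n_structures`, `n_residues`,
#'   `has_metal`, `metal_elements` list column).  Attribute `dropped`
#'   counts `nonstandard` and `unknown_ligand` contact records.
#' @export
call_sites <- function(lifted, registry, threshold = 0.5, inclusive = TRUE) {
  stopifnot(inherits(registry, "coenz_registry"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  dt <- data.table::copy(lifted)
  dt[, class_name := registry$ligand_to_class[ligand]]
  n_unknown_ligand <- dt[partner_is_metal == FALSE & is.na(class_name), .N]
  dt <- dt[!is.na(class_name)]
  excluded_classes <- registry$classes$class_name[registry$classes$excluded]
  dt <- dt[!class_name %in% excluded_classes]

  res <- dt[partner_is_metal == FALSE]
  n_nonstandard <- res[nonstandard == TRUE, .N]
  res <- res[nonstandard == FALSE]
  if (nrow(res) == 0L) {
    warning("no usable residue contacts; zero sites called")
    empty <- .empty_sites()
    data.table::setattr(empty, "dropped",
                        c(nonstandard = n_nonstandard, unknown_ligand = n_unknown_ligand))
    return(empty)
  }

  ## denominator: distinct bound structures per (accession, class)
  denom <- unique(res[, .(accession, class_name, structure_id)])[
    , .(n_structures = .N), by = .(accession, class_name)]

  ## presence per residue per structure (OR over ligand copies and atoms)
  pres <- unique(res[, .(accession, class_name, structure_id, position)])
  cnt <- pres[, .(n_present = .N), by = .(accession, class_name, position)]
  cnt <- denom[cnt, on = c("accession", "class_name")]
  keep <- .ratio_passes(cnt$n_present, cnt$n_structures, threshold, inclusive)
  cnt <- cnt[keep]
  if (nrow(cnt) == 0L) warning("zero sites called at threshold ", threshold)

  ## per-residue annotations (union over all structures of the protein)
  ann <- res[, .(
    resname = resname[1L],
    mode = classify_contact_mode(unique(atom), registry),
    groups = list(setdiff(unique(unlist(groups)), "clashes"))
  ), by = .(accession, class_name, position)]
  residues <- ann[cnt, on = c("accession", "class_name", "position")]
  residues[, `:=`(
    era = unname(registry$era_by_code[resname]),
    ratio = n_present / n_structures,
    temporality = lookup_temporality(registry, class_name)
  )]
  data.table::setorder(residues, accession, class_name, position)
  data.table::setcolorder(residues, c("accession", "class_name", "temporality",
                                      "position", "resname", "era", "ratio",
                                      "n_present", "n_structures", "mode", "groups"))

  ## metal mediation via shared bound environments
  envs <- unique(res[, .(accession, class_name, structure_id, ligand, instance)])
  met <- dt[partner_is_metal == TRUE,
            .(structure_id, ligand, instance, element = resname)]
  met_sites <- if (nrow(met) > 0L) {
    envs[met, on = c("structure_id", "ligand", "instance"), nomatch = NULL][
      , .(metal_elements = list(sort(element))), by = .(accession, class_name)]
  } else {
    data.table::data.table(accession = character(), class_name = character(),
                           metal_elements = list())
  }

  sites <- residues[, .(n_structures = n_structures[1L], n_residues = .N),
                    by = .(accession, class_name, temporality)]
  sites <- met_sites[sites, on = c("accession", "class_name")]
  sites[, has_metal := !vapply(metal_elements, is.null, logical(1))]
  data.table::setorder(sites, accession, class_name)
  data.table::setcolorder(sites, c("accession", "class_name", "temporality",
                                   "n_structures", "n_residues", "has_metal",
                                   "metal_elements"))

  out <- structure(list(residues = residues, sites = sites), class = "coenz_sites")
  data.table::setattr(out, "dropped",
                      c(nonstandard = n_nonstandard, unknown_ligand = n_unknown_ligand))
  out
}

.empty_sites <- function() {
  structure(list(
    residues = data.table::data.table(
      accession = character(), class_name = character(), temporality = character(),
      position = integer(), resname = character(), era = character(),
      ratio = numeric(), n_present = integer(), n_structures = integer(),
      mode = character(), groups = list()),
    sites = data.table::data.table(
      accession = character(), class_name = character(), temporality = character(),
      n_structures = integer(), n_residues = integer(), has_metal = logical(),
      metal_elements = list())
  ), class = "coenz_sites")
}

#' @export
print.coenz_sites <- function(x, ...) {
  cat(sprintf("<coenz_sites> %d sites (%d residues) across %d proteins\n",
              nrow(x$sites), nrow(x$residues), length(unique(x$sites$accession))))
  if (nrow(x$sites) > 0L) {
    tab <- table(x$sites$temporality)
    cat("  temporalities:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize called sites to TSV (+ JSON sidecar)
#'
#' Writes one row per site residue to `<path>` and the site-level fields
#' (structure counts, metal mediation) to `<path>.sites.json`.
#'
#' @param sites A `coenz_sites` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  res <- data.table::copy(sites$residues)
  res[, groups := vapply(groups, function(g) paste(sort(g), collapse = ","), character(1))]
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.table::copy(sites$sites)
  side[, metal_elements := vapply(metal_elements,
                                  function(e) paste(e, collapse = ","), character(1))]
  jsonlite::write_json(side, paste0(path, ".sites.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
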