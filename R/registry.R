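#' Path to the registry configuration shipped with the package
#'
#' @return Path to the default `registry.yaml` file.
#' @export
default_registry_path <- function() {
  system.file("extdata", "registry.yaml", package = "coenzera", mustWork = TRUE)
}

#' Load the evolutionary classification registry
#'
#' The registry holds the fixed tables that drive every downstream
#' statistic: the 20 canonical amino acids split into the early era (the
#' ~10 prebiotically plausible residues Ala, Asp, Glu, Gly, Ile, Leu, Pro,
#' Ser, Thr, Val) and the late era, each with a chronology rank and its
#' legal heavy-atom names; the 28 coenzyme classes (27 CoFactor-derived
#' classes plus ATP) with their temporality (Ancient, LUCA, PostLUCA,
#' Unclassified), nucleotide-derivation and phosphate flags, and member
#' ligand codes; the raw-to-grouped contact-type vocabulary; and the
#' curated metal-ion and water component codes.
#'
#' The file is validated on load: 20 residues partitioning 10/10 into eras,
#' chronology ranks a permutation of 1..20, backbone atoms exactly
#' N/C/CA/O, 28 coenzyme classes with the Unclassified set fixed to
#' Thiamine diphosphate, Coenzyme M, Factor F430 and Glutathione,
#' nucleotide-derived classes Ancient, and ligand codes unique across
#' classes.  Violations are hard errors.
#'
#' @param path Path to a registry YAML file; defaults to the configuration
#'   shipped with the package.
#' @return An object of class `coenz_registry`.
#' @examples
#' reg <- load_registry()
#' lookup_era(reg, "GLY")
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) stop("registry config not found: ", path)
  cfg <- yaml::read_yaml(path)

  aa <- data.table::rbindlist(lapply(cfg$amino_acids, function(a) {
    data.table::data.table(
      three = toupper(a$three), one = toupper(a$one),
      era = a$era, rank = as.integer(a$rank),
      sidechain_atoms = list(as.character(unlist(a$sidechain_atoms)))
    )
  }))
  if (nrow(aa) != 20L) stop("registry must define exactly 20 amino acids, got ", nrow(aa))
  if (!all(aa$era %in% c("early", "late"))) {
    stop("unknown era value(s): ", paste(setdiff(aa$era, c("early", "late")), collapse = ", "))
  }
  early <- sort(aa$three[aa$era == "early"])
  if (!identical(early, sort(c("ALA", "ASP", "GLU", "GLY", "ILE", "LEU",
                               "PRO", "SER", "THR", "VAL")))) {
    stop("early era must be exactly {Ala, Asp, Glu, Gly, Ile, Leu, Pro, Ser, Thr, Val}")
  }
  if (!identical(sort(aa$rank), 1:20)) stop("chronology ranks must be a permutation of 1..20")
  if (anyDuplicated(aa$three) || anyDuplicated(aa$one)) stop("duplicate residue codes in registry")

  backbone <- toupper(as.character(unlist(cfg$backbone_atoms)))
  if (!setequal(backbone, c("N", "C", "CA", "O"))) {
    stop("backbone_atoms must be exactly {N, C, CA, O}")
  }

  groups <- cfg$contact_groups
  expected_groups <- c("covalent", "electrostatic", "amide", "vdw", "hydrophobic",
                       "aromatic", "atom-pi", "metal", "clashes")
  if (!setequal(names(groups), expected_groups)) {
    stop("contact_groups must define the nine grouped interaction types")
  }
  label_to_group <- unlist(lapply(names(groups), function(g) {
    labs <- as.character(unlist(groups[[g]]))
    stats::setNames(rep(g, length(labs)), labs)
  }))
  if (anyDuplicated(names(label_to_group))) {
    stop("raw contact label assigned to more than one group: ",
         paste(unique(names(label_to_group)[duplicated(names(label_to_group))]), collapse = ", "))
  }

  cls <- data.table::rbindlist(lapply(cfg$coenzyme_classes, function(cc) {
    data.table::data.table(
      class_name = cc$name,
      temporality = cc$temporality,
      nucleotide_derived = isTRUE(cc$nucleotide_derived),
      phosphate_containing = isTRUE(cc$phosphate_containing),
      excluded = isTRUE(cc$excluded),
      ligands = list(toupper(as.character(unlist(cc$ligands))))
    )
  }))
  if (nrow(cls) != 28L) stop("registry must define exactly 28 coenzyme classes, got ", nrow(cls))
  temporalities <- c("Ancient", "LUCA", "PostLUCA", "Unclassified")
  if (!all(cls$temporality %in% temporalities)) {
    stop("unknown temporality value(s): ",
         paste(setdiff(cls$temporality, temporalities), collapse = ", "))
  }
  uncls <- sort(cls$class_name[cls$temporality == "Unclassified"])
  if (!identical(uncls, sort(c("Thiamine diphosphate", "Coenzyme M",
                               "Factor F430", "Glutathione")))) {
    stop("Unclassified classes must be exactly {Thiamine diphosphate, Coenzyme M, Factor F430, Glutathione}")
  }
  if (any(cls$nucleotide_derived & cls$temporality != "Ancient")) {
    stop("nucleotide-derived coenzyme classes must be Ancient")
  }
  all_ligands <- unlist(cls$ligands)
  if (anyDuplicated(all_ligands)) {
    stop("ligand code assigned to more than one coenzyme class: ",
         paste(unique(all_ligands[duplicated(all_ligands)]), collapse = ", "))
  }
  if (any(nchar(all_ligands) > 5L | !grepl("^[A-Za-z0-9]+$", all_ligands))) {
    stop("ligand codes must be <= 5 alphanumeric characters")
  }
  ligand_to_class <- stats::setNames(
    rep(cls$class_name, lengths(cls$ligands)), all_ligands)

  era_by_code <- c(stats::setNames(aa$era, aa$three), stats::setNames(aa$era, aa$one))

  reg <- structure(list(
    amino_acids = aa[order(aa$rank)],
    classes = cls,
    backbone_atoms = backbone,
    label_to_group = label_to_group,
    ligand_to_class = ligand_to_class,
    era_by_code = era_by_code,
    metal_codes = toupper(as.character(unlist(cfg$metal_codes))),
    water_codes = toupper(as.character(unlist(cfg$water_codes))),
    path = path
  ), class = "coenz_registry")
  reg
}

#' @export
print.coenz_registry <- function(x, ...) {
  cat("<coenz_registry>\n")
  cat("  amino acids: 20 (10 early / 10 late)\n")
  cat(sprintf("  coenzyme classes: %d (%d analyzed, %d excluded)\n",
              nrow(x$classes), sum(!x$classes$excluded), sum(x$classes$excluded)))
  tab <- table(x$classes$temporality[!x$classes$excluded])
  cat("  temporalities:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  ligand codes: %d; raw contact labels: %d\n",
              length(x$ligand_to_class), length(x$label_to_group)))
  invisible(x)
}

#' Look up the evolutionary era of an amino acid
#'
#' @param registry A `coenz_registry`.
#' @param residue Three-letter (e.g. `"GLY"`) or one-letter residue codes.
#' @return Character vector of `"early"`/`"late"`; `NA` for non-canonical codes.
#' @export
lookup_era <- function(registry, residue) {
  stopifnot(inherits(registry, "coenz_registry"))
  unname(registry$era_by_code[toupper(residue)])
}

#' Look up the temporality of a coenzyme class
#'
#' @param registry A `coenz_registry`.
#' @param class_name Coenzyme class names (e.g. `"Glutathione"`).
#' @return Character vector of temporalities; `NA` for unknown classes.
#' @export
lookup_temporality <- function(registry, class_name) {
  stopifnot(inherits(registry, "coenz_registry"))
  idx <- match(class_name, registry$classes$class_name)
  registry$classes$temporality[idx]
}

#' Look up the coenzyme class of a ligand code
#'
#' @param registry A `coenz_registry`.
#' @param ligand_code PDB chemical-component identifiers (e.g. `"NAD"`).
#' @return Character vector of class names; `NA` for codes outside the registry.
#' @export
lookup_class <- function(registry, ligand_code) {
  stopifnot(inherits(registry, "coenz_registry"))
  unname(registry$ligand_to_class[toupper(ligand_code)])
}

#' Group raw contact-type labels into the nine grouped interaction types
#'
#' Raw contact labels (the vocabulary produced by interatomic contact
#' calculation) are collapsed into nine groups: covalent, electrostatic
#' (ionic, hbond, weak_hbond, polar, weak_polar, xbond, carbonyl), amide,
#' vdw, hydrophobic, aromatic (ring-ring geometries included), atom-pi,
#' metal, and clashes (clash, vdw_clash).  Records whose only group is
#' `clashes` are omitted from downstream statistics; use
#' [is_clash_only()] to identify them.
#'
#' @param labels Character vector of raw contact labels.
#' @param registry A `coenz_registry`.
#' @param unknown How to treat labels outside the vocabulary: `"skip"`
#'   (default; drop with a warning) or `"reject"` (error).
#' @return Character vector of the distinct grouped types represented.
#' @examples
#' reg <- load_registry()
#' classify_contact_group(c("weak_hbond", "CATIONPI"), reg)
#' @export
classify_contact_group <- function(labels, registry, unknown = c("skip", "reject")) {
  stopifnot(inherits(registry, "coenz_registry"))
  unknown <- match.arg(unknown)
  groups <- registry$label_to_group[labels]
  bad <- is.na(groups)
  if (any(bad)) {
    if (unknown == "reject") {
      stop("unknown contact label(s): ", paste(unique(labels[bad]), collapse = ", "))
    }
    warning("skipping unknown contact label(s): ",
            paste(unique(labels[bad]), collapse = ", "))
    groups <- groups[!bad]
  }
  unique(unname(groups))
}

#' Is a set of grouped contact types clash-only?
#'
#' @param groups Character vector of grouped types (from
#'   [classify_contact_group()]).
#' @return `TRUE` if non-empty and every group is `"clashes"`.
#' @export
is_clash_only <- function(groups) {
  length(groups) > 0L && all(groups == "clashes")
}

#' The nine grouped interaction types
#'
#' @param registry A `coenz_registry`.
#' @return Character vector of the nine group names, clashes last.
#' @export
contact_group_names <- function(registry) {
  stopifnot(inherits(registry, "coenz_registry"))
  c("covalent", "electrostatic", "amide", "vdw", "hydrophobic",
    "aromatic", "atom-pi", "metal", "clashes")
}
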