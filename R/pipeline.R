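#' Pipeline configuration
#'
#' @param input_dir Directory with the standard input files
#'   (`sequences.fasta`, `sifts.tsv`, `contacts/*.json`, and optionally
#'   `ss.tsv`, `ecod.tsv`, `conservation.tsv`), e.g. written by
#'   [generate_dataset()].  Ignored when `simulate` is given.
#' @param simulate Optional [simulation_config()]; the bundle is then
#'   generated in memory instead of read from disk.
#' @param out_dir Output directory for report tables and the manifest;
#'   `NULL` computes everything in memory only.
#' @param registry_path Registry YAML (default: the shipped registry).
#' @param cluster_thresholds Sequence-identity thresholds; the first is
#'   used for the analysis, all are recorded in the manifest.
#' @param ratio_threshold Interaction-ratio site-calling threshold.
#' @param ratio_inclusive Include residues exactly at the threshold
#'   ("at least 50%"); `FALSE` gives the strict "more than 50%" reading.
#' @param type_unit Counting unit for [type_distribution()].
#' @return A list of class `coenz_pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL, out_dir = NULL,
                            registry_path = default_registry_path(),
                            cluster_thresholds = 0.9,
                            ratio_threshold = 0.5, ratio_inclusive = TRUE,
                            type_unit = "residue") {
  if (is.null(input_dir) && is.null(simulate)) {
    stop("either input_dir or simulate must be given")
  }
  if (any(cluster_thresholds <= 0 | cluster_thresholds > 1)) {
    stop("cluster thresholds must be in (0, 1]")
  }
  if (!(ratio_threshold > 0 && ratio_threshold <= 1)) {
    stop("ratio threshold must be in (0, 1]")
  }
  structure(list(input_dir = input_dir, simulate = simulate,
                 out_dir = out_dir, registry_path = registry_path,
                 cluster_thresholds = cluster_thresholds,
                 ratio_threshold = ratio_threshold,
                 ratio_inclusive = ratio_inclusive,
                 type_unit = type_unit),
            class = "coenz_pipeline_config")
}

.read_bundle_dir <- function(dir, registry) {
  opt <- function(path, reader) if (file.exists(path)) reader(path) else NULL
  structure(list(
    sequences = read_fasta(file.path(dir, "sequences.fasta")),
    sifts = read_sifts(file.path(dir, "sifts.tsv")),
    contacts = read_contacts_dir(file.path(dir, "contacts"), registry),
    ss = opt(file.path(dir, "ss.tsv"), read_ss_table),
    ecod = opt(file.path(dir, "ecod.tsv"), read_ecod),
    conservation = opt(file.path(dir, "conservation.tsv"), read_conservation),
    truth = NULL, dir = dir), class = "coenz_bundle")
}

#' Run the full analysis pipeline
#'
#' simulate/ingest, lift to UniProt coordinates, remove redundancy by
#' sequence clustering, call consensus binding sites, and produce every
#' report table: early/late composition per temporality and class (raw,
#' background-normalized, and restricted to phosphate-free classes),
#' per-amino-acid composition and pairwise fractional differences,
#' chi-squared statistics, binding-mode and interaction-type
#' distributions, metal mediation, secondary-structure content, ECOD fold
#' diversity, exclusive early/late sites with conservation summaries, and
#' a manifest that reconciles every dropped record by reason.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional pre-built `coenz_bundle` (overrides
#'   `input_dir`/`simulate`).
#' @return A list of class `coenz_report`: `sites`, `tables` (named list),
#'   `manifest`, and `bundle`, invisibly written to `out_dir` when set.
#' @export
run_full <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "coenz_pipeline_config"))
  registry <- load_registry(config$registry_path)
  if (is.null(bundle)) {
    bundle <- if (!is.null(config$simulate)) {
      generate_dataset(config$simulate, registry = registry)
    } else {
      .read_bundle_dir(config$input_dir, registry)
    }
  }

  contacts <- bundle$contacts
  n_parsed <- nrow(contacts) + unname(attr(contacts, "dropped")["water"])
  n_water <- unname(attr(contacts, "dropped")["water"])
  n_malformed <- unname(attr(contacts, "dropped")["malformed"] %||% 0L)

  ## clustering (redundancy removal)
  clusters <- lapply(config$cluster_thresholds, function(t) {
    cluster_sequences(bundle$sequences, t)
  })
  names(clusters) <- as.character(config$cluster_thresholds)
  reps <- cluster_representatives(clusters[[1L]])

  ## lift and filter, counting every dropped record by reason
  lifted <- lift_to_uniprot(contacts, bundle$sifts)
  n_unmapped <- unname(attr(lifted, "dropped")["unmapped"])
  n_metal <- lifted[partner_is_metal == TRUE, .N]
  is_res <- lifted$partner_is_metal == FALSE
  n_nonrep_res <- sum(is_res & !lifted$accession %in% reps)
  lifted <- lifted[partner_is_metal == TRUE | accession %in% reps]

  annotate_contact_groups(lifted, registry)
  n_clash_only <- lifted[partner_is_metal == FALSE & clash_only == TRUE, .N]
  lifted <- lifted[partner_is_metal == TRUE | clash_only == FALSE]
  n_nonstandard <- lifted[partner_is_metal == FALSE & nonstandard == TRUE, .N]
  lifted <- lifted[partner_is_metal == TRUE | nonstandard == FALSE]
  known <- !is.na(registry$ligand_to_class[lifted$ligand])
  analyzed_cls <- registry$classes$class_name[!registry$classes$excluded]
  known <- known & registry$ligand_to_class[lifted$ligand] %in% analyzed_cls
  n_unknown_ligand <- sum(!known & !lifted$partner_is_metal)
  n_metal_dropped <- sum(!known & lifted$partner_is_metal)
  lifted <- lifted[known]
  n_used <- lifted[partner_is_metal == FALSE, .N]

  sites <- call_sites(lifted, registry, config$ratio_threshold,
                      config$ratio_inclusive)

  ## report tables
  tables <- list()
  tables$composition_by_temporality <- site_composition(sites, registry, "temporality")
  tables$composition_by_class <- site_composition(sites, registry, "class_name")
  tables$aa_composition <- aa_composition(sites, registry, "temporality")
  background <- background_composition(bundle$sequences[reps], registry)
  tables$background <- data.table::data.table(
    n_early = background$n_early, n_late = background$n_late,
    early_pct = background$early_pct, late_pct = background$late_pct)
  tables$composition_normalized <-
    normalize_by_background(tables$composition_by_temporality, background)
  tables$phosphate_sensitivity <- phosphate_sensitivity(sites, registry)

  stats_block <- list()
  comp <- tables$composition_by_temporality
  stats_block$chi_goodness_vs_background <- lapply(
    stats::setNames(seq_len(nrow(comp)), comp$group), function(i) {
      chi_squared(c(comp$n_early[i], comp$n_late[i]),
                  c(background$early_pct, background$late_pct) / 100 *
                    (comp$n_early[i] + comp$n_late[i]))
    })
  if (nrow(comp) >= 2L) {
    stats_block$chi_temporality_by_era <- chi_squared(
      as.matrix(comp[, .(n_early, n_late)]))
  }

  aa_comp <- tables$aa_composition
  temps_present <- unique(aa_comp$group)
  fd_pairs <- if (length(temps_present) >= 2L) {
    utils::combn(temps_present, 2L, simplify = FALSE)
  } else list()
  tables$fractional_differences <- data.table::rbindlist(lapply(fd_pairs, function(pr) {
    a <- aa_comp[group == pr[1L]]; b <- aa_comp[group == pr[2L]]
    fd <- fractional_difference(stats::setNames(a$pct, a$resname),
                                stats::setNames(b$pct, b$resname), registry)
    out <- fd$table
    out[, `:=`(comp_a = pr[1L], comp_b = pr[2L])]
    out
  }))

  md <- mode_distribution(sites, registry)
  tables$mode_profile <- md$profile
  tables$mode_era_split <- md$era_mode
  stats_block$chi_era_by_mode <- md$tests
  tables$type_distribution <- type_distribution(sites, config$type_unit)
  mm <- metal_mediation(sites)
  tables$metal_by_temporality <- mm$by_temporality
  tables$metal_by_class <- mm$by_class
  tables$metal_elements <- mm$elements

  n_ss_unobserved <- 0L
  if (!is.null(bundle$ss)) {
    ss_lifted <- lift_secondary_structure(bundle$ss, bundle$sifts)
    ssc <- ss_content(sites, ss_lifted)
    tables$ss_by_temporality <- ssc$by_temporality
    tables$ss_background <- ssc$background
    n_ss_unobserved <- ssc$n_unobserved
  }
  if (!is.null(bundle$ecod)) {
    tables$fold_diversity <- suppressWarnings(
      fold_diversity(sites, bundle$ecod, bundle$sifts))
  }

  excl_early <- find_exclusive_sites(sites, registry, "early")
  excl_late <- find_exclusive_sites(sites, registry, "late")
  tables$exclusive_early <- excl_early$residues
  tables$exclusive_late <- excl_late$residues
  cons_summary <- list()
  if (!is.null(bundle$conservation)) {
    for (nm in c("early", "late")) {
      ex <- if (nm == "early") excl_early else excl_late
      cons_summary[[nm]] <- if (nrow(ex$residues) > 0L) {
        tryCatch(conservation_summary(ex, bundle$conservation, registry),
                 error = function(e) NULL)
      } else NULL
    }
  }
  stats_block$conservation <- cons_summary

  manifest <- list(
    ratio_threshold = config$ratio_threshold,
    ratio_inclusive = config$ratio_inclusive,
    cluster_thresholds = config$cluster_thresholds,
    seed = if (!is.null(config$simulate)) config$simulate$seed else NULL,
    n_sequences = length(bundle$sequences),
    cluster_counts = vapply(clusters, function(cl) length(unique(cl$cluster)),
                            integer(1)),
    accounting = list(
      n_parsed = n_parsed,
      n_malformed = n_malformed,
      used = n_used,
      dropped = c(water = n_water, metal_partner = n_metal,
                  unmapped = n_unmapped, ambiguous_map_rows =
                    unname(attr(bundle$sifts, "dropped")["ambiguous"] %||% 0L),
                  nonrepresentative = n_nonrep_res,
                  clash_only = n_clash_only, nonstandard = n_nonstandard,
                  unknown_or_excluded_ligand = n_unknown_ligand,
                  metal_outside_analyzed_classes = n_metal_dropped)),
    n_ss_unobserved = n_ss_unobserved,
    n_sites = nrow(sites$sites),
    n_site_residues = nrow(sites$residues))

  ok <- manifest$accounting$n_parsed ==
    manifest$accounting$used +
    sum(manifest$accounting$dropped[c("water", "metal_partner", "unmapped",
                                      "nonrepresentative", "clash_only",
                                      "nonstandard",
                                      "unknown_or_excluded_ligand")])
  manifest$accounting$reconciled <- ok
  if (!ok) warning("manifest accounting does not reconcile")

  report <- structure(list(sites = sites, tables = tables,
                           stats = stats_block, manifest = manifest,
                           clusters = clusters, bundle = bundle),
                      class = "coenz_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sites(report$sites, file.path(out_dir, "sites.tsv"))
  for (nm in names(report$tables)) {
    tab <- data.table::copy(data.table::as.data.table(report$tables[[nm]]))
    for (col in names(tab)) {
      if (is.list(tab[[col]])) {
        tab[, (col) := vapply(get(col), function(x) paste(unlist(x), collapse = ","),
                              character(1))]
      }
    }
    utils::write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.coenz_report <- function(x, ...) {
  cat("<coenz_report>\n")
  cat(sprintf("  %d sites, %d site residues\n",
              x$manifest$n_sites, x$manifest$n_site_residues))
  comp <- x$tables$composition_by_temporality
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-12s early %5.1f%% / late %5.1f%%  (n=%d)\n",
                comp$group[i], comp$early_pct[i], comp$late_pct[i],
                comp$n_early[i] + comp$n_late[i]))
  }
  cat(sprintf("  accounting reconciled: %s\n",
              x$manifest$accounting$reconciled))
  invisible(x)
}
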