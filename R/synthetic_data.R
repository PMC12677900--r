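#' Per-temporality block of a simulation configuration
#'
#' Defines the planted parameters for one coenzyme temporality of the
#' synthetic dataset.  The defaults echo the study conditions the package
#' is designed around: per-temporality early-residue occupancies of
#' 0.61 / 0.53 / 0.47 (Ancient / LUCA / Post-LUCA), backbone-only binding
#' more frequent for Ancient coenzymes (0.24), metal mediation of
#' 0.24 / 0.13 / 0.11, strand-richer Ancient sites versus helix-richer
#' Post-LUCA sites, and an electrostatic-dominated interaction-type mix.
#'
#' @param n_proteins Number of proteins (one consensus site each).
#' @param early_occupancy Probability that a site residue is early-era.
#' @param structures_lambda Structures per protein are `1 + Poisson(lambda)`.
#' @param site_size_lambda Site sizes are `2 + Poisson(lambda)` (default
#'   mean 8).
#' @param retention Probability that a true site residue is seen
#'   interacting in any given structure.
#' @param mode_probs Probabilities of `backbone_only`, `sidechain_only`,
#'   `both` contact modes (in that order; must sum to 1).
#' @param type_mix Distribution over the eight non-clash grouped
#'   interaction types.
#' @param clash_rate Probability that a residue-structure interaction
#'   event is recorded as clash-only (such events are omitted downstream).
#' @param metal_prob Probability that a site is mediated by >= 1 metal ion.
#' @param metal_element_mix Distribution over metal element codes.
#' @param ss_mix Distribution of site-residue secondary structure over
#'   `h`, `b`, `c`.
#' @return A list of class `coenz_sim_block`.
#' @export
temporality_block <- function(n_proteins = 200L,
                              early_occupancy = 0.61,
                              structures_lambda = 1.9,
                              site_size_lambda = 6,
                              retention = 0.9,
                              mode_probs = c(backbone_only = 0.24,
                                             sidechain_only = 0.52,
                                             both = 0.24),
                              type_mix = c(electrostatic = 0.40, vdw = 0.22,
                                           hydrophobic = 0.18, aromatic = 0.07,
                                           `atom-pi` = 0.05, amide = 0.04,
                                           covalent = 0.02, metal = 0.02),
                              clash_rate = 0.02,
                              metal_prob = 0.24,
                              metal_element_mix = c(MG = 0.50, CA = 0.25,
                                                    MN = 0.15, FE = 0.10),
                              ss_mix = c(h = 0.25, b = 0.30, c = 0.45)) {
  blk <- list(n_proteins = as.integer(n_proteins),
              early_occupancy = early_occupancy,
              structures_lambda = structures_lambda,
              site_size_lambda = site_size_lambda,
              retention = retention,
              mode_probs = mode_probs, type_mix = type_mix,
              clash_rate = clash_rate, metal_prob = metal_prob,
              metal_element_mix = metal_element_mix, ss_mix = ss_mix)
  .validate_block(blk)
  structure(blk, class = "coenz_sim_block")
}

.validate_block <- function(blk) {
  if (blk$n_proteins < 1L) stop("n_proteins must be >= 1")
  probs <- c(blk$early_occupancy, blk$retention, blk$clash_rate, blk$metal_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  for (nm in c("mode_probs", "type_mix", "metal_element_mix", "ss_mix")) {
    p <- blk[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(nm, " must be a normalized distribution")
    }
  }
  if (!identical(names(blk$mode_probs),
                 c("backbone_only", "sidechain_only", "both"))) {
    stop("mode_probs must be named backbone_only, sidechain_only, both")
  }
  if (!setequal(names(blk$ss_mix), c("h", "b", "c"))) {
    stop("ss_mix must be over h, b, c")
  }
  invisible(blk)
}

#' Simulation configuration for the synthetic dataset
#'
#' Bundles per-temporality blocks with dataset-wide parameters.  The
#' defaults emulate the study conditions: three temporalities with
#' early-site occupancies 0.61 / 0.53 / 0.47, a sequence background of 67%
#' early residues, and a redundancy rate that gives the clustering stage
#' something to remove.
#'
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   seed.
#' @param blocks Named list of [temporality_block()]s; names must be
#'   temporalities known to the registry.
#' @param background_early Probability that a non-site sequence position
#'   is early-era (i.i.d.; no phylogenetic structure is simulated).
#' @param background_ss_mix Secondary-structure distribution of non-site
#'   residues.
#' @param seq_len_range Protein length range (uniform).
#' @param duplicate_rate Probability that a protein gets a near-identical
#'   twin accession (~2% substitutions outside the site), exercising the
#'   redundancy-removal stage.
#' @param nonstandard_rate Per-structure probability of one non-standard
#'   residue contact (MSE).
#' @param water_lambda Poisson mean of water contacts per structure.
#' @param conservation List with `p_high` (probability that a site residue
#'   has grade >= 7) and `p_max_match` (probability that the alignment's
#'   most frequent residue equals the site residue).
#' @return A list of class `coenz_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              blocks = list(
                                Ancient = temporality_block(
                                  n_proteins = 200L, early_occupancy = 0.61,
                                  mode_probs = c(backbone_only = 0.24,
                                                 sidechain_only = 0.52, both = 0.24),
                                  metal_prob = 0.24,
                                  ss_mix = c(h = 0.25, b = 0.30, c = 0.45)),
                                LUCA = temporality_block(
                                  n_proteins = 200L, early_occupancy = 0.53,
                                  mode_probs = c(backbone_only = 0.15,
                                                 sidechain_only = 0.60, both = 0.25),
                                  metal_prob = 0.13,
                                  ss_mix = c(h = 0.30, b = 0.25, c = 0.45)),
                                PostLUCA = temporality_block(
                                  n_proteins = 200L, early_occupancy = 0.47,
                                  mode_probs = c(backbone_only = 0.11,
                                                 sidechain_only = 0.64, both = 0.25),
                                  metal_prob = 0.11,
                                  ss_mix = c(h = 0.45, b = 0.15, c = 0.40))),
                              background_early = 0.67,
                              background_ss_mix = c(h = 0.35, b = 0.22, c = 0.43),
                              seq_len_range = c(150L, 250L),
                              duplicate_rate = 0.1,
                              nonstandard_rate = 0.01,
                              water_lambda = 1,
                              conservation = list(p_high = 0.6, p_max_match = 0.75)) {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("blocks must be a named list of temporality blocks")
  }
  lapply(blocks, .validate_block)
  probs <- c(background_early, duplicate_rate, nonstandard_rate,
             conservation$p_high, conservation$p_max_match)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(background_ss_mix) - 1) > 1e-8) stop("background_ss_mix must be normalized")
  structure(list(seed = as.integer(seed), blocks = blocks,
                 background_early = background_early,
                 background_ss_mix = background_ss_mix,
                 seq_len_range = as.integer(seq_len_range),
                 duplicate_rate = duplicate_rate,
                 nonstandard_rate = nonstandard_rate,
                 water_lambda = water_lambda,
                 conservation = conservation),
            class = "coenz_sim_config")
}

## Run code under a given seed and restore the caller's RNG state.
.local_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

## Sequential 4-character structure identifiers (base-36).
.structure_id <- function(i) {
  chars <- c(0:9, letters)
  d4 <- (i - 1) %% 36L; r <- (i - 1) %/% 36L
  d3 <- r %% 36L; r <- r %/% 36L
  d2 <- r %% 36L; d1 <- r %/% 36L
  paste0(chars[d1 + 1L], chars[d2 + 1L], chars[d3 + 1L], chars[d4 + 1L])
}

.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Generate a complete synthetic input bundle with planted parameters
#'
#' Emits everything the pipeline ingests — sequences (FASTA), a
#' SIFTS-style residue map (range-dialect TSV), one contacts JSON per
#' synthetic structure, secondary-structure / ECOD / conservation TSVs —
#' plus a truth file restating every planted parameter and the realized
#' per-protein site definitions.  The bundle is deterministic given the
#' configuration seed; calling twice with the same config produces
#' byte-identical files.
#'
#' Site residue identities are drawn era-first (early with the block's
#' `early_occupancy`), the contact mode is drawn from `mode_probs`, and
#' the residue is drawn uniformly within its era with glycine eligible
#' only for backbone-only modes, so that no glycine ever exhibits a
#' side-chain contact while the planted mode probabilities stay exact.
#' Contact atoms are always drawn from the residue's legal atom set.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory; `NULL` (default) generates in memory only.
#' @param registry A `coenz_registry`.
#' @param parts Which bundle components to generate (subset of
#'   `"contacts"`, `"ss"`, `"ecod"`, `"conservation"`); sequences, the
#'   SIFTS map and the truth are always produced.
#' @return A list of class `coenz_bundle`: `sequences`, `sifts`,
#'   `contacts` (finalized table, as from [read_contacts_dir()]), `ss`,
#'   `ecod`, `conservation`, `truth`, and `dir`/`files` when written.
#' @export
generate_dataset <- function(config, dir = NULL, registry = load_registry(),
                             parts = c("contacts", "ss", "ecod", "conservation")) {
  stopifnot(inherits(config, "coenz_sim_config"))
  bad <- setdiff(names(config$blocks),
                 unique(registry$classes$temporality[!registry$classes$excluded]))
  if (length(bad) > 0L) stop("unknown temporality block(s): ", paste(bad, collapse = ", "))
  restore <- .local_seed(config$seed)
  on.exit(restore())

  aa <- registry$amino_acids
  early3 <- aa$three[aa$era == "early"]
  late3 <- aa$three[aa$era == "late"]
  one_of <- stats::setNames(aa$one, aa$three)
  sc_atoms <- stats::setNames(aa$sidechain_atoms, aa$three)
  bb_atoms <- registry$backbone_atoms
  labels_by_group <- split(names(registry$label_to_group),
                           unname(registry$label_to_group))
  cls <- registry$classes[!registry$classes$excluded]

  seqs <- character(0)
  sifts_rows <- list()
  contact_tabs <- list()
  ss_tabs <- list()
  ecod_rows <- list()
  cons_rows <- list()
  prot_rows <- list()
  sid_counter <- 0L
  prot_counter <- 0L
  n_clash_events <- 0L

  emit_protein <- function(acc, temporality, blk, plan, n_structures, is_twin,
                           parent) {
    ## plan: list(seq, positions, resnames, eras, modes, group, atoms,
    ##            ss_site, ss_bg, class_name, ligand, has_metal, elements,
    ##            x_groups, dom_ranges)
    L <- nchar(plan$seq)
    S <- length(plan$positions)
    sids <- vapply(sid_counter + seq_len(n_structures), .structure_id, character(1))
    sid_counter <<- sid_counter + n_structures
    offsets <- sample(0:100, n_structures, replace = TRUE)

    sifts_rows[[length(sifts_rows) + 1L]] <<- data.table::data.table(
      PDB = sids, CHAIN = "A", SP_PRIMARY = acc,
      RES_BEG = 1L, RES_END = L,
      PDB_BEG = 1L + offsets, PDB_END = L + offsets,
      SP_BEG = 1L, SP_END = L)

    if ("ecod" %in% parts) {
      n_dom <- length(plan$x_groups)
      si <- rep(seq_len(n_structures), each = n_dom)
      ecod_rows[[length(ecod_rows) + 1L]] <<- data.table::data.table(
        DOMAIN_ID = paste0("d", sids[si], "A", rep(seq_len(n_dom), n_structures)),
        PDB = sids[si], CHAIN = "A",
        RES_BEG = rep(plan$dom_ranges$beg, n_structures) + offsets[si],
        RES_END = rep(plan$dom_ranges$end, n_structures) + offsets[si],
        X_GROUP = rep(plan$x_groups, n_structures))
    }

    if ("ss" %in% parts) {
      codes <- plan$ss_bg
      codes[plan$positions] <- plan$ss_site
      ss_tabs[[length(ss_tabs) + 1L]] <<- data.table::data.table(
        structure_id = rep(sids, each = L),
        chain = "A",
        reskey = as.character(rep(offsets, each = L) + seq_len(L)),
        code = rep(codes, n_structures))
    }

    if ("contacts" %in% parts) {
      n_atoms <- lengths(plan$atoms)
      retained <- matrix(stats::runif(S * n_structures) < blk$retention,
                         nrow = S)
      clash <- matrix(stats::runif(S * n_structures) < blk$clash_rate,
                      nrow = S)
      idx <- which(retained, arr.ind = TRUE)
      ri <- idx[, 1L]; si <- idx[, 2L]
      n_clash_events <<- n_clash_events + sum(clash[idx])
      rep_a <- n_atoms[ri]
      parts_list <- list()
      if (length(ri) > 0L) {
        parts_list$site <- data.table::data.table(
          structure_id = rep(sids[si], rep_a), chain = "A",
          resnum = rep(plan$positions[ri] + offsets[si], rep_a),
          icode = "",
          resname = rep(plan$resnames[ri], rep_a),
          atom = unlist(plan$atoms[ri], use.names = FALSE),
          ligand = plan$ligand, instance = "1",
          labels = as.list(rep(ifelse(clash[idx], "clash", plan$raw_label[ri]),
                               rep_a)))
      }
      n_water <- stats::rpois(n_structures, config$water_lambda)
      if (sum(n_water) > 0L) {
        wsi <- rep(seq_len(n_structures), n_water)
        parts_list$water <- data.table::data.table(
          structure_id = sids[wsi], chain = "W",
          resnum = 500L + unlist(lapply(n_water, seq_len)), icode = "",
          resname = "HOH", atom = "O", ligand = plan$ligand, instance = "1",
          labels = as.list(rep("polar", sum(n_water))))
      }
      nsi <- which(stats::runif(n_structures) < config$nonstandard_rate)
      if (length(nsi) > 0L) {
        parts_list$nonstd <- data.table::data.table(
          structure_id = sids[nsi], chain = "A",
          resnum = offsets[nsi] + 4L, icode = "", resname = "MSE",
          atom = "SD", ligand = plan$ligand, instance = "1",
          labels = as.list(rep("polar", length(nsi))))
      }
      if (plan$has_metal) {
        E <- length(plan$elements)
        msi <- rep(seq_len(n_structures), each = E)
        parts_list$metal <- data.table::data.table(
          structure_id = sids[msi], chain = "M",
          resnum = 900L + rep(seq_len(E), n_structures), icode = "",
          resname = rep(plan$elements, n_structures),
          atom = rep(plan$elements, n_structures),
          ligand = plan$ligand, instance = "1",
          labels = as.list(rep("metal", length(msi))))
      }
      contact_tabs[[length(contact_tabs) + 1L]] <<- data.table::rbindlist(parts_list)
    }

    if ("conservation" %in% parts) {
      high <- stats::runif(S) < config$conservation$p_high
      grade <- ifelse(high, sample(7:9, S, replace = TRUE),
                      sample(1:6, S, replace = TRUE))
      match_max <- stats::runif(S) < config$conservation$p_max_match
      max_aa <- ifelse(match_max, one_of[plan$resnames],
                       vapply(plan$resnames, function(r) {
                         .sample1(setdiff(aa$one, one_of[r]))
                       }, character(1)))
      cons_rows[[length(cons_rows) + 1L]] <<- data.table::data.table(
        ACCESSION = acc, POS = plan$positions, GRADE = grade, MAX_AA = max_aa)
    }

    seqs[acc] <<- plan$seq
    prot_rows[[length(prot_rows) + 1L]] <<- data.table::data.table(
      accession = acc, temporality = temporality,
      class_name = plan$class_name, ligand = plan$ligand,
      n_structures = n_structures, is_twin = is_twin, parent = parent,
      has_metal = plan$has_metal,
      elements = list(plan$elements),
      positions = list(plan$positions), resnames = list(plan$resnames),
      eras = list(plan$eras), modes = list(plan$modes),
      raw_groups = list(plan$group), ss_site = list(plan$ss_site))
  }

  plan_protein <- function(blk, temp_classes) {
    L <- sample(config$seq_len_range[1]:config$seq_len_range[2], 1L)
    S <- 2L + stats::rpois(1L, blk$site_size_lambda)
    S <- min(S, L - 10L)
    positions <- sort(sample(5:(L - 5L), S))
    eras <- ifelse(stats::runif(S) < blk$early_occupancy, "early", "late")
    modes <- sample(names(blk$mode_probs), S, replace = TRUE,
                    prob = blk$mode_probs)
    resnames <- character(S)
    for (i in seq_len(S)) {
      pool <- if (eras[i] == "early") early3 else late3
      if (eras[i] == "early" && modes[i] != "backbone_only") {
        pool <- setdiff(pool, "GLY")
      }
      resnames[i] <- .sample1(pool)
    }
    atoms <- vector("list", S)
    for (i in seq_len(S)) {
      atoms[[i]] <- switch(modes[i],
        backbone_only = sample(bb_atoms, sample(1:2, 1L)),
        sidechain_only = {
          sc <- sc_atoms[[resnames[i]]]
          sample(sc, min(sample(1:2, 1L), length(sc)))
        },
        both = c(.sample1(bb_atoms), .sample1(sc_atoms[[resnames[i]]])))
    }
    group <- sample(names(blk$type_mix), S, replace = TRUE, prob = blk$type_mix)
    raw_label <- vapply(group, function(g) .sample1(labels_by_group[[g]]),
                        character(1))
    bg_era <- ifelse(stats::runif(L) < config$background_early, "early", "late")
    bg_res <- ifelse(bg_era == "early",
                     early3[sample.int(10L, L, replace = TRUE)],
                     late3[sample.int(10L, L, replace = TRUE)])
    letters1 <- unname(one_of[bg_res])
    letters1[positions] <- unname(one_of[resnames])
    cls_row <- temp_classes[sample.int(nrow(temp_classes), 1L)]
    has_metal <- stats::runif(1) < blk$metal_prob
    elements <- if (has_metal) {
      unique(sample(names(blk$metal_element_mix), sample(1:2, 1L),
                    replace = TRUE, prob = blk$metal_element_mix))
    } else character(0)
    n_dom <- sample(1:2, 1L)
    dom_ranges <- if (n_dom == 1L) {
      list(beg = 1L, end = L)
    } else {
      cut <- sample(20:(L - 20L), 1L)
      list(beg = c(1L, cut + 1L), end = c(cut, L))
    }
    list(seq = paste(letters1, collapse = ""), positions = positions,
         resnames = resnames, eras = eras, modes = modes, group = group,
         raw_label = raw_label, atoms = atoms,
         ss_site = sample(names(blk$ss_mix), S, replace = TRUE,
                          prob = blk$ss_mix),
         ss_bg = sample(names(config$background_ss_mix), L, replace = TRUE,
                        prob = config$background_ss_mix),
         class_name = cls_row$class_name, ligand = .sample1(cls_row$ligands[[1L]]),
         has_metal = has_metal, elements = elements,
         x_groups = sprintf("X%03d", sample.int(40L, n_dom)),
         dom_ranges = dom_ranges)
  }

  for (temp in names(config$blocks)) {
    blk <- config$blocks[[temp]]
    temp_classes <- cls[cls$temporality == temp]
    if (nrow(temp_classes) == 0L) stop("no registry classes for temporality ", temp)
    for (p in seq_len(blk$n_proteins)) {
      prot_counter <- prot_counter + 1L
      acc <- sprintf("SP%05d", prot_counter)
      plan <- plan_protein(blk, temp_classes)
      n_structures <- 1L + stats::rpois(1L, blk$structures_lambda)
      emit_protein(acc, temp, blk, plan, n_structures, FALSE, NA_character_)
      if (stats::runif(1) < config$duplicate_rate) {
        twin <- paste0(acc, "T")
        tplan <- plan
        ## mutate ~2% of non-site positions; the site itself is untouched
        letters1 <- strsplit(plan$seq, "")[[1]]
        cand <- setdiff(seq_along(letters1), plan$positions)
        n_mut <- max(1L, round(0.02 * length(cand)))
        mut <- sample(cand, n_mut)
        for (m in mut) letters1[m] <- .sample1(setdiff(aa$one, letters1[m]))
        tplan$seq <- paste(letters1, collapse = "")
        emit_protein(twin, temp, blk, tplan, 1L, TRUE, acc)
      }
    }
  }

  proteins <- data.table::rbindlist(prot_rows)
  raw_contacts <- if ("contacts" %in% parts) data.table::rbindlist(contact_tabs) else NULL
  contacts <- if (!is.null(raw_contacts)) .finalize_contacts(raw_contacts, registry) else NULL
  sifts_tab <- data.table::rbindlist(sifts_rows)
  sifts <- .expand_sifts_ranges(sifts_tab)
  ss <- if ("ss" %in% parts) data.table::rbindlist(ss_tabs) else NULL
  ecod <- if ("ecod" %in% parts) {
    e <- data.table::rbindlist(ecod_rows)
    data.table::data.table(domain_id = e$DOMAIN_ID, structure_id = e$PDB,
                           chain = e$CHAIN, res_beg = e$RES_BEG,
                           res_end = e$RES_END, x_group = e$X_GROUP)
  } else NULL
  conservation <- if ("conservation" %in% parts) {
    cr <- data.table::rbindlist(cons_rows)
    data.table::data.table(accession = cr$ACCESSION, position = cr$POS,
                           grade = cr$GRADE, max_aa = cr$MAX_AA)
  } else NULL

  truth <- .build_truth(config, proteins, n_clash_events)

  bundle <- structure(list(sequences = seqs, sifts = sifts, contacts = contacts,
                           ss = ss, ecod = ecod, conservation = conservation,
                           truth = truth, dir = dir), class = "coenz_bundle")

  if (!is.null(dir)) {
    bundle$files <- .write_bundle(bundle, sifts_tab, raw_contacts, dir)
  }
  bundle
}

.expand_sifts_ranges <- function(tab) {
  len <- tab$PDB_END - tab$PDB_BEG + 1L
  i <- rep(seq_len(nrow(tab)), len)
  off <- sequence(len) - 1L
  map <- data.table::data.table(
    structure_id = tab$PDB[i], chain = tab$CHAIN[i],
    reskey = as.character(tab$PDB_BEG[i] + off),
    accession = tab$SP_PRIMARY[i],
    position = tab$SP_BEG[i] + off)
  data.table::setkeyv(map, c("structure_id", "chain", "reskey"))
  data.table::setattr(map, "dropped", c(ambiguous = 0L))
  map[]
}

.build_truth <- function(config, proteins, n_clash_events) {
  main <- proteins[is_twin == FALSE]
  realized <- main[, {
    eras <- unlist(eras); modes <- unlist(modes); grp <- unlist(raw_groups)
    .(n_proteins = .N,
      n_site_residues = length(eras),
      early_fraction = mean(eras == "early"),
      backbone_only_fraction = mean(modes == "backbone_only"),
      sidechain_only_fraction = mean(modes == "sidechain_only"),
      both_fraction = mean(modes == "both"),
      metal_fraction = mean(has_metal),
      type_counts = list(table(grp)),
      ss_counts = list(table(unlist(ss_site))))
  }, by = temporality]
  list(config = config, proteins = proteins, realized = realized,
       n_clash_events = n_clash_events,
       n_twins = sum(proteins$is_twin))
}

.write_bundle <- function(bundle, sifts_tab, raw_contacts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$fasta <- file.path(dir, "sequences.fasta")
  write_fasta(bundle$sequences, files$fasta)
  files$sifts <- file.path(dir, "sifts.tsv")
  utils::write.table(sifts_tab, files$sifts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(raw_contacts)) {
    cdir <- file.path(dir, "contacts")
    dir.create(cdir, showWarnings = FALSE)
    for (sid in unique(raw_contacts$structure_id)) {
      .write_contacts_json(raw_contacts[structure_id == sid], sid,
                           file.path(cdir, paste0(sid, ".json")))
    }
    files$contacts_dir <- cdir
  }
  if (!is.null(bundle$ss)) {
    files$ss <- file.path(dir, "ss.tsv")
    utils::write.table(
      data.table::data.table(PDB = bundle$ss$structure_id,
                             CHAIN = bundle$ss$chain,
                             PDB_RES = bundle$ss$reskey,
                             CODE = bundle$ss$code),
      files$ss, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$ecod)) {
    files$ecod <- file.path(dir, "ecod.tsv")
    utils::write.table(
      data.table::data.table(DOMAIN_ID = bundle$ecod$domain_id,
                             PDB = bundle$ecod$structure_id,
                             CHAIN = bundle$ecod$chain,
                             RES_BEG = bundle$ecod$res_beg,
                             RES_END = bundle$ecod$res_end,
                             X_GROUP = bundle$ecod$x_group),
      files$ecod, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$conservation)) {
    files$conservation <- file.path(dir, "conservation.tsv")
    utils::write.table(
      data.table::data.table(ACCESSION = bundle$conservation$accession,
                             POS = bundle$conservation$position,
                             GRADE = bundle$conservation$grade,
                             MAX_AA = bundle$conservation$max_aa),
      files$conservation, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- bundle$truth
  if (is.null(truth)) return(files)
  files$truth <- file.path(dir, "truth.json")
  tr <- list(
    seed = truth$config$seed,
    blocks = lapply(truth$config$blocks, unclass),
    background_early = truth$config$background_early,
    n_clash_events = truth$n_clash_events,
    n_twins = truth$n_twins,
    realized = lapply(split(truth$realized, truth$realized$temporality), function(r) {
      list(n_proteins = r$n_proteins, n_site_residues = r$n_site_residues,
           early_fraction = r$early_fraction,
           backbone_only_fraction = r$backbone_only_fraction,
           metal_fraction = r$metal_fraction)
    }),
    proteins = lapply(seq_len(nrow(truth$proteins)), function(i) {
      p <- truth$proteins[i]
      list(accession = p$accession, temporality = p$temporality,
           class_name = p$class_name, ligand = p$ligand,
           n_structures = p$n_structures, is_twin = p$is_twin,
           has_metal = p$has_metal, elements = p$elements[[1L]],
           positions = p$positions[[1L]], resnames = p$resnames[[1L]],
           modes = p$modes[[1L]])
    }))
  jsonlite::write_json(tr, files$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files
}

.write_contacts_json <- function(rows, sid, path) {
  contacts <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i]
    list(chain = r$chain, resnum = r$resnum, icode = r$icode,
         resname = r$resname, atom = r$atom, ligand = r$ligand,
         ligand_instance = r$instance, labels = as.list(r$labels[[1L]]))
  })
  jsonlite::write_json(list(schema = 1L, structure_id = sid, contacts = contacts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.coenz_bundle <- function(x, ...) {
  cat(sprintf("<coenz_bundle> %d proteins, %d structures\n",
              length(x$sequences),
              length(unique(x$sifts$structure_id))))
  if (!is.null(x$contacts)) cat(sprintf("  contact records: %d\n", nrow(x$contacts)))
  if (!is.null(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}
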