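# Shared fixtures and independent oracles.  Oracles are deliberately
# written as plain loops over first principles, independent of the package
# code paths they check.

the_registry <- load_registry()

# ---- random small lifted-contact datasets -------------------------------

# Builds a lifted, group-annotated contact table directly (bypassing the
# package's generator) for oracle-equivalence checks on call_sites().
random_lifted_dataset <- function(n_proteins = 5, max_structures = 5,
                                  max_residues = 20) {
  ligs <- c("NAD", "ATP", "SAM", "PLP", "HEM", "ASC")
  aa3 <- the_registry$amino_acids$three
  rows <- list()
  sid_n <- 0
  for (p in seq_len(n_proteins)) {
    acc <- sprintf("Q%04d", p)
    n_str <- sample(seq_len(max_structures), 1)
    n_res <- sample(2:max_residues, 1)
    positions <- sort(sample(1:300, n_res))
    resnames <- sample(aa3, n_res, replace = TRUE)
    lig <- sample(ligs, 1)
    for (s in seq_len(n_str)) {
      sid_n <- sid_n + 1
      sid <- sprintf("%04d", sid_n)
      present <- runif(n_res) < runif(1, 0.2, 1)
      for (i in which(present)) {
        rows[[length(rows) + 1]] <- data.table::data.table(
          structure_id = sid, chain = "A",
          resnum = positions[i], icode = "", reskey = as.character(positions[i]),
          resname = resnames[i],
          atom = if (resnames[i] == "GLY") "CA" else sample(c("CA", "CB"), 1),
          ligand = lig, instance = "1",
          labels = list("hbond"), partner_is_metal = FALSE,
          nonstandard = FALSE,
          accession = acc, position = positions[i],
          groups = list("electrostatic"), clash_only = FALSE)
      }
    }
  }
  data.table::rbindlist(rows)
}

# Exhaustive per-residue interaction-ratio enumeration (plain loops,
# exact rational comparison by integer arithmetic for threshold p/q).
oracle_call_sites <- function(lifted, registry, num = 1L, den = 2L,
                              inclusive = TRUE) {
  df <- as.data.frame(lifted[lifted$partner_is_metal == FALSE &
                               !lifted$nonstandard & !lifted$clash_only, ])
  df$class <- unname(registry$ligand_to_class[df$ligand])
  out <- list()
  for (acc in sort(unique(df$accession))) {
    for (cl in sort(unique(df$class[df$accession == acc]))) {
      sub <- df[df$accession == acc & df$class == cl, ]
      structs <- unique(sub$structure_id)
      n <- length(structs)
      for (pos in sort(unique(sub$position))) {
        k <- 0
        for (s in structs) {
          if (any(sub$position == pos & sub$structure_id == s)) k <- k + 1
        }
        pass <- if (inclusive) k * den >= num * n else k * den > num * n
        if (pass) {
          out[[length(out) + 1]] <- data.frame(
            accession = acc, class_name = cl, position = pos,
            n_present = k, n_structures = n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(accession = character(), class_name = character(),
                      position = integer(), n_present = integer(),
                      n_structures = integer()))
  }
  do.call(rbind, out)
}

# ---- chi-squared oracle --------------------------------------------------

# Direct Pearson formula; expected values from margins for contingency
# tables, or supplied for goodness-of-fit.
oracle_chisq_stat <- function(observed, expected = NULL) {
  if (is.null(expected)) {
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  }
  s <- 0
  for (i in seq_along(observed)) {
    s <- s + (observed[i] - expected[i])^2 / expected[i]
  }
  s
}

# ---- clustering oracle ---------------------------------------------------

# All-shift ungapped identity (every shift enumerated, no seeding).
oracle_identity <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  na <- length(ia); nb <- length(ib)
  best <- 0
  for (s in (-(nb - 1)):(na - 1)) {
    lo <- max(1, 1 + s); hi <- min(na, nb + s)
    if (hi < lo) next
    m <- sum(ia[lo:hi] == ib[(lo - s):(hi - s)])
    if (m > best) best <- m
  }
  best / min(na, nb)
}

# Greedy clustering over the full all-pairs identity matrix.
oracle_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  n <- length(seqs)
  reps <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (oracle_identity(seqs[reps[j]], seqs[i]) >= threshold) {
        assign[i] <- j; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  stats::setNames(assign, names(seqs))
}

# Synthetic sequence families: n_fam families of fam_size copies with at
# most mut_rate substitutions each.
make_families <- function(n_fam = 10, fam_size = 5, len = 100,
                          mut_rate = 0.05) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(0)
  for (f in seq_len(n_fam)) {
    base <- paste(sample(alpha, len, replace = TRUE), collapse = "")
    for (m in seq_len(fam_size)) {
      s <- strsplit(base, "")[[1]]
      n_mut <- sample(0:floor(mut_rate * len), 1)
      if (n_mut > 0) {
        at <- sample(len, n_mut)
        for (a in at) s[a] <- sample(setdiff(alpha, s[a]), 1)
      }
      seqs[sprintf("F%02dM%02d", f, m)] <- paste(s, collapse = "")
    }
  }
  seqs
}

# ---- small simulation configs -------------------------------------------

small_sim_config <- function(seed, n = 20L) {
  simulation_config(
    seed = seed,
    blocks = list(
      Ancient = temporality_block(n_proteins = n, early_occupancy = 0.61,
                                  metal_prob = 0.24),
      LUCA = temporality_block(n_proteins = n, early_occupancy = 0.53,
                               mode_probs = c(backbone_only = 0.15,
                                              sidechain_only = 0.60, both = 0.25),
                               metal_prob = 0.13),
      PostLUCA = temporality_block(n_proteins = n, early_occupancy = 0.47,
                                   mode_probs = c(backbone_only = 0.11,
                                                  sidechain_only = 0.64, both = 0.25),
                                   metal_prob = 0.11)))
}

# Generate a bundle and estimate the per-temporality early-residue
# occupancy through the standard lift -> annotate -> call-sites path.
estimate_composition <- function(config, registry = the_registry) {
  b <- generate_dataset(config, registry = registry, parts = "contacts")
  lifted <- lift_to_uniprot(b$contacts, b$sifts)
  annotate_contact_groups(lifted, registry)
  lifted <- lifted[lifted$partner_is_metal |
                     (!lifted$clash_only & !lifted$nonstandard)]
  sites <- call_sites(lifted, registry)
  list(bundle = b, sites = sites,
       composition = site_composition(sites, registry))
}
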