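#' Read per-structure residue-ligand contact records
#'
#' Parses a contacts JSON file (one file per structure; schema version 1,
#' emulating an aggregated bound-ligand interaction payload).  Each record
#' describes one contact between a bound coenzyme molecule (`ligand`,
#' distinguished per copy by `ligand_instance`) and a partner entity: a
#' protein residue atom, a water molecule, or a metal ion.  Water partners
#' are dropped; metal-ion partners (recognised against the registry's
#' curated metal component list) are retained with `partner_is_metal =
#' TRUE` and later mark metal mediation of the site sharing their bound
#' environment.  Residue partners outside the 20 canonical amino acids are
#' flagged `nonstandard` and excluded from era statistics downstream.
#'
#' @param path Path to a contacts JSON file.
#' @param registry A `coenz_registry`.
#' @return A `data.table` with columns `structure_id`, `chain`, `resnum`,
#'   `icode`, `reskey`, `resname`, `atom`, `ligand`, `instance`, `labels`
#'   (list column of raw contact labels), `partner_is_metal`,
#'   `nonstandard`.  Drop counts are attached as attribute `dropped`
#'   (named integer: `water`, `malformed`).
#' @export
read_contacts <- function(path, registry) {
  stopifnot(inherits(registry, "coenz_registry"))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema)) stop("contacts file lacks a schema version field: ", path)
  if (doc$schema != 1L) stop("unsupported contacts schema version: ", doc$schema)
  sid <- as.character(doc$structure_id)
  if (!nzchar(sid)) stop("contacts file lacks structure_id: ", path)

  n_malformed <- 0L
  rows <- vector("list", length(doc$contacts))
  for (i in seq_along(doc$contacts)) {
    ct <- doc$contacts[[i]]
    needed <- c("chain", "resnum", "resname", "atom", "ligand", "labels")
    if (!all(needed %in% names(ct)) || length(ct$labels) == 0L) {
      n_malformed <- n_malformed + 1L
      next
    }
    resname <- toupper(as.character(ct$resname))
    icode <- if (!is.null(ct$icode)) as.character(ct$icode) else ""
    rows[[i]] <- data.table::data.table(
      structure_id = sid,
      chain = as.character(ct$chain),
      resnum = as.integer(ct$resnum),
      icode = icode,
      resname = resname,
      atom = toupper(as.character(ct$atom)),
      ligand = toupper(as.character(ct$ligand)),
      instance = if (!is.null(ct$ligand_instance)) as.character(ct$ligand_instance) else "1",
      labels = list(as.character(unlist(ct$labels)))
    )
  }
  if (n_malformed > 0L) {
    warning(sprintf("%s: skipped %d malformed contact record(s)", basename(path), n_malformed))
  }
  raw <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(raw) == 0L) stop("no valid contact records in ", path)
  out <- .finalize_contacts(raw, registry, n_malformed = n_malformed)
  out[]
}

## Shared post-processing for contact rows, whether parsed from JSON or
## built in memory by the synthetic generator: drops water partners,
## derives the residue key and the metal/non-standard flags, attaches drop
## counts.
.finalize_contacts <- function(raw, registry, n_water_dropped = 0L,
                               n_malformed = 0L) {
  is_water <- raw$resname %in% registry$water_codes
  out <- raw[!is_water]
  if (nrow(out) == 0L) stop("no valid contact records after water removal")
  out[, reskey := paste0(resnum, icode)]
  out[, partner_is_metal := resname %in% registry$metal_codes]
  out[, nonstandard := !partner_is_metal & is.na(registry$era_by_code[resname])]
  data.table::setattr(out, "dropped",
                      c(water = n_water_dropped + sum(is_water),
                        malformed = n_malformed))
  out
}

#' Read a directory of contacts JSON files
#'
#' @param dir Directory containing `*.json` contact files (one per structure).
#' @param registry A `coenz_registry`.
#' @return Combined contacts `data.table` (see [read_contacts()]) with
#'   summed `dropped` attribute.
#' @export
read_contacts_dir <- function(dir, registry) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no contact JSON files under ", dir)
  parts <- lapply(files, read_contacts, registry = registry)
  dropped <- Reduce(`+`, lapply(parts, attr, "dropped"))
  out <- data.table::rbindlist(parts)
  data.table::setattr(out, "dropped", dropped)
  out[]
}

#' Read a SIFTS-style structure-to-UniProt residue mapping
#'
#' Two tab-separated dialects are accepted and detected from the header:
#' the range dialect with columns
#' `PDB CHAIN SP_PRIMARY RES_BEG RES_END PDB_BEG PDB_END SP_BEG SP_END`
#' (each row expanded to a per-residue map; PDB and UniProt ranges must
#' have equal lengths) and a per-residue dialect with columns
#' `PDB CHAIN PDB_RES ICODE SP_PRIMARY SP_POS`.
#'
#' Structure residues mapping to more than one (accession, position) are
#' ambiguous (e.g. chimeric chains); they are removed from the map and
#' counted in attribute `dropped["ambiguous"]`.
#'
#' @param path Path to the TSV file (optionally with `#`-comment lines).
#' @return A `data.table` keyed by (`structure_id`, `chain`, `reskey`) with
#'   columns `accession` and `position`.
#' @export
read_sifts <- function(path) {
  hdr <- utils::read.delim(path, comment.char = "#", nrows = 1,
                           check.names = FALSE, colClasses = "character")
  tab <- data.table::as.data.table(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      colClasses = "character"))
  range_cols <- c("PDB", "CHAIN", "SP_PRIMARY", "RES_BEG", "RES_END",
                  "PDB_BEG", "PDB_END", "SP_BEG", "SP_END")
  res_cols <- c("PDB", "CHAIN", "PDB_RES", "ICODE", "SP_PRIMARY", "SP_POS")
  if (all(range_cols %in% names(hdr))) {
    n_bad <- 0L
    parts <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      pdb_beg <- as.integer(tab$PDB_BEG[i]); pdb_end <- as.integer(tab$PDB_END[i])
      sp_beg <- as.integer(tab$SP_BEG[i]);  sp_end <- as.integer(tab$SP_END[i])
      if (anyNA(c(pdb_beg, pdb_end, sp_beg, sp_end)) ||
          (pdb_end - pdb_beg) != (sp_end - sp_beg)) {
        n_bad <- n_bad + 1L
        next
      }
      parts[[i]] <- data.table::data.table(
        structure_id = tab$PDB[i], chain = tab$CHAIN[i],
        reskey = as.character(pdb_beg:pdb_end),
        accession = tab$SP_PRIMARY[i],
        position = sp_beg:sp_end)
    }
    if (n_bad > 0L) warning(sprintf("%s: skipped %d malformed range row(s)", basename(path), n_bad))
    map <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
  } else if (all(res_cols %in% names(hdr))) {
    map <- data.table::data.table(
      structure_id = tab$PDB, chain = tab$CHAIN,
      reskey = paste0(tab$PDB_RES, ifelse(is.na(tab$ICODE), "", tab$ICODE)),
      accession = tab$SP_PRIMARY,
      position = as.integer(tab$SP_POS))
  } else {
    stop("unrecognised SIFTS dialect in ", path)
  }
  if (any(map$position < 1L, na.rm = TRUE)) stop("UniProt positions must be >= 1")
  map <- unique(map)
  key <- paste(map$structure_id, map$chain, map$reskey, sep = "\r")
  dup <- key %in% key[duplicated(key)]
  n_ambiguous <- length(unique(key[dup]))
  map <- map[!dup]
  data.table::setkeyv(map, c("structure_id", "chain", "reskey"))
  data.table::setattr(map, "dropped", c(ambiguous = n_ambiguous))
  map[]
}

#' Lift structure-level contacts to UniProt coordinates
#'
#' Joins protein-residue contact records to a SIFTS-style map on
#' (`structure_id`, `chain`, residue key), attaching `accession` and
#' `position` (1-based UniProt numbering).  Residue contacts without a
#' mapping are dropped and counted; metal-ion partner records are passed
#' through unmapped (they are not protein residues) and remain associated
#' with their bound-ligand environment.  `structure_id` is retained — it is
#' the denominator of the interaction ratio.
#'
#' @param contacts Contacts `data.table` from [read_contacts()].
#' @param map Residue map from [read_sifts()].
#' @return Lifted contacts with columns `accession`, `position` added;
#'   attribute `dropped` counts `unmapped` residue contacts.
#' @export
lift_to_uniprot <- function(contacts, map) {
  if (nrow(map) == 0L) stop("empty SIFTS map")
  res <- contacts[partner_is_metal == FALSE]
  met <- contacts[partner_is_metal == TRUE]
  lifted <- map[res, on = c("structure_id", "chain", "reskey")]
  n_unmapped <- sum(is.na(lifted$accession))
  if (nrow(res) > 0L && n_unmapped == nrow(res)) {
    stop("no residue contact could be mapped to UniProt coordinates")
  }
  lifted <- lifted[!is.na(accession)]
  if (nrow(met) > 0L) {
    met[, `:=`(accession = NA_character_, position = NA_integer_)]
    lifted <- data.table::rbindlist(list(lifted, met), use.names = TRUE)
  }
  data.table::setattr(lifted, "dropped", c(unmapped = n_unmapped))
  lifted[]
}

#' Read an amino acid FASTA file
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return Named character vector (accession -> uppercase sequence).  The
#'   accession is the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

## Ungapped pairwise identity: exact matches at the best candidate shift,
## divided by the length of the shorter sequence.  Candidate shifts come
## from shared k-mer seeds (a documented approximation of the external
## clustering tool's global identity; see the methods vignette).
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

.seq_identity_pre <- function(ia, ib, ka, kb) {
  na <- length(ia); nb <- length(ib)
  if (na == 0L || nb == 0L) return(0)
  hit <- match(ka, kb)
  shifts <- unique(which(!is.na(hit)) - hit[!is.na(hit)])
  shifts <- unique(c(0L, shifts))  # always consider the unshifted alignment
  best <- 0L
  for (s in shifts) {
    # positions i in a align with i - s in b
    lo <- max(1L, 1L + s); hi <- min(na, nb + s)
    if (hi < lo) next
    m <- sum(ia[lo:hi] == ib[(lo - s):(hi - s)])
    if (m > best) best <- m
  }
  best / min(na, nb)
}

.seq_identity <- function(a, b, k = 6L) {
  .seq_identity_pre(utf8ToInt(a), utf8ToInt(b), .kmer_set(a, k), .kmer_set(b, k))
}

#' Greedy sequence-identity clustering
#'
#' Removes redundancy the way the external clustering tool is used in
#' practice: sequences are sorted longest-first (ties broken by accession),
#' and each sequence joins the first existing cluster whose representative
#' it matches at or above the identity threshold, otherwise founds a new
#' cluster.  The representative is therefore the longest member.  Identity
#' is exact matches over an ungapped best seed-anchored alignment, divided
#' by the length of the shorter sequence (a documented approximation; see
#' the methods vignette).
#'
#' @param seqs Named character vector of amino acid sequences.
#' @param threshold Identity threshold in (0, 1]; default 0.9, the primary
#'   analysis setting (a 0.3 secondary setting is also common).
#' @return A `data.table` with columns `accession`, `cluster` (integer id in
#'   representative order), `representative`, `identity_to_rep`.
#' @examples
#' cluster_sequences(c(a = "MGGSSEQ", b = "MGGSSEQ", c = "WWWWYYY"), 0.9)
#' @export
cluster_sequences <- function(seqs, threshold = 0.9) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  short <- names(seqs)[nchar(seqs) < 10L]
  if (length(short) > 0L) {
    warning("sequence(s) shorter than 10 residues become singletons: ",
            paste(short, collapse = ", "))
  }
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  acc <- names(seqs)
  ints <- lapply(seqs, utf8ToInt)
  kmers <- lapply(seqs, .kmer_set, k = 6L)
  reps <- integer(0)              # indices into seqs
  assign <- integer(length(seqs))
  ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    if (nchar(seqs[i]) >= 10L) {
      for (j in seq_along(reps)) {
        r <- reps[j]
        id <- .seq_identity_pre(ints[[r]], ints[[i]], kmers[[r]], kmers[[i]])
        if (id >= threshold) {
          assign[i] <- j; ident[i] <- id; placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
      ident[i] <- 1
    }
  }
  data.table::data.table(
    accession = acc,
    cluster = assign,
    representative = acc[reps[assign]],
    identity_to_rep = ident
  )
}

#' Representative accessions of a clustering
#'
#' @param clusters Result of [cluster_sequences()].
#' @return Character vector of representative accessions, one per cluster.
#' @export
cluster_representatives <- function(clusters) {
  unique(clusters$representative)
}
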