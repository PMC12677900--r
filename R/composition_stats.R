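#' Early/late residue composition of binding sites
#'
#' Counts site residues by evolutionary era, grouped by coenzyme
#' temporality (default) or by coenzyme class.  The counting unit is the
#' site residue: each consensus-site residue counts once per site,
#' independent of how many structures or contacts support it.
#'
#' @param sites A `coenz_sites` object.
#' @param registry A `coenz_registry`.
#' @param group_by `"temporality"` or `"class_name"`.
#' @return A `data.table` with columns `group`, `n_early`, `n_late`,
#'   `early_pct`, `late_pct`.
#' @export
site_composition <- function(sites, registry,
                             group_by = c("temporality", "class_name")) {
  group_by <- match.arg(group_by)
  res <- sites$residues
  if (nrow(res) == 0L) {
    warning("no site residues; empty composition table")
    return(data.table::data.table(group = character(), n_early = integer(),
                                  n_late = integer(), early_pct = numeric(),
                                  late_pct = numeric()))
  }
  tab <- res[, .(n_early = sum(era == "early"), n_late = sum(era == "late")),
             by = c(group_by)]
  data.table::setnames(tab, group_by, "group")
  tab[, `:=`(early_pct = 100 * n_early / (n_early + n_late),
             late_pct = 100 * n_late / (n_early + n_late))]
  data.table::setorder(tab, group)
  tab[]
}

#' Per-amino-acid composition of binding sites
#'
#' Relative frequency (percent) of each of the 20 residues among site
#' residues, per group.  All 20 residues appear in the output (zero when
#' absent), ordered by chronology rank.
#'
#' @inheritParams site_composition
#' @return A `data.table` with columns `group`, `resname`, `era`, `rank`,
#'   `n`, `pct`; `pct` sums to 100 within each group.
#' @export
aa_composition <- function(sites, registry,
                           group_by = c("temporality", "class_name")) {
  group_by <- match.arg(group_by)
  res <- sites$residues
  if (nrow(res) == 0L) stop("no site residues")
  aa <- registry$amino_acids[, .(resname = three, era, rank)]
  out <- res[, .(n = .N), by = c(group_by, "resname")]
  data.table::setnames(out, group_by, "group")
  grid <- data.table::CJ(group = unique(out$group), resname = aa$resname)
  out <- out[grid, on = c("group", "resname")]
  out[is.na(n), n := 0L]
  out <- aa[out, on = "resname"]
  out[, pct := 100 * n / sum(n), by = group]
  data.table::setorder(out, group, rank)
  data.table::setcolorder(out, c("group", "resname", "era", "rank", "n", "pct"))
  out[]
}

#' Early/late composition of a sequence background
#'
#' Residue counts over all sequences (every position, not only binding
#' sites); non-canonical letters are excluded and counted.
#'
#' @param seqs Named character vector of amino acid sequences.
#' @param registry A `coenz_registry`.
#' @return A list with `n_early`, `n_late`, `early_pct`, `late_pct`,
#'   `n_noncanonical`.
#' @examples
#' reg <- load_registry()
#' background_composition(c(p = "GGDD"), reg)
#' @export
background_composition <- function(seqs, registry) {
  stopifnot(inherits(registry, "coenz_registry"))
  if (length(seqs) == 0L) stop("at least one sequence required")
  letters1 <- strsplit(paste(toupper(seqs), collapse = ""), "")[[1]]
  era <- registry$era_by_code[letters1]
  n_non <- sum(is.na(era))
  if (n_non > 0L) {
    message(n_non, " non-canonical residue(s) excluded from background composition")
  }
  n_early <- sum(era == "early", na.rm = TRUE)
  n_late <- sum(era == "late", na.rm = TRUE)
  if (n_early + n_late == 0L) stop("sequences contain no canonical residues")
  list(n_early = n_early, n_late = n_late,
       early_pct = 100 * n_early / (n_early + n_late),
       late_pct = 100 * n_late / (n_early + n_late),
       n_noncanonical = n_non)
}

#' Pearson chi-squared test (contingency or goodness-of-fit)
#'
#' Thin wrapper around [stats::chisq.test()] with no continuity
#' correction.  Given a matrix, an r x k independence test with
#' df = (r-1)(k-1); given observed and expected count vectors, a
#' goodness-of-fit test with df = k-1.  Expected counts of zero are an
#' error; any expected count below 5 sets the `low_expected` flag rather
#' than aborting, since the decision is left to the caller.
#'
#' @param observed Count matrix, or vector of observed counts.
#' @param expected Optional vector of expected counts (goodness-of-fit).
#' @return A list: `statistic`, `df`, `p_value`, `expected`,
#'   `low_expected`.
#' @examples
#' chi_squared(matrix(c(10, 10, 10, 10), 2))
#' @export
chi_squared <- function(observed, expected = NULL) {
  if (is.null(expected)) {
    stopifnot(is.matrix(observed))
    ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  } else {
    stopifnot(length(observed) == length(expected))
    if (any(expected <= 0)) stop("expected counts must be > 0")
    ht <- suppressWarnings(
      stats::chisq.test(observed, p = expected / sum(expected)))
  }
  if (any(ht$expected == 0)) stop("expected count of zero")
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       expected = ht$expected,
       low_expected = any(ht$expected < 5))
}

#' Per-amino-acid fractional difference between two compositions
#'
#' The fractional difference (FD) of residue *i* between compositions A
#' and B is defined here as the percentage-point difference of its
#' relative frequencies, `FD_i = p_i(A) - p_i(B)` (both in percent).  The
#' FDs over any pair of compositions sum to zero, and
#' `FD(A, B) = -FD(B, A)`.  Mean FDs over the early and the late residue
#' sets summarise which era is enriched in A relative to B.
#'
#' @param comp_a,comp_b Named numeric vectors of per-residue percentages
#'   over the 20 canonical residues (three-letter names), each summing
#'   to 100.
#' @param registry A `coenz_registry`.
#' @return A list: `table` (`data.table` with `resname`, `era`, `freq_a`,
#'   `freq_b`, `fd`), `mean_fd_early`, `mean_fd_late`.
#' @export
fractional_difference <- function(comp_a, comp_b, registry) {
  stopifnot(inherits(registry, "coenz_registry"))
  aa <- registry$amino_acids
  for (nm in list(comp_a, comp_b)) {
    if (!all(aa$three %in% names(nm))) {
      stop("composition missing residue(s): ",
           paste(setdiff(aa$three, names(nm)), collapse = ", "))
    }
  }
  tab <- data.table::data.table(
    resname = aa$three, era = aa$era, rank = aa$rank,
    freq_a = unname(comp_a[aa$three]),
    freq_b = unname(comp_b[aa$three]))
  tab[, fd := freq_a - freq_b]
  data.table::setorder(tab, rank)
  list(table = tab[],
       mean_fd_early = mean(tab$fd[tab$era == "early"]),
       mean_fd_late = mean(tab$fd[tab$era == "late"]))
}

#' Composition restricted to phosphate-free coenzyme classes
#'
#' Sensitivity analysis for the possibility that early-residue enrichment
#' is driven by phosphate-group binding: recomputes the site composition
#' using only sites of coenzyme classes without phosphate groups (e.g.
#' SAM, tetrahydrofolic acid, biopterin and heme among the Ancient
#' classes).
#'
#' @inheritParams site_composition
#' @return Same shape as [site_composition()].
#' @export
phosphate_sensitivity <- function(sites, registry,
                                  group_by = c("temporality", "class_name")) {
  group_by <- match.arg(group_by)
  no_p <- registry$classes$class_name[!registry$classes$phosphate_containing]
  keep <- sites$residues$class_name %in% no_p
  sub <- structure(list(residues = sites$residues[keep],
                        sites = sites$sites[sites$sites$class_name %in% no_p]),
                   class = "coenz_sites")
  site_composition(sub, registry, group_by)
}

#' Normalize an early/late composition by a sequence background
#'
#' Enrichment-style normalization: each era's proportion is divided by its
#' background proportion and the two ratios are rescaled to sum to 100.  A
#' composition equal to the background maps to 50/50; a 50/50 background
#' leaves the composition unchanged.
#'
#' @param composition A table from [site_composition()] (columns
#'   `early_pct`, `late_pct`).
#' @param background A list with `early_pct` and `late_pct` (see
#'   [background_composition()]).
#' @return The composition table with `early_pct_norm` and
#'   `late_pct_norm` columns added.
#' @export
normalize_by_background <- function(composition, background) {
  stopifnot(background$early_pct > 0, background$late_pct > 0)
  e <- composition$early_pct / background$early_pct
  l <- composition$late_pct / background$late_pct
  out <- data.table::copy(composition)
  out[, `:=`(early_pct_norm = 100 * e / (e + l),
             late_pct_norm = 100 * l / (e + l))]
  out[]
}
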