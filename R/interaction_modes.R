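#' Backbone/side-chain binding-mode distribution
#'
#' Percentage of site residues interacting purely through backbone atoms
#' (N, C, CA, O), purely through side-chain atoms, or through both, per
#' coenzyme temporality, together with the era split within each mode and
#' a per-temporality era x mode chi-squared test of independence.
#'
#' @param sites A `coenz_sites` object.
#' @param registry A `coenz_registry`.
#' @return A list: `profile` (`data.table`: `temporality`, `mode`, `n`,
#'   `pct`, with the three mode percentages summing to 100 per
#'   temporality), `era_mode` (`data.table`: `temporality`, `mode`, `era`,
#'   `n`, `pct_within_mode`, `pct_of_temporality`), and `tests` (named
#'   list of [chi_squared()] results per temporality; `NULL` where the
#'   cross-tab is degenerate).
#' @export
mode_distribution <- function(sites, registry) {
  res <- sites$residues
  if (nrow(res) == 0L) stop("no site residues")
  modes <- c("backbone_only", "sidechain_only", "both")
  prof <- res[, .(n = .N), by = .(temporality, mode)]
  grid <- data.table::CJ(temporality = unique(res$temporality), mode = modes)
  prof <- prof[grid, on = c("temporality", "mode")]
  prof[is.na(n), n := 0L]
  prof[, pct := 100 * n / sum(n), by = temporality]
  prof[, mode := factor(mode, levels = modes)]
  data.table::setorder(prof, temporality, mode)
  prof[, mode := as.character(mode)]

  em <- res[, .(n = .N), by = .(temporality, mode, era)]
  em[, pct_within_mode := 100 * n / sum(n), by = .(temporality, mode)]
  em[, pct_of_temporality := 100 * n / sum(n), by = temporality]
  data.table::setorder(em, temporality, mode, era)

  tests <- lapply(split(res, res$temporality), function(d) {
    tab <- table(d$era, d$mode)
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(NULL)
    chi_squared(unclass(tab))
  })
  list(profile = prof[], era_mode = em[], tests = tests)
}

#' Grouped interaction-type distribution
#'
#' Distribution of site residues over the grouped interaction types
#' (clashes are excluded upstream, so at most eight groups appear).  Under
#' the default `"residue"` counting unit a residue contributes once to
#' every grouped type it exhibits (so a residue with both electrostatic
#' and vdw contacts counts in both bins); under `"dominant"` each residue
#' contributes once, to its alphabetically first group (a deterministic
#' single-count alternative).
#'
#' @param sites A `coenz_sites` object.
#' @param unit `"residue"` (residue x group contributions, default) or
#'   `"dominant"`.
#' @return A `data.table`: `temporality`, `group`, `n`, `pct` (percent of
#'   contributions within the temporality).
#' @export
type_distribution <- function(sites, unit = c("residue", "dominant")) {
  unit <- match.arg(unit)
  res <- sites$residues
  if (nrow(res) == 0L) stop("no site residues")
  if (unit == "residue") {
    long <- res[, .(group = unlist(groups)), by = .(temporality, accession,
                                                    class_name, position)]
  } else {
    long <- res[, .(group = vapply(groups, function(g) sort(g)[1L], character(1))),
                by = .(temporality, accession, class_name, position)]
  }
  long <- long[!is.na(group) & group != "clashes"]
  out <- long[, .(n = .N), by = .(temporality, group)]
  out[, pct := 100 * n / sum(n), by = temporality]
  data.table::setorder(out, temporality, -n, group)
  out[]
}

#' Metal-ion mediation of coenzyme binding sites
#'
#' Fraction of binding sites with at least one mediating metal ion, per
#' temporality and per coenzyme class, plus per-element statistics.  A
#' site counts once for "has at least one metal" regardless of how many
#' ions are present (set semantics); the element tally keeps every
#' observed ion (multiset semantics).
#'
#' @param sites A `coenz_sites` object.
#' @return A list: `by_temporality` (`data.table`: `temporality`,
#'   `n_sites`, `n_metal`, `fraction`), `by_class` (same per class), and
#'   `elements` (`data.table`: `class_name`, `element`, `n_sites` with
#'   that element, `fraction` of the class's sites; ranked by frequency).
#' @export
metal_mediation <- function(sites) {
  st <- sites$sites
  if (nrow(st) == 0L) stop("no sites")
  by_temp <- st[, .(n_sites = .N, n_metal = sum(has_metal)), by = temporality]
  by_temp[, fraction := n_metal / n_sites]
  data.table::setorder(by_temp, temporality)
  by_class <- st[, .(n_sites = .N, n_metal = sum(has_metal)),
                 by = .(class_name, temporality)]
  by_class[, fraction := n_metal / n_sites]
  data.table::setorder(by_class, -fraction, class_name)
  cand <- st[has_metal == TRUE]
  el <- if (nrow(cand) > 0L) {
    cand[, .(element = unique(unlist(metal_elements))),
         by = .(class_name, accession)]
  } else cand[, .(class_name = character(), accession = character(),
                  element = character())]
  elements <- if (nrow(el) > 0L) {
    tot <- st[, .(n_total = .N), by = class_name]
    e <- el[, .(n_sites = .N), by = .(class_name, element)]
    e <- tot[e, on = "class_name"]
    e[, fraction := n_sites / n_total]
    data.table::setorder(e, -n_sites, class_name, element)
    e[]
  } else {
    data.table::data.table(class_name = character(), n_total = integer(),
                           element = character(), n_sites = integer(),
                           fraction = numeric())
  }
  list(by_temporality = by_temp[], by_class = by_class[], elements = elements)
}
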