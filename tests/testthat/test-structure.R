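fixture_all <- function() {
  fx <- make_minimal_fixture(registry = the_registry)
  lifted <- lift_to_uniprot(fx$contacts, fx$sifts)
  annotate_contact_groups(lifted, the_registry)
  list(fx = fx, sites = call_sites(lifted, the_registry))
}

test_that("per-residue secondary-structure profiles remove redundancy", {
  f <- fixture_all()
  ssl <- lift_secondary_structure(f$fx$ss, f$fx$sifts)
  # helix in both PA structures -> the single code {h}
  expect_equal(residue_ss_profile(ssl, "PA", 12L), "h")
  # helix in one structure, coil in the other -> {c, h}
  expect_equal(residue_ss_profile(ssl, "PA", 40L), c("c", "h"))
  # single structure -> its single code
  expect_equal(residue_ss_profile(ssl, "PC", 12L), "b")
  # unobserved -> empty
  expect_length(residue_ss_profile(ssl, "ZZ", 1L), 0L)
})

test_that("secondary-structure content counts (residue, code) pairs", {
  f <- fixture_all()
  ssl <- lift_secondary_structure(f$fx$ss, f$fx$sifts)
  ssc <- ss_content(f$sites, ssl)
  tab <- ssc$by_temporality
  # site residues: PA12 {h}, PA40 {c,h}, PB7 {c}, PC12 {b}, PC60 {h}
  expect_equal(sum(tab$n), 6L)
  expect_equal(tab$n[tab$code == "h"], 3L)
  expect_equal(tab$n[tab$code == "b"], 1L)
  expect_equal(tab$n[tab$code == "c"], 2L)
  expect_equal(sum(tab$pct), 100)
  expect_equal(sum(ssc$background$pct), 100)
  expect_equal(ssc$n_unobserved, 0L)
})

test_that("all-coil input yields 100% coil content", {
  f <- fixture_all()
  ss_coil <- data.table::copy(f$fx$ss)
  ss_coil$code <- "c"
  ssc <- ss_content(f$sites, lift_secondary_structure(ss_coil, f$fx$sifts))
  expect_equal(ssc$by_temporality$code, "c")
  expect_equal(ssc$by_temporality$pct, 100)
})

test_that("DSSP-style codes collapse to the three-letter vocabulary", {
  expect_equal(collapse_ss_code(c("H", "G", "I", "E", "B", "T", "S", "-")),
               c("h", "h", "h", "b", "b", "c", "c", "c"))
  expect_equal(collapse_ss_code(c("h", "b", "c")), c("h", "b", "c"))
})

test_that("fold diversity counts distinct X-groups at residue level", {
  f <- fixture_all()
  fd <- fold_diversity(f$sites, f$fx$ecod, f$fx$sifts)
  fd <- as.data.frame(fd)
  # SAM site spans two domains -> both X-groups
  expect_equal(fd$n_xgroups[fd$class_name == "SAM"], 2L)
  expect_equal(sort(fd$x_groups[fd$class_name == "SAM"][[1]]), c("X001", "X002"))
  expect_equal(fd$n_xgroups[fd$class_name == "NAD"], 1L)
  expect_equal(fd$n_xgroups[fd$class_name == "ATP"], 1L)
})

test_that("fold diversity is invariant to duplicated structures", {
  f <- fixture_all()
  # duplicate PA structure 1pa1 under a new id in both ECOD and SIFTS
  dup_ecod <- data.table::copy(f$fx$ecod[f$fx$ecod$structure_id == "1pa1", ])
  dup_ecod$structure_id <- "9pa9"
  dup_map <- data.table::copy(f$fx$sifts[f$fx$sifts$structure_id == "1pa1", ])
  dup_map$structure_id <- "9pa9"
  fd1 <- fold_diversity(f$sites, f$fx$ecod, f$fx$sifts)
  fd2 <- fold_diversity(f$sites,
                        data.table::rbindlist(list(f$fx$ecod, dup_ecod)),
                        data.table::rbindlist(list(f$fx$sifts, dup_map)))
  expect_equal(fd1$n_xgroups, fd2$n_xgroups)
})

test_that("classes without domain coverage report zero with a warning", {
  f <- fixture_all()
  ecod_pa_only <- f$fx$ecod[f$fx$ecod$structure_id %in% c("1pa1", "1pa2"), ]
  expect_warning(fd <- fold_diversity(f$sites, ecod_pa_only, f$fx$sifts),
                 "no ECOD coverage")
  fd <- as.data.frame(fd)
  expect_equal(fd$n_xgroups[fd$class_name == "SAM"], 0L)
})

test_that("exclusive-site detection applies the two-residue and single-era rules", {
  f <- fixture_all()
  early <- find_exclusive_sites(f$sites, the_registry, "early")
  late <- find_exclusive_sites(f$sites, the_registry, "late")
  # PA {Gly, Asp} is early-exclusive; PB is a singleton; PC is mixed
  expect_equal(unique(early$residues$accession), "PA")
  expect_equal(nrow(late$residues), 0L)
  # disjoint by construction
  expect_length(intersect(unique(early$residues$accession),
                          unique(late$residues$accession)), 0L)
})

test_that("conservation summary reports both fractions with denominators", {
  f <- fixture_all()
  early <- find_exclusive_sites(f$sites, the_registry, "early")
  cs <- conservation_summary(early, f$fx$conservation, the_registry)
  expect_equal(cs$frac_conserved, 1.0)
  expect_equal(cs$frac_max_aa, 1.0)
  expect_equal(cs$n_covered, 2L)
  # grades [7,8,2,9] -> 3/4 conserved; MAX AA mismatch halves the identity
  cons <- data.table::data.table(
    accession = "PA", position = c(12L, 40L),
    grade = c(2L, 9L), max_aa = c("G", "T"))
  cs2 <- conservation_summary(early, cons, the_registry)
  expect_equal(cs2$frac_conserved, 0.5)
  expect_equal(cs2$frac_max_aa, 0.5)
  # no coverage at all is an error
  empty_cons <- cons[0, ]
  expect_error(conservation_summary(early, empty_cons, the_registry),
               "coverage")
})

test_that("grade vector [7,8,2,9] gives 0.75 conserved", {
  s <- structure(list(residues = data.table::data.table(
    accession = "PX", class_name = "ATP", temporality = "Ancient",
    position = 1:4, resname = c("GLY", "SER", "ALA", "ASP"),
    era = "early", ratio = 1, n_present = 1L, n_structures = 1L,
    mode = "backbone_only",
    groups = replicate(4, "vdw", simplify = FALSE)),
    sites = NULL), class = "coenz_sites")
  cons <- data.table::data.table(accession = "PX", position = 1:4,
                                 grade = c(7L, 8L, 2L, 9L),
                                 max_aa = c("G", "T", "A", "D"))
  cs <- conservation_summary(s, cons, the_registry)
  expect_equal(cs$frac_conserved, 0.75)
  expect_equal(cs$frac_max_aa, 0.75)
})
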