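test_that("simulation configs validate their distributions", {
  expect_error(temporality_block(mode_probs = c(backbone_only = 0.5,
                                                sidechain_only = 0.4,
                                                both = 0.2)),
               "normalized")
  expect_error(temporality_block(early_occupancy = 1.2), "probabilities")
  expect_error(temporality_block(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(blocks = list(temporality_block())), "named")
})

test_that("the generator is deterministic: same seed, byte-identical bundles", {
  cfg <- small_sim_config(99, n = 8L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  a <- runif(3)
  set.seed(1234)
  invisible(generate_dataset(small_sim_config(5, n = 3L), parts = "contacts"))
  b <- runif(3)
  expect_equal(a, b)
})

test_that("written bundles round-trip through the readers", {
  cfg <- small_sim_config(55, n = 6L)
  d <- withr::local_tempdir()
  b <- generate_dataset(cfg, dir = d)
  expect_equal(read_fasta(file.path(d, "sequences.fasta")), b$sequences)
  m <- read_sifts(file.path(d, "sifts.tsv"))
  expect_equal(as.data.frame(m), as.data.frame(b$sifts))
  ct <- read_contacts_dir(file.path(d, "contacts"), the_registry)
  data.table::setorder(ct, structure_id, chain, resnum, atom)
  mem <- data.table::copy(b$contacts)
  data.table::setorder(mem, structure_id, chain, resnum, atom)
  expect_equal(ct$resname, mem$resname)
  expect_equal(ct$labels, mem$labels)
  expect_equal(attr(ct, "dropped")[["water"]], attr(b$contacts, "dropped")[["water"]])
  expect_equal(as.data.frame(read_ss_table(file.path(d, "ss.tsv"))),
               as.data.frame(b$ss))
  expect_equal(as.data.frame(read_ecod(file.path(d, "ecod.tsv"))),
               as.data.frame(b$ecod))
  expect_equal(as.data.frame(read_conservation(file.path(d, "conservation.tsv"))),
               as.data.frame(b$conservation))
})

test_that("full retention plants interaction ratios of exactly 1", {
  cfg <- simulation_config(
    seed = 3,
    blocks = list(Ancient = temporality_block(n_proteins = 15L, retention = 1,
                                              clash_rate = 0)),
    duplicate_rate = 0, nonstandard_rate = 0)
  est <- estimate_composition(cfg)
  expect_true(all(est$sites$residues$ratio == 1))
  # every planted residue is recovered
  truth <- est$bundle$truth$proteins
  expect_equal(nrow(est$sites$residues), sum(lengths(truth$positions)))
})

test_that("low retention shrinks recovered sites to a subset of the truth", {
  cfg <- simulation_config(
    seed = 4,
    blocks = list(Ancient = temporality_block(
      n_proteins = 40L, retention = 0.4, clash_rate = 0,
      structures_lambda = 4)),
    duplicate_rate = 0, nonstandard_rate = 0)
  est <- estimate_composition(cfg)
  truth <- est$bundle$truth$proteins
  planted <- sum(lengths(truth$positions))
  recovered <- nrow(est$sites$residues)
  # Binomial tail: with retention 0.4 most residues fall below the 50% rule
  expect_lt(recovered, 0.5 * planted)
  # and every recovered residue is a true site residue
  truth_keys <- unlist(lapply(seq_len(nrow(truth)), function(i) {
    paste(truth$accession[i], truth$positions[[i]])
  }))
  got_keys <- paste(est$sites$residues$accession, est$sites$residues$position)
  expect_true(all(got_keys %in% truth_keys))
})

test_that("synthetic contacts never use atoms outside the residue's legal set", {
  b <- generate_dataset(small_sim_config(77, n = 25L), parts = "contacts")
  res <- b$contacts[b$contacts$partner_is_metal == FALSE &
                      !b$contacts$nonstandard, ]
  aa <- the_registry$amino_acids
  legal <- stats::setNames(lapply(seq_len(nrow(aa)), function(i) {
    c(the_registry$backbone_atoms, aa$sidechain_atoms[[i]])
  }), aa$three)
  ok <- vapply(seq_len(nrow(res)), function(i) {
    res$atom[i] %in% legal[[res$resname[i]]]
  }, logical(1))
  expect_true(all(ok))
})

test_that("planted glycines are always backbone-only", {
  b <- generate_dataset(small_sim_config(88, n = 30L), parts = "contacts")
  truth <- b$truth$proteins
  for (i in seq_len(nrow(truth))) {
    gly <- truth$resnames[[i]] == "GLY"
    expect_true(all(truth$modes[[i]][gly] == "backbone_only"))
  }
})

test_that("truth realizations converge toward planted values as n grows", {
  err_at <- function(n, seed) {
    b <- generate_dataset(small_sim_config(seed, n = n), parts = "contacts")
    r <- b$truth$realized
    mean(abs(r$early_fraction - c(Ancient = 0.61, LUCA = 0.53,
                                  PostLUCA = 0.47)[r$temporality]))
  }
  e_small <- mean(vapply(1:3, function(s) err_at(10L, s), numeric(1)))
  e_large <- mean(vapply(1:3, function(s) err_at(160L, s), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("the minimal fixture reproduces its stored expected outputs", {
  fx <- make_minimal_fixture(registry = the_registry)
  lifted <- lift_to_uniprot(fx$contacts, fx$sifts)
  annotate_contact_groups(lifted, the_registry)
  sites <- call_sites(lifted, the_registry)
  got <- sites$residues[, c("accession", "class_name", "position", "resname",
                            "era", "ratio", "mode")]
  expect_equal(as.data.frame(got),
               as.data.frame(fx$expected$residues[, names(got), with = FALSE]))
  got_sites <- sites$sites[, c("accession", "class_name", "n_structures",
                               "n_residues", "has_metal")]
  expect_equal(as.data.frame(got_sites), as.data.frame(fx$expected$sites))
  comp <- site_composition(sites, the_registry)
  expect_equal(comp$n_early, fx$expected$composition$n_early)
  expect_equal(comp$early_pct, fx$expected$composition$early_pct)
})
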