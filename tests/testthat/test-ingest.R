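write_contacts_fixture <- function(path, contacts, sid = "1abc") {
  jsonlite::write_json(list(schema = 1, structure_id = sid, contacts = contacts),
                       path, auto_unbox = TRUE)
}

test_that("water contacts are dropped and metal partners flagged", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_contacts_fixture(tmp, list(
    list(chain = "A", resnum = 10, resname = "GLY", atom = "CA",
         ligand = "NAD", ligand_instance = "1", labels = list("hbond")),
    list(chain = "A", resnum = 501, resname = "HOH", atom = "O",
         ligand = "NAD", ligand_instance = "1", labels = list("polar")),
    list(chain = "M", resnum = 901, resname = "MG", atom = "MG",
         ligand = "NAD", ligand_instance = "1", labels = list("metal"))))
  ct <- read_contacts(tmp, the_registry)
  expect_equal(nrow(ct), 2L)
  expect_equal(unname(attr(ct, "dropped")["water"]), 1L)
  expect_equal(ct$partner_is_metal, c(FALSE, TRUE))
})

test_that("non-standard residues are flagged, malformed records counted", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_contacts_fixture(tmp, list(
    list(chain = "A", resnum = 10, resname = "MSE", atom = "SD",
         ligand = "SAM", labels = list("polar")),
    list(chain = "A", resnum = 11, resname = "ALA", atom = "CB",
         ligand = "SAM", labels = list("vdw")),
    list(chain = "A", resnum = 12)))  # malformed
  expect_warning(ct <- read_contacts(tmp, the_registry), "malformed")
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$nonstandard, c(TRUE, FALSE))
  expect_equal(unname(attr(ct, "dropped")["malformed"]), 1L)
})

test_that("contacts without a schema field or with no valid records error", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(structure_id = "1abc", contacts = list()),
                       tmp, auto_unbox = TRUE)
  expect_error(read_contacts(tmp, the_registry), "schema")
  write_contacts_fixture(tmp, list(
    list(chain = "A", resnum = 1, resname = "HOH", atom = "O",
         ligand = "NAD", labels = list("polar"))))
  expect_error(read_contacts(tmp, the_registry), "water removal")
})

test_that("both SIFTS dialects parse to the same per-residue map", {
  rng <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PDB\tCHAIN\tSP_PRIMARY\tRES_BEG\tRES_END\tPDB_BEG\tPDB_END\tSP_BEG\tSP_END",
               "1abc\tA\tP12345\t1\t3\t101\t103\t11\t13"), rng)
  m1 <- read_sifts(rng)
  per <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PDB\tCHAIN\tPDB_RES\tICODE\tSP_PRIMARY\tSP_POS",
               "1abc\tA\t101\t\tP12345\t11",
               "1abc\tA\t102\t\tP12345\t12",
               "1abc\tA\t103\t\tP12345\t13"), per)
  m2 <- read_sifts(per)
  expect_equal(m1$reskey, c("101", "102", "103"))
  expect_equal(m1$position, 11:13)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("ambiguous structure residues are removed from the map and counted", {
  per <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PDB\tCHAIN\tPDB_RES\tICODE\tSP_PRIMARY\tSP_POS",
               "1abc\tA\t101\t\tP12345\t11",
               "1abc\tA\t101\t\tQ99999\t50",
               "1abc\tA\t102\t\tP12345\t12"), per)
  m <- read_sifts(per)
  expect_equal(nrow(m), 1L)
  expect_equal(unname(attr(m, "dropped")["ambiguous"]), 1L)
})

test_that("lifting keys contacts by UniProt position across author numberings", {
  fx <- make_minimal_fixture(registry = the_registry)
  lifted <- lift_to_uniprot(fx$contacts, fx$sifts)
  pa <- lifted[lifted$accession == "PA" & !lifted$partner_is_metal, ]
  # the two structures use offsets 100 and 0 but land on the same positions
  expect_setequal(pa$position, c(12L, 40L))
  expect_equal(sort(unique(pa$structure_id)), c("1pa1", "1pa2"))
})

test_that("unmapped contacts are dropped and counted; empty map errors", {
  fx <- make_minimal_fixture(registry = the_registry)
  map <- fx$sifts[fx$sifts$structure_id != "1pb1", ]
  lifted <- lift_to_uniprot(fx$contacts, map)
  expect_equal(unname(attr(lifted, "dropped")["unmapped"]), 1L)
  expect_false("PB" %in% lifted$accession)
  expect_error(lift_to_uniprot(fx$contacts, fx$sifts[0, ]), "empty")
  expect_error(lift_to_uniprot(fx$contacts,
                               fx$sifts[fx$sifts$structure_id == "none", ]),
               "empty")
})

test_that("identical sequences cluster together; distant ones stay apart", {
  cl <- cluster_sequences(c(a = "MGGSSEQVVKKLLAA", b = "MGGSSEQVVKKLLAA",
                            c = "WWWWYYYHHHHFFFF"), 0.9)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$representative[cl$accession == "b"],
               cl$representative[cl$accession == "a"])
  # ~50% identity at threshold 0.9 -> singletons
  two <- c(x = "AAAAAAAAAAGGGGGGGGGG", y = "AAAAAAAAAACCCCCCCCCC")
  expect_equal(length(unique(cluster_sequences(two, 0.9)$cluster)), 2L)
})

test_that("short sequences warn and become singletons", {
  expect_warning(cl <- cluster_sequences(
    c(a = "MGGSSEQVVKKLLAA", b = "MGGSSEQVVKKLLAA", tiny = "GGSS"), 0.9),
    "singleton")
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$representative[cl$accession == "tiny"], "tiny")
})

test_that("mutated families cluster with their parents at 90% identity", {
  withr::local_seed(101)
  seqs <- make_families(n_fam = 10, fam_size = 5, len = 100, mut_rate = 0.05)
  cl <- cluster_sequences(seqs, 0.9)
  expect_equal(length(unique(cl$cluster)), 10L)
  # members of one family share a representative
  fam <- substr(cl$accession, 1, 3)
  expect_equal(length(unique(paste(fam, cl$cluster))), 10L)
  # agrees with the all-pairs brute-force oracle
  orc <- oracle_cluster(seqs, 0.9)
  got <- stats::setNames(cl$cluster, cl$accession)[names(orc)]
  expect_equal(unname(got), unname(orc))
})

test_that("cluster count is monotone in threshold and exact at 1.0", {
  withr::local_seed(202)
  seqs <- make_families(n_fam = 6, fam_size = 4, len = 80, mut_rate = 0.05)
  counts <- vapply(c(0.05, 0.5, 0.9, 1.0), function(t) {
    length(unique(cluster_sequences(seqs, t)$cluster))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # at 1.0, only exact duplicates co-cluster
  cl1 <- cluster_sequences(seqs, 1.0)
  for (k in unique(cl1$cluster)) {
    members <- cl1$accession[cl1$cluster == k]
    expect_equal(length(unique(seqs[members])), 1L)
  }
})
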