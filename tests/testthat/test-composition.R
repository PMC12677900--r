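fixture_sites <- function() {
  fx <- make_minimal_fixture(registry = the_registry)
  lifted <- lift_to_uniprot(fx$contacts, fx$sifts)
  annotate_contact_groups(lifted, the_registry)
  call_sites(lifted, the_registry)
}

test_that("site composition counts site residues by era", {
  sites <- fixture_sites()
  comp <- site_composition(sites, the_registry)
  expect_equal(comp$group, "Ancient")
  expect_equal(comp$n_early, 4L)
  expect_equal(comp$n_late, 1L)
  expect_equal(comp$early_pct, 80)
  expect_equal(comp$late_pct, 20)
  expect_equal(comp$early_pct + comp$late_pct, 100)
})

test_that("background composition over sequences", {
  expect_equal(background_composition(c(p = "GGDD"), the_registry)$early_pct, 100)
  bg <- background_composition(c(p = "GF"), the_registry)
  expect_equal(bg$early_pct, 50)
  expect_equal(bg$late_pct, 50)
  # non-canonical letters are excluded and counted
  expect_message(bg2 <- background_composition(c(p = "GGXX"), the_registry),
                 "non-canonical")
  expect_equal(bg2$early_pct, 100)
  expect_equal(bg2$n_noncanonical, 2L)
})

test_that("background early fraction converges at large n", {
  withr::local_seed(7)
  aa <- the_registry$amino_acids
  pool_e <- aa$one[aa$era == "early"]; pool_l <- aa$one[aa$era == "late"]
  draws <- ifelse(runif(1e5) < 0.67, sample(pool_e, 1e5, replace = TRUE),
                  sample(pool_l, 1e5, replace = TRUE))
  bg <- background_composition(c(p = paste(draws, collapse = "")), the_registry)
  expect_lt(abs(bg$early_pct - 67), 1)
})

test_that("chi-squared handles trivial and degenerate inputs", {
  res <- chi_squared(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
  gof <- chi_squared(c(30, 70), c(30, 70))
  expect_equal(gof$statistic, 0)
  expect_equal(gof$df, 1)
  expect_error(chi_squared(c(5, 5), c(0, 10)), "expected")
  low <- chi_squared(c(3, 4), c(3.5, 3.5))
  expect_true(low$low_expected)
})

test_that("chi-squared matches the direct Pearson formula on random tables", {
  withr::local_seed(13)
  for (i in 1:100) {
    k <- sample(2:3, 1)
    tab <- matrix(rpois(2 * k, lambda = 20) + 1, nrow = 2)
    expect_equal(chi_squared(tab)$statistic, oracle_chisq_stat(tab),
                 tolerance = 1e-12)
    obs <- rpois(k, 30) + 1
    exp_ <- runif(k, 5, 30)
    expect_equal(chi_squared(obs, exp_ / sum(exp_) * sum(obs))$statistic,
                 oracle_chisq_stat(obs, exp_ / sum(exp_) * sum(obs)),
                 tolerance = 1e-12)
  }
})

test_that("fractional differences are antisymmetric and sum to zero", {
  aa <- the_registry$amino_acids$three
  mk <- function(x) {
    p <- x / sum(x) * 100
    stats::setNames(p, aa)
  }
  withr::local_seed(17)
  a <- mk(runif(20)); b <- mk(runif(20))
  fd_ab <- fractional_difference(a, b, the_registry)
  fd_ba <- fractional_difference(b, a, the_registry)
  expect_equal(fd_ab$table$fd, -fd_ba$table$fd)
  expect_equal(sum(fd_ab$table$fd), 0, tolerance = 1e-9)
  same <- fractional_difference(a, a, the_registry)
  expect_true(all(same$table$fd == 0))
  expect_equal(same$mean_fd_early, 0)
  # a 10% vs 5.6% glycine frequency gives FD 4.4 percentage points
  a2 <- a; b2 <- a
  a2["GLY"] <- 10; b2["GLY"] <- 5.6
  expect_equal(
    fractional_difference(a2, b2, the_registry)$table$fd[
      the_registry$amino_acids[order(rank)]$three == "GLY"], 4.4)
  expect_error(fractional_difference(a[-1], b, the_registry), "missing")
})

test_that("phosphate-exclusion keeps only phosphate-free coenzyme classes", {
  sites <- fixture_sites()
  # fixture classes: NAD, ATP (phosphate) and SAM (phosphate-free)
  comp <- phosphate_sensitivity(sites, the_registry, "class_name")
  expect_equal(comp$group, "SAM")
  expect_equal(comp$n_early + comp$n_late, 2L)
})

test_that("background normalization follows the enrichment formula", {
  comp <- data.table::data.table(group = "Ancient", n_early = 80L, n_late = 20L,
                                 early_pct = 80, late_pct = 20)
  # equal to background -> 50/50
  n1 <- normalize_by_background(comp, list(early_pct = 80, late_pct = 20))
  expect_equal(n1$early_pct_norm, 50)
  # 80% early vs 67/33 background: (80/67)/((80/67)+(20/33))
  n2 <- normalize_by_background(comp, list(early_pct = 67, late_pct = 33))
  expect_equal(n2$early_pct_norm,
               100 * (80 / 67) / ((80 / 67) + (20 / 33)), tolerance = 1e-12)
  expect_equal(round(n2$early_pct_norm, 1), 66.3)
  # 50/50 background is the identity
  n3 <- normalize_by_background(comp, list(early_pct = 50, late_pct = 50))
  expect_equal(n3$early_pct_norm, comp$early_pct)
})

test_that("counts are conserved between site tables and composition tables", {
  est <- local({
    withr::local_seed(19)
    estimate_composition(small_sim_config(19, n = 30L))
  })
  comp <- est$composition
  expect_equal(sum(comp$n_early + comp$n_late), nrow(est$sites$residues))
  aac <- aa_composition(est$sites, the_registry)
  expect_equal(sum(aac$n), nrow(est$sites$residues))
  expect_equal(as.numeric(tapply(aac$pct, aac$group, sum)),
               rep(100, length(unique(aac$group))), tolerance = 1e-9)
})
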