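toy_pair <- function() {
  u <- paste0("gene", 1:6)
  list(r = ternary_signature(stats::setNames(c(1, 1, -1, 0, 0, -1), u), "aging"),
       z = ternary_signature(stats::setNames(c(1, -1, -1, 1, 0, 0), u), "drug"))
}

test_that("vectorized specificity and concordance match the per-gene loop oracle", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(20:500, 1)
    u <- make_universe(n)
    r <- random_ternary(u, sample.int(n %/% 3, 1), sample.int(n %/% 3, 1), "aging")
    z <- random_ternary(u, sample.int(n %/% 3, 1), sample.int(n %/% 3, 1), "drug")
    expect_identical(compute_specificity(r, z), oracle_specificity(r, z))
    got <- compute_concordance(r, z)
    ora <- oracle_concordance(r, z)
    expect_identical(got$n_concordant, ora$n_concordant)
    expect_identical(got$n_discordant, ora$n_discordant)
    expect_identical(got$adj_cr, ora$adj_cr)
  }
})

test_that("degenerate specificity and concordance cases behave as defined", {
  u <- make_universe(8)
  r <- ternary_signature(stats::setNames(c(1, 1, -1, -1, 0, 0, 0, 0), u), "aging")
  z_same <- ternary_signature(r$values, "drug")
  expect_equal(compute_specificity(r, z_same), 1)
  conc <- compute_concordance(r, z_same)
  expect_equal(conc$n_concordant, 4L)
  expect_equal(conc$n_discordant, 0L)
  expect_true(conc$cr_infinite)
  expect_equal(conc$cr, Inf)
  expect_equal(conc$adj_cr, 5)
  z_flip <- ternary_signature(-r$values, "drug")
  expect_equal(compute_concordance(r, z_flip)$adj_cr, 1 / 5)
  z_zero <- ternary_signature(stats::setNames(integer(8), u), "drug")
  expect_equal(compute_specificity(r, z_zero), 0)
  r_zero <- ternary_signature(stats::setNames(integer(8), u), "aging")
  expect_error(compute_specificity(r_zero, z_same), "nonzero")
  r_other <- ternary_signature(stats::setNames(c(1, rep(0, 7)), make_universe(9)[-1]), "aging")
  expect_error(compute_specificity(r_other, z_same), "universe")
})

test_that("sign-flip duality: adjCR(-z, r) = (n_disc+1)/(n_conc+1)", {
  set.seed(22)
  u <- make_universe(300)
  for (i in 1:10) {
    r <- random_ternary(u, 40, 40, "aging")
    z <- random_ternary(u, 60, 30, "drug")
    a <- compute_concordance(r, z)
    b <- compute_concordance(r, ternary_signature(-z$values, "drug"))
    expect_equal(b$adj_cr, (a$n_discordant + 1) / (a$n_concordant + 1))
  }
})

test_that("S and CR are invariant under a joint permutation of gene order", {
  set.seed(23)
  u <- make_universe(200)
  r <- random_ternary(u, 30, 30, "aging")
  z <- random_ternary(u, 50, 20, "drug")
  perm <- sample(u)
  rp <- ternary_signature(r$values[perm], "aging")
  zp <- ternary_signature(z$values[perm], "drug")
  expect_equal(compute_specificity(rp, zp), compute_specificity(r, z))
  expect_equal(compute_concordance(rp, zp)$adj_cr, compute_concordance(r, z)$adj_cr)
})

test_that("the hypergeometric null engine matches explicit label shuffling", {
  set.seed(24)
  u <- make_universe(400)
  r <- random_ternary(u, 60, 50, "aging")
  z <- random_ternary(u, 70, 40, "drug")
  fit <- permutation_test(r, z, n_perm = 4000, seed = 99)
  ora <- oracle_perm_null(r, z, 4000, seed = 123)
  # same null distribution: mean and sd agree within Monte Carlo error
  se_mean <- sd(ora) / sqrt(length(ora))
  expect_lt(abs(fit$null_mean - mean(ora)), 5 * se_mean)
  expect_lt(abs(fit$null_sd - sd(ora)) / sd(ora), 0.15)
  expect_gt(suppressWarnings(ks.test(fit$perm_values, ora))$p.value, 0.001)
})

test_that("permutation test is bit-reproducible and stable in n_perm", {
  set.seed(25)
  u <- make_universe(500)
  r <- random_ternary(u, 50, 50, "aging")
  z <- random_ternary(u, 80, 40, "drug")
  a <- permutation_test(r, z, n_perm = 1000, seed = 7)
  b <- permutation_test(r, z, n_perm = 1000, seed = 7)
  expect_identical(a$perm_values, b$perm_values)
  expect_identical(a$p_value, b$p_value)
  big <- permutation_test(r, z, n_perm = 2000, seed = 7)
  sd_phat <- sqrt(max(a$p_value, 1e-3) * (1 - max(a$p_value, 1e-3)) / 1000)
  expect_lt(abs(big$p_value - a$p_value), max(3 * sd_phat, 0.05))
})

test_that("fully concordant signatures are highly significant", {
  set.seed(26)
  u <- make_universe(2000)
  r <- random_ternary(u, 100, 100, "aging")
  z <- ternary_signature(r$values, "drug")
  fit <- permutation_test(r, z, n_perm = 1000, seed = 5)
  expect_lt(fit$p_value, 0.01)
  expect_gt(fit$obs_adj_cr, fit$null_mean)
})

test_that("a degenerate null (sd = 0) warns and returns p = 1", {
  u <- make_universe(6)
  r <- ternary_signature(stats::setNames(rep(1L, 6), u), "aging")
  z <- ternary_signature(stats::setNames(rep(1L, 6), u), "drug")
  expect_warning(fit <- permutation_test(r, z, n_perm = 200, seed = 1),
                 "degenerate")
  expect_equal(fit$p_value, 1)
})

test_that("score_all_pairs crosses drugs with matched tissues only", {
  set.seed(27)
  u <- make_universe(300)
  aging <- list(muscle = random_ternary(u, 30, 30, "aging"),
                kidney = random_ternary(u, 30, 30, "aging"),
                cortex = random_ternary(u, 30, 30, "aging"))
  drugs <- list("dasatinib::SKL" = random_ternary(u, 40, 40, "drug"),
                "doxorubicin::SKL" = random_ternary(u, 40, 40, "drug"),
                "orphan::XXX" = random_ternary(u, 40, 40, "drug"))
  map <- data.frame(cell_line = c("SKL", "SKL", "SKL"),
                    tissue = c("muscle", "kidney", "cortex"))
  recs <- suppressMessages(score_all_pairs(aging, drugs, map, n_perm = 200, seed = 3))
  expect_length(recs, 6L)
  expect_setequal(unique(vapply(recs, `[[`, "", "drug")),
                  c("dasatinib", "doxorubicin"))
  expect_error(suppressMessages(
    score_all_pairs(aging, drugs["orphan::XXX"], map, n_perm = 200, seed = 3)),
    "no \\(drug, tissue\\) pairs")
  expect_error(score_all_pairs(aging, drugs, map[0, ], n_perm = 200), "empty")
})

test_that("planted S and concordance are recovered exactly from truth signatures", {
  gid <- make_universe(1000)
  r <- truth_signature(gid[1:100], gid[101:200], gid, "aging")
  z <- truth_signature(gid[1:60], gid[101:140], gid, "drug")
  expect_equal(compute_specificity(r, z), 100 / 200, tolerance = 1e-12)
  conc <- compute_concordance(r, z)
  expect_identical(conc$n_concordant, 100L)
  expect_identical(conc$n_discordant, 0L)
  expect_equal(conc$adj_cr, 101, tolerance = 1e-12)
})

test_that("event calling applies the S, adjCR dead zone and p thresholds", {
  mk <- function(s, adj_cr, p) structure(list(
    drug = "d", cell_line = "c", tissue = "t", s = s,
    n_concordant = 10L, n_discordant = 2L, cr = 5, cr_infinite = FALSE,
    adj_cr = adj_cr, p_value = p, null_mean = 1, null_sd = 0.1,
    quadrants = list(), call = NA_character_), class = "InteractionRecord")
  recs <- list(mk(0.60, 2.2, 1e-4),   # accelerating
               mk(0.60, 1.05, 1e-4),  # dead zone
               mk(0.40, 2.2, 1e-4),   # specificity fails
               mk(0.60, 0.5, 1e-4),   # protective
               mk(0.60, 2.2, 0.5))    # p fails
  out <- suppressMessages(call_significant(recs))
  expect_equal(out$table$call,
               c("accelerating", "none", "none", "protective", "none"))
  expect_equal(nrow(out$edges), 2L)
  expect_true(all(out$table$p_bh >= out$table$p_value))
})

test_that("calling is monotone when thresholds are relaxed", {
  set.seed(28)
  u <- make_universe(800)
  aging <- list(t1 = random_ternary(u, 80, 80, "aging"))
  drugs <- list("d1::c1" = random_ternary(u, 100, 100, "drug"),
                "d2::c1" = random_ternary(u, 100, 100, "drug"))
  map <- data.frame(cell_line = "c1", tissue = "t1")
  recs <- suppressMessages(score_all_pairs(aging, drugs, map, n_perm = 500, seed = 4))
  strict <- suppressMessages(call_significant(recs, s_min = 0.45,
                                              cr_lo = 0.9, cr_hi = 1.1, p_max = 0.01))
  loose <- suppressMessages(call_significant(recs, s_min = 0.45,
                                             cr_lo = 0.95, cr_hi = 1.05, p_max = 0.2))
  called_strict <- strict$table$call != "none"
  called_loose <- loose$table$call != "none"
  expect_true(all(called_loose[called_strict]))
})
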