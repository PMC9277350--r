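make_expr <- function(values, ages, tissue = "muscle") {
  sm <- sprintf("S%02d", seq_along(ages))
  colnames(values) <- sm
  list(expr = expression_matrix(values),
       ann = sample_annotation(sm, ages, rep(tissue, length(ages))))
}

test_that("monotone, antitone and constant genes give rho 1, -1 and 0", {
  ages <- seq(21, 66, by = 5)
  vals <- rbind(up = seq_along(ages),
                down = rev(seq_along(ages)),
                flat = rep(3, length(ages)))
  rownames(vals) <- c("up", "down", "flat")
  ex <- make_expr(vals, ages)
  ct <- spearman_age_correlation(ex$expr, ex$ann)
  expect_equal(ct$rho[ct$gene == "up"], 1)
  expect_equal(ct$rho[ct$gene == "down"], -1)
  expect_equal(ct$rho[ct$gene == "flat"], 0)
  expect_equal(ct$p_value[ct$gene == "flat"], 1)
  expect_equal(unique(ct$n), length(ages))
})

test_that("rho and p match cor.test's t-approximation on random data", {
  set.seed(42)
  ages <- runif(30, 20, 71)
  vals <- matrix(rnorm(20 * 30), 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  ex <- make_expr(vals, ages)
  ct <- spearman_age_correlation(ex$expr, ex$ann)
  for (i in c(1, 7, 20)) {
    ref <- cor.test(vals[i, ], ages, method = "spearman", exact = FALSE)
    expect_equal(ct$rho[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ct$p_value[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("negating all expression values negates every rho exactly", {
  set.seed(7)
  ages <- runif(25, 20, 71)
  vals <- matrix(rnorm(15 * 25), 15, dimnames = list(sprintf("g%02d", 1:15), NULL))
  ex1 <- make_expr(vals, ages)
  ex2 <- make_expr(-vals, ages)
  expect_equal(spearman_age_correlation(ex1$expr, ex1$ann)$rho,
               -spearman_age_correlation(ex2$expr, ex2$ann)$rho)
})

test_that("too few samples or constant age are hard errors", {
  ex <- make_expr(matrix(1:2, 1, dimnames = list("g1", NULL)), c(30, 40))
  expect_error(spearman_age_correlation(ex$expr, ex$ann), "3 samples")
  ex2 <- make_expr(matrix(1:4, 1, dimnames = list("g1", NULL)), rep(50, 4))
  expect_error(spearman_age_correlation(ex2$expr, ex2$ann), "constant age")
})

test_that("primary selection rule counts match a direct filter", {
  set.seed(1)
  n <- 2000
  corr <- data.frame(gene = sprintf("g%04d", 1:n),
                     rho = runif(n, -0.6, 0.6),
                     p_value = runif(n), n = 100)
  sig <- build_aging_signature(corr, min_total = 1)
  expect_equal(sig$n_pos, sum(corr$rho > 0.2 & corr$p_value < 0.05))
  expect_equal(sig$n_neg, sum(corr$rho < -0.2 & corr$p_value < 0.05))
  expect_false(attr(sig, "fallback"))
  picked <- names(sig$values)[sig$values == 1L]
  expect_setequal(picked, corr$gene[corr$rho > 0.2 & corr$p_value < 0.05])
})

test_that("sparse primary selection falls back to exactly 500+500 genes", {
  set.seed(2)
  n <- 5000
  corr <- data.frame(gene = sprintf("g%04d", 1:n),
                     rho = runif(n, -0.1, 0.1),  # nothing passes |rho| > 0.2
                     p_value = runif(n), n = 50)
  sig <- suppressMessages(build_aging_signature(corr, min_total = 1000))
  expect_true(attr(sig, "fallback"))
  expect_equal(sig$n_pos, 500L)
  expect_equal(sig$n_neg, 500L)
  # fallback ranks by rho: the +1 genes are exactly the top 500 by rho
  top <- corr$gene[order(-corr$rho, corr$gene)][1:500]
  expect_setequal(names(sig$values)[sig$values == 1L], top)
})

test_that("all-zero rho falls back with deterministic lexicographic ties", {
  n <- 1200
  corr <- data.frame(gene = sprintf("g%04d", n:1),  # shuffled-ish input order
                     rho = 0, p_value = 1, n = 10)
  sig <- suppressMessages(build_aging_signature(corr, fallback_k = 500, min_total = 10))
  expect_equal(sig$n_pos, 500L)
  expect_equal(sig$n_neg, 500L)
  pos <- sort(names(sig$values)[sig$values == 1L])
  expect_equal(pos, sort(sprintf("g%04d", 1:n))[1:500])
})

test_that("fallback on a too-small universe errors with guidance", {
  corr <- data.frame(gene = sprintf("g%03d", 1:600), rho = 0, p_value = 1, n = 10)
  expect_error(build_aging_signature(corr, min_total = 10), "fallback_k")
})

test_that("an age-unrelated gene does not change other genes' membership", {
  set.seed(3)
  corr <- data.frame(gene = sprintf("g%03d", 1:300),
                     rho = runif(300, -0.5, 0.5), p_value = runif(300), n = 80)
  before <- build_aging_signature(corr, min_total = 1)
  corr2 <- rbind(corr, data.frame(gene = "null_gene", rho = 0.001,
                                  p_value = 0.99, n = 80))
  after <- build_aging_signature(corr2, min_total = 1)
  expect_equal(before$values[corr$gene], after$values[corr$gene])
  expect_equal(unname(after$values["null_gene"]), 0L)
})

test_that("planted rho 0.4 genes are recovered and nulls obey the p_cut rate", {
  sim <- simulate_expression(n_genes = 2000, n_samples = 200,
                             n_pos = 100, n_neg = 100,
                             effect = effect_for_rho(0.4), noise_sd = 1,
                             seed = 101)
  ct <- spearman_age_correlation(sim$expr, sim$annotation)
  sig <- build_aging_signature(ct, min_total = 1)
  planted <- c(sim$truth$pos_genes, sim$truth$neg_genes)
  sens <- (sum(sig$values[sim$truth$pos_genes] == 1L) +
           sum(sig$values[sim$truth$neg_genes] == -1L)) / length(planted)
  expect_gte(sens, 0.95)
  # null genes pass only via |rho|>0.2 AND p<0.05; at n=200 the rho cut is
  # the binding constraint: P(|rho| > 0.2) = 2*(1 - pnorm(0.2*sqrt(199)))
  nulls <- setdiff(sim$expr$gene_ids, planted)
  fp <- mean(sig$values[nulls] != 0L)
  p_fp <- 2 * (1 - pnorm(0.2 * sqrt(197)))
  bound <- qbinom(0.995, length(nulls), p_fp) / length(nulls)
  expect_lte(fp, bound)
})

test_that("ranked-list export orders by rho with lexicographic ties", {
  dir <- withr::local_tempdir()
  corr <- data.frame(gene = c("G1", "G2", "G3", "A2", "A1"),
                     rho = c(0.5, -0.2, 0.9, 0.5, 0.5),
                     p_value = 0.5, n = 10)
  path <- file.path(dir, "out.rnk")
  export_ranked_list(corr, path)
  got <- utils::read.delim(path, header = FALSE)
  expect_equal(got$V1, c("G3", "A1", "A2", "G1", "G2"))
  expect_error(export_ranked_list(corr[0, ], path), "empty")
})
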