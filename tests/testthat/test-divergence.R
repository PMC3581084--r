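fake_dm <- function(labels, values, model = "p") {
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, model = model, values = values,
                 n_undefined = 0), class = "dist_matrix")
}

fake_corpus <- function(ids, genus, species) {
  new_corpus(data.frame(record_id = ids, genus = genus, species = species,
                        sequence = strrep("A", 50), stringsAsFactors = FALSE))
}

test_that("intraspecific components match brute-force pair enumeration", {
  ids <- c("a1", "a2", "a3", "b1", "b2")
  v <- matrix(0, 5, 5)
  v[1, 2] <- v[2, 1] <- 0.01
  v[1, 3] <- v[3, 1] <- 0.02
  v[2, 3] <- v[3, 2] <- 0.03
  v[4, 5] <- v[5, 4] <- 0.04
  cp <- fake_corpus(ids, "Aus", c("alba", "alba", "alba", "rubra", "rubra"))
  res <- intraspecific_summary(fake_dm(ids, v), cp)
  expect_equal(res$components$mean,
               c(mean(c(0.02, 0.04)),      # avg of per-species means
                 mean(c(0.03, 0.04)),      # avg of per-species maxima
                 mean(c(0.01, 0.02, 0.03, 0.04))))  # pooled
  expect_equal(res$n_species_used, 2)
  # one species with a single pair: all three components equal it
  one <- intraspecific_summary(fake_dm(ids[4:5],
                                       matrix(c(0, 0.04, 0.04, 0), 2)),
                               fake_corpus(ids[4:5], "Aus", "rubra"))
  expect_equal(one$components$mean, rep(0.04, 3))
  # all identical sequences: all components zero
  zero <- intraspecific_summary(fake_dm(ids, matrix(0, 5, 5)), cp)
  expect_equal(zero$components$mean, rep(0, 3))
})

test_that("interspecific components match brute-force pair enumeration", {
  ids <- c("a1", "b1", "c1")
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.10
  v[1, 3] <- v[3, 1] <- 0.12
  v[2, 3] <- v[3, 2] <- 0.20
  cp <- fake_corpus(ids, "Aus", c("alba", "rubra", "nigra"))
  res <- interspecific_summary(fake_dm(ids, v), cp)
  expect_equal(res$components$mean[1], mean(c(0.10, 0.12, 0.20)))
  expect_equal(res$components$mean[2], mean(c(0.10, 0.10, 0.12)),
               tolerance = 1e-12)
  expect_equal(res$components$mean[3], mean(c(0.10, 0.12, 0.20)))
  expect_equal(res$n_genera_used, 1)
})

test_that("cross-genus pairs never enter the congeneric summaries", {
  ids <- c("a1", "b1", "x1", "x2")
  v <- matrix(0.9, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.10
  v[3, 4] <- v[4, 3] <- 0.30
  cp <- fake_corpus(ids, c("Aus", "Aus", "Zus", "Zus"),
                    c("alba", "rubra", "una", "dua"))
  res <- interspecific_summary(fake_dm(ids, v), cp)
  expect_equal(res$components$mean[3], mean(c(0.10, 0.30)))
  # adding an unrelated genus leaves the other genus' pooled values alone
  res1 <- interspecific_summary(fake_dm(ids[1:2], v[1:2, 1:2]), cp[1:2, ])
  expect_equal(res1$components$mean[3], 0.10)
})

test_that("errors are raised when no unit qualifies", {
  ids <- c("a1", "b1")
  cp <- fake_corpus(ids, c("Aus", "Bus"), c("alba", "nigra"))
  dm <- fake_dm(ids, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_error(intraspecific_summary(dm, cp), ">= 2")
  expect_error(interspecific_summary(dm, cp), ">= 2")
})

test_that("pooled means are pair-count-weighted averages of unit means", {
  set.seed(211)
  cp <- random_small_corpus(n_species = 6, max_samples = 4, dup_prob = 0)
  dm <- distance_matrix(cp, model = "p")
  res_w <- intraspecific_summary(dm, cp, weighted = TRUE)
  expect_equal(res_w$components$mean[1], res_w$components$mean[3],
               tolerance = 1e-12)
  rei_w <- interspecific_summary(dm, cp, weighted = TRUE)
  expect_equal(rei_w$components$mean[1], rei_w$components$mean[3],
               tolerance = 1e-12)
})

test_that("barcode gap appears whenever d_intra < d_inter", {
  for (seed in c(3, 5)) {
    cfg <- simulation_config(n_genera = 5, species_per_genus = 3,
                             samples_per_species = 2,
                             d_intra = 0.008, d_inter = 0.06, seed = seed)
    s <- simulate_corpus(cfg)
    its2 <- excise_true_region(s$corpus, s$truth, "ITS2")
    dm <- distance_matrix(its2, model = "p")
    ds <- divergence_summary(dm, its2)
    cm <- setNames(ds$components$mean, ds$components$parameter)
    expect_lt(cm["avg_intra_avg"], cm["avg_interbyG_avg"])
    expect_lte(cm["avg_intra_avg"], cm["avg_intra_max"])
    expect_lte(cm["avg_interbyG_min"], cm["avg_interbyG_avg"])
  }
})

test_that("wilcoxon signed rank reproduces hand counts and the rank-sum identity", {
  r1 <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r1$w_plus, 6)
  expect_equal(r1$w_minus, 0)
  expect_identical(r1$direction, "A_GT_B")

  r2 <- wilcoxon_signed_rank(c(1, -2, 3), c(0, 0, 0))
  expect_equal(r2$w_plus, 4)
  expect_equal(r2$w_minus, 2)
  orc <- oracle_wilcoxon_enum(c(1, -2, 3), c(0, 0, 0))
  expect_equal(r2$p_value, orc$p)

  set.seed(223)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    a <- sample(-5:5, n, replace = TRUE)
    b <- sample(-5:5, n, replace = TRUE)
    r <- wilcoxon_signed_rank(a, b)
    expect_equal(r$w_plus + r$w_minus, r$n * (r$n + 1) / 2)
  }
})

test_that("exact p-values match stats::wilcox.test on tie-free data", {
  set.seed(227)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(mine$w_plus, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample p-values match the tie-corrected normal approximation", {
  set.seed(229)
  for (i in 1:10) {
    n <- 60
    a <- sample(0:6, n, replace = TRUE)
    b <- sample(0:6, n, replace = TRUE)
    keep <- a != b
    if (sum(keep) <= 25) next
    mine <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                        correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate paired input gives p = 1 and no direction", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  expect_identical(r$direction, "NONE")
  expect_equal(r$n, 0L)
})

test_that("compare_loci detects a uniform shift and identical loci", {
  set.seed(233)
  cp <- random_small_corpus(n_species = 5, max_samples = 3, dup_prob = 0)
  dm1 <- distance_matrix(cp, model = "p")
  dm2 <- dm1
  dm2$values <- dm1$values + 0.01
  diag(dm2$values) <- 0
  res <- compare_loci(dm1, dm2, cp)
  expect_identical(res$inter$direction, "B_GT_A")
  expect_equal(res$inter$w_plus, 0)
  expect_identical(res$intra$direction, "B_GT_A")

  same <- compare_loci(dm1, dm1, cp)
  expect_equal(same$inter$p_value, 1)
  expect_identical(same$inter$direction, "NONE")
})
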