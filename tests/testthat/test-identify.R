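seq_with_diffs <- function(base, k, at = seq_len(k)) {
  # substitute k sites with transversions so distances are exact ratios
  x <- strsplit(base, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  x[at] <- swap[x[at]]
  paste(x, collapse = "")
}

tie_corpus <- function() {
  base <- strrep("ACGT", 25)   # 100 nt
  new_corpus(data.frame(
    record_id = c("q", "r1", "r2", "far"),
    genus = c("Aus", "Aus", "Aus", "Bus"),
    species = c("alba", "rubra", "nigra", "zeta"),
    sequence = c(base, base, base, seq_with_diffs(base, 40)),
    stringsAsFactors = FALSE))
}

test_that("best hit resolves correct, tied-ambiguous and congener cases", {
  cp <- tie_corpus()
  # two equally perfect references from different congeneric species
  amb <- best_hit_identify("q", cp)
  expect_identical(amb$category, "AMBIGUOUS")
  expect_identical(best_hit_identify("q", cp, rank = "genus")$category,
                   "CORRECT")

  # unique conspecific top hit
  cp2 <- new_corpus(data.frame(
    record_id = c("q", "same", "other"),
    genus = "Aus", species = c("alba", "alba", "rubra"),
    sequence = c(strrep("ACGT", 25), strrep("ACGT", 25),
                 seq_with_diffs(strrep("ACGT", 25), 30)),
    stringsAsFactors = FALSE))
  expect_identical(best_hit_identify("q", cp2)$category, "CORRECT")

  # top hit is a congener of another species
  cp3 <- cp2
  cp3$species <- c("alba", "rubra", "rubra")
  class(cp3) <- class(cp2)
  expect_identical(best_hit_identify("q", cp3)$category, "INCORRECT")
  expect_identical(best_hit_identify("q", cp3, rank = "genus")$category,
                   "CORRECT")
})

test_that("best match follows the nearest neighbour and flags ties", {
  base <- strrep("TGCA", 30)
  cp <- new_corpus(data.frame(
    record_id = c("q", "near", "far"),
    genus = "Aus", species = c("alba", "alba", "rubra"),
    sequence = c(base, seq_with_diffs(base, 1), seq_with_diffs(base, 20)),
    stringsAsFactors = FALSE))
  dm <- distance_matrix(cp, model = "p")
  r <- best_match_identify("q", cp, dm)
  expect_identical(r$category, "CORRECT")
  expect_equal(r$best_distance_or_score, 1 / 120)

  cpt <- tie_corpus()
  rt <- best_match_identify("q", cpt, distance_matrix(cpt, model = "p"))
  expect_identical(rt$category, "AMBIGUOUS")
})

test_that("singleton-species queries can never be CORRECT under best match", {
  set.seed(307)
  for (i in 1:5) {
    cp <- random_small_corpus(n_species = 5, max_samples = 3)
    dm <- distance_matrix(cp, model = "p")
    res <- identify_corpus(cp, "BEST_MATCH", "species", dm = dm)
    pq <- res$per_query
    expect_false(any(pq$category[pq$singleton] == "CORRECT"))
  }
  # all-singleton corpus: correct rate exactly 0
  cp1 <- new_corpus(data.frame(
    record_id = c("a", "b", "c"),
    genus = "Aus", species = c("s1", "s2", "s3"),
    sequence = c(strrep("ACGT", 30), seq_with_diffs(strrep("ACGT", 30), 5),
                 seq_with_diffs(strrep("ACGT", 30), 10)),
    stringsAsFactors = FALSE))
  res1 <- identify_corpus(cp1, "BEST_MATCH", "species")
  expect_equal(res1$report$pct_correct, 0)
})

test_that("best close match applies the inclusive 3% gate", {
  base <- strrep("GATC", 25)     # 100 nt
  mk <- function(k) seq_with_diffs(base, k)
  cp <- new_corpus(data.frame(
    record_id = c("q", "r"),
    genus = "Aus", species = c("alba", "alba"),
    sequence = c(base, mk(5)),   # 5% away
    stringsAsFactors = FALSE))
  dm <- distance_matrix(cp, model = "p")
  r <- best_close_match_identify("q", cp, dm, threshold = 0.03)
  expect_identical(r$category, "NO_MATCH")

  cp$sequence[2] <- mk(1)        # 1% away
  class(cp) <- c("barcode_corpus", "data.frame")
  r2 <- best_close_match_identify("q", cp, distance_matrix(cp, "p"),
                                  threshold = 0.03)
  expect_identical(r2$category, "CORRECT")

  cp$sequence[2] <- mk(3)        # exactly 3%: inclusive boundary
  class(cp) <- c("barcode_corpus", "data.frame")
  r3 <- best_close_match_identify("q", cp, distance_matrix(cp, "p"),
                                  threshold = 0.03)
  expect_identical(r3$category, "CORRECT")
})

test_that("best close match converges to best match as the threshold grows", {
  set.seed(311)
  for (i in 1:5) {
    cp <- random_small_corpus(n_species = 5, max_samples = 3)
    dm <- distance_matrix(cp, model = "p")
    bm <- identify_corpus(cp, "BEST_MATCH", "species", dm = dm)$per_query
    bcm <- identify_corpus(cp, "BEST_CLOSE_MATCH", "species", dm = dm,
                           threshold = 0.999)$per_query
    expect_identical(bcm$category, bm$category)
  }
})

test_that("raising the threshold never increases the NO_MATCH count", {
  set.seed(313)
  cp <- random_small_corpus(n_species = 6, max_samples = 3)
  dm <- distance_matrix(cp, model = "p")
  nn <- vapply(c(0.01, 0.05, 0.2, 0.8), function(th) {
    pq <- identify_corpus(cp, "BEST_CLOSE_MATCH", "species", dm = dm,
                          threshold = th)$per_query
    sum(pq$category == "NO_MATCH")
  }, 0)
  expect_true(all(diff(nn) <= 0))
})

test_that("report percentages always partition the queries", {
  set.seed(317)
  for (crit in c("BEST_HIT", "BEST_MATCH", "BEST_CLOSE_MATCH")) {
    cp <- random_small_corpus(n_species = 5, max_samples = 3)
    res <- identify_corpus(cp, crit, "species")
    r <- res$report
    expect_equal(r$pct_correct + r$pct_ambiguous + r$pct_incorrect +
                   r$pct_no_match, 100, tolerance = 0.1)
    expect_equal(r$n_queries, nrow(cp))
  }
})

test_that("genus-rank accuracy dominates species-rank accuracy for best hit", {
  set.seed(331)
  for (i in 1:5) {
    cp <- random_small_corpus(n_species = 5, max_samples = 3)
    sp <- identify_corpus(cp, "BEST_HIT", "species")$report$pct_correct
    ge <- identify_corpus(cp, "BEST_HIT", "genus")$report$pct_correct
    expect_gte(ge, sp)
  }
})

test_that("per-genus report computes the unidentified percentage", {
  pq <- data.frame(
    query_id = sprintf("q%02d", 1:24),
    genus = c(rep("Gunnera", 20), rep("Tiny", 4)),
    species = c(sprintf("sp%02d", 1:20), sprintf("t%d", 1:4)),
    category = c(rep("CORRECT", 19), "INCORRECT", rep("CORRECT", 4)),
    stringsAsFactors = FALSE)
  rep20 <- per_genus_report(pq, min_species = 20)
  expect_equal(nrow(rep20), 1)
  expect_identical(rep20$genus, "Gunnera")
  expect_equal(rep20$n_samples, 20)
  expect_equal(rep20$pct_unidentified, 5.00)
  # genus below the species cut-off is excluded
  expect_false("Tiny" %in% rep20$genus)
  rep1 <- per_genus_report(pq, min_species = 1)
  expect_equal(rep1$pct_unidentified[rep1$genus == "Tiny"], 0.00)
})
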