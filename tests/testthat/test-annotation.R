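ref12 <- function(x) paste(rep(x, 3), collapse = "")  # "ACGT" -> 12-mer

test_that("profile emissions follow the pseudocount closed forms", {
  # identical references, pseudocount 0: observed base has probability 1,
  # log-odds log2(1/0.25) = 2 bits
  p0 <- build_profile(c(ref12("ACGT"), ref12("ACGT")), pseudocount = 0)
  expect_equal(p0$length, 12)
  expect_equal(unname(p0$logodds[1, "A"]), 2)
  expect_equal(unname(p0$logodds[2, "C"]), 2)
  expect_true(all(is.infinite(p0$logodds[1, c("C", "G", "T")])))

  # references differing at one column: {T, A} split -> 0.5 -> 1 bit each
  pa <- build_profile(c(ref12("ACGT"), ref12("ACGA")), pseudocount = 0)
  expect_equal(unname(pa$logodds[4, "T"]), 1)
  expect_equal(unname(pa$logodds[4, "A"]), 1)

  # Laplace pseudocount 1 with 2 references: unseen base (0+1)/(2+4) = 1/6
  p1 <- build_profile(c(ref12("ACGT"), ref12("ACGT")), pseudocount = 1)
  expect_equal(unname(p1$logodds[1, "C"]), log2((1 / 6) / 0.25))
  expect_equal(unname(p1$logodds[1, "A"]), log2((3 / 6) / 0.25))
})

test_that("majority-gap columns are dropped from the match states", {
  refs <- c("ACGTACGTACGTA", "ACGT-CGTACGTA", "ACGT-CGTACGTA")
  p <- build_profile(refs, pseudocount = 1)
  expect_equal(p$length, 12)
  expect_error(build_profile(c("ACGT", "ACGTA")), "equal length")
  expect_error(build_profile("ACGTACGTACGT"), ">= 2")
})

test_that("profile TSV serialization round-trips", {
  p <- build_profile(c(ref12("ACGT"), ref12("ACGA")), pseudocount = 1)
  f <- tempfile(fileext = ".tsv")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$logodds, p$logodds, ignore_attr = TRUE)
})

test_that("planted motifs are recovered exactly at zero conserved noise", {
  cfg <- simulation_config(n_genera = 3, species_per_genus = 2,
                           samples_per_species = 2,
                           d_intra = 0.01, d_inter = 0.05,
                           conserved_rate_5_8s = 0, seed = 17)
  s <- simulate_corpus(cfg)
  ac <- annotate_corpus(s$corpus, reference_profiles())
  expect_true(all(ac$annotation$status == "OK"))
  b <- s$truth$boundaries[match(ac$annotation$record_id,
                                s$truth$boundaries$record_id), ]
  expect_equal(ac$annotation$its1_start, b$its1_start)
  expect_equal(ac$annotation$its1_end, b$its1_end)
  expect_equal(ac$annotation$r5_8s_end, b$r5_8s_end)
  expect_equal(ac$annotation$its2_end, b$its2_end)
  # excised corpus equals the truth excision
  its2 <- excise_true_region(s$corpus, s$truth, "ITS2")
  expect_identical(ac$corpus$sequence, its2$sequence)
})

test_that("a motif-free sequence is reported NO_5_8S and excluded", {
  set.seed(31)
  pr <- reference_profiles()
  rnd <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  a <- annotate(rnd, pr$r5_8s, pr$flank_28s)
  expect_identical(a$status, "NO_5_8S")

  cfg <- simulation_config(n_genera = 2, species_per_genus = 2,
                           samples_per_species = 1, seed = 23)
  s <- simulate_corpus(cfg)
  cp <- s$corpus
  cp$sequence[1] <- rnd
  ac <- annotate_corpus(cp, pr)
  expect_false(cp$record_id[1] %in% ac$corpus$record_id)
  expect_identical(ac$annotation$status[1], "NO_5_8S")
  expect_equal(nrow(ac$annotation), nrow(cp))
})

test_that("truncated records (no 28S flank) keep ITS2 to the sequence end", {
  cfg <- simulation_config(n_genera = 1, species_per_genus = 2,
                           samples_per_species = 1, seed = 29)
  s <- simulate_corpus(cfg)
  b <- s$truth$boundaries
  trunc <- substr(s$corpus$sequence[1], 1, b$its2_end[1] - 10)
  pr <- reference_profiles()
  a <- annotate(trunc, pr$r5_8s, pr$flank_28s)
  expect_identical(a$status, "TRUNCATED")
  expect_equal(a$its2_end, nchar(trunc))
  expect_equal(a$r5_8s_end, b$r5_8s_end[1])
})

test_that("reverse-complemented records are flipped before annotation", {
  cfg <- simulation_config(n_genera = 1, species_per_genus = 2,
                           samples_per_species = 1, seed = 37)
  s <- simulate_corpus(cfg)
  pr <- reference_profiles()
  fwd <- annotate(s$corpus$sequence[1], pr$r5_8s, pr$flank_28s,
                  pr$flank_18s)
  rc <- annotate(revcomp(s$corpus$sequence[1]), pr$r5_8s, pr$flank_28s,
                 pr$flank_18s)
  expect_identical(rc$strand, "-")
  expect_equal(rc[, c("its1_start", "its1_end", "r5_8s_end", "its2_end")],
               fwd[, c("its1_start", "its1_end", "r5_8s_end", "its2_end")])
})

test_that("placement score is invariant under motif-free flank extension", {
  set.seed(41)
  pr <- reference_profiles()
  core <- reference_motifs()[["r5_8s"]]
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  scores <- vapply(c(20, 120, 400), function(n) {
    annotate(paste0(pad(n), core, pad(n)), pr$r5_8s, pr$flank_28s)$score_5_8s
  }, 0)
  expect_equal(scores[1], scores[2])
  expect_equal(scores[1], scores[3])
})

test_that("annotating a pre-excised ITS2 with planted flanks reproduces it", {
  cfg <- simulation_config(n_genera = 2, species_per_genus = 2,
                           samples_per_species = 1, seed = 43)
  s <- simulate_corpus(cfg)
  its2 <- excise_true_region(s$corpus, s$truth, "ITS2")
  m <- reference_motifs()
  planted <- its2
  planted$sequence <- paste0(m[["r5_8s"]], its2$sequence, m[["flank_28s"]])
  ac <- annotate_corpus(planted, reference_profiles())
  expect_identical(ac$corpus$sequence, its2$sequence)
})

test_that("boundary recovery degrades monotonically with conserved-site noise", {
  recov <- vapply(c(0.005, 0.02, 0.08), function(rate) {
    cfg <- simulation_config(n_genera = 4, species_per_genus = 2,
                             samples_per_species = 2,
                             d_intra = max(rate, 0.01), d_inter = 0.30,
                             conserved_rate_5_8s = rate, seed = 47)
    s <- simulate_corpus(cfg)
    ac <- annotate_corpus(s$corpus, reference_profiles())
    b <- s$truth$boundaries[match(ac$annotation$record_id,
                                  s$truth$boundaries$record_id), ]
    ok <- ac$annotation$status == "OK" &
      abs(ac$annotation$r5_8s_end - b$r5_8s_end) <= 3 &
      abs(ac$annotation$its2_end - b$its2_end) <= 3
    mean(ok)
  }, 0)
  expect_true(all(diff(recov) <= 0))
  expect_gt(recov[1], 0.9)
})
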