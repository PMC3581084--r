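# Independent oracles used across the suite.  Alignment scores and aligned
# strings come from Biostrings::pairwiseAlignment (an implementation the
# package does not share code with); identification categories and the
# Wilcoxon distribution are recomputed by naive enumeration.

oracle_subst_matrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

oracle_global_score <- function(a, b, scoring = align_scoring()) {
  Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = oracle_subst_matrix(scoring$match, scoring$mismatch),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    scoreOnly = TRUE)
}

oracle_local_score <- function(a, b, scoring = local_scoring()) {
  Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = oracle_subst_matrix(scoring$match, scoring$mismatch),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    scoreOnly = TRUE)
}

# counts (compared sites, transitions, transversions) read off the aligned
# strings of the oracle aligner
oracle_global_counts <- function(a, b, scoring = align_scoring()) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = oracle_subst_matrix(scoring$match, scoring$mismatch),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- sa %in% c("A", "C", "G", "T") & sb %in% c("A", "C", "G", "T")
  diff <- ok & sa != sb
  ts <- diff & ((sa == "A" & sb == "G") | (sa == "G" & sb == "A") |
                  (sa == "C" & sb == "T") | (sa == "T" & sb == "C"))
  list(n_compared = sum(ok), n_transitions = sum(ts),
       n_transversions = sum(diff & !ts),
       score = Biostrings::score(pa))
}

oracle_p_dist_matrix <- function(corpus, scoring = align_scoring()) {
  n <- nrow(corpus)
  v <- matrix(0, n, n, dimnames = list(corpus$record_id, corpus$record_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cc <- oracle_global_counts(corpus$sequence[i], corpus$sequence[j],
                                 scoring)
      d <- if (cc$n_compared == 0) NaN
      else (cc$n_transitions + cc$n_transversions) / cc$n_compared
      v[i, j] <- v[j, i] <- d
    }
  }
  v
}

# naive re-statement of the three identification criteria over a
# precomputed distance / score matrix (independent of the package's code
# paths)
oracle_category <- function(top_g, top_s, qg, qs, rank) {
  taxa <- if (rank == "species") unique(paste(top_g, top_s))
  else unique(top_g)
  q <- if (rank == "species") paste(qg, qs) else qg
  if (length(taxa) > 1) return("AMBIGUOUS")
  if (taxa == q) "CORRECT" else "INCORRECT"
}

oracle_identify <- function(corpus, criterion, rank, dist_or_score,
                            threshold = 0.03) {
  n <- nrow(corpus)
  vapply(seq_len(n), function(i) {
    x <- dist_or_score[i, -i]
    g <- corpus$genus[-i]; s <- corpus$species[-i]
    keep <- !is.nan(x)
    x <- x[keep]; g <- g[keep]; s <- s[keep]
    if (criterion == "BEST_HIT") {
      top <- x == max(x)
    } else {
      if (criterion == "BEST_CLOSE_MATCH" && min(x) > threshold) {
        return("NO_MATCH")
      }
      top <- x <= min(x) * (1 + 1e-9)
    }
    oracle_category(g[top], s[top], corpus$genus[i], corpus$species[i], rank)
  }, "")
}

# exact Wilcoxon signed-rank p-value by enumerating all 2^n sign vectors
oracle_wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(w_plus = 0, w_minus = 0, p = 1))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_plus + 1e-9)
  p_ge <- mean(w_all >= w_plus - 1e-9)
  list(w_plus = w_plus, w_minus = sum(r[d < 0]),
       p = min(1, 2 * min(p_le, p_ge)))
}

# small random corpora built directly in the helper (plain R, no use of
# the package generator): 2-3 genera, random ancestors, light
# substitution/indel noise, occasional exact duplicates to force ties
random_small_corpus <- function(n_species = 5, max_samples = 4,
                                len = 120, sub_rate = 0.03,
                                dup_prob = 0.3, del_prob = 0.2) {
  bases <- c("A", "C", "G", "T")
  recs <- list()
  k <- 0
  genus_of <- sample(c("Aus", "Bus", "Cus"), n_species, replace = TRUE)
  for (s in seq_len(n_species)) {
    anc <- sample(bases, len, replace = TRUE)
    for (r in seq_len(sample.int(max_samples, 1))) {
      x <- anc
      hit <- runif(len) < sub_rate
      x[hit] <- sample(bases, sum(hit), replace = TRUE)
      if (runif(1) < del_prob) x <- x[-sample.int(length(x), 1)]
      k <- k + 1
      recs[[k]] <- data.frame(
        record_id = sprintf("sp%02d_r%02d", s, r),
        genus = genus_of[s], species = sprintf("species%02d", s),
        sequence = paste(x, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  # duplicate one sequence onto another record to create exact ties
  if (nrow(df) >= 3 && runif(1) < dup_prob) {
    ij <- sample.int(nrow(df), 2)
    df$sequence[ij[2]] <- df$sequence[ij[1]]
  }
  new_corpus(df)
}

# equal-length corpora in which every pair keeps >= ~55% identity, so the
# optimal global alignment is the ungapped one by a wide score margin and
# the p-distance is exactly the naive Hamming mismatch fraction
hamming_corpus <- function(n_species = 5, max_samples = 3, len = 110,
                           div_species = 0.2, div_sample = 0.04,
                           dup_prob = 0.5) {
  bases <- c("A", "C", "G", "T")
  mut <- function(x, rate) {
    hit <- runif(length(x)) < rate
    x[hit] <- sample(bases, sum(hit), replace = TRUE)
    x
  }
  base <- sample(bases, len, replace = TRUE)
  genus_of <- sample(c("Aus", "Bus", "Cus"), n_species, replace = TRUE)
  recs <- list(); k <- 0
  for (s in seq_len(n_species)) {
    anc <- mut(base, div_species)
    for (r in seq_len(sample.int(max_samples, 1))) {
      k <- k + 1
      recs[[k]] <- data.frame(
        record_id = sprintf("sp%02d_r%02d", s, r),
        genus = genus_of[s], species = sprintf("species%02d", s),
        sequence = paste(mut(anc, div_sample), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  if (nrow(df) >= 3 && runif(1) < dup_prob) {
    ij <- sample.int(nrow(df), 2)
    df$sequence[ij[2]] <- df$sequence[ij[1]]
  }
  new_corpus(df)
}

oracle_hamming_matrix <- function(corpus) {
  chars <- strsplit(corpus$sequence, "")
  n <- nrow(corpus)
  v <- matrix(0, n, n, dimnames = list(corpus$record_id, corpus$record_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v[i, j] <- v[j, i] <- mean(chars[[i]] != chars[[j]])
  }
  v
}

expect_file_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
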