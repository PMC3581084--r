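# helpers shared by the divergence summaries: logical pair masks over the
# distance matrix, aligned to the corpus rows
check_dm_corpus <- function(dm, corpus) {
  if (!identical(dm$labels, corpus$record_id)) {
    idx <- match(dm$labels, corpus$record_id)
    if (anyNA(idx)) stop("distance matrix and corpus record ids disagree")
    corpus <- corpus[idx, , drop = FALSE]
    class(corpus) <- c("barcode_corpus", "data.frame")
  }
  corpus
}

#' Intraspecific divergence summary
#'
#' For every species with at least two samples, takes its conspecific
#' pairwise distances and computes (i) their mean and (ii) their maximum
#' (the coalescent-depth analogue).  Reports three components, each as
#' mean and SD over its averaging units:
#' `avg_intra_avg` (over per-species means), `avg_intra_max` (over
#' per-species maxima) and `avg_intra_between_intra_species` (over all
#' conspecific pairs pooled; the theta analogue).  `NaN` distances are
#' excluded and counted.
#'
#' @param dm a [distance_matrix()].
#' @param corpus the matching corpus (genus/species labels).
#' @param weighted if `TRUE`, per-species means are weighted by their
#'   number of pairs when averaged (default `FALSE`, every species equal).
#' @return list: `components` data frame (`parameter`, `mean`, `sd`, `n`),
#'   `n_species_used`, `n_nan_excluded`.
#' @export
intraspecific_summary <- function(dm, corpus, weighted = FALSE) {
  corpus <- check_dm_corpus(dm, corpus)
  sp <- species_key(corpus)
  v <- dm$values
  species_means <- c(); species_maxs <- c(); pooled <- c()
  wts <- c(); n_nan <- 0L
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) < 2) next
    d <- v[idx, idx][upper.tri(diag(length(idx)))]
    n_nan <- n_nan + sum(is.nan(d))
    d <- d[!is.nan(d)]
    if (length(d) == 0) next
    species_means <- c(species_means, mean(d))
    species_maxs <- c(species_maxs, max(d))
    wts <- c(wts, length(d))
    pooled <- c(pooled, d)
  }
  if (length(species_means) == 0) {
    stop("no species with >= 2 comparable samples")
  }
  w <- if (weighted) wts else rep(1, length(wts))
  wmean <- function(x) sum(w * x) / sum(w)
  comp <- data.frame(
    parameter = c("avg_intra_avg", "avg_intra_max",
                  "avg_intra_between_intra_species"),
    mean = c(wmean(species_means), wmean(species_maxs), mean(pooled)),
    sd = c(sd_or_zero(species_means), sd_or_zero(species_maxs),
           sd_or_zero(pooled)),
    n = c(length(species_means), length(species_maxs), length(pooled)))
  list(components = comp,
       n_species_used = length(species_means),
       n_nan_excluded = n_nan)
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Interspecific (congeneric) divergence summary
#'
#' Considers only congeneric heterospecific pairs, in genera with at least
#' two species.  Components: `avg_interbyG_avg` (mean over genera of the
#' per-genus mean congeneric distance; theta-prime analogue),
#' `avg_interbyG_min` (mean over species of each species' nearest
#' heterospecific congener distance) and `avg_between_interbyGenus` (all
#' congeneric heterospecific pairs pooled).  `NaN` distances are excluded
#' and counted.
#'
#' @inheritParams intraspecific_summary
#' @return list: `components` data frame, `n_genera_used`,
#'   `n_species_used`, `n_nan_excluded`.
#' @export
interspecific_summary <- function(dm, corpus, weighted = FALSE) {
  corpus <- check_dm_corpus(dm, corpus)
  sp <- species_key(corpus)
  v <- dm$values
  genus_means <- c(); genus_wts <- c()
  species_mins <- c(); pooled <- c(); n_nan <- 0L
  for (g in unique(corpus$genus)) {
    idx <- which(corpus$genus == g)
    if (length(unique(sp[idx])) < 2) next
    sub <- v[idx, idx, drop = FALSE]
    hetero <- outer(sp[idx], sp[idx], "!=")
    d_all <- sub[hetero & upper.tri(sub)]
    n_nan <- n_nan + sum(is.nan(d_all))
    d_all <- d_all[!is.nan(d_all)]
    if (length(d_all) > 0) {
      genus_means <- c(genus_means, mean(d_all))
      genus_wts <- c(genus_wts, length(d_all))
      pooled <- c(pooled, d_all)
    }
    for (k in seq_along(idx)) {
      dk <- sub[k, hetero[k, ]]
      dk <- dk[!is.nan(dk)]
      if (length(dk) > 0) species_mins <- c(species_mins, min(dk))
    }
  }
  if (length(genus_means) == 0) stop("no genus with >= 2 comparable species")
  w <- if (weighted) genus_wts else rep(1, length(genus_wts))
  comp <- data.frame(
    parameter = c("avg_interbyG_avg", "avg_interbyG_min",
                  "avg_between_interbyGenus"),
    mean = c(sum(w * genus_means) / sum(w), mean(species_mins), mean(pooled)),
    sd = c(sd_or_zero(genus_means), sd_or_zero(species_mins),
           sd_or_zero(pooled)),
    n = c(length(genus_means), length(species_mins), length(pooled)))
  list(components = comp,
       n_genera_used = length(genus_means),
       n_species_used = length(species_mins),
       n_nan_excluded = n_nan)
}

#' The six divergence parameters of a barcode corpus
#'
#' Combines [intraspecific_summary()] and [interspecific_summary()] into
#' the standard six-parameter characterization of a barcode locus (three
#' intraspecific, three interspecific components, each mean +/- SD in
#' substitutions/site).
#'
#' @inheritParams intraspecific_summary
#' @return object of class `divergence_summary`: data frame `components`
#'   with the six rows, plus unit counts.
#' @export
divergence_summary <- function(dm, corpus, weighted = FALSE) {
  intra <- intraspecific_summary(dm, corpus, weighted)
  inter <- interspecific_summary(dm, corpus, weighted)
  structure(list(components = rbind(intra$components, inter$components),
                 n_species_intra = intra$n_species_used,
                 n_genera_used = inter$n_genera_used,
                 n_species_inter = inter$n_species_used,
                 n_nan_excluded = intra$n_nan_excluded +
                   inter$n_nan_excluded),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Divergence summary (substitutions/site, mean +/- SD)\n")
  c <- x$components
  for (i in seq_len(nrow(c))) {
    cat(sprintf("  %-33s %.4f +/- %.4f  (n = %d)\n",
                c$parameter[i], c$mean[i], c$sd[i], c$n[i]))
  }
  cat(sprintf("  species (intra) %d, genera %d, NaN excluded %d\n",
              x$n_species_intra, x$n_genera_used, x$n_nan_excluded))
  invisible(x)
}

#' Write a divergence summary as TSV
#' @param summary a `divergence_summary`.
#' @param path output path.
#' @export
write_divergence_summary <- function(summary, path) {
  write.table(summary$components, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(summary)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' mid-rank ties.  The two-sided p-value is exact (distribution of the
#' rank sum over all sign assignments, computed by convolution, which for
#' tied mid-ranks equals full enumeration) for `n <= exact_limit`, and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @param exact_limit largest `n` for which the exact distribution is used
#'   (default 25).
#' @return object of class `wilcoxon_result`: `w_plus`, `w_minus`, `n`,
#'   `p_value`, `direction` (`A_GT_B`, `B_GT_A`, `NONE`), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 exact_limit = 25) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 1)
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(w_plus = 0, w_minus = 0, n = 0L, p_value = 1,
                          direction = "NONE", method = "degenerate"),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (x in r2) {
      f <- (f + c(rep(0, x), f[seq_len(total + 1 - x)])) / 2
    }
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    num <- w_plus - mu
    z <- (num - sign(num) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  direction <- if (w_plus > w_minus) "A_GT_B"
  else if (w_minus > w_plus) "B_GT_A" else "NONE"
  structure(list(w_plus = w_plus, w_minus = w_minus, n = as.integer(n),
                 p_value = p, direction = direction, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: W+ = %g, W- = %g, n = %d, p = %.4g (%s)\n",
              x$w_plus, x$w_minus, x$n, x$p_value, x$direction))
  invisible(x)
}

#' Paired Wilcoxon comparison of two loci
#'
#' Compares the pairwise divergences of the same records under two loci
#' (e.g. full ITS vs excised ITS2).  The pairing unit is the individual
#' sequence pair: congeneric heterospecific pairs for the interspecific
#' test and conspecific pairs for the intraspecific test.  Pairs with an
#' undefined distance under either locus are dropped.
#'
#' In the result of each class, direction `A_GT_B` means locus 1 tends to
#' exceed locus 2.
#'
#' @param dm1,dm2 [distance_matrix()] objects for the two loci; their
#'   record ids must overlap (the tests run on the shared records).
#' @param corpus corpus supplying genus/species labels for the shared ids.
#' @return list with `inter` and `intra` elements, each a
#'   [wilcoxon_signed_rank()] result with an added `n_pairs` field.
#' @export
compare_loci <- function(dm1, dm2, corpus) {
  shared <- intersect(dm1$labels, dm2$labels)
  if (length(shared) < 2) stop("loci share fewer than 2 record ids")
  i1 <- match(shared, dm1$labels)
  i2 <- match(shared, dm2$labels)
  v1 <- dm1$values[i1, i1]
  v2 <- dm2$values[i2, i2]
  ic <- match(shared, corpus$record_id)
  if (anyNA(ic)) stop("corpus lacks labels for shared records")
  gen <- corpus$genus[ic]
  sp <- paste(gen, corpus$species[ic])
  ut <- upper.tri(v1)
  same_sp <- outer(sp, sp, "==")
  same_gen <- outer(gen, gen, "==")
  run_class <- function(mask) {
    a <- v1[mask & ut]
    b <- v2[mask & ut]
    ok <- !is.nan(a) & !is.nan(b)
    res <- wilcoxon_signed_rank(a[ok], b[ok])
    res$n_pairs <- sum(ok)
    res
  }
  list(inter = run_class(same_gen & !same_sp),
       intra = run_class(same_sp))
}
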