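#' Simulation configuration for synthetic barcode corpora
#'
#' Defines a hierarchical genus/species/sample corpus of composite
#' ribosomal sequences: leading 18S-3' flank + ITS1 + 5.8S + ITS2 +
#' trailing 28S-5' flank.  Spacers (ITS1, ITS2) evolve fast, the 5.8S and
#' flanks are near-invariant, so the generated data reproduce the
#' barcode-gap regime (intraspecific divergence well below congeneric
#' interspecific divergence) and exercise motif-based region annotation.
#'
#' Default lengths centre the full ITS near 634 nt and ITS2 near 233 nt,
#' the average lengths typical of plant nuclear ribosomal ITS.  Divergence
#' defaults (`d_intra = 0.010`, `d_inter = 0.040` per site per lineage on
#' spacer sites) yield realized pairwise full-ITS divergences of roughly
#' 0.015 within species and 0.07-0.08 between congeneric species, the
#' regime reported for large plant ITS corpora.
#'
#' @param n_genera number of genera.
#' @param species_per_genus integer range `c(lo, hi)`, sampled uniformly.
#' @param samples_per_species integer range `c(lo, hi)`, sampled uniformly.
#' @param len_its1,len_its2,len_flank integer ranges for spacer and flank
#'   lengths (drawn per genus).  The 5.8S segment has the fixed length of
#'   the reference motif (160 nt).
#' @param d_intra per-site substitution probability on spacer sites when a
#'   sample is derived from its species ancestor.
#' @param d_inter per-site substitution probability on spacer sites when a
#'   species ancestor is derived from its genus root.
#' @param conserved_rate_5_8s per-site substitution probability in 5.8S and
#'   flanks (both derivation steps); must not exceed `d_intra`.
#' @param indel_rate per-site probability of a single-base indel in
#'   spacers (applied after substitutions, both derivation steps).
#' @param ts_tv_ratio transition:transversion ratio of the substitution
#'   process (default 2).
#' @param seed integer seed; the same config and seed give byte-identical
#'   corpora.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genera = 20,
                              species_per_genus = c(2, 8),
                              samples_per_species = c(1, 4),
                              len_its1 = c(230, 252),
                              len_its2 = c(220, 246),
                              len_flank = c(60, 60),
                              d_intra = 0.010,
                              d_inter = 0.040,
                              conserved_rate_5_8s = 0.002,
                              indel_rate = 0.002,
                              ts_tv_ratio = 2,
                              seed = 1) {
  as_range <- function(x) {
    if (length(x) == 1) x <- c(x, x)
    stopifnot(length(x) == 2, x[1] <= x[2], x[1] >= 1)
    as.integer(round(x))
  }
  cfg <- list(n_genera = as.integer(n_genera),
              species_per_genus = as_range(species_per_genus),
              samples_per_species = as_range(samples_per_species),
              len_its1 = as_range(len_its1),
              len_its2 = as_range(len_its2),
              len_flank = as_range(len_flank),
              d_intra = d_intra,
              d_inter = d_inter,
              conserved_rate_5_8s = conserved_rate_5_8s,
              indel_rate = indel_rate,
              ts_tv_ratio = ts_tv_ratio,
              seed = as.integer(seed))
  if (cfg$n_genera < 1) stop("n_genera must be >= 1")
  if (!(d_intra >= 0 && d_intra < d_inter && d_inter <= 0.75)) {
    stop("require 0 <= d_intra < d_inter <= 0.75")
  }
  if (conserved_rate_5_8s > d_intra) {
    stop("conserved_rate_5_8s must not exceed d_intra")
  }
  if (indel_rate < 0 || ts_tv_ratio <= 0) stop("invalid indel_rate/ts_tv_ratio")
  structure(cfg, class = "simulation_config")
}

# substitute sites iid with prob `rate`; transition with odds ts_tv : 1
mutate_sites <- function(chars, rate, ts_tv) {
  n <- length(chars)
  if (n == 0 || rate <= 0) return(chars)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(chars)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- runif(length(hit)) < ts_tv / (ts_tv + 1)
  out <- chars
  out[hit[is_ts]] <- unname(ts_map[chars[hit[is_ts]]])
  for (i in hit[!is_ts]) {
    tvs <- if (chars[i] %in% c("A", "G")) c("C", "T") else c("A", "G")
    out[i] <- tvs[sample.int(2, 1)]
  }
  out
}

# single-base indels (half deletions, half insertions of a random base)
apply_indels <- function(chars, rate) {
  n <- length(chars)
  if (n == 0 || rate <= 0) return(chars)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(chars)
  del <- runif(length(hit)) < 0.5
  out <- as.list(chars)
  for (i in hit[del]) out[[i]] <- character(0)
  ins_at <- hit[!del]
  if (length(ins_at) > 0) {
    ins_bases <- sample(c("A", "C", "G", "T"), length(ins_at), replace = TRUE)
    for (k in seq_along(ins_at)) {
      i <- ins_at[k]
      out[[i]] <- c(ins_bases[k], chars[i])
    }
  }
  unlist(out, use.names = FALSE)
}

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# fit a conserved reference motif to a drawn length: truncate or pad with
# random bases on the side away from the ITS
fit_flank <- function(motif, len, side) {
  mc <- chars_of(motif)
  if (len == length(mc)) return(mc)
  if (len < length(mc)) {
    if (side == "left") return(mc[(length(mc) - len + 1):length(mc)])
    return(mc[seq_len(len)])
  }
  pad <- sample(c("A", "C", "G", "T"), len - length(mc), replace = TRUE)
  if (side == "left") c(pad, mc) else c(mc, pad)
}

#' Simulate a synthetic barcode corpus
#'
#' Generation scheme: one root per genus (spacers uniform random, conserved
#' segments from the fixed reference motifs); each species ancestor derived
#' from its genus root by substituting spacer sites with probability
#' `d_inter` and conserved sites with `conserved_rate_5_8s`; each sample
#' derived from its species ancestor with `d_intra` (spacers) and
#' `conserved_rate_5_8s` (conserved).  Substitutions use the configured
#' transition:transversion ratio; single-base indels occur in spacers only.
#'
#' @param config a [simulation_config()].
#' @return list with elements `corpus` (a [new_corpus()] with region
#'   `UNKNOWN`; sequences include the flanks) and `truth` (class
#'   `synthetic_truth`: data frame of 0-based half-open true boundaries
#'   `its1_start`, `its1_end`, `r5_8s_end`, `its2_end` per record, plus the
#'   genus/species ancestors).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1)

  recs <- list()
  truths <- list()
  ancestors <- list()
  k <- 0L
  for (g in seq_len(config$n_genera)) {
    genus <- sprintf("Genus%02d", g)
    lf1 <- rint(config$len_flank)
    lf2 <- rint(config$len_flank)
    root <- list(
      flank1 = fit_flank(MOTIF_FLANK_18S, lf1, "left"),
      its1 = sample(c("A", "C", "G", "T"), rint(config$len_its1), TRUE),
      r5_8s = chars_of(MOTIF_5_8S),
      its2 = sample(c("A", "C", "G", "T"), rint(config$len_its2), TRUE),
      flank2 = fit_flank(MOTIF_FLANK_28S, lf2, "right"))
    n_sp <- rint(config$species_per_genus)
    for (s in seq_len(n_sp)) {
      species <- sprintf("species%02d", s)
      anc <- list(
        flank1 = mutate_sites(root$flank1, config$conserved_rate_5_8s,
                              config$ts_tv_ratio),
        its1 = apply_indels(mutate_sites(root$its1, config$d_inter,
                                         config$ts_tv_ratio),
                            config$indel_rate),
        r5_8s = mutate_sites(root$r5_8s, config$conserved_rate_5_8s,
                             config$ts_tv_ratio),
        its2 = apply_indels(mutate_sites(root$its2, config$d_inter,
                                         config$ts_tv_ratio),
                            config$indel_rate),
        flank2 = mutate_sites(root$flank2, config$conserved_rate_5_8s,
                              config$ts_tv_ratio))
      ancestors[[paste(genus, species)]] <- anc
      n_sam <- rint(config$samples_per_species)
      for (r in seq_len(n_sam)) {
        smp <- list(
          flank1 = mutate_sites(anc$flank1, config$conserved_rate_5_8s,
                                config$ts_tv_ratio),
          its1 = apply_indels(mutate_sites(anc$its1, config$d_intra,
                                           config$ts_tv_ratio),
                              config$indel_rate),
          r5_8s = mutate_sites(anc$r5_8s, config$conserved_rate_5_8s,
                               config$ts_tv_ratio),
          its2 = apply_indels(mutate_sites(anc$its2, config$d_intra,
                                           config$ts_tv_ratio),
                              config$indel_rate),
          flank2 = mutate_sites(anc$flank2, config$conserved_rate_5_8s,
                                config$ts_tv_ratio))
        k <- k + 1L
        id <- sprintf("G%02dS%02dR%02d", g, s, r)
        lens <- vapply(smp, length, 0L)
        recs[[k]] <- data.frame(
          record_id = id, genus = genus, species = species,
          sequence = paste(unlist(smp, use.names = FALSE), collapse = ""),
          region = "UNKNOWN", stringsAsFactors = FALSE)
        truths[[k]] <- data.frame(
          record_id = id,
          its1_start = unname(lens["flank1"]),
          its1_end = unname(lens["flank1"] + lens["its1"]),
          r5_8s_end = unname(lens["flank1"] + lens["its1"] + lens["r5_8s"]),
          its2_end = unname(lens["flank1"] + lens["its1"] + lens["r5_8s"] +
                              lens["its2"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  corpus <- new_corpus(do.call(rbind, recs))
  truth <- structure(list(boundaries = do.call(rbind, truths),
                          ancestors = ancestors,
                          config = config),
                     class = "synthetic_truth")
  list(corpus = corpus, truth = truth)
}

#' Excise a region from a synthetic corpus using the generator's truth
#'
#' @param corpus corpus emitted by [simulate_corpus()].
#' @param truth matching `synthetic_truth`.
#' @param region one of `"ITS1"`, `"R5_8S"`, `"ITS2"`, `"ITS_FULL"`.
#' @return corpus of excised sequences with the region tag set; taxonomy
#'   preserved.
#' @export
excise_true_region <- function(corpus, truth, region) {
  region <- match.arg(region, c("ITS1", "R5_8S", "ITS2", "ITS_FULL"))
  b <- truth$boundaries
  idx <- match(corpus$record_id, b$record_id)
  if (anyNA(idx)) {
    stop("records absent from truth: ",
         paste(corpus$record_id[is.na(idx)], collapse = ", "))
  }
  b <- b[idx, ]
  start <- switch(region,
                  ITS1 = b$its1_start, R5_8S = b$its1_end,
                  ITS2 = b$r5_8s_end, ITS_FULL = b$its1_start)
  end <- switch(region,
                ITS1 = b$its1_end, R5_8S = b$r5_8s_end,
                ITS2 = b$its2_end, ITS_FULL = b$its2_end)
  out <- corpus
  out$sequence <- substr(corpus$sequence, start + 1, end)
  out$region <- region
  class(out) <- class(corpus)
  out
}

#' Write the true region boundaries as TSV
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$boundaries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(truth)
}
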