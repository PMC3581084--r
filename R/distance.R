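#' Alignment scoring schemes
#'
#' A gap of length `L` costs `gap_open + L * gap_extend` (i.e. the first
#' gap character costs `gap_open + gap_extend`).  Defaults: global
#' alignment uses match +1 / mismatch -1 / open -5 / extend -2; local
#' (search-style) alignment uses the stricter mismatch -3 typical of
#' nucleotide database search.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores (penalties
#'   negative).
#' @return a named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1,
                          gap_open = -5, gap_extend = -2) {
  stopifnot(match > 0, mismatch < match, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' @rdname align_scoring
#' @export
local_scoring <- function(match = 1, mismatch = -3,
                          gap_open = -5, gap_extend = -2) {
  align_scoring(match, mismatch, gap_open, gap_extend)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (Gotoh), deterministic tie-breaking
#' (diagonal, then up, then left).  Aligned positions where either symbol
#' is a gap or an ambiguity code are excluded from `n_compared` (pairwise
#' deletion); transitions are A<->G and C<->T.
#'
#' @param a,b nucleotide strings (non-empty).
#' @param scoring an [align_scoring()].
#' @return object of class `pairwise_alignment`: `aligned_a`, `aligned_b`,
#'   `score`, `n_compared`, `n_transitions`, `n_transversions`.
#' @export
align_global <- function(a, b, scoring = align_scoring()) {
  a <- normalize_sequence(a); b <- normalize_sequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_align_global(a, b, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  structure(r, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %d, %d sites compared, %d ts / %d tv\n",
              x$score, x$n_compared, x$n_transitions, x$n_transversions))
  invisible(x)
}

#' Uncorrected p-distance of an alignment
#'
#' `(n_transitions + n_transversions) / n_compared`; `NaN` when no sites
#' are comparable.
#'
#' @param aln a `pairwise_alignment` (or any list with the count fields).
#' @return numeric distance (substitutions/site).
#' @export
p_distance <- function(aln) {
  if (aln$n_compared < 1) return(NaN)
  (aln$n_transitions + aln$n_transversions) / aln$n_compared
}

k2p_from_PQ <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  bad <- is.na(arg1) | is.na(arg2) | arg1 <= 0 | arg2 <= 0
  arg1[bad] <- 1; arg2[bad] <- 1
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  d[bad] <- NaN
  d
}

#' Kimura 2-parameter distance of an alignment
#'
#' With `P` the transition and `Q` the transversion proportion over the
#' compared sites, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  Returns
#' `NaN` at saturation (either log argument <= 0) or when no sites are
#' comparable.
#'
#' @inheritParams p_distance
#' @return numeric distance (substitutions/site).
#' @export
k2p_distance <- function(aln) {
  if (aln$n_compared < 1) return(NaN)
  k2p_from_PQ(aln$n_transitions / aln$n_compared,
              aln$n_transversions / aln$n_compared)
}

#' All-pairs substitution counts for a corpus
#'
#' Globally aligns every unordered pair of sequences once and records the
#' compared-site, transition and transversion counts (and alignment
#' scores).  Distance matrices under any model are derived from these
#' counts without re-aligning.
#'
#' @param corpus a `barcode_corpus` with >= 2 records.
#' @param scoring an [align_scoring()].
#' @return object of class `pair_counts`: `labels` plus symmetric integer
#'   matrices `n_compared`, `n_transitions`, `n_transversions`, `score`.
#' @export
pairwise_counts <- function(corpus, scoring = align_scoring()) {
  if (nrow(corpus) < 2) stop("corpus must have >= 2 records")
  r <- cpp_pair_counts(corpus$sequence, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  for (nm in names(r)) dimnames(r[[nm]]) <- list(corpus$record_id,
                                                 corpus$record_id)
  structure(c(list(labels = corpus$record_id), r), class = "pair_counts")
}

#' Pairwise distance matrix for a corpus
#'
#' @param corpus a `barcode_corpus` with >= 2 records.
#' @param model `"K2P"` (default) or `"p"` (uncorrected).
#' @param scoring an [align_scoring()] used for the global alignments.
#' @param counts optional precomputed [pairwise_counts()] (so that one
#'   alignment pass can serve several models).
#' @return object of class `dist_matrix`: `labels`, `model`, symmetric
#'   numeric matrix `values` (diagonal 0; `NaN` where the model is
#'   undefined), and `n_undefined`, the count of `NaN` off-diagonal pairs
#'   (unordered).
#' @export
distance_matrix <- function(corpus, model = c("K2P", "p"),
                            scoring = align_scoring(), counts = NULL) {
  model <- match.arg(model)
  if (is.null(counts)) counts <- pairwise_counts(corpus, scoring)
  nc <- counts$n_compared
  P <- counts$n_transitions / nc
  Q <- counts$n_transversions / nc
  if (model == "p") {
    values <- P + Q
  } else {
    values <- k2p_from_PQ(P, Q)
  }
  values[nc == 0] <- NaN
  diag(values) <- 0
  n_undef <- sum(is.nan(values[upper.tri(values)]))
  if (n_undef > 0 && model == "K2P") {
    warning(sprintf("%d pair(s) saturated or incomparable (NaN distance)",
                    n_undef))
  }
  structure(list(labels = counts$labels, model = model, values = values,
                 n_undefined = n_undef),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s over %d records (%d undefined pairs)\n",
              x$model, length(x$labels), x$n_undefined))
  invisible(x)
}

#' Write a distance matrix as square TSV or PHYLIP
#'
#' @param dm a `dist_matrix`.
#' @param path output path.
#' @param format `"tsv"` (header row/column of record ids) or `"phylip"`
#'   (square PHYLIP).
#' @export
write_dist_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  v <- dm$values
  if (format == "tsv") {
    df <- data.frame(record_id = dm$labels, v, check.names = FALSE)
    colnames(df) <- c("record_id", dm$labels)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$labels)), con)
    for (i in seq_along(dm$labels)) {
      writeLines(paste(c(formatC(dm$labels[i], width = -10),
                         formatC(v[i, ], format = "f", digits = 6)),
                       collapse = "  "), con)
    }
  }
  invisible(dm)
}
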