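#' Build a nucleotide motif profile from aligned references
#'
#' Builds a position-specific log-odds profile (the match-state emissions
#' of a small profile HMM) from two or more equal-length, possibly gapped,
#' reference sequences.  Alignment columns with more than 50% gaps are
#' dropped from the match-state set.  Per-column emission probabilities are
#' `(count + pseudocount) / (total + 4 * pseudocount)` and are converted to
#' log-odds (bits) against a uniform 0.25 background.
#'
#' @param aligned_references character vector (>= 2) of equal-length gapped
#'   sequences.
#' @param pseudocount Laplace pseudocount added per base (default 1).
#' @param name profile name.
#' @param score_threshold minimum placement score (bits) for a hit
#'   (default 10).
#' @param ins_open,ins_ext,del_open,del_ext transition penalties
#'   (log2-probabilities, bits) for opening/extending insertions and
#'   deletions relative to the profile.
#' @return object of class `motif_profile` with the `L x 4` log-odds matrix
#'   (columns A, C, G, T).
#' @export
build_profile <- function(aligned_references, pseudocount = 1,
                          name = "motif", score_threshold = 10,
                          ins_open = -4, ins_ext = -1,
                          del_open = -4, del_ext = -1) {
  refs <- normalize_sequence(aligned_references)
  if (length(refs) < 2) stop("need >= 2 reference sequences")
  lens <- nchar(refs)
  if (length(unique(lens)) != 1) stop("references must have equal length")
  mat <- do.call(rbind, strsplit(refs, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 10) stop("profile must have >= 10 match positions")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  counts <- matrix(counts, ncol = 4,
                   dimnames = list(NULL, bases))
  totals <- rowSums(counts)
  probs <- (counts + pseudocount) / (totals + 4 * pseudocount)
  structure(list(name = name,
                 logodds = log2(probs / 0.25),
                 length = nrow(probs),
                 score_threshold = score_threshold,
                 ins_open = ins_open, ins_ext = ins_ext,
                 del_open = del_open, del_ext = del_ext,
                 pseudocount = pseudocount),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> '%s': %d match positions, threshold %.1f bits\n",
              x$name, x$length, x$score_threshold))
  invisible(x)
}

#' Serialize / read a motif profile as TSV
#'
#' Columns: `position`, `logodds_A`, `logodds_C`, `logodds_G`, `logodds_T`.
#' @param profile a `motif_profile`.
#' @param path output (input) path.
#' @return the profile, invisibly (or, for the reader, the profile).
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$length),
                   logodds_A = profile$logodds[, "A"],
                   logodds_C = profile$logodds[, "C"],
                   logodds_G = profile$logodds[, "G"],
                   logodds_T = profile$logodds[, "T"])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' @rdname write_profile
#' @param name,score_threshold,ins_open,ins_ext,del_open,del_ext profile
#'   metadata for the reader (not stored in the TSV).
#' @export
read_profile <- function(path, name = "motif", score_threshold = 10,
                         ins_open = -4, ins_ext = -1,
                         del_open = -4, del_ext = -1) {
  df <- read.delim(path)
  lo <- as.matrix(df[, c("logodds_A", "logodds_C", "logodds_G", "logodds_T")])
  colnames(lo) <- c("A", "C", "G", "T")
  structure(list(name = name, logodds = lo, length = nrow(lo),
                 score_threshold = score_threshold,
                 ins_open = ins_open, ins_ext = ins_ext,
                 del_open = del_open, del_ext = del_ext,
                 pseudocount = NA_real_),
            class = "motif_profile")
}

#' Default annotation profiles from the synthetic reference motifs
#'
#' Profiles for the conserved 5.8S segment and the 28S 5' flank (plus the
#' optional leading 18S 3' flank), built from the fixed synthetic motifs
#' that the corpus generator plants.  For biological data, build profiles
#' from real reference alignments instead.
#'
#' @param pseudocount passed to [build_profile()].
#' @return named list with `r5_8s`, `flank_28s`, `flank_18s` profiles.
#' @export
reference_profiles <- function(pseudocount = 1) {
  m <- reference_motifs()
  list(r5_8s = build_profile(rep(m[["r5_8s"]], 2), pseudocount,
                             name = "5.8S"),
       flank_28s = build_profile(rep(m[["flank_28s"]], 2), pseudocount,
                                 name = "28S-flank"),
       flank_18s = build_profile(rep(m[["flank_18s"]], 2), pseudocount,
                                 name = "18S-flank"))
}

encode_seq_int <- function(sequence) {
  x <- match(strsplit(sequence, "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  x[is.na(x)] <- 5L
  x - 1L
}

place_profile <- function(seq_int, profile) {
  r <- cpp_viterbi_glocal(seq_int, profile$logodds,
                          profile$ins_open, profile$ins_ext,
                          profile$del_open, profile$del_ext)
  list(score = r$score, start = r$start, end = r$end)
}

#' Annotate ITS1/5.8S/ITS2 on a full-length ITS sequence
#'
#' Places the 5.8S profile and the 28S-flank profile on the sequence by
#' Viterbi decoding (global over the profile, local over the sequence).
#' ITS2 is the interval between the end of the 5.8S placement and the
#' start of the flank placement.  If the flank is absent but the 5.8S is
#' found, ITS2 extends to the sequence end and the record is flagged
#' `TRUNCATED` (or `NO_FLANK` if no ITS2 sequence remains).  When the two
#' placements overlap or are out of order, the lower-scoring one is
#' rejected.  Both profiles are also scored on the reverse complement; if
#' the reverse orientation wins for both, the sequence is flipped before
#' annotation.
#'
#' When a leading-flank (18S 3') profile is supplied, its placement (if
#' found before the 5.8S) sets the ITS1 start; otherwise ITS1 starts at
#' the sequence start.
#'
#' @param sequence a nucleotide string (or a single-row corpus record).
#' @param profile_5_8s,profile_flank `motif_profile`s for the 5.8S segment
#'   and the 28S 5' flank.
#' @param profile_lead optional `motif_profile` for the leading 18S flank.
#' @param record_id id stored in the result.
#' @return one-row data frame (class `region_annotation`): `record_id`,
#'   `its1_start`, `its1_end`, `r5_8s_end`, `its2_end` (0-based half-open;
#'   `its1_end` is the 5.8S start), `score_5_8s`, `score_flank`, `strand`,
#'   `status` in `OK`, `TRUNCATED`, `NO_FLANK`, `NO_5_8S`.
#' @export
annotate <- function(sequence, profile_5_8s, profile_flank,
                     profile_lead = NULL, record_id = "query") {
  seq_fwd <- normalize_sequence(sequence)
  n <- nchar(seq_fwd)
  fwd <- encode_seq_int(seq_fwd)
  rev <- encode_seq_int(revcomp(seq_fwd))
  p58_f <- place_profile(fwd, profile_5_8s)
  pfl_f <- place_profile(fwd, profile_flank)
  p58_r <- place_profile(rev, profile_5_8s)
  pfl_r <- place_profile(rev, profile_flank)
  strand <- "+"
  if (p58_r$score > p58_f$score && pfl_r$score > pfl_f$score) {
    strand <- "-"
    p58 <- p58_r; pfl <- pfl_r; seq_int <- rev
  } else {
    p58 <- p58_f; pfl <- pfl_f; seq_int <- fwd
  }

  have_58 <- p58$score >= profile_5_8s$score_threshold
  have_fl <- pfl$score >= profile_flank$score_threshold
  if (have_58 && have_fl && pfl$start < p58$end) {
    # out of order / overlapping: reject the lower-scoring placement
    if (pfl$score < p58$score) have_fl <- FALSE else have_58 <- FALSE
  }

  if (!have_58) {
    status <- "NO_5_8S"
    out <- data.frame(record_id = record_id, its1_start = NA_integer_,
                      its1_end = NA_integer_, r5_8s_end = NA_integer_,
                      its2_end = NA_integer_,
                      score_5_8s = p58$score, score_flank = pfl$score,
                      strand = strand, status = status,
                      stringsAsFactors = FALSE)
    class(out) <- c("region_annotation", "data.frame")
    return(out)
  }

  its1_start <- 0L
  if (!is.null(profile_lead)) {
    plead <- place_profile(seq_int, profile_lead)
    if (plead$score >= profile_lead$score_threshold &&
        plead$end <= p58$start) {
      its1_start <- plead$end
    }
  }
  if (have_fl) {
    its2_end <- pfl$start
    status <- "OK"
  } else {
    its2_end <- n
    status <- if (p58$end < n) "TRUNCATED" else "NO_FLANK"
  }
  out <- data.frame(record_id = record_id,
                    its1_start = its1_start,
                    its1_end = p58$start,
                    r5_8s_end = p58$end,
                    its2_end = its2_end,
                    score_5_8s = p58$score, score_flank = pfl$score,
                    strand = strand, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Annotate a corpus and excise ITS2
#'
#' Runs [annotate()] on every record and returns the corpus of excised
#' ITS2 sequences (records with status `OK` or `TRUNCATED` only) together
#' with the per-record annotation table.
#'
#' @param corpus a `barcode_corpus` of full-length (or unknown-region)
#'   sequences.
#' @param profiles list with elements `r5_8s`, `flank_28s` and optionally
#'   `flank_18s`, e.g. from [reference_profiles()].
#' @param region which region to excise (default `"ITS2"`; `"ITS_FULL"`
#'   excises ITS1+5.8S+ITS2).
#' @return list with `corpus` (excised records) and `annotation` (one row
#'   per input record).
#' @export
annotate_corpus <- function(corpus, profiles, region = "ITS2") {
  region <- match.arg(region, c("ITS2", "ITS_FULL"))
  if (nrow(corpus) == 0) {
    return(list(corpus = corpus, annotation = data.frame()))
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(corpus)), function(i) {
    annotate(corpus$sequence[i], profiles$r5_8s, profiles$flank_28s,
             profile_lead = profiles$flank_18s,
             record_id = corpus$record_id[i])
  }))
  keep <- ann$status %in% c("OK", "TRUNCATED")
  out <- corpus[keep, , drop = FALSE]
  b <- ann[keep, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(out)), function(i) {
    s <- out$sequence[i]
    if (b$strand[i] == "-") s <- revcomp(s)
    if (region == "ITS2") {
      substr(s, b$r5_8s_end[i] + 1, b$its2_end[i])
    } else {
      substr(s, b$its1_start[i] + 1, b$its2_end[i])
    }
  }, "")
  out$sequence <- seqs
  out$region <- rep(region, nrow(out))
  out <- out[nzchar(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(corpus)
  list(corpus = out, annotation = ann)
}

#' Write an annotation table as TSV
#' @param annotation table from [annotate_corpus()].
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotation)
}
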