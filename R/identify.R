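# category of a query given the taxa of its top-tied neighbours
category_from_taxa <- function(top_genus, top_species, q_genus, q_species,
                               rank) {
  if (rank == "species") {
    taxa <- unique(paste(top_genus, top_species))
    q <- paste(q_genus, q_species)
  } else {
    taxa <- unique(top_genus)
    q <- q_genus
  }
  if (length(taxa) >= 2) "AMBIGUOUS"
  else if (taxa == q) "CORRECT"
  else "INCORRECT"
}

# tied-minimum set of a distance vector, relative tolerance for real ties
min_tie_set <- function(d, rel_tol = 1e-9) {
  dmin <- min(d)
  which(d <= dmin * (1 + rel_tol))
}

#' Best-hit identification (exhaustive local-alignment search)
#'
#' Scores the query against every reference by optimal Smith-Waterman
#' local alignment (exhaustive, no heuristic seeding) and assigns the
#' query to the taxa of the top-scoring reference(s).  Ties (exact integer
#' score equality) across several taxa give `AMBIGUOUS`.
#'
#' @param query_id record id of the query within `corpus`, or a one-row
#'   corpus if `reference` is given.
#' @param corpus corpus holding query and references (the query itself is
#'   excluded from the search: leave-one-out).
#' @param scoring a [local_scoring()].
#' @param rank `"species"` or `"genus"`.
#' @return one-row data frame: `query_id`, `criterion`, `rank`,
#'   `category`, `best_distance_or_score`, `matched_taxa` (comma-separated).
#' @export
best_hit_identify <- function(query_id, corpus, scoring = local_scoring(),
                              rank = "species") {
  rank <- match.arg(rank, c("species", "genus"))
  qi <- match(query_id, corpus$record_id)
  if (is.na(qi)) stop("query not in corpus: ", query_id)
  if (nrow(corpus) < 2) stop("reference is empty")
  refs <- corpus[-qi, , drop = FALSE]
  sc <- cpp_local_scores_query(corpus$sequence[qi], refs$sequence,
                               scoring$match, scoring$mismatch,
                               scoring$gap_open, scoring$gap_extend)
  top <- which(sc == max(sc))
  category <- category_from_taxa(refs$genus[top], refs$species[top],
                                 corpus$genus[qi], corpus$species[qi], rank)
  data.frame(query_id = query_id, criterion = "BEST_HIT", rank = rank,
             category = category, best_distance_or_score = max(sc),
             matched_taxa = paste(unique(paste(refs$genus[top],
                                               refs$species[top])),
                                  collapse = ","),
             stringsAsFactors = FALSE)
}

# shared worker for the nearest-neighbour criteria given a distance row
nn_identify_row <- function(d, ref_genus, ref_species, q_genus, q_species,
                            rank, criterion, threshold = NA_real_,
                            rel_tol = 1e-9) {
  ok <- !is.nan(d)
  if (!any(ok)) stop("all reference distances undefined for query")
  d <- d[ok]; ref_genus <- ref_genus[ok]; ref_species <- ref_species[ok]
  dmin <- min(d)
  if (criterion == "BEST_CLOSE_MATCH" && dmin > threshold) {
    category <- "NO_MATCH"
    taxa <- character(0)
  } else {
    top <- min_tie_set(d, rel_tol)
    category <- category_from_taxa(ref_genus[top], ref_species[top],
                                   q_genus, q_species, rank)
    taxa <- unique(paste(ref_genus[top], ref_species[top]))
  }
  data.frame(criterion = criterion, rank = rank, category = category,
             best_distance_or_score = dmin,
             matched_taxa = paste(taxa, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Best-match identification (nearest neighbour, no threshold)
#'
#' Assigns the query to the species (or genus) of its minimum-distance
#' reference(s); equally good best matches from several taxa give
#' `AMBIGUOUS`, regardless of how distant the best match is.
#'
#' @param query_id record id of the query.
#' @param corpus corpus holding query and references.
#' @param dm [distance_matrix()] over the corpus (p-distance by
#'   convention for this criterion).
#' @param rank `"species"` or `"genus"`.
#' @param rel_tol relative tolerance for distance ties (default 1e-9).
#' @return one-row data frame as in [best_hit_identify()], with
#'   `best_distance_or_score` holding a distance or a local-alignment score depending on the criterion.
#' @export
best_match_identify <- function(query_id, corpus, dm, rank = "species",
                                rel_tol = 1e-9) {
  rank <- match.arg(rank, c("species", "genus"))
  qi <- match(query_id, corpus$record_id)
  if (is.na(qi)) stop("query not in corpus: ", query_id)
  if (nrow(corpus) < 2) stop("reference is empty")
  di <- match(query_id, dm$labels)
  ri <- match(corpus$record_id[-qi], dm$labels)
  out <- nn_identify_row(dm$values[di, ri],
                         corpus$genus[-qi], corpus$species[-qi],
                         corpus$genus[qi], corpus$species[qi],
                         rank, "BEST_MATCH", rel_tol = rel_tol)
  cbind(data.frame(query_id = query_id, stringsAsFactors = FALSE), out)
}

#' Best-close-match identification (nearest neighbour with threshold)
#'
#' As [best_match_identify()], but a query whose nearest neighbour is
#' farther than `threshold` is left unidentified (`NO_MATCH`).  The
#' boundary is inclusive: a nearest neighbour at exactly the threshold is
#' within it.  The threshold gates only whether identification is
#' attempted; the assignment itself still uses the minimum-distance set.
#'
#' @inheritParams best_match_identify
#' @param threshold distance threshold (default 0.03, i.e. the 97%
#'   similarity rule).
#' @export
best_close_match_identify <- function(query_id, corpus, dm,
                                      threshold = 0.03, rank = "species",
                                      rel_tol = 1e-9) {
  stopifnot(threshold > 0, threshold < 1)
  rank <- match.arg(rank, c("species", "genus"))
  qi <- match(query_id, corpus$record_id)
  if (is.na(qi)) stop("query not in corpus: ", query_id)
  if (nrow(corpus) < 2) stop("reference is empty")
  di <- match(query_id, dm$labels)
  ri <- match(corpus$record_id[-qi], dm$labels)
  out <- nn_identify_row(dm$values[di, ri],
                         corpus$genus[-qi], corpus$species[-qi],
                         corpus$genus[qi], corpus$species[qi],
                         rank, "BEST_CLOSE_MATCH", threshold = threshold,
                         rel_tol = rel_tol)
  cbind(data.frame(query_id = query_id, stringsAsFactors = FALSE), out)
}

#' Leave-one-out identification of a whole corpus
#'
#' Queries every record once against all the others and tabulates the
#' outcome percentages.  Singleton-species queries are included in the
#' denominator by default (they can never be CORRECT under the
#' nearest-neighbour criteria); set `exclude_singletons = TRUE` to drop
#' them.
#'
#' @param corpus a `barcode_corpus` with >= 2 records.
#' @param criterion `"BEST_HIT"`, `"BEST_MATCH"` or `"BEST_CLOSE_MATCH"`.
#' @param rank `"species"` or `"genus"`.
#' @param dm precomputed [distance_matrix()] (nearest-neighbour criteria;
#'   computed with p-distances if missing).
#' @param scoring [local_scoring()] for `BEST_HIT`.
#' @param threshold distance threshold for `BEST_CLOSE_MATCH`.
#' @param exclude_singletons drop queries whose species has no other
#'   sample.
#' @param rel_tol relative tolerance for distance ties.
#' @return list with `report` (class `identification_report`: criterion,
#'   rank, n_queries and the four percentages) and `per_query` (one row
#'   per query).
#' @export
identify_corpus <- function(corpus,
                            criterion = c("BEST_CLOSE_MATCH", "BEST_MATCH",
                                          "BEST_HIT"),
                            rank = c("species", "genus"),
                            dm = NULL, scoring = local_scoring(),
                            threshold = 0.03, exclude_singletons = FALSE,
                            rel_tol = 1e-9) {
  criterion <- match.arg(criterion)
  rank <- match.arg(rank)
  if (nrow(corpus) < 2) stop("corpus must have >= 2 records")
  sp <- species_key(corpus)
  n <- nrow(corpus)

  if (criterion == "BEST_HIT") {
    sc <- cpp_local_score_matrix(corpus$sequence, scoring$match,
                                 scoring$mismatch, scoring$gap_open,
                                 scoring$gap_extend)
    rows <- lapply(seq_len(n), function(i) {
      s <- sc[i, -i]
      top <- which(s == max(s))
      refs_g <- corpus$genus[-i][top]
      refs_s <- corpus$species[-i][top]
      data.frame(query_id = corpus$record_id[i], criterion = criterion,
                 rank = rank,
                 category = category_from_taxa(refs_g, refs_s,
                                               corpus$genus[i],
                                               corpus$species[i], rank),
                 best_distance_or_score = max(s),
                 matched_taxa = paste(unique(paste(refs_g, refs_s)),
                                      collapse = ","),
                 stringsAsFactors = FALSE)
    })
  } else {
    if (is.null(dm)) dm <- distance_matrix(corpus, model = "p")
    idx <- match(corpus$record_id, dm$labels)
    if (anyNA(idx)) stop("distance matrix lacks corpus records")
    v <- dm$values[idx, idx]
    rows <- lapply(seq_len(n), function(i) {
      out <- nn_identify_row(v[i, -i], corpus$genus[-i], corpus$species[-i],
                             corpus$genus[i], corpus$species[i], rank,
                             criterion,
                             threshold = threshold, rel_tol = rel_tol)
      cbind(data.frame(query_id = corpus$record_id[i],
                       stringsAsFactors = FALSE), out)
    })
  }
  per_query <- do.call(rbind, rows)
  per_query$genus <- corpus$genus
  per_query$species <- corpus$species
  per_query$singleton <- !(sp %in% sp[duplicated(sp)])
  used <- if (exclude_singletons) per_query[!per_query$singleton, ]
  else per_query
  nq <- nrow(used)
  pct <- function(cat) 100 * sum(used$category == cat) / nq
  report <- structure(
    list(criterion = criterion, rank = rank, n_queries = nq,
         pct_correct = pct("CORRECT"),
         pct_ambiguous = pct("AMBIGUOUS"),
         pct_incorrect = pct("INCORRECT"),
         pct_no_match = pct("NO_MATCH")),
    class = "identification_report")
  list(report = report, per_query = per_query)
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("%s at %s rank (%d queries)\n", x$criterion, x$rank,
              x$n_queries))
  cat(sprintf("  correct %.2f%%  ambiguous %.2f%%  incorrect %.2f%%  no match %.2f%%\n",
              x$pct_correct, x$pct_ambiguous, x$pct_incorrect,
              x$pct_no_match))
  invisible(x)
}

report_as_df <- function(report) {
  data.frame(criterion = report$criterion, rank = report$rank,
             n_queries = report$n_queries,
             pct_correct = report$pct_correct,
             pct_ambiguous = report$pct_ambiguous,
             pct_incorrect = report$pct_incorrect,
             pct_no_match = report$pct_no_match,
             stringsAsFactors = FALSE)
}

#' Per-genus identification failure rates
#'
#' For every genus with at least `min_species` species among the queries,
#' reports its species count, sample count and the percentage of queries
#' that were not CORRECT ("unidentified" in the broad sense).
#'
#' @param per_query per-query table from [identify_corpus()].
#' @param min_species minimum number of species for a genus to be listed
#'   (default 20).
#' @return data frame: `genus`, `n_species`, `n_samples`,
#'   `pct_unidentified` (numeric percentage, 2-decimal precision).
#' @export
per_genus_report <- function(per_query, min_species = 20) {
  stopifnot(min_species >= 1)
  out <- lapply(split(per_query, per_query$genus), function(d) {
    data.frame(genus = d$genus[1],
               n_species = length(unique(d$species)),
               n_samples = nrow(d),
               pct_unidentified = round(100 * mean(d$category != "CORRECT"),
                                        2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_species >= min_species, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$genus), , drop = FALSE]
}
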