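#' Barcode corpus
#'
#' A corpus is an ordered collection of taxon records: one DNA sequence per
#' record together with its genus and species labels and a region tag
#' (`ITS_FULL`, `ITS1`, `R5_8S`, `ITS2` or `UNKNOWN`).  Internally it is a
#' data frame with columns `record_id`, `genus`, `species`, `sequence`,
#' `region`, in ingest order, with unique record ids.
#'
#' Sequences are stored uppercase with `U` normalized to `T`; the permitted
#' alphabet is the IUPAC nucleotide codes plus `-`.
#'
#' @param records data frame with columns `record_id`, `genus`, `species`,
#'   `sequence` and optionally `region`.
#' @return An object of class `barcode_corpus` (a data frame).
#' @export
new_corpus <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("record_id", "genus", "species", "sequence")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(records$region)) records$region <- "UNKNOWN"
  records <- records[, c("record_id", "genus", "species", "sequence", "region")]
  records$record_id <- as.character(records$record_id)
  records$genus <- as.character(records$genus)
  records$species <- as.character(records$species)
  records$sequence <- normalize_sequence(as.character(records$sequence))
  records$region <- as.character(records$region)
  bad_region <- !records$region %in% c("UNKNOWN", "ITS_FULL", "ITS1",
                                       "R5_8S", "ITS2")
  if (any(bad_region)) {
    stop("invalid region tag: ",
         paste(unique(records$region[bad_region]), collapse = ", "))
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    stop("duplicate record_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for record: ",
         paste(records$record_id[!nzchar(records$sequence)], collapse = ", "))
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", records$sequence)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence of record: ",
         paste(records$record_id[bad], collapse = ", "))
  }
  rownames(records) <- NULL
  class(records) <- c("barcode_corpus", "data.frame")
  records
}

#' Normalize a nucleotide string
#'
#' Uppercases and converts RNA `U` to `T`.  Used on every ingest path.
#' @param x character vector of sequences.
#' @return normalized character vector.
#' @export
normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

#' @export
print.barcode_corpus <- function(x, ...) {
  cat(sprintf("<barcode_corpus> %d records, %d genera, %d species\n",
              nrow(x), length(unique(x$genus)),
              length(unique(paste(x$genus, x$species)))))
  print.data.frame(utils::head(as.data.frame(x), 6),
                   row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more records\n", nrow(x) - 6))
  invisible(x)
}

species_key <- function(corpus) paste(corpus$genus, corpus$species, sep = " ")

#' Read a corpus from FASTA plus a taxonomy table
#'
#' Sequences come from a (multi-record, wrapped or unwrapped) FASTA file and
#' taxonomy from a sidecar TSV with header `record_id`, `genus`, `species`.
#' Taxonomy deliberately travels in a sidecar table rather than being parsed
#' out of FASTA description lines, whose formats are inconsistent across
#' databases; `parse_descriptions = TRUE` enables a fallback that takes the
#' first two words of the description as "Genus epithet".
#'
#' @param fasta_path path to the FASTA file.
#' @param taxonomy_path path to the taxonomy TSV (ignored when
#'   `parse_descriptions = TRUE` and `taxonomy_path` is `NULL`).
#' @param parse_descriptions fall back to parsing "Genus species" from the
#'   FASTA description line (off by default).
#' @param region region tag to assign to every record.
#' @return a [new_corpus()] object, in FASTA order.
#' @export
read_corpus <- function(fasta_path, taxonomy_path = NULL,
                        parse_descriptions = FALSE, region = "UNKNOWN") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (parse_descriptions && is.null(taxonomy_path)) {
    desc <- sub("^\\S+\\s*", "", headers)
    words <- strsplit(desc, "\\s+")
    genus <- vapply(words, function(w) if (length(w) >= 1) w[[1]] else "", "")
    species <- vapply(words, function(w) if (length(w) >= 2) w[[2]] else "", "")
    tax <- data.frame(record_id = ids, genus = genus, species = species,
                      stringsAsFactors = FALSE)
  } else {
    tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("record_id", "genus", "species")
    if (!all(need %in% names(tax))) {
      stop("taxonomy table must have columns record_id, genus, species")
    }
    missing_ids <- setdiff(ids, tax$record_id)
    if (length(missing_ids) > 0) {
      stop("records absent from taxonomy table: ",
           paste(missing_ids, collapse = ", "))
    }
    tax <- tax[match(ids, tax$record_id), ]
  }
  new_corpus(data.frame(record_id = ids,
                        genus = tax$genus,
                        species = tax$species,
                        sequence = as.character(seqs),
                        region = region,
                        stringsAsFactors = FALSE))
}

#' Write a corpus as FASTA plus taxonomy TSV
#'
#' @param corpus a `barcode_corpus`.
#' @param fasta_path output FASTA path (unwrapped, one line per sequence).
#' @param taxonomy_path output taxonomy TSV path (optional).
#' @return invisibly, the corpus.
#' @export
write_corpus <- function(corpus, fasta_path, taxonomy_path = NULL) {
  x <- Biostrings::BStringSet(setNames(corpus$sequence, corpus$record_id))
  Biostrings::writeXStringSet(x, fasta_path, width = 20000L)
  if (!is.null(taxonomy_path)) {
    write.table(corpus[, c("record_id", "genus", "species")],
                taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(corpus)
}

#' Curate a corpus
#'
#' Applies the pre-analysis filters: sequences shorter than `min_length_bp`
#' are removed, as are records lacking a genus or species label.  The
#' returned report partitions the input counts exactly.
#'
#' @param corpus a `barcode_corpus`.
#' @param min_length_bp minimum sequence length kept (default 100).
#' @return list with elements `corpus` (filtered) and `report` (class
#'   `curation_report`: n_input, n_removed_short, n_removed_unlabelled,
#'   n_kept, min_length_bp).
#' @export
curate <- function(corpus, min_length_bp = 100) {
  stopifnot(min_length_bp >= 1)
  len <- nchar(corpus$sequence)
  unlabelled <- !nzchar(trimws(corpus$genus)) | !nzchar(trimws(corpus$species))
  short <- !unlabelled & len < min_length_bp
  keep <- !unlabelled & !short
  report <- structure(
    list(n_input = nrow(corpus),
         n_removed_short = sum(short),
         n_removed_unlabelled = sum(unlabelled),
         n_kept = sum(keep),
         min_length_bp = min_length_bp),
    class = "curation_report")
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(corpus)
  list(corpus = out, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(paste0("Curation: %d records in; %d removed (<%d bp), ",
                     "%d unlabelled; %d kept\n"),
              x$n_input, x$n_removed_short, x$min_length_bp,
              x$n_removed_unlabelled, x$n_kept))
  invisible(x)
}

#' Serialize a curation report as TSV
#' @param report a `curation_report`.
#' @param path output path.
#' @export
write_curation_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Summarize a corpus
#'
#' @param corpus a non-empty `barcode_corpus`.
#' @return data frame with one row: `samples`, `genera`, `species`,
#'   `mean_length` (1 decimal).
#' @export
corpus_summary <- function(corpus) {
  if (nrow(corpus) == 0) stop("corpus is empty")
  data.frame(samples = nrow(corpus),
             genera = length(unique(corpus$genus)),
             species = length(unique(species_key(corpus))),
             mean_length = round(mean(nchar(corpus$sequence)), 1))
}
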