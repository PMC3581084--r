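#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end barcode evaluation:
#' curation, region annotation/excision, distance computation, divergence
#' summaries with the paired locus comparison, and the identification
#' reports.  Input is either a FASTA + taxonomy pair or a
#' [simulation_config()].
#'
#' @param input_fasta,input_taxonomy paths to input sequences and
#'   taxonomy (mutually exclusive with `sim`).
#' @param sim a [simulation_config()]; when given, the corpus is
#'   simulated.
#' @param region_mode `"BOTH"` (full ITS and excised ITS2, with the locus
#'   comparison), `"FULL_ITS"` or `"ITS2"`.
#' @param divergence_model distance model for the divergence summaries
#'   (`"K2P"` default).
#' @param identify_model distance model for the nearest-neighbour
#'   identification criteria (`"p"` default).
#' @param criteria identification criteria to run.
#' @param threshold best-close-match distance threshold.
#' @param min_length_bp curation length filter.
#' @param min_species_per_genus genus filter of the per-genus report.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (the simulation seed
#'   comes from `sim$seed`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_fasta = NULL, input_taxonomy = NULL,
                            sim = NULL,
                            region_mode = c("BOTH", "FULL_ITS", "ITS2"),
                            divergence_model = "K2P",
                            identify_model = "p",
                            criteria = c("BEST_HIT", "BEST_MATCH",
                                         "BEST_CLOSE_MATCH"),
                            threshold = 0.03,
                            min_length_bp = 100,
                            min_species_per_genus = 20,
                            out_dir = "minibarcode_run",
                            seed = 1) {
  region_mode <- match.arg(region_mode)
  if (is.null(sim) && (is.null(input_fasta) || is.null(input_taxonomy))) {
    stop("provide either sim or input_fasta + input_taxonomy")
  }
  stopifnot(threshold > 0, threshold < 1)
  structure(list(input_fasta = input_fasta,
                 input_taxonomy = input_taxonomy,
                 sim = sim,
                 region_mode = region_mode,
                 divergence_model = divergence_model,
                 identify_model = identify_model,
                 criteria = match.arg(criteria,
                                      c("BEST_HIT", "BEST_MATCH",
                                        "BEST_CLOSE_MATCH"),
                                      several.ok = TRUE),
                 threshold = threshold,
                 min_length_bp = min_length_bp,
                 min_species_per_genus = min_species_per_genus,
                 out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL          # the hash identifies the analysis, not where it lands
  rlang::hash(x)
}

run_region <- function(corpus, region_label, config, out_dir) {
  tag <- tolower(region_label)
  write_corpus(corpus, file.path(out_dir, paste0(tag, ".fasta")),
               file.path(out_dir, paste0(tag, ".taxonomy.tsv")))
  counts <- pairwise_counts(corpus)
  dm_div <- distance_matrix(corpus, model = config$divergence_model,
                            counts = counts)
  dm_id <- if (config$identify_model == config$divergence_model) dm_div
  else distance_matrix(corpus, model = config$identify_model,
                       counts = counts)
  write_dist_matrix(dm_div, file.path(out_dir,
                                      paste0(tag, ".dist.",
                                             tolower(dm_div$model), ".tsv")))
  div <- divergence_summary(dm_div, corpus)
  write_divergence_summary(div, file.path(out_dir,
                                          paste0(tag, ".divergence.tsv")))
  reports <- list(); per_query <- list()
  for (crit in config$criteria) {
    for (rank in c("species", "genus")) {
      res <- identify_corpus(corpus, criterion = crit, rank = rank,
                             dm = dm_id, threshold = config$threshold)
      key <- paste(crit, rank, sep = ".")
      reports[[key]] <- res$report
      per_query[[key]] <- res$per_query
    }
  }
  rep_df <- do.call(rbind, lapply(reports, report_as_df))
  rownames(rep_df) <- NULL
  write.table(rep_df, file.path(out_dir, paste0(tag, ".identification.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pq_species <- per_query[[grep("\\.species$", names(per_query))[1]]]
  genus_rep <- per_genus_report(pq_species,
                                min_species = config$min_species_per_genus)
  if (nrow(genus_rep) > 0) {
    write.table(genus_rep,
                file.path(out_dir, paste0(tag, ".per_genus.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(corpus = corpus, dm_div = dm_div, dm_id = dm_id,
       divergence = div, reports = rep_df, per_query = per_query,
       per_genus = genus_rep)
}

#' Run the whole barcode-evaluation pipeline
#'
#' Stages: obtain the corpus (simulate or read), curate, annotate and
#' excise regions as required by the region mode, compute distance
#' matrices, summarize divergences, compare the two loci by paired
#' Wilcoxon tests (BOTH mode) and produce the identification reports.
#' All outputs are written as TSV/FASTA under `config$out_dir` together
#' with a JSON manifest carrying the config hash; re-running with the
#' same config produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results: `curation`,
#'   `annotation`, per-region results (`full_its`, `its2`), `wilcoxon`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$sim)) {
    simres <- simulate_corpus(config$sim)
    corpus0 <- simres$corpus
    write_truth(simres$truth, file.path(out_dir, "truth.tsv"))
  } else {
    corpus0 <- read_corpus(config$input_fasta, config$input_taxonomy)
  }

  cur <- curate(corpus0, config$min_length_bp)
  write_curation_report(cur$report, file.path(out_dir, "curation.tsv"))
  corpus <- cur$corpus
  if (nrow(corpus) < 2) stop("stage curate: fewer than 2 records kept")

  profiles <- reference_profiles()
  ann_its2 <- NULL; ann <- NULL
  regions <- list()
  if (config$region_mode %in% c("BOTH", "ITS2")) {
    ann_its2 <- annotate_corpus(corpus, profiles, region = "ITS2")
    ann <- ann_its2$annotation
    if (nrow(ann_its2$corpus) < 2) {
      stop("stage annotate: fewer than 2 records annotated ",
           "(statuses: ", paste(unique(ann$status), collapse = ", "), ")")
    }
    regions$its2 <- ann_its2$corpus
  }
  if (config$region_mode %in% c("BOTH", "FULL_ITS")) {
    ann_full <- annotate_corpus(corpus, profiles, region = "ITS_FULL")
    if (is.null(ann)) ann <- ann_full$annotation
    if (nrow(ann_full$corpus) < 2) {
      stop("stage annotate: fewer than 2 records annotated ",
           "(statuses: ",
           paste(unique(ann_full$annotation$status), collapse = ", "), ")")
    }
    regions$full_its <- ann_full$corpus
  }
  write_annotation(ann, file.path(out_dir, "annotation.tsv"))

  if (config$region_mode == "BOTH") {
    shared <- intersect(regions$full_its$record_id, regions$its2$record_id)
    regions <- lapply(regions, function(cc) {
      out <- cc[cc$record_id %in% shared, , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- class(cc)
      out
    })
  }

  results <- list()
  for (nm in names(regions)) {
    results[[nm]] <- run_region(regions[[nm]],
                                if (nm == "its2") "ITS2" else "FULL_ITS",
                                config, out_dir)
  }

  wilcoxon <- NULL
  comparison <- NULL
  if (config$region_mode == "BOTH") {
    wilcoxon <- compare_loci(results$full_its$dm_div, results$its2$dm_div,
                             results$its2$corpus)
    wdf <- do.call(rbind, lapply(names(wilcoxon), function(cl) {
      w <- wilcoxon[[cl]]
      data.frame(divergence_class = cl, w_plus = w$w_plus,
                 w_minus = w$w_minus, n = w$n, p_value = w$p_value,
                 direction = c(A_GT_B = "FULL_ITS > ITS2",
                               B_GT_A = "ITS2 > FULL_ITS",
                               NONE = "NONE")[w$direction],
                 stringsAsFactors = FALSE)
    }))
    write.table(wdf, file.path(out_dir, "wilcoxon.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    comparison <- compare_regions_report(results$full_its, results$its2,
                                         wilcoxon)
    write.table(comparison, file.path(out_dir, "locus_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("minibarcode")),
    config = unclass(config)[c("region_mode", "divergence_model",
                               "identify_model", "criteria", "threshold",
                               "min_length_bp", "min_species_per_genus",
                               "seed")],
    simulated = !is.null(config$sim),
    config_hash = config_hash(config),
    n_input = cur$report$n_input,
    n_kept = cur$report$n_kept,
    regions = names(regions),
    n_records_analyzed = vapply(regions, nrow, 0L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(curation = cur$report, annotation = ann,
                 full_its = results$full_its, its2 = results$its2,
                 wilcoxon = wilcoxon, comparison = comparison,
                 manifest = manifest))
}

#' Side-by-side locus comparison table
#'
#' Juxtaposes the six divergence parameters, the Wilcoxon directions and
#' the identification percentages of two pipeline region runs.
#'
#' @param full_res,its2_res per-region result lists from a
#'   [run_pipeline()] BOTH run (or built manually with matching record
#'   sets).
#' @param wilcoxon optional result of [compare_loci()].
#' @return data frame with columns `quantity`, `FULL_ITS`, `ITS2`.
#' @export
compare_regions_report <- function(full_res, its2_res, wilcoxon = NULL) {
  if (!setequal(full_res$corpus$record_id, its2_res$corpus$record_id)) {
    stop("record sets of the two region runs differ")
  }
  rows <- data.frame(
    quantity = full_res$divergence$components$parameter,
    FULL_ITS = full_res$divergence$components$mean,
    ITS2 = its2_res$divergence$components$mean,
    stringsAsFactors = FALSE)
  fr <- full_res$reports; ir <- its2_res$reports
  key <- paste(fr$criterion, fr$rank, sep = ".")
  id_rows <- data.frame(
    quantity = paste0("pct_correct.", key),
    FULL_ITS = fr$pct_correct,
    ITS2 = ir$pct_correct[match(key, paste(ir$criterion, ir$rank,
                                           sep = "."))],
    stringsAsFactors = FALSE)
  out <- rbind(rows, id_rows)
  if (!is.null(wilcoxon)) {
    lab <- function(w) c(A_GT_B = "FULL_ITS > ITS2",
                         B_GT_A = "ITS2 > FULL_ITS",
                         NONE = "NONE")[w$direction]
    out <- rbind(out, data.frame(
      quantity = c("wilcoxon_direction.inter", "wilcoxon_direction.intra"),
      FULL_ITS = c(lab(wilcoxon$inter), lab(wilcoxon$intra)),
      ITS2 = c(sprintf("p=%.3g", wilcoxon$inter$p_value),
               sprintf("p=%.3g", wilcoxon$intra$p_value)),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
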