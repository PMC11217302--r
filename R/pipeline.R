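# Pipeline orchestration: spectra -> peptide predictions -> contigs ->
# protein report, with file-based stage handoff (each stage's outputs are
# plain TSV read by the next), a YAML configuration and a JSON run
# manifest recording seeds, hashes and per-stage counts.

.PIPELINE_DEFAULTS <- list(
  stages = c("denovo", "assemble", "infer"),
  rescorer_checkpoint = NULL,
  fasta = NULL,
  seed = 1L,
  beam_width = 5L,
  mass_tolerance = 0.1,
  knapsack_resolution = 1e-4,
  refine_quantile = 0.1,
  kmer = 7L,
  collapse_il = TRUE,
  top_contigs = 20L,
  search_k = 5L,
  identity_threshold = 0.8,
  max_rejects = 8L)

.PIPELINE_KEYS <- c("spectra", "denovo_checkpoint", "output_dir",
                    names(.PIPELINE_DEFAULTS))

#' Pipeline configuration
#'
#' Assemble (or read from YAML) the configuration driving
#' \code{\link{run_pipeline}}. Unknown keys are a validation error
#' naming the key; missing optional keys take documented defaults.
#' Configurations round-trip unchanged through
#' \code{\link{write_pipeline_config}} / \code{read_pipeline_config}.
#'
#' @param spectra path to an MGF or mzML file
#' @param denovo_checkpoint path to a \code{denovo_model} checkpoint
#' @param output_dir run output directory
#' @param ... optional keys: \code{stages} (subset of denovo, assemble,
#'   infer), \code{rescorer_checkpoint}, \code{fasta} (required for the
#'   infer stage), \code{seed}, \code{beam_width},
#'   \code{mass_tolerance}, \code{knapsack_resolution},
#'   \code{refine_quantile}, \code{kmer}, \code{collapse_il},
#'   \code{top_contigs}, \code{search_k}, \code{identity_threshold},
#'   \code{max_rejects}
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(spectra, denovo_checkpoint, output_dir, ...) {
  extra <- list(...)
  bad <- setdiff(names(extra), .PIPELINE_KEYS)
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, extra)
  cfg$spectra <- spectra
  cfg$denovo_checkpoint <- denovo_checkpoint
  cfg$output_dir <- output_dir
  # drop NULL-valued optional keys so configs round-trip through YAML
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  req <- c("spectra", "denovo_checkpoint", "output_dir")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("pipeline config missing required key(s): ",
         paste(miss, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks stage names and that every referenced input file exists.
#' @param config a \code{pipeline_config}
#' @return the config, invisibly (errors otherwise)
#' @export
validate_pipeline_config <- function(config) {
  bad <- setdiff(config$stages, c("denovo", "assemble", "infer"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (key in c("spectra", "denovo_checkpoint", "rescorer_checkpoint",
                "fasta")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("pipeline config key '", key, "' points to a missing file: ", p)
  }
  if ("infer" %in% config$stages && is.null(config$fasta))
    stop("the infer stage requires a 'fasta' database path")
  invisible(config)
}

read_spectra_auto <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) read_mzml(path)
  else read_mgf(path)
}

#' Run the sequencing pipeline
#'
#' Executes the configured stages in order. Each stage writes its
#' output table into the run directory and the next stage reads it back
#' from file, so any stage can be re-run or inspected in isolation. A
#' manifest (JSON) records the configuration hash, seed, checkpoint
#' hashes and per-stage counts; reruns with the same configuration and
#' seed are identical. On stage failure, outputs of completed stages
#' and a partial manifest are preserved before the error propagates.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param quiet suppress progress messages
#' @return invisible list: paths of written outputs and per-stage counts
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = logf,
        append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  paths <- list()
  counts <- list()
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    checkpoints = list())
  flush_manifest <- function() {
    jsonlite::write_json(c(manifest, list(counts = counts)),
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(flush_manifest())
  set.seed(config$seed)

  if ("denovo" %in% config$stages) {
    say("stage denovo: reading %s", config$spectra)
    spectra <- read_spectra_auto(config$spectra)
    counts$spectra <- length(spectra)
    model <- load_checkpoint(config$denovo_checkpoint)
    manifest$checkpoints$denovo <-
      unname(tools::md5sum(config$denovo_checkpoint))
    rescorer <- NULL
    if (!is.null(config$rescorer_checkpoint)) {
      rescorer <- load_checkpoint(config$rescorer_checkpoint)
      manifest$checkpoints$rescorer <-
        unname(tools::md5sum(config$rescorer_checkpoint))
    }
    mm <- max(vapply(spectra, function(s) s$precursor_neutral_mass,
                     numeric(1))) - MASS_WATER + 1
    knap <- build_knapsack(model$config$vocab,
                           resolution = config$knapsack_resolution,
                           max_mass = mm)
    preds <- predict(model, spectra, knapsack = knap,
                     beam_width = config$beam_width,
                     tolerance = config$mass_tolerance,
                     rescorer = rescorer,
                     refine_quantile = config$refine_quantile)
    paths$predictions <- file.path(config$output_dir, "predictions.tsv")
    write_predictions(preds, paths$predictions)
    counts$predictions <- sum(nzchar(preds$peptide))
    say("stage denovo: %d/%d spectra predicted", counts$predictions,
        counts$spectra)
  }

  if ("assemble" %in% config$stages) {
    src <- file.path(config$output_dir, "predictions.tsv")
    if (!file.exists(src)) stop("assemble stage: missing ", src)
    preds <- read_predictions(src)
    keep <- nzchar(preds$peptide)
    say("stage assemble: %d peptides, k = %d", sum(keep), config$kmer)
    gr <- build_graph(preds$peptide[keep], preds$residue_scores[keep],
                      k = config$kmer, ids = preds$spectrum_id[keep],
                      collapse_il = config$collapse_il)
    contigs <- extract_contigs(gr, top_n = config$top_contigs)
    contigs <- cbind(contig_id = sprintf("ctg%04d", seq_len(nrow(contigs))),
                     contigs)
    paths$contigs <- file.path(config$output_dir, "contigs.tsv")
    write_contigs(contigs, paths$contigs)
    counts$contigs <- nrow(contigs)
    say("stage assemble: %d contigs", counts$contigs)
  }

  if ("infer" %in% config$stages) {
    src <- file.path(config$output_dir, "contigs.tsv")
    if (!file.exists(src)) stop("infer stage: missing ", src)
    contigs <- read_contigs(src)
    db <- read_fasta(config$fasta)
    say("stage infer: %d contigs vs %d proteins", nrow(contigs), nrow(db))
    hit_rows <- list()
    for (i in seq_len(nrow(contigs))) {
      if (nchar(contigs$contig[i]) < config$search_k) next
      cand <- search_candidates(contigs$contig[i], db, k = config$search_k,
                                identity_threshold = config$identity_threshold,
                                max_rejects = config$max_rejects)
      hits <- cand[cand$status == "hit", , drop = FALSE]
      if (nrow(hits))
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(contig = contigs$contig_id[i],
                     accession = hits$accession)
    }
    if (length(hit_rows)) {
      hits <- do.call(rbind, hit_rows)
      scores <- stats::setNames(contigs$score, contigs$contig_id)
      assignments <- infer_proteins(hits, scores)
      cs <- stats::setNames(contigs$contig, contigs$contig_id)
      report <- protein_report(assignments, cs, db,
                               identity_threshold = config$identity_threshold)
    } else {
      report <- data.frame(accession = character(0), n_contigs = integer(0),
                           longest = integer(0), longest_pct = numeric(0),
                           coverage_pct = numeric(0),
                           accuracy_pct = numeric(0), score = numeric(0),
                           subset_of = character(0))
    }
    paths$proteins <- file.path(config$output_dir, "proteins.tsv")
    write_protein_report(report, paths$proteins)
    counts$proteins <- nrow(report)
    say("stage infer: %d proteins reported", counts$proteins)
  }

  flush_manifest()
  paths$manifest <- file.path(config$output_dir, "manifest.json")
  paths$log <- logf
  invisible(list(paths = paths, counts = counts))
}

#' Evaluate predictions against ground truth
#'
#' Convenience wrapper over \code{\link{match_residues}} /
#' \code{\link{corpus_metrics}} / \code{\link{pr_curve}} for a
#' prediction table and a truth table keyed by spectrum id.
#'
#' @param predictions data.frame with spectrum_id, peptide, confidence
#' @param truth named character vector: spectrum_id -> true peptide
#' @param vocab a \code{\link{residue_vocab}}
#' @param residue_tol,prefix_tol matching tolerances (Da)
#' @return list: \code{metrics} (named vector), \code{curve}
#'   (data.frame), \code{matches} (per-spectrum results)
#' @export
evaluate_predictions <- function(predictions, truth, vocab,
                                 residue_tol = 0.1, prefix_tol = 0.5) {
  ids <- names(truth)
  res <- vector("list", length(ids))
  conf <- numeric(length(ids))
  for (i in seq_along(ids)) {
    row <- match(ids[i], predictions$spectrum_id)
    pred <- if (is.na(row)) "" else predictions$peptide[row]
    conf[i] <- if (is.na(row)) NA_real_ else predictions$confidence[row]
    res[[i]] <- match_residues(pred, truth[[i]], vocab,
                               residue_tol = residue_tol,
                               prefix_tol = prefix_tol)
  }
  emitted <- !is.na(conf)
  correct <- vapply(res, `[[`, logical(1), "peptide_match")
  list(metrics = corpus_metrics(res),
       curve = pr_curve(conf[emitted], correct[emitted],
                        n_total = length(ids)),
       matches = res)
}
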