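# Orchestration: one call runs simulate -> classify (built-in k-mer LCA
# classifier, simulated classifier output, or ingested Kraken-dialect
# output) -> evaluate -> abundance, persists every stage's outputs, and
# assembles a machine-readable benchmark report.

#' Pipeline configuration
#'
#' All parameters of a benchmark run. Unknown arguments are a hard error.
#'
#' @param community A [community_config()].
#' @param classifier_mode `"kmer"` (built-in k-mer LCA classifier),
#'   `"simulate"` (inject errors via [simulate_classifier_output()]), or
#'   `"ingest"` (read an existing Kraken-dialect output file).
#' @param k K-mer size for `"kmer"` mode.
#' @param error An [error_spec()] for `"simulate"` mode.
#' @param kraken_output_path Input path for `"ingest"` mode.
#' @param ranks Canonical ranks to evaluate.
#' @param top_n Size of the most-abundant-taxa comparison tables.
#' @param seed Global seed; stage seeds are derived from it.
#' @param outdir Output directory (created if needed). `NULL` keeps
#'   everything in memory and writes nothing.
#' @param emit_map Fill the per-k-mer LCA-map column of the output file
#'   (`"kmer"` mode).
#' @param ... Unknown keys: hard error.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(community = community_config(),
                            classifier_mode = c("kmer", "simulate", "ingest"),
                            k = 21L,
                            error = error_spec(),
                            kraken_output_path = NULL,
                            ranks = c("phylum", "family", "genus", "species"),
                            top_n = 10L,
                            seed = community$seed,
                            outdir = NULL,
                            emit_map = TRUE,
                            ...) {
  dots <- list(...)
  if (length(dots)) {
    stop("unknown pipeline_config key(s): ", paste(names(dots), collapse = ", "))
  }
  classifier_mode <- match.arg(classifier_mode)
  stopifnot(inherits(community, "community_config"))
  if (classifier_mode == "simulate") stopifnot(inherits(error, "error_spec"))
  if (classifier_mode == "ingest" && is.null(kraken_output_path)) {
    stop("classifier_mode = 'ingest' requires kraken_output_path")
  }
  structure(list(community = community, classifier_mode = classifier_mode,
                 k = as.integer(k), error = error,
                 kraken_output_path = kraken_output_path,
                 ranks = ranks, top_n = as.integer(top_n),
                 seed = as.integer(seed), outdir = outdir,
                 emit_map = isTRUE(emit_map)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full benchmark pipeline
#'
#' Simulates a community and its reads, obtains a classification (per the
#' configured mode), evaluates it per rank against the ground truth, builds
#' the abundance comparisons, and — when `outdir` is set — persists every
#' stage's output (taxdump pair, genome FASTA, paired FASTQ, truth TSV,
#' Kraken-dialect output, report file, evaluation tables, JSON report).
#' A rerun with the same config and seed reproduces every file byte for
#' byte.
#'
#' @param config A [pipeline_config()].
#'
#' @return An object of class `benchmark_report`: list with `evaluation`
#'   (an `evaluation_summary`), `concordance` and `taxon_comparison` and
#'   `top_n` (one entry per rank), `truth`, `classification`, `db`,
#'   `genome_taxids`, `files` (paths written), and a `provenance` block.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$community
  seed <- config$seed
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  fp <- function(x) if (is.null(outdir)) NULL else file.path(outdir, x)
  files <- character(0)

  tax <- .stage("simulate-taxonomy", generate_taxonomy(cc, seed = seed))
  db <- tax$db
  genomes <- .stage("simulate-genomes",
                    generate_genomes(db, tax$genome_taxids, cc, seed = seed + 1L))
  sim <- .stage("simulate-reads", simulate_reads(genomes, db, cc, seed = seed + 2L))

  if (!is.null(outdir)) {
    write_taxdump(db, fp("nodes.dmp"), fp("names.dmp"))
    Biostrings::writeXStringSet(genomes, fp("genomes.fasta"), width = 80L)
    write_fastq(sim$r1, fp("reads_R1.fastq"))
    write_fastq(sim$r2, fp("reads_R2.fastq"))
    write_truth(sim$truth, fp("truth.tsv"))
    files <- c(files, fp(c("nodes.dmp", "names.dmp", "genomes.fasta",
                           "reads_R1.fastq", "reads_R2.fastq", "truth.tsv")))
  }

  classification <- .stage("classify", switch(
    config$classifier_mode,
    kmer = {
      index <- build_kmer_index(genomes, db, k = config$k)
      classify_reads(index, sim$r1, sim$r2, emit_map = config$emit_map)
    },
    simulate = simulate_classifier_output(sim$truth, db, config$error,
                                          seed = seed + 3L),
    ingest = read_kraken_output(config$kraken_output_path)
  ))

  if (!is.null(outdir)) {
    write_kraken_output(classification, fp("classification.kraken"))
    write_kraken_report(classification, db, fp("report.txt"))
    files <- c(files, fp(c("classification.kraken", "report.txt")))
  }

  ev <- .stage("evaluate", evaluate(sim$truth, classification, db,
                                    ranks = config$ranks))

  conc <- list(); tsc <- list(); topn <- list()
  .stage("abundance", for (r in config$ranks) {
    at_truth <- abundance_table(sim$truth, db, r, source = "truth")
    at_cls <- abundance_table(classification, db, r, source = "classified")
    conc[[r]] <- concordance(at_truth, at_cls)
    tsc[[r]] <- taxon_set_comparison(at_truth, at_cls, r)
    topn[[r]] <- top_n_comparison(at_truth, at_cls, n = config$top_n)
  })

  report <- structure(list(
    evaluation = ev,
    concordance = conc,
    taxon_comparison = tsc,
    top_n = topn,
    truth = sim$truth,
    classification = classification,
    abundance = sim$abundance,
    db = db,
    genome_taxids = tax$genome_taxids,
    files = files,
    provenance = list(
      package = "taxbench",
      version = as.character(packageVersion("taxbench")),
      seed = seed,
      classifier_mode = config$classifier_mode,
      k = if (config$classifier_mode == "kmer") config$k else NA_integer_,
      community = unclass(cc),
      ranks = config$ranks)
  ), class = "benchmark_report")

  if (!is.null(outdir)) {
    write_evaluation_tsv(ev, fp("evaluation.tsv"))
    write_benchmark_report(report, fp("report.json"))
    report$files <- c(files, fp(c("evaluation.tsv", "report.json")))
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> seed ", x$provenance$seed, ", mode ",
      x$provenance$classifier_mode, "\n", sep = "")
  print(x$evaluation)
  for (r in names(x$concordance)) print(x$concordance[[r]])
  invisible(x)
}

#' Write the per-rank status table as TSV
#'
#' Three columns: rank, status, percent.
#'
#' @param ev An `evaluation_summary` from [evaluate()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_tsv <- function(ev, path) {
  data.table::fwrite(ev$status_pct, path, sep = "\t")
  invisible(path)
}

#' Serialise / reload a benchmark report as JSON
#'
#' The JSON carries the provenance block, the evaluation summary, and the
#' per-rank concordance, taxon-set and top-N tables — everything needed to
#' re-examine a run without its intermediate files. Writing is deterministic
#' (no timestamps), so identical runs give identical files.
#'
#' @param report A `benchmark_report` from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_benchmark_report <- function(report, path) {
  conc <- lapply(report$concordance, function(cr) {
    list(n_points = cr$n_points, insufficient_data = cr$insufficient_data,
         slope = cr$slope, intercept = cr$intercept,
         r_squared_ols = cr$r_squared_ols,
         r_squared_identity = cr$r_squared_identity)
  })
  tsc <- lapply(report$taxon_comparison, function(ts) {
    list(n_fp = ts$n_fp, n_fn = ts$n_fn,
         false_positive_taxa = ts$false_positive_taxa,
         false_negative_taxa = ts$false_negative_taxa)
  })
  obj <- list(
    provenance = report$provenance,
    n_reads = report$evaluation$n_reads,
    overall_classified_pct = report$evaluation$overall_classified_pct,
    status_pct = report$evaluation$status_pct,
    rank_rates = report$evaluation$rank_rates,
    concordance = conc,
    taxon_comparison = tsc,
    top_n = report$top_n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_benchmark_report
#' @return `read_benchmark_report()`: the report as a nested list.
#' @export
read_benchmark_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
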