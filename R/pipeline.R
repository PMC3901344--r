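# Pipeline orchestration: validated configuration and a single entry point
# running the stages simulate -> assemble -> annotate -> stretches ->
# compare -> fragstats, writing each stage's standard outputs plus a
# machine-readable summary.

.PIPELINE_STAGES <- c("simulate", "assemble", "annotate", "stretches",
                      "compare", "fragstats")

#' Pipeline configuration
#'
#' @param stages subset of `simulate`, `assemble`, `annotate`,
#'   `stretches`, `compare`, `fragstats`, run in that order.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing every stochastic stage.
#' @param simulation a [simulation_config()] for the simulate stage.
#' @param min_overlap,min_identity assembly parameters.
#' @param stretch_reps,stretch_revcomp shared-stretch scan parameters.
#' @param catalog_paths named character vector of two arrangement-catalog
#'   TSVs for the compare stage; defaults to the packaged Polyplax
#'   catalogs.
#' @param ... unknown keys are rejected.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = .PIPELINE_STAGES,
                            out_dir = tempfile("minichrom_run_"),
                            seed = 1L,
                            simulation = NULL,
                            min_overlap = 50, min_identity = 0.98,
                            stretch_reps = 200, stretch_revcomp = FALSE,
                            catalog_paths = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(simulation))
    simulation <- simulation_config(seed = seed)
  if (is.null(catalog_paths)) {
    catalog_paths <- c(
      a = system.file("extdata", "catalog_polyplax_asiatica.tsv",
                      package = "minichrom"),
      b = system.file("extdata", "catalog_polyplax_spinulosa.tsv",
                      package = "minichrom"))
  }
  structure(list(stages = stages, out_dir = out_dir,
                 seed = as.integer(seed), simulation = simulation,
                 min_overlap = min_overlap, min_identity = min_identity,
                 stretch_reps = stretch_reps,
                 stretch_revcomp = stretch_revcomp,
                 catalog_paths = catalog_paths),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # the hash describes the analysis, not its location
  txt <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's standard
#' outputs under `config$out_dir` and a machine-readable `summary.json`
#' with the headline counts (minichromosomes, genes, identical
#' minichromosomes, differing tRNAs, flagged stretch pairs, fragmentation
#' metrics). Progress and timings go to stderr; results never do. Every
#' output records the package version and a configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return the summary, invisibly (a list mirroring `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  log_stage <- function(stage, t0) {
    message(sprintf("[minichrom] %-10s %.1fs", stage,
                    as.numeric(Sys.time()) - t0))
  }
  summary <- list(
    tool = "minichrom",
    version = as.character(utils::packageVersion("minichrom")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = config$stages)
  sim <- NULL; contigs <- NULL; annotated <- NULL
  for (stage in .PIPELINE_STAGES) {
    if (!stage %in% config$stages) next
    t0 <- as.numeric(Sys.time())
    if (stage == "simulate") {
      sim <- generate_genome(config$simulation)
      write_genome_fasta(sim$genome, out("genome.fasta"))
      write_catalog(sim$truth$catalog, out("truth_catalog.tsv"))
      reads <- simulate_reads(sim$genome,
                              read_length = config$simulation$read_length,
                              coverage = config$simulation$coverage,
                              error_rate = config$simulation$error_rate,
                              seed = derive_seed(config$seed, 2),
                              region = "amplicon")
      write_reads_fastq(reads, out("reads.fastq"))
      summary$simulate <- list(
        n_minichromosomes = length(sim$genome$minichromosomes),
        n_genes = n_genes(sim$genome),
        n_reads = nrow(reads))
    } else if (stage == "assemble") {
      if (!file.exists(out("reads.fastq")))
        stop("assemble stage needs reads.fastq (run simulate first ",
             "or place reads in the output directory)")
      contigs <- assemble(out("reads.fastq"),
                          min_overlap = config$min_overlap,
                          min_identity = config$min_identity)
      write_contigs_fasta(contigs, out("contigs.fasta"))
      summary$assemble <- list(
        n_contigs = length(contigs),
        n_circular = sum(vapply(contigs, `[[`, TRUE, "circular")))
    } else if (stage == "annotate") {
      if (is.null(contigs)) stop("annotate stage needs assembled contigs")
      if (is.null(sim)) stop("annotate stage needs the simulated ",
                             "reference gene set")
      keep <- Filter(function(x) nchar(x$sequence) >= 500, contigs)
      annotated <- annotate_genome(keep, sim$truth$reference_genes)
      write_gff3(annotated, out("annotations.gff3"))
      write_catalog(genome_to_catalog(annotated),
                    out("assembled_catalog.tsv"))
      summary$annotate <- list(
        n_minichromosomes = length(annotated$minichromosomes),
        n_genes = n_genes(annotated),
        catalog_matches_truth = catalogs_equal(
          genome_to_catalog(annotated), sim$truth$catalog))
    } else if (stage == "stretches") {
      if (is.null(sim)) stop("stretches stage needs a simulated genome")
      rep_df <- scan_gene_pairs(sim, reps = config$stretch_reps,
                                seed = derive_seed(config$seed, 3),
                                search_revcomp = config$stretch_revcomp)
      write_stretch_report(rep_df, out("stretches.tsv"))
      summary$stretches <- list(n_pairs = nrow(rep_df),
                                n_flagged = sum(rep_df$flagged))
    } else if (stage == "compare") {
      cat_a <- load_catalog(config$catalog_paths[[1]])
      cat_b <- load_catalog(config$catalog_paths[[2]])
      cmp <- compare_catalogs(cat_a, cat_b)
      summary$compare <- list(
        species = c(cat_a$species, cat_b$species),
        n_minichromosomes = c(length(cat_a$entries),
                              length(cat_b$entries)),
        n_identical = cmp$n_identical,
        n_differing_trnas = cmp$n_differing_trnas,
        differing_trnas = cmp$differing_trnas)
      jsonlite::write_json(cmp, out("comparison.json"), auto_unbox = TRUE,
                           pretty = TRUE)
    } else if (stage == "fragstats") {
      cat_a <- load_catalog(config$catalog_paths[[1]])
      cat_b <- load_catalog(config$catalog_paths[[2]])
      frag <- rbind(genes_per_minichromosome(cat_a),
                    genes_per_minichromosome(cat_b))
      assoc_lc <- life_history_association(trait = "life_cycle")
      assoc_bl <- life_history_association(trait = "body_length")
      summary$fragstats <- list(
        genes_per_minichromosome = setNames(
          frag$genes_per_minichromosome, frag$species),
        life_cycle_spearman = assoc_lc$spearman_rho,
        life_cycle_concordant = assoc_lc$concordant_ordering,
        body_length_concordant = assoc_bl$concordant_ordering)
    }
    log_stage(stage, t0)
  }
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
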