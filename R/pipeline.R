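#' Configuration for an end-to-end pipeline run
#'
#' Collects every numeric default of the pipeline in one place: scaffold
#' filter 1500 nt, BBH threshold 60 bits, fragment ANI at 1020 nt / 30%
#' identity / 70% coverage, 500 subsets per curve point.
#'
#' @param genomes Either a genome-set tibble (see [read_genome()]), a
#'   simulation preset name (e.g. `"guyparkeria-like"`), or a `sim_config`.
#' @param reference Reference genome name; defaults to the first genome.
#' @param min_scaffold_len Scaffold length filter (nt).
#' @param min_bitscore BBH bit-score threshold.
#' @param frag_len,ani_min_id,ani_min_cov Fragment ANI parameters.
#' @param max_samples_per_n Development-curve sampling cap.
#' @param compute_ani Set `FALSE` to skip the (comparatively slow) ANI
#'   matrix.
#' @param seed RNG seed recorded in the manifest and used for simulation
#'   and subsampling.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genomes, reference = NULL,
                       min_scaffold_len = 1500, min_bitscore = 60,
                       frag_len = 1020, ani_min_id = 30, ani_min_cov = 0.70,
                       max_samples_per_n = 500, compute_ani = TRUE,
                       seed = 1, out_dir = tempfile("pancore_run_")) {
  structure(list(
    genomes = genomes, reference = reference,
    min_scaffold_len = min_scaffold_len, min_bitscore = min_bitscore,
    frag_len = frag_len, ani_min_id = ani_min_id, ani_min_cov = ani_min_cov,
    max_samples_per_n = max_samples_per_n, compute_ani = compute_ani,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full pangenome pipeline
#'
#' Executes scaffold filtering, genome summaries, ortholog-table
#' construction, core/accessory/singleton partitioning, the development
#' curve, Heaps'-law and exponential-decay fits, and the AAI (and
#' optionally ANI) matrix, writing fixed-name artifacts plus a JSON run
#' manifest into `config$out_dir` (fits are skipped, with a log line and
#' `null` entries in `fits.json`, when the set has fewer genomes than the
#' fit needs — 3 for Heaps, 4 for the decay): `summaries.tsv`, `orthologs.tsv`,
#' `partition.json`, `curve.tsv`, `curve_medians.tsv`, `fits.json`,
#' `aai.tsv`, `ani.tsv`, `manifest.json`. A rerun with the same
#' configuration and seed reproduces all numeric outputs exactly.
#'
#' @param config A [run_config()].
#' @return The manifest (a list), invisibly; its `results` element carries
#'   the in-memory objects (`summaries`, `table`, `partition`, `curve`,
#'   `heaps`, `decay`, `aai`, `ani`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  truth <- NULL
  genomes <- stage("input", {
    g <- config$genomes
    if (is.character(g) && length(g) == 1) {
      g <- sim_config_preset(g, seed = config$seed)
    }
    if (inherits(g, "sim_config")) {
      sim <- simulate_genome_set(g)
      truth <- sim$truth
      sim$genomes
    } else {
      check_genome_set(g)
      g
    }
  })
  genome_names <- unique(genomes$genome)
  reference <- config$reference %||% genome_names[1]
  if (!reference %in% genome_names) {
    abort(paste0("reference genome '", reference,
                 "' not in the genome set"))
  }

  log_stage <- function(...) inform(paste0("[pancore] ", sprintf(...)))

  genomes <- stage("filter", filter_scaffolds(genomes,
                                              config$min_scaffold_len))
  log_stage("filter: %d genomes, %d contigs kept",
            length(genome_names), sum(genomes$type == "contig"))

  summaries <- stage("summaries", summarize_genomes(genomes))
  write_summary_tsv(summaries, file.path(config$out_dir, "summaries.tsv"))
  log_stage("summaries: mean GC %.1f%%", mean(summaries$gc_percent))

  table <- stage("orthologs", build_ortholog_table(
    genomes, reference, min_bitscore = config$min_bitscore))
  write_ortholog_table(table, file.path(config$out_dir, "orthologs.tsv"))
  log_stage("orthologs: %d families", nrow(table))

  part <- stage("partition", partition_counts(table))
  jsonlite::write_json(as.list(part),
                       file.path(config$out_dir, "partition.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("partition: pan %d = core %d + accessory %d + singleton %d",
            part$pan, part$core, part$accessory, part$singleton)

  curve <- stage("development", pan_development(
    table, max_samples_per_n = config$max_samples_per_n,
    seed = config$seed))
  write_curve_tsv(curve, file.path(config$out_dir, "curve.tsv"),
                  file.path(config$out_dir, "curve_medians.tsv"))
  log_stage("development: %d subsets sampled", nrow(curve))

  G <- length(genome_names)
  heaps <- NULL; decay <- NULL
  if (G >= 3) {
    heaps <- stage("fit_heaps", fit_heaps(curve))
  } else {
    log_stage("fit_heaps skipped: needs >= 3 genomes, have %d", G)
  }
  if (G >= 4) {
    decay <- stage("fit_decay", fit_decay(curve))
  } else {
    log_stage("fit_decay skipped: needs >= 4 genomes, have %d", G)
  }
  jsonlite::write_json(
    list(heaps = if (is.null(heaps)) NULL else
           list(k = heaps$k, gamma = heaps$gamma, alpha = heaps$alpha,
                residual_ss = heaps$residual_ss,
                openness = classify_openness(heaps)),
         decay = if (is.null(decay)) NULL else
           list(k = decay$k, tau = decay$tau, tg_theta = decay$tg_theta,
                residual_ss = decay$residual_ss)),
    file.path(config$out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (!is.null(heaps) && !is.null(decay)) {
    log_stage("fits: gamma %.3f (alpha %.3f, %s), tau %.3f",
              heaps$gamma, heaps$alpha, classify_openness(heaps), decay$tau)
  }

  aai <- stage("aai", identity_matrix(genomes, "AAI",
                                      min_bitscore = config$min_bitscore))
  write_identity_tsv(aai, file.path(config$out_dir, "aai.tsv"))
  ani <- NULL
  if (isTRUE(config$compute_ani)) {
    ani <- stage("ani", identity_matrix(
      genomes, "ANI", frag_len = config$frag_len,
      min_id = config$ani_min_id, min_cov = config$ani_min_cov))
    write_identity_tsv(ani, file.path(config$out_dir, "ani.tsv"))
  }
  log_stage("identity: AAI%s computed",
            if (is.null(ani)) "" else " and ANI")

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "pancore",
    version = as.character(utils::packageVersion("pancore")),
    seed = config$seed,
    reference = reference,
    config_hash = rlang::hash(cfg_for_hash),
    config = cfg_for_hash[!vapply(cfg_for_hash, is.data.frame, logical(1))],
    counts = list(
      genomes = length(genome_names),
      contigs = sum(genomes$type == "contig"),
      proteins = sum(genomes$type == "protein"),
      families = nrow(table),
      partition = as.list(part),
      curve_subsets = nrow(curve)
    )
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$results <- list(summaries = summaries, table = table,
                           partition = part, curve = curve, heaps = heaps,
                           decay = decay, aai = aai, ani = ani,
                           truth = truth)
  invisible(manifest)
}
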