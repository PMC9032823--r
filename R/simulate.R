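#' Configuration for the synthetic genome-set generator
#'
#' The generator emulates a genus-level genome set with a star phylogeny: a
#' shared core gene pool, accessory families distributed over genome subsets,
#' and per-genome singletons. Each gene family has a random root protein and
#' a back-translated root CDS (plus a root intergenic spacer); every genome
#' carrying the family receives a copy with i.i.d. substitutions at half
#' the configured divergence, so the realized divergence *between any two
#' genomes* is the configured value: pairwise protein identity is about
#' `100 * (1 - aa_divergence)` and nucleotide identity about
#' `100 * (1 - nt_divergence)` — the quantities AAI and ANI recover.
#'
#' @param n_genomes Number of genomes G.
#' @param n_core Number of families present in all genomes.
#' @param accessory_spectrum Data frame with columns `occupancy` (m, between
#'   2 and G-1) and `n_families`, or `NULL` for none.
#' @param n_singletons Singleton families per genome: a scalar or a length-G
#'   vector (totals that do not divide evenly by G need the vector form).
#' @param protein_len Protein length in residues (fixed; the generator does
#'   not model length variation).
#' @param aa_divergence Expected pairwise per-site protein divergence
#'   between two genomes of the set, in `[0, 0.5)`; each genome's copy lies
#'   at `aa_divergence / 2` from the family root.
#' @param nt_divergence Same for the CDS (and spacer) nucleotide copy.
#' @param spacer_len Length of the intergenic spacer preceding each gene
#'   (nt); spacers are family-rooted and diverge like the CDS, as real
#'   intergenic DNA would between close genomes.
#' @param n_contigs Contigs per genome; genes are split into consecutive
#'   blocks.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return A `sim_config` list.
#' @seealso [simulate_genome_set()], [expected_counts()], [sim_config_preset()]
#' @export
sim_config <- function(n_genomes, n_core,
                       accessory_spectrum = NULL,
                       n_singletons = 0,
                       protein_len = 100,
                       aa_divergence = 0.02,
                       nt_divergence = 0.02,
                       spacer_len = 100,
                       n_contigs = 1,
                       seed = 1) {
  stopifnot(n_genomes >= 1, n_core >= 0, protein_len >= 1, spacer_len >= 0,
            n_contigs >= 1)
  if (aa_divergence < 0 || aa_divergence >= 0.5 ||
      nt_divergence < 0 || nt_divergence >= 0.5) {
    abort("divergences must lie in [0, 0.5)")
  }
  if (length(n_singletons) == 1L) {
    n_singletons <- rep(n_singletons, n_genomes)
  }
  if (length(n_singletons) != n_genomes || any(n_singletons < 0)) {
    abort("n_singletons must be a scalar or a length-G vector of counts >= 0")
  }
  if (!is.null(accessory_spectrum)) {
    accessory_spectrum <- as_tibble(accessory_spectrum)
    stopifnot(all(c("occupancy", "n_families") %in% names(accessory_spectrum)))
    if (any(accessory_spectrum$occupancy < 2 |
            accessory_spectrum$occupancy > n_genomes - 1)) {
      abort("accessory occupancies must lie in 2..G-1")
    }
    stopifnot(all(accessory_spectrum$n_families >= 0))
  }
  structure(list(
    n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
    accessory_spectrum = accessory_spectrum,
    n_singletons = as.integer(n_singletons),
    protein_len = as.integer(protein_len),
    aa_divergence = aa_divergence, nt_divergence = nt_divergence,
    spacer_len = as.integer(spacer_len), n_contigs = as.integer(n_contigs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Named simulation presets
#'
#' `"guyparkeria-like"` reproduces the partition structure of an
#' eight-genome *Guyparkeria*-type genome set — 1458 core families, 909
#' accessory families spread over occupancies 2..7, and 837 singletons
#' (105/105/105/105/105/104/104/104 per genome), a 3204-family pangenome —
#' at short protein length so full-scale family counts stay cheap to align.
#'
#' @param name Preset name (currently `"guyparkeria-like"`).
#' @param ... Overrides passed to [sim_config()] (e.g. `seed`,
#'   `aa_divergence`).
#' @return A `sim_config`.
#' @export
sim_config_preset <- function(name = "guyparkeria-like", ...) {
  if (!identical(name, "guyparkeria-like")) {
    abort(paste0("unknown preset: ", name))
  }
  defaults <- list(
    n_genomes = 8L, n_core = 1458L,
    accessory_spectrum = tibble(occupancy = 2:7,
                                n_families = c(152L, 152L, 152L, 151L, 151L, 151L)),
    n_singletons = c(105L, 105L, 105L, 105L, 105L, 104L, 104L, 104L),
    protein_len = 50L, aa_divergence = 0.02, nt_divergence = 0.02,
    spacer_len = 50L, n_contigs = 1L, seed = 1L
  )
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

#' Expected pangenome partition of a simulation configuration
#'
#' Pure arithmetic on the configuration; used as the ground-truth oracle for
#' the ortholog pipeline.
#'
#' @param config A `sim_config`.
#' @return One-row tibble `pan`, `core`, `accessory`, `singleton`.
#' @export
#' @examples
#' expected_counts(sim_config(n_genomes = 2, n_core = 1, n_singletons = 1))
expected_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  acc <- if (is.null(config$accessory_spectrum)) 0L else
    sum(config$accessory_spectrum$n_families)
  sng <- sum(config$n_singletons)
  tibble(pan = config$n_core + acc + sng, core = config$n_core,
         accessory = as.integer(acc), singleton = as.integer(sng))
}

#' Simulate a genome set with known gene-family ground truth
#'
#' @param config A `sim_config`.
#' @return A list with elements `genomes` (a genome-set tibble, see
#'   [read_genome()]), `truth` (tibble `family_id`, `class`, `genome`,
#'   `gene_id`) and `config`.
#' @details For each family a root protein is drawn uniformly over the 20
#'   residues and back-translated with uniform synonymous codon choice.
#'   Substitutions are i.i.d. per site and never restore the original
#'   character. Genomes are emitted as contigs of concatenated CDS separated
#'   by random spacers. The accessory occupancy sets are drawn uniformly at
#'   random without replacement. Output is byte-identical for a fixed seed.
#' @export
simulate_genome_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_genome_set_impl(config))
}

simulate_genome_set_impl <- function(config) {
  G <- config$n_genomes
  genome_names <- sprintf("g%02d", seq_len(G))
  codons <- synonymous_codons()

  # family design: class + carrier set per family
  carriers <- list(); classes <- character(0)
  if (config$n_core > 0) {
    carriers <- c(carriers, replicate(config$n_core, seq_len(G),
                                      simplify = FALSE))
    classes <- c(classes, rep("core", config$n_core))
  }
  if (!is.null(config$accessory_spectrum)) {
    for (r in seq_len(nrow(config$accessory_spectrum))) {
      m <- config$accessory_spectrum$occupancy[r]
      nf <- config$accessory_spectrum$n_families[r]
      if (nf == 0) next
      carriers <- c(carriers,
                    replicate(nf, sort(sample.int(G, m)), simplify = FALSE))
      classes <- c(classes, rep("accessory", nf))
    }
  }
  for (g in seq_len(G)) {
    ns <- config$n_singletons[g]
    if (ns == 0) next
    carriers <- c(carriers, replicate(ns, g, simplify = FALSE))
    classes <- c(classes, rep("singleton", ns))
  }
  n_fam <- length(carriers)
  fam_ids <- sprintf("F%06d", seq_len(n_fam))

  # per-genome gene accumulators
  prot <- lapply(seq_len(G), function(g) list())
  cds <- lapply(seq_len(G), function(g) list())
  truth <- vector("list", n_fam)

  for (f in seq_len(n_fam)) {
    root_aa <- sample(AA_ALPHABET20, config$protein_len, replace = TRUE)
    root_nt <- unlist(strsplit(vapply(root_aa, function(a) {
      cs <- codons[[a]]
      cs[[sample.int(length(cs), 1L)]]
    }, character(1)), "", fixed = TRUE), use.names = FALSE)
    root_sp <- if (config$spacer_len > 0) {
      sample(c("A", "C", "G", "T"), config$spacer_len, replace = TRUE)
    } else character(0)
    members <- character(0)
    for (g in carriers[[f]]) {
      aa <- mutate_chars(root_aa, config$aa_divergence / 2, AA_ALPHABET20)
      nt <- mutate_chars(c(root_sp, root_nt), config$nt_divergence / 2,
                         c("A", "C", "G", "T"))
      idx <- length(prot[[g]]) + 1L
      gid <- sprintf("%s_%05d", genome_names[g], idx)
      prot[[g]][[gid]] <- paste(aa, collapse = "")
      cds[[g]][[gid]] <- paste(nt, collapse = "")
      members <- c(members, genome_names[g], gid)
    }
    truth[[f]] <- tibble(
      family_id = fam_ids[f], class = classes[f],
      genome = members[c(TRUE, FALSE)], gene_id = members[c(FALSE, TRUE)])
  }
  truth <- bind_rows(truth)

  genomes <- purrr::map_dfr(seq_len(G), function(g) {
    gname <- genome_names[g]
    gene_ids <- names(prot[[g]])
    n_genes <- length(gene_ids)
    nc <- min(config$n_contigs, max(n_genes, 1L))
    block <- if (n_genes > 0) {
      as.integer(ceiling(seq_len(n_genes) * nc / n_genes))
    } else integer(0)
    contig_ids <- sprintf("%s_c%02d", gname, seq_len(nc))
    contig_seq <- vapply(seq_len(nc), function(ci) {
      genes <- which(block == ci)
      pieces <- unlist(cds[[g]][genes], use.names = FALSE)
      if (length(pieces) == 0) {
        pieces <- paste(sample(c("A", "C", "G", "T"),
                               max(config$spacer_len, 1L), replace = TRUE),
                        collapse = "")
      }
      paste(pieces, collapse = "")
    }, character(1))
    bind_rows(
      tibble(genome = gname, type = "contig", seq_id = contig_ids,
             seq = contig_seq, contig_id = NA_character_),
      tibble(genome = gname, type = "protein", seq_id = gene_ids,
             seq = unlist(prot[[g]], use.names = FALSE) %||% character(0),
             contig_id = contig_ids[block] %||% character(0))
    )
  })

  list(genomes = genomes, truth = truth, config = config)
}

# substitute each position independently with probability `rate`, never back
# to the original character
mutate_chars <- function(x, rate, alphabet) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit) == 0) return(x)
  k <- length(alphabet)
  cur <- match(x[hit], alphabet)
  x[hit] <- alphabet[(cur - 1L + sample.int(k - 1L, length(hit),
                                            replace = TRUE)) %% k + 1L]
  x
}

synonymous_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

# evaluate `code` under a fixed RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file holds the [sim_config()] arguments by name;
#' `accessory_spectrum` as a mapping/object with `occupancy` and
#' `n_families` arrays. A top-level `preset` key loads
#' [sim_config_preset()] with the remaining keys as overrides.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configurations requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$accessory_spectrum)) {
    vals$accessory_spectrum <- as_tibble(vals$accessory_spectrum)
  }
  if (!is.null(vals$preset)) {
    preset <- vals$preset
    vals$preset <- NULL
    return(do.call(sim_config_preset, c(list(name = preset), vals)))
  }
  do.call(sim_config, vals)
}

#' Write the simulation ground truth as TSV
#' @param truth Truth tibble from [simulate_genome_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
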