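# Independent oracles and fixture builders, deliberately naive.

# Brute-force affine-gap Smith-Waterman (score only). Three-matrix DP,
# written directly from the recurrence; a gap of length L costs
# open + L * ext.
sw_oracle <- function(query, subject, mat = oracle_blosum62(),
                      open = 11, ext = 1) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[q[i - 1], s[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")
random_dna <- function(len) paste(sample(c("A","C","G","T"), len, TRUE),
                                  collapse = "")

# build a genome-set tibble from named lists:
#   toy_genome_set(A = list(contigs = c(c1 = "ACGT"), proteins = c(p1 = "MK")))
toy_genome_set <- function(...) {
  gs <- list(...)
  purrr::map_dfr(names(gs), function(g) {
    ct <- gs[[g]]$contigs %||% character(0)
    pr <- gs[[g]]$proteins %||% character(0)
    map <- gs[[g]]$map %||% setNames(rep(NA_character_, length(pr)),
                                     names(pr))
    dplyr::bind_rows(
      tibble::tibble(genome = g, type = "contig",
                     seq_id = names(ct) %||% character(0),
                     seq = unname(ct), contig_id = NA_character_),
      tibble::tibble(genome = g, type = "protein",
                     seq_id = names(pr) %||% character(0),
                     seq = unname(pr), contig_id = unname(map[names(pr)]))
    )
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-built ortholog table from a list of named member vectors
toy_ortholog_table <- function(members, genome_names,
                               reference = genome_names[1]) {
  mat <- matrix(NA_character_, length(members), length(genome_names),
                dimnames = list(NULL, genome_names))
  for (f in seq_along(members)) mat[f, names(members[[f]])] <- members[[f]]
  wide <- dplyr::bind_cols(
    tibble::tibble(family_id = sprintf("T%03d", seq_along(members)),
                   occupancy = as.integer(rowSums(!is.na(mat)))),
    tibble::as_tibble(mat))
  pancore:::new_ortholog_table(wide, genome_names, reference)
}

# exhaustive pan/core medians, written independently of pan_development
enumerate_medians <- function(table) {
  P <- presence_matrix(table)
  G <- ncol(P)
  purrr::map_dfr(seq_len(G), function(N) {
    subs <- utils::combn(G, N, simplify = FALSE)
    pan <- vapply(subs, function(s) sum(rowSums(P[, s, drop = FALSE]) > 0),
                  numeric(1))
    core <- vapply(subs, function(s) sum(rowSums(P[, s, drop = FALSE]) == N),
                   numeric(1))
    tibble::tibble(n = N, pan_median = median(pan), core_median = median(core))
  })
}

# small diverged genome set used across tests
small_sim <- function(seed = 101, ...) {
  args <- list(n_genomes = 4, n_core = 12,
               accessory_spectrum = data.frame(occupancy = c(2, 3),
                                               n_families = c(4, 3)),
               n_singletons = 2, protein_len = 80, aa_divergence = 0.02,
               nt_divergence = 0.02, spacer_len = 30, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  simulate_genome_set(do.call(sim_config, args))
}
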