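# Gapped Karlin-Altschul parameters for BLOSUM62 with affine gaps (open 11,
# extend 1) — the standard constants behind protein bit scores.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Convert a raw Smith-Waterman score to bits
#'
#' `bits = (lambda * raw - ln K) / ln 2` with the gapped BLOSUM62(11,1)
#' constants (lambda = 0.267, K = 0.041). Strictly increasing in the raw
#' score.
#'
#' @param raw_score Numeric raw score(s) in substitution-matrix units.
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score) {
  (KA_LAMBDA * raw_score - log(KA_K)) / log(2)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

#' Local protein alignment with bit score
#'
#' Exact Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (a gap of length L costs `gap_open + L * gap_ext`; defaults 11 and 1).
#' Percent identity is computed over aligned columns (gaps included in the
#' column count); query coverage is the aligned fraction of the query.
#'
#' @param query,subject Amino-acid sequences (single strings; 20 standard
#'   residues plus X).
#' @param query_id,subject_id Labels carried into the result.
#' @param gap_open,gap_ext Affine gap parameters.
#' @return One-row tibble: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `pident`, `aln_len`, `query_cov`, `significant`
#'   (`FALSE` when no positive-scoring cell exists; `pident` is then `NA`).
#' @export
#' @examples
#' align_protein("HEAGAWGHEE", "PAWHEAE")
align_protein <- function(query, subject, query_id = "query",
                          subject_id = "subject", gap_open = 11, gap_ext = 1) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1, length(subject) == 1)
  if (!nzchar(query) || !nzchar(subject)) {
    abort("both sequences must be non-empty")
  }
  check_protein_residues(c(query, subject))
  m <- blosum62_matrix()
  r <- .sw_pair_cpp(toupper(query), toupper(subject), m,
                    paste(rownames(m), collapse = ""), gap_open, gap_ext)
  empty <- r$score <= 0 || r$aln_len == 0
  tibble(
    query_id = query_id, subject_id = subject_id,
    raw_score = r$score, bit_score = bit_score(r$score),
    pident = if (empty) NA_real_ else 100 * r$n_ident / r$aln_len,
    aln_len = r$aln_len,
    query_cov = if (empty) 0 else (r$q_end - r$q_start + 1) / nchar(query),
    significant = !empty
  )
}

check_protein_residues <- function(seqs) {
  ok <- paste0(c(AA_ALPHABET20, "X"), collapse = "")
  bad <- grepl(paste0("[^", ok, "]"), toupper(seqs))
  if (any(bad)) abort("illegal residue in protein sequence")
  invisible(seqs)
}

#' Best subject hit for every protein of a query genome
#'
#' Aligns every protein of genome `query` against every protein of genome
#' `subject` and keeps, per query gene, the subject hit with maximal bit
#' score, retained only when it reaches `min_bitscore` (inclusive; default
#' 60 bits). Score ties are broken toward the lexicographically smallest
#' subject id and flagged in the `tie` column.
#'
#' An exact k-mer prescreen (default on, `kmer = 4`) restricts the dynamic
#' programming to subject proteins sharing at least one length-k word with
#' the query; with the bit-score floor this does not change results on
#' realistic data, and `prescreen = FALSE` disables it.
#'
#' @param genomes A genome-set tibble.
#' @param query,subject Genome names within `genomes`.
#' @param min_bitscore Bit-score retention threshold (inclusive).
#' @param gap_open,gap_ext Affine gap parameters.
#' @param prescreen,kmer k-mer prescreen switch and word length.
#' @return Tibble: `query_id`, `subject_id`, `raw_score`, `bit_score`,
#'   `pident`, `aln_len`, `query_cov`, `tie`.
#' @export
best_hits <- function(genomes, query, subject, min_bitscore = 60,
                      gap_open = 11, gap_ext = 1,
                      prescreen = TRUE, kmer = 4) {
  check_genome_set(genomes, need_proteins = TRUE)
  q <- genome_seqs(genomes, query, "protein")
  s <- genome_seqs(genomes, subject, "protein")
  if (length(q) == 0 || length(s) == 0) {
    abort("both genomes must contain at least one protein")
  }
  m <- blosum62_matrix()
  df <- .best_hits_cpp(q, s, m, paste(rownames(m), collapse = ""),
                       gap_open, gap_ext, 1L, as.integer(kmer),
                       isTRUE(prescreen))
  qlen <- nchar(q)[df$query_id]
  out <- as_tibble(df) |>
    mutate(bit_score = bit_score(.data$raw_score),
           pident = 100 * .data$n_ident / .data$aln_len,
           query_cov = (.data$q_end - .data$q_start + 1) / qlen) |>
    filter(.data$bit_score >= min_bitscore) |>
    select("query_id", "subject_id", "raw_score", "bit_score", "pident",
           "aln_len", "query_cov", "tie")
  if (any(out$tie)) {
    inform(paste0(sum(out$tie), " best-hit tie(s) between '", query,
                  "' and '", subject, "' broken lexicographically"))
  }
  out
}

#' One-way fragment-based nucleotide identity
#'
#' The classic fragment recipe for average nucleotide identity: the query
#' genome's contigs are cut into consecutive windows of `frag_len`
#' nucleotides (default 1020 nt; a trailing partial window is dropped), each
#' fragment is placed at its best-supported location in the subject by exact
#' k-mer diagonal voting, and aligned there with an affine-gap local DP
#' (match +1, mismatch -1, gap of length L costs `gap_open + L * gap_ext`).
#' Fragments with identity >= `min_id` percent over >= `min_cov` of their
#' length are retained; the one-way ANI is the mean identity of retained
#' fragments.
#'
#' @param genomes A genome-set tibble.
#' @param query,subject Genome names.
#' @param frag_len Fragment length (nt).
#' @param min_id Minimum percent identity for a fragment to count.
#' @param min_cov Minimum aligned fraction of the fragment.
#' @param kmer Nucleotide word length for placement (default 13).
#' @param match,mismatch,gap_open,gap_ext Fragment scoring parameters.
#' @return One-row tibble: `query`, `subject`, `one_way_ani` (`NA` with a
#'   warning when no fragment passes the filters), `n_fragments`,
#'   `n_retained`.
#' @export
ani_fragments <- function(genomes, query, subject, frag_len = 1020,
                          min_id = 30, min_cov = 0.70, kmer = 13,
                          match = 1, mismatch = -1, gap_open = 5,
                          gap_ext = 2) {
  check_genome_set(genomes, need_contigs = TRUE)
  qc <- genome_seqs(genomes, query, "contig")
  sc <- genome_seqs(genomes, subject, "contig")
  if (length(qc) == 0 || length(sc) == 0) {
    abort("both genomes must contain nucleotide contigs")
  }
  df <- .ani_fragments_cpp(unname(qc), unname(sc), as.integer(frag_len),
                           as.integer(kmer), as.integer(match),
                           as.integer(mismatch), as.integer(gap_open),
                           as.integer(gap_ext))
  keep <- !is.na(df$pident) & df$pident >= min_id & df$coverage >= min_cov
  ani <- if (any(keep)) mean(df$pident[keep]) else NA_real_
  if (!any(keep)) {
    warn(paste0("no fragment of '", query, "' aligned to '", subject,
                "' passed the identity/coverage filters; ANI undefined"))
  }
  tibble(query = query, subject = subject, one_way_ani = ani,
         n_fragments = nrow(df), n_retained = sum(keep))
}
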