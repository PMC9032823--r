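#' Read one genome from FASTA files into a tidy sequence table
#'
#' A genome is represented as a tibble with one row per sequence record:
#' contigs (nucleotide) and proteins (amino acid) share the table,
#' distinguished by `type`. Several genomes bound together with
#' [dplyr::bind_rows()] form a genome set; every downstream function takes
#' such a table as its first argument.
#'
#' @param name Unique genome label.
#' @param fasta_nt Path to the nucleotide FASTA (contigs/scaffolds).
#' @param fasta_aa Path to the protein FASTA (predicted CDS translations).
#' @param gff3 Optional GFF3 path; only CDS records are used, to map each
#'   protein (`ID` attribute) to its contig (`seqid`). Requires the
#'   rtracklayer package.
#'
#' @return A tibble with columns `genome`, `type` (`"contig"` or
#'   `"protein"`), `seq_id`, `seq`, and `contig_id` (the contig carrying a
#'   protein; `NA` when no GFF3 mapping was given).
#'
#' @details Sequence ids are the first whitespace-delimited token of the
#'   FASTA header. Duplicated ids within a genome are an error. Nucleotide
#'   sequences must use A/C/G/T/N (case-insensitive; stored upper-case);
#'   proteins the 20 standard residues plus X (a single trailing `*` stop
#'   symbol is stripped). An empty protein FASTA is permitted but flagged
#'   with a message.
#' @export
#' @examples
#' nt <- tempfile(fileext = ".fna"); aa <- tempfile(fileext = ".faa")
#' writeLines(c(">c1", "ATGCATGC", ">c2", "GGGCCC"), nt)
#' writeLines(c(">p1", "MKL", ">p2", "MAV"), aa)
#' read_genome("toy", nt, aa)
read_genome <- function(name, fasta_nt, fasta_aa, gff3 = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (p in c(fasta_nt, fasta_aa)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  nt <- read_fasta_checked(fasta_nt, "DNA")
  aa <- read_fasta_checked(fasta_aa, "AA")
  validate_nt_alphabet(nt, fasta_nt)
  aa[] <- sub("\\*$", "", aa)
  validate_aa_alphabet(aa, fasta_aa)
  if (length(aa) == 0L) {
    inform(paste0("genome '", name, "': protein FASTA is empty"))
  }

  gene_to_contig <- rep(NA_character_, length(aa))
  names(gene_to_contig) <- names(aa)
  if (!is.null(gff3)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(gff3, format = "gff3")
    cds <- as.data.frame(gr[gr$type == "CDS"])
    hit <- match(names(aa), as.character(cds$ID))
    gene_to_contig[] <- as.character(cds$seqnames)[hit]
  }

  bind_rows(
    tibble(genome = name, type = "contig", seq_id = names(nt),
           seq = unname(nt), contig_id = NA_character_),
    tibble(genome = name, type = "protein", seq_id = names(aa),
           seq = unname(aa), contig_id = unname(gene_to_contig))
  )
}

read_fasta_checked <- function(path, kind) {
  set <- tryCatch(
    if (kind == "DNA") Biostrings::readBStringSet(path)
    else Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0) {
    abort(paste0("duplicated record id(s) in '", path, "': ",
                 paste(dup, collapse = ", ")))
  }
  seqs
}

validate_nt_alphabet <- function(seqs, path) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in nucleotide record '",
                 names(seqs)[bad][1], "' of '", path, "'"))
  }
}

validate_aa_alphabet <- function(seqs, path) {
  ok <- paste0(c(AA_ALPHABET20, "X"), collapse = "")
  bad <- grepl(paste0("[^", ok, "]"), seqs)
  if (any(bad)) {
    abort(paste0("illegal residue in protein record '",
                 names(seqs)[bad][1], "' of '", path, "'"))
  }
}

#' Write a genome set back to per-genome FASTA files
#'
#' @param genomes A genome-set tibble (see [read_genome()]).
#' @param dir Output directory; one `<genome>.fna` and `<genome>.faa` per
#'   genome.
#' @return Invisibly, a tibble with the paths written.
#' @export
write_genome_fasta <- function(genomes, dir) {
  check_genome_set(genomes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- purrr::map_dfr(unique(genomes$genome), function(g) {
    sub <- genomes[genomes$genome == g, ]
    fna <- file.path(dir, paste0(g, ".fna"))
    faa <- file.path(dir, paste0(g, ".faa"))
    ct <- sub[sub$type == "contig", ]
    pr <- sub[sub$type == "protein", ]
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(ct$seq, ct$seq_id)), fna)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(pr$seq, pr$seq_id)), faa)
    tibble(genome = g, fasta_nt = fna, fasta_aa = faa)
  })
  invisible(out)
}

check_genome_set <- function(genomes, need_proteins = FALSE,
                             need_contigs = FALSE) {
  need <- c("genome", "type", "seq_id", "seq", "contig_id")
  if (!is.data.frame(genomes) || !all(need %in% names(genomes))) {
    abort(paste0("expected a genome-set tibble with columns ",
                 paste(need, collapse = ", ")))
  }
  dup <- genomes |>
    group_by(.data$genome, .data$type) |>
    filter(duplicated(.data$seq_id)) |>
    ungroup()
  if (nrow(dup) > 0) {
    abort(paste0("duplicated sequence id within genome '", dup$genome[1],
                 "': ", dup$seq_id[1]))
  }
  if (need_proteins && !any(genomes$type == "protein")) {
    abort("genome set contains no protein records")
  }
  if (need_contigs && !any(genomes$type == "contig")) {
    abort("genome set contains no contig records")
  }
  invisible(genomes)
}

# named character vector of one genome's proteins (or contigs)
genome_seqs <- function(genomes, name, type = "protein") {
  sub <- genomes[genomes$genome == name & genomes$type == type, ]
  if (nrow(sub) == 0 && !name %in% genomes$genome) {
    abort(paste0("genome '", name, "' not present in the genome set"))
  }
  setNames(sub$seq, sub$seq_id)
}

#' Drop scaffolds below a minimum length
#'
#' Removes contigs shorter than `min_len` nucleotides from every genome
#' (default 1500 nt, the conventional draft-assembly cutoff). The threshold
#' is inclusive: a contig of exactly `min_len` is kept. Proteins mapped to a
#' dropped contig (via `contig_id`) are removed as well; proteins without a
#' contig mapping are kept and a message is emitted.
#'
#' @param genomes A genome-set tibble.
#' @param min_len Minimum scaffold length in nucleotides (>= 1).
#' @return The filtered genome-set tibble. Idempotent.
#' @export
filter_scaffolds <- function(genomes, min_len = 1500) {
  check_genome_set(genomes)
  stopifnot(min_len >= 1)
  contigs <- genomes[genomes$type == "contig", ]
  keep <- nchar(contigs$seq) >= min_len
  dropped <- contigs[!keep, c("genome", "seq_id")]
  out_contigs <- contigs[keep, ]
  proteins <- genomes[genomes$type == "protein", ]
  if (nrow(dropped) > 0 && nrow(proteins) > 0) {
    mapped <- !is.na(proteins$contig_id)
    if (any(!mapped)) {
      inform(paste0(sum(!mapped), " protein(s) have no contig mapping; ",
                    "kept despite scaffold filtering"))
    }
    drop_prot <- mapped & paste(proteins$genome, proteins$contig_id) %in%
      paste(dropped$genome, dropped$seq_id)
    proteins <- proteins[!drop_prot, ]
  }
  empty <- setdiff(unique(genomes$genome), unique(out_contigs$genome))
  if (length(empty) > 0) {
    warn(paste0("all scaffolds removed from genome(s): ",
                paste(empty, collapse = ", ")))
  }
  bind_rows(out_contigs, proteins) |>
    arrange(match(.data$genome, unique(genomes$genome)),
            match(.data$type, c("contig", "protein")))
}

#' Per-genome summary statistics
#'
#' @param genomes A genome-set tibble.
#' @return A tibble with one row per genome: `n_scaffolds`, `n_bases`
#'   (all bases including N), `gc_percent` (G+C over A+C+G+T; N excluded
#'   from numerator and denominator), `n_cds`.
#' @export
summarize_genomes <- function(genomes) {
  check_genome_set(genomes, need_contigs = TRUE)
  purrr::map_dfr(unique(genomes$genome), function(g) {
    ct <- genomes[genomes$genome == g & genomes$type == "contig", ]
    if (nrow(ct) == 0) abort(paste0("genome '", g, "' has no contigs"))
    counts <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(ct$seq), letters = c("A", "C", "G", "T", "N"))
    tot <- colSums(counts)
    acgt <- sum(tot[c("A", "C", "G", "T")])
    if (acgt == 0) {
      abort(paste0("genome '", g, "': GC content undefined (no A/C/G/T bases)"))
    }
    tibble(
      genome = g,
      n_scaffolds = nrow(ct),
      n_bases = sum(nchar(ct$seq)),
      gc_percent = 100 * sum(tot[c("G", "C")]) / acgt,
      n_cds = sum(genomes$genome == g & genomes$type == "protein")
    )
  })
}

#' Mean and standard deviation of GC content across a genome set
#'
#' @param summaries Either the tibble returned by [summarize_genomes()] or a
#'   bare numeric vector of GC percentages.
#' @return One-row tibble with `n`, `mean_gc`, `sd_gc` (sample SD, `n - 1`
#'   denominator; `NA` for a single genome). Values are unrounded; round at
#'   reporting time (1 decimal is conventional).
#' @export
#' @examples
#' gc_summary(c(50, 70))
gc_summary <- function(summaries) {
  gc <- if (is.numeric(summaries)) summaries else {
    stopifnot("gc_percent" %in% names(summaries))
    summaries$gc_percent
  }
  if (length(gc) < 1) abort("need at least one GC value")
  stopifnot(all(gc >= 0 & gc <= 100))
  tibble(n = length(gc), mean_gc = mean(gc),
         sd_gc = if (length(gc) >= 2) sd(gc) else NA_real_)
}

#' Write the per-genome summary table as TSV
#' @param summaries Tibble from [summarize_genomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summaries, path) {
  readr::write_tsv(summaries, path)
  invisible(path)
}
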