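#' Bidirectional best hits between two genomes
#'
#' A gene pair (x, y) is a BBH when y is x's best hit in genome `b` and x is
#' y's best hit in genome `a`, both at or above `min_bitscore` bits. The
#' result is a partial matching: each gene occurs in at most one pair.
#'
#' @inheritParams best_hits
#' @param a,b Genome names.
#' @param ... Passed to [best_hits()] (gap and prescreen parameters).
#' @return Tibble: `gene_a`, `gene_b`, `bit_ab`, `bit_ba`, `pident_ab`,
#'   `pident_ba`.
#' @export
bbh_pairs <- function(genomes, a, b, min_bitscore = 60, ...) {
  ab <- best_hits(genomes, a, b, min_bitscore = min_bitscore, ...)
  ba <- best_hits(genomes, b, a, min_bitscore = min_bitscore, ...)
  inner_join(
    ab |> select(gene_a = "query_id", gene_b = "subject_id",
                 bit_ab = "bit_score", pident_ab = "pident"),
    ba |> select(gene_b = "query_id", gene_a = "subject_id",
                 bit_ba = "bit_score", pident_ba = "pident"),
    by = c("gene_a", "gene_b")
  ) |>
    select("gene_a", "gene_b", "bit_ab", "bit_ba", "pident_ab", "pident_ba") |>
    arrange(.data$gene_a)
}

# all pairwise BBH tables for a genome set, keyed "a|b" with a < b in the
# genome order given
bbh_all_pairs <- function(genomes, genome_names, min_bitscore = 60, ...) {
  pairs <- utils::combn(genome_names, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    bbh_pairs(genomes, p[1], p[2], min_bitscore = min_bitscore, ...)
  })
  names(res) <- vapply(pairs, paste, character(1), collapse = "|")
  res
}

bbh_lookup <- function(bbh, a, b) {
  key <- paste(a, b, sep = "|")
  if (!is.null(bbh[[key]])) return(bbh[[key]])
  key <- paste(b, a, sep = "|")
  tab <- bbh[[key]]
  tibble(gene_a = tab$gene_b, gene_b = tab$gene_a,
         bit_ab = tab$bit_ba, bit_ba = tab$bit_ab,
         pident_ab = tab$pident_ba, pident_ba = tab$pident_ab)
}

#' Build the ortholog table of a genome set
#'
#' Families are seeded by the genes of the declared reference genome; each
#' non-reference genome contributes the BBH partner of each reference gene.
#' Genes without a reference partner are then clustered among themselves by
#' single-linkage over the remaining pairwise BBH graph, and leftover
#' unmatched genes become singleton families. Every gene of every genome
#' belongs to exactly one family (partition property). When a mop-up cluster
#' contains two genes of one genome, the member with the higher summed BBH
#' bit score stays and the other starts its own family (logged).
#'
#' @param genomes A genome-set tibble.
#' @param reference Name of the reference genome (must be in the set).
#' @param min_bitscore BBH bit-score threshold (inclusive; default 60).
#' @param ... Passed to [best_hits()].
#' @return An `ortholog_table`: a wide tibble with columns `family_id`,
#'   `occupancy`, and one gene-id column per genome (`NA` where absent),
#'   with attributes `genomes` (ordered names) and `reference`. Family ids
#'   are the reference gene id for reference-anchored families and
#'   `FAM<k>` for the rest, in deterministic (genome, gene) order.
#' @export
build_ortholog_table <- function(genomes, reference, min_bitscore = 60, ...) {
  check_genome_set(genomes, need_proteins = TRUE)
  genome_names <- unique(genomes$genome)
  if (length(genome_names) < 2) abort("need at least two genomes")
  if (!reference %in% genome_names) {
    abort(paste0("reference genome '", reference, "' not in the genome set"))
  }

  bbh <- bbh_all_pairs(genomes, genome_names, min_bitscore = min_bitscore, ...)
  prot <- genomes |> filter(.data$type == "protein")
  gene_key <- function(g, id) paste(g, id, sep = "\r")

  assigned <- new.env(parent = emptyenv())  # gene key -> family index
  fam_members <- list()                     # list of named chr: genome -> gene
  fam_ids <- character(0)

  # 1. reference-anchored families
  ref_genes <- prot$seq_id[prot$genome == reference]
  others <- setdiff(genome_names, reference)
  partner <- matrix(NA_character_, length(ref_genes), length(others),
                    dimnames = list(ref_genes, others))
  for (g in others) {
    tab <- bbh_lookup(bbh, reference, g)
    partner[, g] <- tab$gene_b[match(ref_genes, tab$gene_a)]
  }
  for (rg in ref_genes) {
    p <- setNames(partner[rg, ], others)
    members <- c(setNames(rg, reference), p[!is.na(p)])
    fam_members[[length(fam_members) + 1L]] <- members
    fam_ids <- c(fam_ids, rg)
    for (g in names(members)) {
      assign(gene_key(g, members[[g]]), length(fam_members),
             envir = assigned)
    }
  }

  # 2. single-linkage mop-up over BBH pairs among still-unassigned genes
  is_free <- function(g, id) !exists(gene_key(g, id), envir = assigned)
  edges <- purrr::map_dfr(names(bbh), function(key) {
    gs <- strsplit(key, "|", fixed = TRUE)[[1]]
    tab <- bbh[[key]]
    if (nrow(tab) == 0) return(NULL)
    tibble(ga = gs[1], ia = tab$gene_a, gb = gs[2], ib = tab$gene_b,
           w = (tab$bit_ab + tab$bit_ba) / 2)
  })
  if (nrow(edges) > 0) {
    free <- mapply(is_free, edges$ga, edges$ia) &
      mapply(is_free, edges$gb, edges$ib)
    edges <- edges[free, ]
  }
  n_split <- 0L
  if (nrow(edges) > 0) {
    va <- gene_key(edges$ga, edges$ia)
    vb <- gene_key(edges$gb, edges$ib)
    gr <- igraph::graph_from_data_frame(
      data.frame(from = va, to = vb), directed = FALSE)
    comp <- igraph::components(gr)
    membership <- split(names(comp$membership), comp$membership)
    # deterministic order: by smallest (genome, gene) key in the component
    membership <- membership[order(vapply(membership, min, character(1)))]
    for (cl in membership) {
      parts <- do.call(rbind, strsplit(cl, "\r", fixed = TRUE))
      cl_tab <- tibble(genome = parts[, 1], gene = parts[, 2])
      # weight per gene = summed bit score of its edges inside the component
      wtab <- bind_rows(
        tibble(genome = edges$ga, gene = edges$ia, w = edges$w,
               key = va, other = vb),
        tibble(genome = edges$gb, gene = edges$ib, w = edges$w,
               key = vb, other = va)
      ) |> filter(.data$key %in% cl)
      wsum <- wtab |> group_by(.data$genome, .data$gene) |>
        summarise(w = sum(.data$w), .groups = "drop")
      cl_tab <- left_join(cl_tab, wsum, by = c("genome", "gene")) |>
        mutate(w = ifelse(is.na(.data$w), 0, .data$w)) |>
        arrange(.data$genome, dplyr::desc(.data$w), .data$gene)
      keep <- cl_tab[!duplicated(cl_tab$genome), ]
      spill <- cl_tab[duplicated(cl_tab$genome), ]
      n_split <- n_split + nrow(spill)
      fam_members[[length(fam_members) + 1L]] <-
        setNames(keep$gene, keep$genome)
      fam_ids <- c(fam_ids, NA_character_)
      for (i in seq_len(nrow(keep))) {
        assign(gene_key(keep$genome[i], keep$gene[i]),
               length(fam_members), envir = assigned)
      }
      for (i in seq_len(nrow(spill))) {  # each spilled gene: own family
        fam_members[[length(fam_members) + 1L]] <-
          setNames(spill$gene[i], spill$genome[i])
        fam_ids <- c(fam_ids, NA_character_)
        assign(gene_key(spill$genome[i], spill$gene[i]),
               length(fam_members), envir = assigned)
      }
    }
  }
  if (n_split > 0) {
    inform(paste0(n_split, " gene(s) split out of mop-up families ",
                  "(one gene per genome per family)"))
  }

  # 3. leftover singletons, deterministic (genome, gene) order
  prot_sorted <- prot |> arrange(match(.data$genome, genome_names),
                                 .data$seq_id)
  for (i in seq_len(nrow(prot_sorted))) {
    g <- prot_sorted$genome[i]; id <- prot_sorted$seq_id[i]
    if (is_free(g, id)) {
      fam_members[[length(fam_members) + 1L]] <- setNames(id, g)
      fam_ids <- c(fam_ids, NA_character_)
      assign(gene_key(g, id), length(fam_members), envir = assigned)
    }
  }
  fam_ids[is.na(fam_ids)] <- sprintf("FAM%05d", seq_len(sum(is.na(fam_ids))))

  mat <- matrix(NA_character_, length(fam_members), length(genome_names),
                dimnames = list(NULL, genome_names))
  for (f in seq_along(fam_members)) {
    mat[f, names(fam_members[[f]])] <- fam_members[[f]]
  }
  wide <- dplyr::bind_cols(
    tibble(family_id = fam_ids,
           occupancy = as.integer(rowSums(!is.na(mat)))),
    as_tibble(mat))
  new_ortholog_table(wide, genome_names, reference)
}

new_ortholog_table <- function(tbl, genome_names, reference) {
  out <- as_tibble(tbl)
  attr(out, "genomes") <- genome_names
  attr(out, "reference") <- reference
  class(out) <- c("ortholog_table", class(out))
  validate_ortholog_table(out)
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("Ortholog table: ", nrow(x), " families x ",
      length(attr(x, "genomes")), " genomes (reference: ",
      attr(x, "reference") %||% "none", ")\n", sep = "")
  NextMethod()
}

validate_ortholog_table <- function(tab) {
  gn <- attr(tab, "genomes")
  if (is.null(gn) || !all(gn %in% names(tab))) {
    abort("ortholog table lacks its genome columns")
  }
  pres <- !is.na(as.matrix(tab[, gn, drop = FALSE]))
  occ <- rowSums(pres)
  if (any(occ < 1)) abort("empty family row (occupancy must be >= 1)")
  if (!all(tab$occupancy == occ)) {
    abort("stored occupancy disagrees with family membership")
  }
  for (g in gn) {
    ids <- tab[[g]][!is.na(tab[[g]])]
    if (anyDuplicated(ids)) {
      abort(paste0("gene assigned to more than one family in genome '",
                   g, "'"))
    }
  }
  tab
}

#' Write / read an ortholog table as TSV
#'
#' Lossless round trip of the wide presence/absence table: columns
#' `family_id`, `occupancy`, then one gene-id column per genome (empty cell
#' where absent). A header comment line records the reference genome.
#'
#' @param table An `ortholog_table`.
#' @param path Output path.
#' @return `path` invisibly (write); an `ortholog_table` (read).
#' @export
write_ortholog_table <- function(table, path) {
  stopifnot(inherits(table, "ortholog_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reference: ", attr(table, "reference")), con)
  out <- as.data.frame(table)
  out[is.na(out)] <- ""
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_table
#' @export
read_ortholog_table <- function(path) {
  first <- readLines(path, n = 1)
  reference <- sub("^# reference: ", "", first)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "")
  if (!all(c("family_id", "occupancy") %in% names(raw))) {
    abort("not an ortholog table: missing family_id/occupancy columns")
  }
  genome_names <- setdiff(names(raw), c("family_id", "occupancy"))
  if (length(genome_names) == 0) abort("ortholog table has no genome columns")
  raw$occupancy <- as.integer(raw$occupancy)
  new_ortholog_table(raw, genome_names,
                     if (reference %in% genome_names) reference else NA)
}

#' Presence/absence matrix of an ortholog table
#'
#' @param table An `ortholog_table`.
#' @return Logical matrix, families x genomes.
#' @export
presence_matrix <- function(table) {
  gn <- attr(table, "genomes")
  m <- !is.na(as.matrix(table[, gn, drop = FALSE]))
  rownames(m) <- table$family_id
  m
}
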