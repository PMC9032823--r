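#' Average amino-acid identity between two genomes
#'
#' AAI is the mean percent identity over all bidirectional best-hit protein
#' pairs, symmetrized as the mean of the two alignment directions (identical
#' under exact Smith-Waterman with a symmetric matrix). By default the mean
#' is unweighted; `length_weighted = TRUE` weights each pair by its
#' alignment length.
#'
#' @param genomes A genome-set tibble.
#' @param a,b Genome names.
#' @param min_bitscore BBH bit-score threshold.
#' @param length_weighted Weight pairs by alignment length.
#' @param ... Passed to [best_hits()].
#' @return One-row tibble: `genome_a`, `genome_b`, `aai` (`NA` when there
#'   are no BBH pairs), `n_pairs`.
#' @export
compute_aai <- function(genomes, a, b, min_bitscore = 60,
                        length_weighted = FALSE, ...) {
  if (identical(a, b)) {
    return(tibble(genome_a = a, genome_b = b, aai = 100,
                  n_pairs = sum(genomes$genome == a &
                                  genomes$type == "protein")))
  }
  pairs <- bbh_pairs(genomes, a, b, min_bitscore = min_bitscore, ...)
  if (nrow(pairs) == 0) {
    return(tibble(genome_a = a, genome_b = b, aai = NA_real_, n_pairs = 0L))
  }
  pid <- (pairs$pident_ab + pairs$pident_ba) / 2
  w <- if (length_weighted) {
    ab <- best_hits(genomes, a, b, min_bitscore = min_bitscore, ...)
    ab$aln_len[match(pairs$gene_a, ab$query_id)]
  } else rep(1, length(pid))
  tibble(genome_a = a, genome_b = b,
         aai = sum(pid * w) / sum(w), n_pairs = nrow(pairs))
}

#' Average nucleotide identity between two genomes
#'
#' Mean of the two one-way fragment ANI values (see [ani_fragments()]);
#' `NA` in either direction propagates.
#'
#' @param genomes A genome-set tibble.
#' @param a,b Genome names.
#' @param ... Passed to [ani_fragments()] (fragment length, filters,
#'   scoring).
#' @return One-row tibble: `genome_a`, `genome_b`, `ani`, `n_fragments`
#'   (retained, both directions summed).
#' @export
compute_ani <- function(genomes, a, b, ...) {
  if (identical(a, b)) {
    return(tibble(genome_a = a, genome_b = b, ani = 100, n_fragments = NA_integer_))
  }
  fwd <- ani_fragments(genomes, a, b, ...)
  rev <- ani_fragments(genomes, b, a, ...)
  tibble(genome_a = a, genome_b = b,
         ani = (fwd$one_way_ani + rev$one_way_ani) / 2,
         n_fragments = fwd$n_retained + rev$n_retained)
}

#' Pairwise identity matrix over a genome set
#'
#' Computes AAI ([compute_aai()]) or ANI ([compute_ani()]) for every genome
#' pair and returns a tidy symmetric matrix: diagonal exactly 100,
#' `value(i,j) == value(j,i)`, `NA` where the metric is undefined.
#'
#' @param genomes A genome-set tibble.
#' @param kind `"AAI"` or `"ANI"`.
#' @param ... Passed to the pairwise computation.
#' @return An `identity_matrix`: a long tibble (`genome_a`, `genome_b`,
#'   `value`, `n_used`) covering all ordered pairs, with attributes `kind`
#'   and `genomes` (display order). Use [as.matrix()] for the square form.
#' @export
identity_matrix <- function(genomes, kind = c("AAI", "ANI"), ...) {
  kind <- match.arg(kind)
  check_genome_set(genomes)
  gn <- unique(genomes$genome)
  pairs <- utils::combn(gn, 2, simplify = FALSE)
  fun <- if (kind == "AAI") compute_aai else compute_ani
  upper <- purrr::map_dfr(pairs, function(p) {
    r <- fun(genomes, p[1], p[2], ...)
    names(r)[3:4] <- c("value", "n_used")
    r
  })
  long <- bind_rows(
    tibble(genome_a = gn, genome_b = gn, value = 100, n_used = NA_integer_),
    upper,
    upper |> rename(genome_a = "genome_b", genome_b = "genome_a")
  )
  new_identity_matrix(long, kind, gn)
}

new_identity_matrix <- function(long, kind, genome_order) {
  out <- as_tibble(long)
  attr(out, "kind") <- kind
  attr(out, "genomes") <- genome_order
  class(out) <- c("identity_matrix", class(out))
  out
}

#' @export
print.identity_matrix <- function(x, digits = 2, ...) {
  cat(attr(x, "kind"), "matrix over",
      length(attr(x, "genomes")), "genomes\n")
  print(round(as.matrix(x), digits))
  invisible(x)
}

#' @export
#' @method as.matrix identity_matrix
as.matrix.identity_matrix <- function(x, ...) {
  gn <- attr(x, "genomes")
  m <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  m[cbind(match(x$genome_a, gn), match(x$genome_b, gn))] <- x$value
  m
}

#' Reorder an identity matrix by average-linkage clustering
#'
#' Genomes are reordered by hierarchical clustering (average linkage) on
#' the distance `100 - identity`, the conventional ordering of pairwise
#' identity heatmaps. Genomes with any `NA` cell are excluded (listed in a
#' message). When all off-diagonal values are equal the input order is
#' preserved.
#'
#' @param x An `identity_matrix`.
#' @return The reordered `identity_matrix`.
#' @export
order_identity_matrix <- function(x) {
  stopifnot(inherits(x, "identity_matrix"))
  m <- as.matrix(x)
  bad <- rownames(m)[apply(is.na(m), 1, any)]
  if (length(bad) > 0) {
    inform(paste0("excluding genome(s) with undefined identity: ",
                  paste(bad, collapse = ", ")))
    keep <- setdiff(rownames(m), bad)
    m <- m[keep, keep, drop = FALSE]
  }
  if (nrow(m) <= 2) return(subset_identity_matrix(x, rownames(m)))
  off <- m[lower.tri(m)]
  if (diff(range(off)) == 0) return(subset_identity_matrix(x, rownames(m)))
  hc <- hclust(as.dist(100 - m), method = "average")
  subset_identity_matrix(x, rownames(m)[hc$order])
}

subset_identity_matrix <- function(x, genome_order) {
  long <- x |>
    as_tibble() |>
    filter(.data$genome_a %in% genome_order,
           .data$genome_b %in% genome_order)
  new_identity_matrix(long, attr(x, "kind"), genome_order)
}

#' @export
tidy.identity_matrix <- function(x, ...) as_tibble(x)

#' Heatmap of an identity matrix
#' @param object An `identity_matrix` (typically after
#'   [order_identity_matrix()]).
#' @param label Print values in the cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identity_matrix <- function(object, label = TRUE, ...) {
  gn <- attr(object, "genomes")
  d <- object |>
    as_tibble() |>
    mutate(genome_a = factor(.data$genome_a, gn),
           genome_b = factor(.data$genome_b, rev(gn)))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$genome_a, .data$genome_b,
                                       fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0(attr(object, "kind"), " (%)"),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (label) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$value)), size = 2.6)
  }
  p
}

#' Write an identity matrix as a square TSV
#'
#' Header row and column of genome names; `NA` written as an empty cell;
#' values rounded to 2 decimals.
#'
#' @param x An `identity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(x, path) {
  m <- round(as.matrix(x), 2)
  df <- data.frame(genome = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Pairwise rank-classification report
#'
#' Combines an AAI and an ANI matrix (and optional user-supplied 16S
#' identities) into a per-pair report with the [classify_pair()] call.
#'
#' @param aai,ani `identity_matrix` objects over the same genomes (either
#'   may be `NULL`).
#' @param sixteen_s Optional data frame `genome_a`, `genome_b`, `identity`
#'   with 16S rRNA percent identities.
#' @param thresholds A [rank_thresholds()].
#' @return Tibble: `genome_a`, `genome_b`, `aai`, `ani`, `sixteen_s`,
#'   `call`, one row per unordered genome pair.
#' @export
rank_report <- function(aai = NULL, ani = NULL, sixteen_s = NULL,
                        thresholds = rank_thresholds()) {
  if (is.null(aai) && is.null(ani)) abort("need at least one identity matrix")
  gn <- attr(aai %||% ani, "genomes")
  pairs <- utils::combn(sort(gn), 2)
  out <- tibble(genome_a = pairs[1, ], genome_b = pairs[2, ])
  pick <- function(m, a, b) {
    if (is.null(m)) return(NA_real_)
    as.matrix(m)[cbind(a, b)]
  }
  out$aai <- pick(aai, out$genome_a, out$genome_b)
  out$ani <- pick(ani, out$genome_a, out$genome_b)
  out$sixteen_s <- NA_real_
  if (!is.null(sixteen_s)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(out$genome_a, out$genome_b),
               key(sixteen_s$genome_a, sixteen_s$genome_b))
    out$sixteen_s <- sixteen_s$identity[m]
  }
  out$call <- classify_pair(out$aai, out$ani, out$sixteen_s, thresholds)
  out
}

#' Genus/species rank thresholds
#'
#' Conventional whole-genome rank boundaries: same genus when AAI lies in
#' 65-95% (supported, when available, by 16S rRNA identity in 95-98.6%);
#' same species when ANI exceeds 95% (the conservative lower end of the
#' ">95-96%" convention).
#'
#' @param genus_aai Two-sided AAI interval (percent).
#' @param genus_16s Two-sided 16S identity interval (percent).
#' @param species_ani Lower ANI bound for conspecificity (percent,
#'   exclusive).
#' @return A `rank_thresholds` list.
#' @export
rank_thresholds <- function(genus_aai = c(65, 95), genus_16s = c(95, 98.6),
                            species_ani = 95) {
  stopifnot(length(genus_aai) == 2, diff(genus_aai) > 0,
            length(genus_16s) == 2, diff(genus_16s) > 0,
            length(species_ani) == 1)
  structure(list(genus_aai = genus_aai, genus_16s = genus_16s,
                 species_ani = species_ani), class = "rank_thresholds")
}

#' Classify a genome pair at genus/species rank
#'
#' Precedence species > genus: `same_species` when ANI exceeds the species
#' bound; otherwise `same_genus` when AAI falls in the genus interval and,
#' when a 16S identity is supplied, 16S falls in its interval; otherwise
#' `different_genus`. Vectorized over the three metrics; all-`NA` input is
#' an error.
#'
#' @param aai,ani,sixteen_s Percent identities (`NA` where unavailable).
#' @param thresholds A [rank_thresholds()] object.
#' @return Character vector in
#'   `c("same_species", "same_genus", "different_genus")`.
#' @export
#' @examples
#' classify_pair(aai = 82.36, ani = 90, sixteen_s = 96.46)
classify_pair <- function(aai = NA, ani = NA, sixteen_s = NA,
                          thresholds = rank_thresholds()) {
  stopifnot(inherits(thresholds, "rank_thresholds"))
  len <- max(length(aai), length(ani), length(sixteen_s))
  aai <- rep_len(aai, len); ani <- rep_len(ani, len)
  sixteen_s <- rep_len(sixteen_s, len)
  if (any(is.na(aai) & is.na(ani) & is.na(sixteen_s))) {
    abort("at least one of aai/ani/sixteen_s must be non-NA for each pair")
  }
  species <- !is.na(ani) & ani > thresholds$species_ani
  genus_aai_ok <- !is.na(aai) & aai >= thresholds$genus_aai[1] &
    aai <= thresholds$genus_aai[2]
  genus_16s_ok <- is.na(sixteen_s) |
    (sixteen_s >= thresholds$genus_16s[1] &
       sixteen_s <= thresholds$genus_16s[2])
  ifelse(species, "same_species",
         ifelse(genus_aai_ok & genus_16s_ok, "same_genus",
                "different_genus"))
}
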