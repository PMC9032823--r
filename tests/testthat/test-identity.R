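test_that("AAI of identical genomes is 100 and disjoint proteomes are NA", {
  set.seed(17)
  prots <- setNames(replicate(5, random_protein(70)), paste0("p", 1:5))
  gs <- toy_genome_set(A = list(proteins = prots),
                       B = list(proteins = prots))
  expect_equal(compute_aai(gs, "A", "B")$aai, 100)

  gs2 <- toy_genome_set(
    A = list(proteins = setNames(replicate(3, random_protein(50)), paste0("a", 1:3))),
    B = list(proteins = setNames(replicate(3, random_protein(50)), paste0("b", 1:3))))
  r <- compute_aai(gs2, "A", "B")
  expect_true(is.na(r$aai))
  expect_equal(r$n_pairs, 0)
})

test_that("AAI recovers the programmed protein divergence", {
  sim <- simulate_genome_set(sim_config(2, n_core = 40, protein_len = 120,
                                        aa_divergence = 0.10, seed = 71))
  r <- compute_aai(sim$genomes, "g01", "g02")
  expect_gt(r$aai, 88)
  expect_lt(r$aai, 92)
  expect_equal(r$n_pairs, 40)
})

test_that("ANI mirrors the one-way fragment values and propagates NA", {
  sim <- simulate_genome_set(sim_config(2, n_core = 40, protein_len = 200,
                                        nt_divergence = 0.03, spacer_len = 50,
                                        seed = 73))
  r <- compute_ani(sim$genomes, "g01", "g02", frag_len = 510)
  expect_gt(r$ani, 96)
  expect_lt(r$ani, 98)
  expect_equal(compute_ani(sim$genomes, "g01", "g01")$ani, 100)

  set.seed(3)
  gs <- toy_genome_set(A = list(contigs = c(c1 = random_dna(4000))),
                       B = list(contigs = c(c1 = random_dna(4000))))
  suppressWarnings(r2 <- compute_ani(gs, "A", "B", frag_len = 1020))
  expect_true(is.na(r2$ani))
})

test_that("identity matrices are symmetric with diagonal exactly 100", {
  sim <- small_sim(seed = 83, n_genomes = 3,
                   accessory_spectrum = data.frame(occupancy = 2, n_families = 4))
  m <- as.matrix(identity_matrix(sim$genomes, "AAI"))
  expect_equal(diag(m), setNames(rep(100, 3), rownames(m)))
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_true(all(m >= 0 & m <= 100))
})

test_that("identity recovery is within one percentage point on the grid", {
  # protein length 300 and >= 100 kb of genome per the recovery contract
  for (d in c(0.01, 0.05, 0.10)) {
    sim <- simulate_genome_set(
      sim_config(2, n_core = 110, protein_len = 300, aa_divergence = d,
                 nt_divergence = d, spacer_len = 100, seed = 1000 + d * 100))
    ct <- sim$genomes[sim$genomes$type == "contig", ]
    expect_gte(min(nchar(ct$seq)), 1e5)
    aai <- compute_aai(sim$genomes, "g01", "g02")$aai
    ani <- compute_ani(sim$genomes, "g01", "g02")$ani
    expect_lt(abs(aai - 100 * (1 - d)), 1.0)
    expect_lt(abs(ani - 100 * (1 - d)), 1.0)
  }
})

test_that("rank classification follows the genus/species thresholds", {
  expect_equal(classify_pair(ani = 97.0), "same_species")
  expect_equal(classify_pair(aai = 82.36, ani = 90, sixteen_s = 96.46),
               "same_genus")
  expect_equal(classify_pair(aai = 50, ani = 75, sixteen_s = 90),
               "different_genus")
  # species precedence over genus
  expect_equal(classify_pair(aai = 82, ani = 96, sixteen_s = 97),
               "same_species")
  # 16S only consulted when available
  expect_equal(classify_pair(aai = 80, ani = 90), "same_genus")
  expect_error(classify_pair(), "non-NA")
})

test_that("raising ANI never demotes a classification (monotonicity)", {
  rank_level <- function(x) match(x, c("different_genus", "same_genus",
                                       "same_species"))
  set.seed(91)
  for (i in 1:50) {
    aai <- runif(1, 40, 100)
    s16 <- sample(c(NA, runif(1, 80, 100)), 1)
    anis <- sort(runif(3, 70, 100))
    lv <- rank_level(classify_pair(aai = aai, ani = anis, sixteen_s = s16))
    expect_true(all(diff(lv) >= 0))
  }
})

test_that("matrix ordering places the most similar genomes adjacently", {
  long <- tibble::tibble(
    genome_a = c("A", "B", "C", "A", "C", "B", "A", "B", "C"),
    genome_b = c("A", "B", "C", "B", "A", "C", "C", "A", "B"),
    value = c(100, 100, 100, 99, 70, 70, 70, 99, 70),
    n_used = NA_integer_)
  im <- pancore:::new_identity_matrix(long, "AAI", c("A", "B", "C"))
  ord <- attr(order_identity_matrix(im), "genomes")
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)

  # two genomes: order unchanged
  im2 <- pancore:::new_identity_matrix(
    long[long$genome_a != "C" & long$genome_b != "C", ], "AAI", c("A", "B"))
  expect_equal(attr(order_identity_matrix(im2), "genomes"), c("A", "B"))

  # all off-diagonal values equal: input order preserved
  long$value <- ifelse(long$genome_a == long$genome_b, 100, 80)
  im3 <- pancore:::new_identity_matrix(long, "AAI", c("A", "B", "C"))
  expect_equal(attr(order_identity_matrix(im3), "genomes"), c("A", "B", "C"))
})

test_that("rank_report combines matrices into per-pair calls", {
  long <- function(vals, gn) {
    m <- utils::combn(gn, 2)
    tibble::tibble(
      genome_a = c(gn, m[1, ], m[2, ]),
      genome_b = c(gn, m[2, ], m[1, ]),
      value = c(rep(100, length(gn)), vals, vals),
      n_used = NA_integer_)
  }
  gn <- c("A", "B", "C")
  aai <- pancore:::new_identity_matrix(long(c(90, 80, 50), gn), "AAI", gn)
  ani <- pancore:::new_identity_matrix(long(c(96, 85, 70), gn), "ANI", gn)
  rep <- rank_report(aai, ani)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$call[rep$genome_a == "A" & rep$genome_b == "B"],
               "same_species")
  expect_equal(rep$call[rep$genome_a == "A" & rep$genome_b == "C"],
               "same_genus")
  expect_equal(rep$call[rep$genome_a == "B" & rep$genome_b == "C"],
               "different_genus")
})

test_that("identity matrix TSV and heatmap outputs build", {
  sim <- small_sim(seed = 97, n_genomes = 3,
                   accessory_spectrum = data.frame(occupancy = 2, n_families = 4))
  im <- identity_matrix(sim$genomes, "AAI")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_identity_tsv(im, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$genome, attr(im, "genomes"))
  expect_equal(back[[2]][1], 100)
  expect_s3_class(autoplot(im), "ggplot")
})
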