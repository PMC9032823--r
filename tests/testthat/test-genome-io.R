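write_fasta_lines <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
}

test_that("read_genome parses nt + aa FASTA into a tidy genome table", {
  nt <- withr::local_tempfile(fileext = ".fna")
  aa <- withr::local_tempfile(fileext = ".faa")
  write_fasta_lines(c(c1 = "ATGCATGCAT", c2 = "GGGCCCAAA"), nt)
  write_fasta_lines(c(p1 = "MKL", p2 = "MAVX", p3 = "WYV"), aa)
  g <- read_genome("toy", nt, aa)
  expect_equal(sum(g$type == "contig"), 2)
  expect_equal(sum(g$type == "protein"), 3)
  expect_equal(g$seq[g$seq_id == "c1"], "ATGCATGCAT")

  # header description after whitespace is dropped from the id
  write_fasta_lines(c("c1 some description" = "ACGT"), nt)
  g2 <- read_genome("toy2", nt, aa)
  expect_equal(g2$seq_id[g2$type == "contig"], "c1")
})

test_that("read_genome flags empty protein FASTA and rejects bad input", {
  nt <- withr::local_tempfile(fileext = ".fna")
  aa <- withr::local_tempfile(fileext = ".faa")
  write_fasta_lines(c(c1 = "ATGC"), nt)
  writeLines(character(0), aa)
  expect_message(g <- read_genome("toy", nt, aa), "empty")
  expect_equal(sum(g$type == "protein"), 0)

  # duplicated ids violate uniqueness
  write_fasta_lines(c(p1 = "MKL", p1 = "MAV"), aa)
  expect_error(read_genome("toy", nt, aa), "duplicated")

  # illegal characters
  write_fasta_lines(c(p1 = "MKJ"), aa)   # J is not a standard residue
  expect_error(read_genome("toy", nt, aa), "illegal residue")
  write_fasta_lines(c(p1 = "MKL"), aa)
  write_fasta_lines(c(c1 = "ACGU"), nt)  # RNA letter
  expect_error(read_genome("toy", nt, aa), "non-ACGTN")
})

test_that("a GFF3 file maps proteins to their contigs", {
  skip_if_not_installed("rtracklayer")
  nt <- withr::local_tempfile(fileext = ".fna")
  aa <- withr::local_tempfile(fileext = ".faa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fasta_lines(c(c1 = "ATGAAATTTTAG", c2 = "ATGCCCGGGTAG"), nt)
  write_fasta_lines(c(p1 = "MKF", p2 = "MPG"), aa)
  writeLines(c(
    "##gff-version 3",
    "c1\tsim\tCDS\t1\t12\t.\t+\t0\tID=p1",
    "c2\tsim\tCDS\t1\t12\t.\t+\t0\tID=p2"), gff)
  g <- read_genome("toy", nt, aa, gff3 = gff)
  pr <- g[g$type == "protein", ]
  expect_equal(pr$contig_id[pr$seq_id == "p1"], "c1")
  expect_equal(pr$contig_id[pr$seq_id == "p2"], "c2")
})

test_that("FASTA round trip preserves ids and sequences", {
  nt <- withr::local_tempfile(fileext = ".fna")
  aa <- withr::local_tempfile(fileext = ".faa")
  set.seed(7)
  contigs <- setNames(replicate(3, random_dna(120)), paste0("c", 1:3))
  prots <- setNames(replicate(4, random_protein(35)), paste0("p", 1:4))
  write_fasta_lines(contigs, nt)
  write_fasta_lines(prots, aa)
  g <- read_genome("rt", nt, aa)
  dir <- withr::local_tempdir()
  write_genome_fasta(g, dir)
  g2 <- read_genome("rt", file.path(dir, "rt.fna"), file.path(dir, "rt.faa"))
  expect_equal(g2, g)
})

test_that("filter_scaffolds keeps contigs >= min_len inclusive and is idempotent", {
  g <- toy_genome_set(A = list(contigs = c(
    long = random_dna(2000), short = random_dna(1499),
    edge = random_dna(1500))))
  f <- filter_scaffolds(g)
  expect_setequal(f$seq_id, c("long", "edge"))
  expect_equal(filter_scaffolds(f), f)

  # all contigs >= threshold: unchanged
  g2 <- toy_genome_set(A = list(contigs = c(a = random_dna(1600))))
  expect_equal(filter_scaffolds(g2), g2)

  # all contigs below: empty genome with a warning
  g3 <- toy_genome_set(A = list(contigs = c(a = random_dna(100))))
  expect_warning(f3 <- filter_scaffolds(g3), "all scaffolds removed")
  expect_equal(nrow(f3), 0)
})

test_that("filter_scaffolds drops proteins of dropped contigs when mapped", {
  g <- toy_genome_set(A = list(
    contigs = c(big = random_dna(2000), tiny = random_dna(200)),
    proteins = c(p1 = "MKLV", p2 = "MAVW"),
    map = c(p1 = "big", p2 = "tiny")))
  f <- filter_scaffolds(g)
  expect_setequal(f$seq_id[f$type == "protein"], "p1")

  # unmapped proteins are kept (with a message)
  g2 <- toy_genome_set(A = list(
    contigs = c(big = random_dna(2000), tiny = random_dna(200)),
    proteins = c(p1 = "MKLV", p2 = "MAVW")))
  expect_message(f2 <- filter_scaffolds(g2), "no contig mapping")
  expect_setequal(f2$seq_id[f2$type == "protein"], c("p1", "p2"))
})

test_that("GC content excludes N from both numerator and denominator", {
  gc_of <- function(seq) {
    g <- toy_genome_set(A = list(contigs = c(c1 = seq)))
    summarize_genomes(g)$gc_percent
  }
  expect_equal(gc_of("GGCC"), 100)
  expect_equal(gc_of("ATGC"), 50)
  expect_equal(gc_of("ATNN"), 0)           # denominator 2, not 4
  expect_equal(gc_of("GCNN"), 100)
  expect_error(gc_of("NNNN"), "undefined")
  # n_bases counts everything including N
  g <- toy_genome_set(A = list(contigs = c(c1 = "ATNN", c2 = "GGC")))
  s <- summarize_genomes(g)
  expect_equal(s$n_bases, 7)
  expect_equal(s$n_scaffolds, 2)
})

test_that("gc_summary uses the arithmetic mean and sample SD", {
  expect_equal(gc_summary(c(50, 70))$mean_gc, 60)
  expect_equal(gc_summary(c(50, 70))$sd_gc, sqrt(200), tolerance = 1e-12)
  expect_equal(round(gc_summary(c(50, 70))$sd_gc, 3), 14.142)
  s <- gc_summary(c(60, 60, 60))
  expect_equal(s$mean_gc, 60)
  expect_equal(s$sd_gc, 0)
  expect_true(is.na(gc_summary(55)$sd_gc))
})

test_that("gc_summary of a single repeated value v is v across [0, 100]", {
  for (v in c(0, 13.7, 50, 64.2, 100)) {
    expect_equal(gc_summary(rep(v, 5))$mean_gc, v)
  }
})
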