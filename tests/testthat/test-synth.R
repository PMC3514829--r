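test_that("chromatin partition tiles each chromosome exactly", {
  spec <- genome_spec(n_chromosomes = 2, chrom_length = 5e5,
                      euchromatin_fraction = 0.4,
                      repeat_families = NULL, gene_density = 0, seed = 3)
  ref <- generate_reference(spec)
  part <- as.data.frame(ref$partition)
  for (ch in c("chr01", "chr02")) {
    p <- part[part$seqnames == ch, ]
    p <- p[order(p$start), ]
    expect_equal(p$start[1], 1)
    expect_equal(p$end[nrow(p)], 5e5)
    # blocks tile with no overlap and no gap
    expect_true(all(p$start[-1] == p$end[-nrow(p)] + 1))
    expect_equal(sum(p$width[p$label == "H"]), 3e5)
    expect_equal(sum(p$width[p$label == "E"]), 2e5)
  }
})

test_that("reference generation is byte-identical for a fixed seed", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 5e4, seed = 12,
                      gene_density = 20)
  a <- generate_reference(spec)
  b <- generate_reference(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$repeat_library),
                   as.character(b$repeat_library))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
})

test_that("zero-divergence repeat copies are exact, found by substring scan", {
  ref <- fx_small_ref()
  unit <- as.character(ref$repeat_library[["repfam01"]])
  n_found <- sum(vapply(as.character(ref$genome), function(s) {
    m <- gregexpr(unit, s, fixed = TRUE)[[1]]
    sum(m > 0)
  }, numeric(1)))
  ann <- as.data.frame(ref$repeat_annotation)
  expect_equal(nrow(ann), 20)  # all copies placed at this scale
  expect_equal(n_found, nrow(ann))
})

test_that("gene models lie within bounds with CDS/UTR/intron structure", {
  ref <- fx_small_ref()
  g <- as.data.frame(ref$genes)
  expect_true(all(g$start >= 1))
  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  expect_true(all(g$end <= lens[as.character(g$seqnames)]))
  expect_setequal(unique(g$type),
                  c("gene", "mRNA", "exon", "CDS",
                    "five_prime_UTR", "three_prime_UTR"))
  # every mRNA has a CDS inside its exons
  for (tx in unique(g$ID[g$type == "mRNA"])[1:3]) {
    ex <- g[g$type == "exon" & g$Parent == tx, ]
    cds <- g[g$type == "CDS" & g$Parent == tx, ]
    expect_gt(nrow(cds), 0)
    expect_true(all(vapply(seq_len(nrow(cds)), function(i)
      any(cds$start[i] >= ex$start & cds$end[i] <= ex$end), logical(1))))
  }
})

test_that("oversized partition blocks are rejected", {
  expect_error(genome_spec(chrom_length = -5), "positive")
  expect_error(genome_spec(euchromatin_fraction = 1.2), "0, 1")
})

test_that("enumerated SNP positions are planted verbatim", {
  ref <- fx_small_ref()
  pos <- data.frame(chrom = rep(c("chr01", "chr02"), each = 50),
                    pos = seq(1000, 50 * 1000, by = 1000))
  mspec <- mutation_spec(snp_rate = 0, indel_rate = 0,
                         snp_positions = pos, seed = 5)
  cult <- derive_cultivar(ref, mspec)
  expect_equal(nrow(cult$truth$snps), 100)
  expect_equal(cult$truth$snps$pos, pos$pos)
  expect_equal(nrow(cult$truth$indels), 0)
})

test_that("a planted inversion is the reverse complement of the reference", {
  ref <- fx_small_ref()
  mspec <- mutation_spec(snp_rate = 0, indel_rate = 0,
                         inversions = data.frame(chrom = "chr01",
                                                 start = 50001,
                                                 length = 20000),
                         seed = 6)
  cult <- derive_cultivar(ref, mspec)
  rs <- as.character(ref$genome[["chr01"]])
  cs <- as.character(cult$genome[["chr01"]])
  expect_identical(substr(cs, 50001, 70000), rc(substr(rs, 50001, 70000)))
  expect_identical(substr(cs, 1, 50000), substr(rs, 1, 50000))
  expect_identical(substr(cs, 70001, nchar(rs)),
                   substr(rs, 70001, nchar(rs)))
})

test_that("a translocation moves its segment to the destination", {
  ref <- fx_small_ref()
  mspec <- mutation_spec(snp_rate = 0, indel_rate = 0,
                         translocations = data.frame(
                           chrom = "chr01", start = 20001, length = 5000,
                           dest_chrom = "chr02", dest_pos = 100000,
                           inverted = FALSE),
                         seed = 6)
  cult <- derive_cultivar(ref, mspec)
  r1 <- as.character(ref$genome[["chr01"]])
  r2 <- as.character(ref$genome[["chr02"]])
  c1 <- as.character(cult$genome[["chr01"]])
  c2 <- as.character(cult$genome[["chr02"]])
  seg <- substr(r1, 20001, 25000)
  expect_equal(nchar(c1), nchar(r1) - 5000)
  expect_equal(nchar(c2), nchar(r2) + 5000)
  expect_identical(substr(c2, 100001, 105000), seg)
  expect_identical(substr(c1, 20001, 20010), substr(r1, 25001, 25010))
})

test_that("an empty mutation spec reproduces the reference", {
  ref <- fx_small_ref()
  cult <- derive_cultivar(ref, mutation_spec(snp_rate = 0, indel_rate = 0,
                                             seed = 1))
  expect_identical(as.character(cult$genome), as.character(ref$genome))
  expect_equal(nrow(cult$truth$snps), 0)
  expect_equal(nrow(cult$truth$events), 0)
})

test_that("overlapping planted events are rejected", {
  ref <- fx_small_ref()
  mspec <- mutation_spec(
    inversions = data.frame(chrom = c("chr01", "chr01"),
                            start = c(10001, 15001),
                            length = c(10000, 10000)), seed = 1)
  expect_error(derive_cultivar(ref, mspec), "overlap")
})

test_that("indel lengths respect the 26 bp cap and truth alleles match", {
  ref <- fx_small_ref()
  cult <- derive_cultivar(ref, mutation_spec(snp_rate = 0,
                                             indel_rate = 1 / 2000,
                                             seed = 31))
  ti <- cult$truth$indels
  expect_gt(nrow(ti), 50)
  expect_true(all(ti$length >= 1 & ti$length <= 26))
  # INS records carry the deleted reference bases in ref_allele
  ins <- ti[ti$type == "INS", ][1, ]
  rs <- as.character(ref$genome[[ins$chrom]])
  expect_identical(ins$ref_allele,
                   substr(rs, ins$pos, ins$pos + ins$length))
})

test_that("zero-error clone reads are exact cultivar substrings facing inward", {
  ref <- fx_small_ref()
  cult <- derive_cultivar(ref, mutation_spec(snp_rate = 0, indel_rate = 0,
                                             seed = 1))
  lib <- simulate_bac_library(cult, library_spec(
    n_clones = 1, insert_mean = 100000, insert_sd = 0,
    read_length_range = c(700L, 700L), per_base_error = 0, seed = 2))
  led <- lib$ledger
  expect_equal(led$insert_length, 100000)
  cs <- as.character(cult$genome[[led$chrom]])
  r1 <- as.character(lib$reads[[led$read1_id]])
  r2 <- as.character(lib$reads[[led$read2_id]])
  expect_identical(r1, substr(cs, led$read1_start, led$read1_end))
  expect_identical(r2, rc(substr(cs, led$read2_start, led$read2_end)))
  expect_lt(led$read1_start, led$read2_start)
  expect_true(led$read1_strand == "+" && led$read2_strand == "-")
})

test_that("empirical insert mean is within three standard errors", {
  cult <- derive_cultivar(fx_small_ref(),
                          mutation_spec(snp_rate = 0, indel_rate = 0,
                                        seed = 1))
  # a 200 kb chromosome cannot hold 101.3 kb +/- 10 kb inserts six sigma
  # deep, so scale the library to the fixture genome
  lib <- simulate_bac_library(cult, library_spec(
    n_clones = 2000, insert_mean = 101300 / 2, insert_sd = 5000,
    per_base_error = 0, seed = 4))
  m <- mean(lib$ledger$insert_length)
  se <- 5000 / sqrt(2000)
  expect_lt(abs(m - 101300 / 2), 3 * se)
})

test_that("library simulation is deterministic and honours the ledger", {
  cult <- derive_cultivar(fx_small_ref(),
                          mutation_spec(snp_rate = 0, indel_rate = 0,
                                        seed = 1))
  ls <- library_spec(n_clones = 30, insert_mean = 60000, insert_sd = 3000,
                     per_base_error = 0, seed = 77)
  a <- simulate_bac_library(cult, ls)
  b <- simulate_bac_library(cult, ls)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$ledger, b$ledger)
  expect_true(all(a$ledger$read1_strand == "+" &
                    a$ledger$read2_strand == "-"))
  expect_true(all(a$ledger$read1_start < a$ledger$read2_start))
  # qualities are Sanger Phred in [2, 60]
  qv <- as(Biostrings::quality(a$reads), "IntegerList")
  expect_true(all(unlist(qv) >= 2 & unlist(qv) <= 60))
})

test_that("invalid library specs are rejected", {
  expect_error(library_spec(n_clones = 0), "positive")
  expect_error(library_spec(per_base_error = 1), "0, 1")
  expect_error(library_spec(insert_mean = 800,
                            read_length_range = c(500L, 900L)),
               "exceed")
})

test_that("reference bundle round-trips through its on-disk formats", {
  ref <- fx_small_ref()
  dir <- withr::local_tempdir()
  write_reference_bundle(ref, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fa", "repeats.fa", "genes.gff3", "partition.tsv",
           "repeat_annotation.tsv")))))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome), as.character(ref$genome))
  part <- read_partition(file.path(dir, "partition.tsv"))
  expect_equal(GenomicRanges::start(part), GenomicRanges::start(ref$partition))
  expect_equal(part$label, ref$partition$label)
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"))
  expect_equal(sum(gff$type == "gene"), sum(ref$genes$type == "gene"))
})
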