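mk_aln_hit <- function(qaln, saln, sstart = 101, read = "r.T7",
                       chrom = "chr01") {
  data.frame(qseqid = read, sseqid = chrom, sstart = sstart,
             send = sstart + sum(strsplit(saln, "")[[1]] != "-") - 1L,
             strand = "+", qaln = qaln, saln = saln,
             stringsAsFactors = FALSE)
}

test_that("the column walk calls SNPs and anchors indels VCF-style", {
  # mismatch column -> SNP at the subject coordinate
  calls <- call_polymorphisms(mk_aln_hit("ACAT", "ACGT"))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "SNP")
  expect_equal(calls$pos, 103)
  expect_equal(c(calls$ref_allele, calls$alt_allele), c("G", "A"))
  # gap in the subject string -> DEL (the read carries an extra base)
  calls <- call_polymorphisms(mk_aln_hit("ACGT", "AC-T"))
  expect_equal(calls$type, "DEL")
  expect_equal(calls$pos, 102)          # anchored at the base left of the gap
  expect_equal(calls$ref_allele, "C")
  expect_equal(calls$alt_allele, "CG")
  expect_equal(calls$indel_length, 1L)
  # gap in the query string -> INS (the reference carries extra bases)
  calls <- call_polymorphisms(mk_aln_hit("AC--T", "ACGGT"))
  expect_equal(calls$type, "INS")
  expect_equal(calls$pos, 102)
  expect_equal(calls$ref_allele, "CGG")
  expect_equal(calls$alt_allele, "C")
  expect_equal(calls$indel_length, 2L)
  # subject coordinates are carried through gaps
  calls <- call_polymorphisms(mk_aln_hit("AA-CCT", "AAGCCA"))
  expect_equal(calls$pos, c(102, 106))
  expect_equal(calls$type, c("INS", "SNP"))
})

test_that("ambiguous bases and malformed alignments are handled", {
  expect_equal(nrow(call_polymorphisms(mk_aln_hit("ACNT", "ACGT"))), 0)
  expect_error(call_polymorphisms(mk_aln_hit("ACG", "ACGT")), "unequal")
  long_gap <- paste(rep("-", 27), collapse = "")
  expect_error(call_polymorphisms(
    mk_aln_hit(paste0("AAAA", long_gap, "AAAA"),
               paste0("AAAA", rand_dna(27), "AAAA"))), "gap run")
})

test_that("transition/transversion classification is exhaustive", {
  expect_equal(classify_snp("A", "G"), "TRANSITION")
  expect_equal(classify_snp("C", "G"), "TRANSVERSION")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_snp(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "TRANSITION"), 4)
  expect_equal(sum(cls == "TRANSVERSION"), 8)
  expect_error(classify_snp("A", "A"), "distinct")
  expect_error(classify_snp("A", "N"), "distinct")
})

test_that("deduplication merges identical calls and flags conflicts", {
  calls <- rbind(
    call_polymorphisms(mk_aln_hit("ACAT", "ACGT", read = "r1.T7")),
    call_polymorphisms(mk_aln_hit("ACAT", "ACGT", read = "r2.SP6")),
    call_polymorphisms(mk_aln_hit("ACTT", "ACGT", read = "r3.T7")))
  dd <- dedupe_polymorphisms(calls)
  expect_equal(nrow(dd), 2)
  both <- dd[dd$alt_allele == "A", ]
  expect_equal(both$support, 2L)
  expect_setequal(strsplit(both$read_id, ",")[[1]], c("r1.T7", "r2.SP6"))
  expect_true(all(dd$conflict))
  empty <- dedupe_polymorphisms(calls[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("minus-strand hits report alleles on the reference forward strand", {
  set.seed(41)
  ref <- Biostrings::DNAStringSet(c(chr01 = rand_dna(5000)))
  rs <- as.character(ref[[1]])
  seg <- substr(rs, 2001, 2600)
  mut <- seg
  substr(mut, 300, 300) <- if (substr(seg, 300, 300) == "A") "C" else "A"
  h <- local_align(setNames(rc(mut), "rev.T7"), ref)
  expect_equal(h$strand[1], "-")
  calls <- call_polymorphisms(h[1, c("qseqid", "sseqid", "sstart",
                                     "qaln", "saln")])
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 2300)
  expect_equal(calls$ref_allele, substr(rs, 2300, 2300))
  expect_equal(calls$alt_allele, substr(mut, 300, 300))
})

test_that("indel left-normalisation matches a homopolymer truth anchor", {
  genome <- Biostrings::DNAStringSet(c(chr01 = "ACGTTTTTGCAT"))
  # a deletion of one T reported at the right edge of the run
  call <- data.frame(chrom = "chr01", pos = 7, type = "INS",
                     ref_allele = "TT", alt_allele = "T",
                     stringsAsFactors = FALSE)
  norm <- normalize_indels(call, genome)
  expect_equal(norm$pos, 3)
  expect_equal(norm$ref_allele, "GT")
  expect_equal(norm$alt_allele, "G")
})

test_that("genic annotation follows the class priority", {
  g <- function(type, start, end, id, parent)
    data.frame(type = type, start = start, end = end, ID = id,
               Parent = parent)
  feats <- rbind(
    g("gene", 1001, 2500, "gene1", NA),
    g("mRNA", 1001, 2500, "gene1.1", "gene1"),
    g("exon", 1001, 1500, "e1", "gene1.1"),
    g("exon", 2001, 2500, "e2", "gene1.1"),
    g("five_prime_UTR", 1001, 1100, "u5", "gene1.1"),
    g("CDS", 1101, 1500, "c1", "gene1.1"),
    g("CDS", 2001, 2300, "c2", "gene1.1"),
    g("three_prime_UTR", 2301, 2500, "u3", "gene1.1"))
  genes <- GenomicRanges::GRanges("chr01",
                                  IRanges::IRanges(feats$start, feats$end),
                                  type = feats$type, ID = feats$ID,
                                  Parent = feats$Parent)
  calls <- data.frame(
    chrom = "chr01",
    pos = c(1200,   # CDS
            1050,   # 5' UTR
            2400,   # 3' UTR
            1502,   # second base of the intron: splice junction
            1999,   # penultimate base of the intron: splice junction
            1700,   # intron interior
            5000))  # intergenic
  ann <- annotate_polymorphisms(calls, genes)
  expect_equal(ann$annotation,
               c("CDS", "UTR5", "UTR3", "SPLICE_JUNCTION",
                 "SPLICE_JUNCTION", "INTRON", "INTERGENIC"))
})

test_that("polymorphism densities reproduce the published table arithmetic", {
  tab <- published_density_table()
  s <- summarize_density_table(tab)
  expect_equal(s$bp_per_polymorphism_euchromatin, 3565)
  expect_equal(s$bp_per_polymorphism_heterochromatin, 2737)
  expect_equal(s$bp_per_polymorphism_total, 2886)
  expect_equal(s$n_total, 171792)
  expect_equal(s$covered_total, 495833423)
})

test_that("density rows handle empty partitions and reconcile totals", {
  part <- chromatin_partition(c(chr01 = 10000), 0.4)
  cov <- coverage_stats(build_contigs(mk_clone("a", "chr01", 1000, 3000)),
                        part, c(chr01 = 10000))
  calls <- data.frame(chrom = "chr01", pos = c(1500, 1800))
  d <- density_stats(calls, cov, part)
  e_row <- d[d$chromosome == "chr01" & d$partition == "E", ]
  expect_equal(e_row$n_polymorphisms, 2)
  expect_equal(e_row$bp_per_polymorphism, round(e_row$covered / 2))
  h_row <- d[d$chromosome == "chr01" & d$partition == "H", ]
  expect_equal(h_row$n_polymorphisms, 0)
  expect_true(is.na(h_row$bp_per_polymorphism))
  tot <- d[d$chromosome == "Total" & d$partition == "total", ]
  expect_equal(tot$n_polymorphisms, 2)
})

test_that("calls in an error-free run equal the planted truth where covered", {
  p <- fx_event_pipeline()
  r <- p$recovery
  expect_equal(r$snp_precision, 1)
  expect_equal(r$indel_precision, 1)
  expect_equal(r$snp_recall, r$snp_covered_fraction)
  expect_equal(r$indel_recall, r$indel_covered_fraction)
  # every reported site lies inside an accepted alignment footprint
  u <- p$ends[p$ends$status == "UNIQUE", ]
  fp <- GenomicRanges::GRanges(u$chrom, IRanges::IRanges(u$start, u$end))
  pos <- GenomicRanges::GRanges(p$calls$chrom,
                                IRanges::IRanges(p$calls$pos, p$calls$pos))
  expect_true(all(GenomicRanges::countOverlaps(pos, fp) > 0))
})

test_that("VCF output round-trips through a VCF parser", {
  p <- fx_event_pipeline()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(p$calls, f,
                     setNames(Biostrings::width(p$reference$genome),
                              names(p$reference$genome)))
  vcf <- VariantAnnotation::readVcf(f)
  expect_equal(nrow(vcf), nrow(p$calls))
  expect_equal(as.character(GenomicRanges::seqnames(vcf)), p$calls$chrom)
  expect_equal(BiocGenerics::start(vcf), p$calls$pos)
  expect_equal(as.character(VariantAnnotation::ref(vcf)),
               p$calls$ref_allele)
  info <- VariantAnnotation::info(vcf)
  expect_equal(info$TYPE, p$calls$type)
  expect_equal(info$SUPPORT, p$calls$support)
})
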