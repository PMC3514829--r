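test_that("quality filter keeps and removes by mean Phred, partitioning input", {
  set.seed(1)
  reads <- reads_with_qv(setNames(replicate(2, rand_dna(100)),
                                  c("good", "bad")), c(30L, 10L))
  qf <- quality_filter(reads, 20)
  expect_equal(names(qf$kept), "good")
  expect_equal(names(qf$removed), "bad")
  expect_error(quality_filter(reads, -1), "non-negative")
})

test_that("quality filter agrees with an independent per-read average", {
  set.seed(2)
  n <- 1000
  seqs <- setNames(replicate(n, rand_dna(60)), sprintf("r%04d", 1:n))
  qv <- sample(10:30, n, replace = TRUE)
  reads <- reads_with_qv(seqs, qv)
  qf <- quality_filter(reads, 20)
  # independent oracle: decode the Phred+33 characters directly
  mean_qv <- vapply(as.character(Biostrings::quality(reads)), function(s)
    mean(utf8ToInt(s) - 33), numeric(1))
  expect_equal(length(qf$kept), sum(mean_qv >= 20))
  expect_setequal(names(qf$kept), names(seqs)[mean_qv >= 20])
  expect_equal(length(qf$kept) + length(qf$removed), n)
})

test_that("reads without qualities pass unfiltered with a flag", {
  d <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC"))
  expect_warning(qf <- quality_filter(d, 20), "no quality")
  expect_equal(length(qf$kept), 1)
})

test_that("an exact substring yields a perfect top hit; strands are symmetric", {
  set.seed(3)
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(20000)))
  q <- substr(as.character(ref[[1]]), 5001, 5700)
  h <- local_align(c(fwd = q, rev = rc(q)), ref)
  fwd <- h[h$qseqid == "fwd", ][1, ]
  rev <- h[h$qseqid == "rev", ][1, ]
  expect_equal(fwd$pident, 100)
  expect_equal(fwd$qcovg, 1)
  expect_equal(fwd$score, 700)    # 700 matches x (+1)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(c(rev$sstart, rev$send), c(fwd$sstart, fwd$send))
  expect_equal(rev$score, fwd$score)
})

test_that("top-hit scores equal the Smith-Waterman oracle on mutated queries", {
  set.seed(4)
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(20000)))
  rs <- as.character(ref[[1]])
  for (i in 1:10) {
    st <- sample(1:19800, 1)
    q <- mutate_at(substr(rs, st, st + 199), 0.05)
    h <- local_align(setNames(q, "m"), ref)
    expect_gt(nrow(h), 0)
    expect_equal(h$score[1], sw_oracle_score(q, rs))
  }
})

test_that("hit records are self-consistent with their aligned strings", {
  set.seed(5)
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(30000)))
  rs <- as.character(ref[[1]])
  qs <- setNames(vapply(1:8, function(i)
    mutate_at(substr(rs, i * 3000, i * 3000 + 399), 0.03), character(1)),
    paste0("q", 1:8))
  h <- local_align(qs, ref)
  expect_gt(nrow(h), 0)
  for (i in seq_len(nrow(h))) {
    qa <- strsplit(h$qaln[i], "")[[1]]
    sa <- strsplit(h$saln[i], "")[[1]]
    expect_equal(length(qa), h$length[i])
    aligned <- qa != "-" & sa != "-"
    expect_equal(sum(aligned & qa != sa), h$mismatch[i])
    expect_equal(100 * sum(aligned & qa == sa) / length(qa), h$pident[i])
    runs <- rle(ifelse(qa == "-", 1L, ifelse(sa == "-", 2L, 0L)))
    expect_equal(sum(runs$values != 0), h$gapopen[i])
    # subject footprint length equals non-gap subject columns
    expect_equal(sum(sa != "-"), h$send[i] - h$sstart[i] + 1)
    # the aligned subject string matches the reference at the claimed spot
    expect_identical(paste(sa[sa != "-"], collapse = ""),
                     substr(rs, h$sstart[i], h$send[i]))
  }
})

test_that("no emitted gap run exceeds 26 bases; long deletions split hits", {
  set.seed(6)
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(10000)))
  rs <- as.character(ref[[1]])
  # query with a 40 bp deletion relative to the reference: gap would
  # exceed the cap, so extension stops and two hits emerge
  q40 <- paste0(substr(rs, 2001, 2400), substr(rs, 2441, 2840))
  # query with a small 5 bp deletion: one gapped hit
  q5 <- paste0(substr(rs, 5001, 5400), substr(rs, 5406, 5805))
  h <- local_align(c(big = q40, small = q5), ref)
  expect_false(any(grepl("-{27,}", c(h$qaln, h$saln))))
  hb <- h[h$qseqid == "big", ]
  expect_gte(nrow(hb), 2)
  hs <- h[h$qseqid == "small", ]
  expect_equal(nrow(hs), 1)
  expect_equal(hs$gapopen, 1)
})

test_that("queries shorter than the seed length are skipped with a warning", {
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(1000)))
  expect_warning(h <- local_align(c(tiny = "ACGT"), ref), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("E-values follow the Karlin-Altschul closed form", {
  p <- align_params(lambda = 1.33, kappa = 0.621)
  # direct evaluation of kappa m n exp(-lambda S)
  expect_equal(evalue(30, 1000, 1000, p), 0.621 * 1e6 * exp(-1.33 * 30))
  expect_equal(evalue(50, 1000, 2000, p) / evalue(50, 1000, 1000, p), 2)
  expect_lt(evalue(100, 1000, 1000, p), evalue(99, 1000, 1000, p))
  expect_equal(evalue(1e6, 1000, 1000, p), 0)  # S -> Inf drives E -> 0
  expect_error(evalue(30, 0, 1000, p), "positive")
})

test_that("repeat screening partitions reads with a strict E cutoff", {
  ref <- fx_small_ref()
  unit <- as.character(ref$repeat_library[["repfam01"]])
  set.seed(7)
  reads <- c(repread = paste0(unit, substr(unit, 1, 250)),  # 550 bp of repeat
             randread = rand_dna(600))
  scr <- screen_repeats(reads, ref$repeat_library)
  expect_equal(scr$repeat_ids, "repread")
  expect_equal(names(scr$nonrepeat), "randread")
  # strictness: a cutoff equal to the best E keeps the read non-repeat
  h <- local_align(reads["repread"], ref$repeat_library)
  best <- min(h$evalue)
  scr2 <- screen_repeats(reads, ref$repeat_library, evalue_cutoff = best)
  expect_false("repread" %in% scr2$repeat_ids)
  # empty read set is not an error
  scr3 <- screen_repeats(reads[0], ref$repeat_library)
  expect_equal(length(scr3$repeat_ids), 0)
})

test_that("hits round-trip through the tabular dialect", {
  set.seed(8)
  ref <- Biostrings::DNAStringSet(c(chrA = rand_dna(20000)))
  rs <- as.character(ref[[1]])
  qs <- c(fwd = substr(rs, 1001, 1600), rev = rc(substr(rs, 3001, 3600)))
  h <- local_align(qs, ref)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(h, f)
  # minus-strand rows carry sstart > send in the file
  raw <- read.table(f, sep = "\t")
  expect_true(any(raw$V9 > raw$V10))
  back <- read_hits(f, qlen = setNames(nchar(qs), names(qs)))
  expect_equal(back$sstart, h$sstart)
  expect_equal(back$send, h$send)
  expect_equal(back$strand, h$strand)
  expect_equal(back$qcovg, h$qcovg)
  expect_identical(back$qaln, h$qaln)
  # 12-column files read back without aligned strings
  write_hits(h, f, aligned_strings = FALSE)
  back12 <- read_hits(f)
  expect_true(all(is.na(back12$qaln)))
})
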