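test_that("significance thresholds are strict at their boundaries", {
  h <- rbind(mk_hit("a.T7", pident = 95, qcovg = 0.6, evalue = 1e-120),
             mk_hit("b.T7", pident = 90, qcovg = 0.6, evalue = 1e-120),
             mk_hit("c.T7", pident = 95, qcovg = 0.5, evalue = 1e-120),
             mk_hit("d.T7", pident = 95, qcovg = 0.6, evalue = 1e-100))
  kept <- filter_hits(h, placement_rules())
  expect_equal(kept$qseqid, "a.T7")
})

test_that("clone classes and concordance follow the pairing criteria", {
  rules <- placement_rules()
  hits <- rbind(
    # concordant unique pair, 100 kb apart, inward facing
    mk_hit("cl1.T7", sstart = 100000, send = 100700, strand = "+"),
    mk_hit("cl1.SP6", sstart = 199300, send = 200000, strand = "-"),
    # discordant: both minus (Table-2-style inversion geometry, ch02)
    mk_hit("cl2.T7", sseqid = "ch02", sstart = 29374874, send = 29375640,
           strand = "-"),
    mk_hit("cl2.SP6", sseqid = "ch02", sstart = 29494209, send = 29494781,
           strand = "-"),
    # discordant: 49 Mb apart and both minus (ch03 geometry)
    mk_hit("cl3.T7", sseqid = "ch03", sstart = 6601537, send = 6602368,
           strand = "-"),
    mk_hit("cl3.SP6", sseqid = "ch03", sstart = 55664754, send = 55665559,
           strand = "-"),
    # one end redundant (two significant hits), mate unique
    mk_hit("cl4.T7", sstart = 1000, send = 1700),
    mk_hit("cl4.T7", sseqid = "chr02", sstart = 5000, send = 5700),
    mk_hit("cl4.SP6", sstart = 90000, send = 90700, strand = "-"),
    # weak end: a hit below the thresholds
    mk_hit("cl5.T7", pident = 85, sstart = 1000, send = 1600),
    mk_hit("cl5.SP6", sstart = 50000, send = 50700, strand = "-"))
  reads <- c("cl1.T7", "cl1.SP6", "cl2.T7", "cl2.SP6", "cl3.T7", "cl3.SP6",
             "cl4.T7", "cl4.SP6", "cl5.T7", "cl5.SP6", "cl6.T7", "cl6.SP6",
             "cl7.T7")
  ends <- classify_ends(hits, reads, rules, repeat_ids = c("cl6.T7",
                                                           "cl6.SP6"))
  st <- setNames(ends$status, ends$read_id)
  expect_equal(unname(st[c("cl1.T7", "cl4.T7", "cl5.T7", "cl6.T7",
                           "cl7.T7")]),
               c("UNIQUE", "REDUNDANT", "WEAK", "REPEAT", "NO_HIT"))

  clones <- classify_clones(ends, rules)
  cl <- clones[match(paste0("cl", 1:7), clones$clone_id), ]
  expect_equal(cl$class,
               c("UNIQUE_PAIR", "UNIQUE_PAIR", "UNIQUE_PAIR", "UNIQUE_END",
                 "UNIQUE_END", "EXCLUDED", "EXCLUDED"))
  expect_equal(cl$concordance[1:3],
               c("CONCORDANT", "DISCORDANT", "DISCORDANT"))
  expect_equal(cl$span[1], 100001)
  # missing mate read is treated as NO_HIT for that end
  expect_equal(cl$end2_status[7], "NO_HIT")
})

test_that("outward-facing and over-distance unique pairs are discordant", {
  rules <- placement_rules()
  hits <- rbind(
    mk_hit("o.T7", sstart = 100000, send = 100700, strand = "-"),
    mk_hit("o.SP6", sstart = 150000, send = 150700, strand = "+"),
    mk_hit("far.T7", sstart = 100000, send = 100700, strand = "+"),
    mk_hit("far.SP6", sstart = 340000, send = 340700, strand = "-"))
  ends <- classify_ends(hits, unique(hits$qseqid), rules)
  clones <- classify_clones(ends, rules)
  expect_true(all(clones$concordance == "DISCORDANT"))
})

test_that("placement matches an exhaustive rule-by-rule evaluator", {
  set.seed(11)
  n <- 200
  rows <- list()
  for (i in 1:n) {
    for (suf in c("T7", "SP6")) {
      id <- sprintf("MTX%04d.%s", i, suf)
      for (k in seq_len(sample(0:3, 1)))
        rows[[length(rows) + 1L]] <- mk_hit(
          id, sseqid = sample(c("chr01", "chr02"), 1),
          strand = sample(c("+", "-"), 1),
          pident = runif(1, 80, 100), qcovg = runif(1, 0.3, 1),
          evalue = 10^-runif(1, 60, 200),
          sstart = (s <- sample.int(5e6, 1)), send = s + 699)
    }
  }
  hits <- do.call(rbind, rows)
  reads <- sort(unique(c(sprintf("MTX%04d.T7", 1:n),
                         sprintf("MTX%04d.SP6", 1:n))))
  repeat_ids <- sample(reads, 20)
  rules <- placement_rules()

  ends <- classify_ends(hits, reads, rules, repeat_ids)
  clones <- classify_clones(ends, rules)

  ## ---- independent exhaustive evaluator (loops, no shared helpers) ----
  eval_end <- function(id) {
    if (id %in% repeat_ids) return(list(status = "REPEAT"))
    hh <- hits[hits$qseqid == id, , drop = FALSE]
    if (nrow(hh) == 0) return(list(status = "NO_HIT"))
    sig <- list()
    for (j in seq_len(nrow(hh)))
      if (hh$pident[j] > 90 && hh$qcovg[j] > 0.5 && hh$evalue[j] < 1e-100)
        sig[[length(sig) + 1L]] <- hh[j, ]
    if (length(sig) == 0) return(list(status = "WEAK"))
    if (length(sig) >= 2) return(list(status = "REDUNDANT"))
    list(status = "UNIQUE", hit = sig[[1]])
  }
  for (i in 1:n) {
    cid <- sprintf("MTX%04d", i)
    e1 <- eval_end(paste0(cid, ".T7"))
    e2 <- eval_end(paste0(cid, ".SP6"))
    nu <- (e1$status == "UNIQUE") + (e2$status == "UNIQUE")
    want_class <- if (nu == 2) "UNIQUE_PAIR" else if (nu == 1) "UNIQUE_END"
                  else "EXCLUDED"
    row <- clones[clones$clone_id == cid, ]
    expect_equal(row$class, want_class, info = cid)
    if (nu == 2) {
      want_conc <- "DISCORDANT"
      if (e1$hit$sseqid == e2$hit$sseqid) {
        lo <- min(e1$hit$sstart, e2$hit$sstart)
        hi <- max(e1$hit$send, e2$hit$send)
        left <- if (e1$hit$sstart <= e2$hit$sstart) e1$hit else e2$hit
        right <- if (e1$hit$sstart <= e2$hit$sstart) e2$hit else e1$hit
        if (left$strand == "+" && right$strand == "-" &&
            (hi - lo + 1) < 200000) want_conc <- "CONCORDANT"
      }
      expect_equal(row$concordance, want_conc, info = cid)
    }
  }
})

test_that("flow counts partition the reads and give the selected fraction", {
  p <- fx_negative_pipeline()
  f <- p$flow
  expect_equal(f$`repeat` + f$no_hit + f$weak + f$redundant +
                 f$unique_pair_ends + f$unique_ends, f$total)
  expect_equal(f$selection_fraction,
               round(100 * (f$unique_pair_ends + f$unique_ends) / f$total, 1))
})

test_that("insert spans and histogram fractions follow the definition", {
  ends <- classify_ends(rbind(
    mk_hit("c.T7", sstart = 1, send = 700, strand = "+"),
    mk_hit("c.SP6", sstart = 100101, send = 100800, strand = "-")),
    c("c.T7", "c.SP6"), placement_rules())
  clones <- classify_clones(ends)
  expect_equal(clones$span, 100800)
  s <- insert_size_stats(clones)
  expect_equal(s$n, 1)
  expect_equal(sum(s$histogram$count), 1)
  # modal-bin arithmetic, fed the published mapped-clone counts
  rest <- 14101 - 6396
  spans <- c(rep(110000, 6396),
             rep(c(70000, 130000, 150000, 170000), length.out = rest))
  fake <- data.frame(class = "UNIQUE_PAIR", concordance = "CONCORDANT",
                     span = spans)
  s2 <- insert_size_stats(fake)
  expect_equal(s2$modal_bin_fraction, 45.4)
  expect_equal(sum(s2$histogram$count), 14101)
})

test_that("no concordant placements yields empty statistics with a warning", {
  fake <- data.frame(class = "UNIQUE_PAIR", concordance = "DISCORDANT",
                     span = NA_integer_)
  expect_warning(s <- insert_size_stats(fake), "no concordant")
  expect_equal(s$n, 0)
})
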