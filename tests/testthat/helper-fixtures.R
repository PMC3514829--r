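# shared fixtures, built once per test run and memoized

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# random DNA string helper for tests (independent of package internals)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substitute bases at rate r (test-side mutator, independent of the package)
mutate_at <- function(s, r) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < r)
  v[i] <- vapply(v[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

# +1/-3 local-alignment scoring matrix for the Biostrings oracle
sw_matrix <- function() {
  m <- matrix(-3, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 1
  m
}

sw_oracle_score <- function(query, subject) {
  sc <- function(q) Biostrings::score(Biostrings::pairwiseAlignment(
    q, subject, type = "local", substitutionMatrix = sw_matrix(),
    gapOpening = 5, gapExtension = 2))
  max(sc(query), sc(rc(query)))
}

# an error-free run with one planted inversion and one inverted
# translocation, each spanned by many clones
fx_event_config <- function(seed = 42) {
  pipeline_config(
    gspec = genome_spec(n_chromosomes = 2, chrom_length = 1e6,
                        repeat_families = NULL, gene_density = 30),
    mspec = mutation_spec(
      snp_rate = 300 / 2e6, indel_rate = 60 / 2e6,
      inversions = data.frame(chrom = "chr01", start = 400001,
                              length = 50000),
      translocations = data.frame(chrom = "chr02", start = 150001,
                                  length = 30000, dest_chrom = "chr02",
                                  dest_pos = 800000, inverted = TRUE)),
    lspec = library_spec(n_clones = 400, per_base_error = 0),
    seed = seed)
}

fx_event_pipeline <- function() memo("event_pipeline", function()
  run_pipeline(fx_event_config()))

# rearrangement-free negative control on a repeat-rich genome
fx_negative_pipeline <- function() memo("negative_pipeline", function()
  run_pipeline(pipeline_config(
    gspec = genome_spec(n_chromosomes = 1, chrom_length = 5e5,
                        gene_density = 30),
    mspec = mutation_spec(snp_rate = 1 / 3000, indel_rate = 1 / 10000),
    lspec = library_spec(n_clones = 120, per_base_error = 0),
    seed = 9)))

# small reference bundle for synth tests
fx_small_ref <- function() memo("small_ref", function()
  generate_reference(genome_spec(
    n_chromosomes = 2, chrom_length = 2e5,
    repeat_families = data.frame(unit_length = 300L, copies = 20L,
                                 divergence = 0),
    gene_density = 40, seed = 101)))

# build a QualityScaledDNAStringSet with given per-read mean qualities
reads_with_qv <- function(seqs, qv) {
  q <- vapply(seq_along(seqs), function(i)
    rawToChar(as.raw(rep(qv[i], nchar(seqs[i])) + 33L)), character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
}

# concordant-clone row constructor for contig/coverage tests
mk_clone <- function(id, chrom, start, end) {
  data.frame(clone_id = id, class = "UNIQUE_PAIR",
             concordance = "CONCORDANT", chrom = chrom,
             start = start, end = end, span = end - start + 1,
             stringsAsFactors = FALSE)
}

# hit-frame row constructor for placement tests
mk_hit <- function(qseqid, sseqid = "chr01", strand = "+", pident = 99,
                   qcovg = 0.9, evalue = 1e-150, sstart = 1000,
                   send = 1700, qlen = 700) {
  data.frame(qseqid = qseqid, sseqid = sseqid, strand = strand,
             pident = pident, length = as.integer(qlen * qcovg),
             mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = as.integer(qlen * qcovg), sstart = sstart, send = send,
             score = as.integer(qlen * qcovg), bitscore = 500,
             evalue = evalue, qlen = qlen, qcovg = qcovg,
             qaln = NA_character_, saln = NA_character_,
             stringsAsFactors = FALSE)
}
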