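# collapsing, exact mapping vs brute-force oracle, exclusivity filter

test_that("collapse_reads aggregates FASTA/FASTQ/counts input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1", "GATTACAGATTACA", ">r2", "GATTACAGATTACA",
               ">r3", "CCGGTTAACCGGAA"), fa)
  out <- collapse_reads(fa)
  expect_equal(out$library_total, 3L)
  expect_equal(out$reads$count[out$reads$sequence == "GATTACAGATTACA"], 2L)
  expect_equal(nrow(out$reads), 2L)

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "GATTACAGATTACA", "+", "IIIIIIIIIIIIII"), fq)
  out_fq <- collapse_reads(fq)
  expect_equal(out_fq$library_total, 1L)
  expect_equal(out_fq$reads$sequence, "GATTACAGATTACA")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("ACGTACGTACGTAC\t7", "acguacguacguac\t3"), tsv)
  out_tsv <- collapse_reads(tsv)
  # U->T and case folding merge the two rows
  expect_equal(nrow(out_tsv$reads), 1L)
  expect_equal(out_tsv$reads$count, 10L)
  expect_equal(out_tsv$library_total, 10L)
})

test_that("length bounds and N exclude reads from mapping, not the total", {
  tsv <- tempfile()
  writeLines(c("ACGTA\t5", "ACGTACGTACGTACG\t2", "ACGNACGTACGTACG\t1"), tsv)
  out <- collapse_reads(tsv, min_len = 14, max_len = 40)
  expect_equal(out$library_total, 8L)
  expect_equal(sum(out$reads$mappable), 1L)
  expect_equal(out$reads$sequence[out$reads$mappable], "ACGTACGTACGTACG")
  aln <- map_exact(out$reads, tiny_fixture()$ref)
  expect_false(any(aln$sequence == "ACGTA"))
})

test_that("map_exact places reads at every occurrence with exact offsets", {
  fx <- tiny_fixture()
  # the 8-mer prefix of mature 1 recurs at offset 7 (GATTACAG twice)
  aln <- map_exact(substr(TINY_MATURE1, 1, 8), fx$ref)
  expect_equal(aln$offset, c(0L, 7L))
  expect_equal(unique(aln$segment), "mature_plus_cca")
  expect_equal(unique(aln$gene), "tiny.trna1")
  # the 9-mer prefix is unique
  aln9 <- map_exact(substr(TINY_MATURE1, 1, 9), fx$ref)
  expect_equal(aln9$offset, 0L)
  # a read equal to a full trailer
  aln_tr <- map_exact(TINY_TRAILER2, fx$ref)
  expect_true(any(aln_tr$segment == "trailer" & aln_tr$offset == 0L &
                    aln_tr$gene == "tiny.trna2"))
  # suffix ending in appended CCA
  suffix <- substr(paste0(TINY_MATURE1, "CCA"), 12, 19)
  aln_3 <- map_exact(suffix, fx$ref)
  expect_equal(aln_3$end_offset[aln_3$gene == "tiny.trna1"],
               nchar(TINY_MATURE1) + 3L)
  # absent read
  expect_equal(nrow(map_exact("TTTTTTTTTTTTTT", fx$ref)), 0L)
})

test_that("overlapping occurrences are all reported", {
  ref <- random_reference(1, mature_len = 10)
  ref$entries$mature_plus_cca <- "AAAAAAACCA"
  ref$entries$trailer <- "GCGCGCGCGC"
  aln <- map_exact("AAAA", ref)
  expect_equal(aln$offset, 0:3)
  expect_equal(alignment_key(aln), alignment_key(oracle_map("AAAA", ref)))
})

test_that("every alignment reconstructs the read from the segment slice", {
  fx <- tiny_fixture()
  set.seed(3)
  reads <- vapply(1:50, function(i) random_read(fx$ref, len_range = c(4, 20)),
                  character(1))
  aln <- map_exact(reads, fx$ref)
  expect_gt(nrow(aln), 0)
  for (i in seq_len(nrow(aln))) {
    seg <- fx$ref$entries[[aln$segment[i]]][
      fx$ref$entries$name == aln$gene[i]]
    expect_identical(substr(seg, aln$offset[i] + 1L, aln$end_offset[i]),
                     aln$sequence[i])
  }
})

test_that("map_exact agrees with the brute-force oracle on random batteries", {
  set.seed(11)
  for (trial in 1:5) {
    ref <- random_reference(sample(3:10, 1), mature_len = sample(60:90, 1))
    reads <- unique(vapply(1:100, function(i) random_read(ref),
                           character(1)))
    got <- map_exact(reads, ref)
    want <- do.call(rbind, lapply(reads, oracle_map, ref = ref))
    expect_identical(alignment_key(got), alignment_key(want))
  }
})

test_that("exclusivity filter keeps tRNA-only reads and drops decoys", {
  read5 <- substr(TINY_MATURE1, 1, 14)
  fx_clean <- tiny_fixture()
  fx_decoy <- tiny_fixture(intergenic = paste0("GGTTCC", read5, "AACCGG"))
  # trailer reads are inside the padded locus, not "outside"
  expect_true(all(genome_exclusivity_filter(
    c(read5, TINY_TRAILER1), fx_clean$genome, fx_clean$genes, pad3 = 10)))
  # same read with an intergenic copy is dropped
  keep <- genome_exclusivity_filter(c(read5, TINY_TRAILER1),
                                    fx_decoy$genome, fx_decoy$genes,
                                    pad3 = 10)
  expect_equal(keep, c(FALSE, TRUE))
  # a read occurring in two tRNA loci only is kept (multi-parent)
  g2 <- c(chrD = paste0("AAATTT", TINY_MATURE1, "CGCGCG", TINY_MATURE1,
                        "TTTAAA"))
  genes2 <- validate_trna_genes(data.frame(
    name = c("d1", "d2"), chrom = "chrD",
    start = c(6L, 6L + nchar(TINY_MATURE1) + 6L),
    end = c(6L + nchar(TINY_MATURE1),
            6L + 2L * nchar(TINY_MATURE1) + 6L),
    strand = "+", stringsAsFactors = FALSE))
  expect_true(genome_exclusivity_filter(read5, g2, genes2, pad3 = 0))
})

test_that("exclusivity decisions are symmetric under genome revcomp", {
  fx <- tiny_fixture(intergenic = paste0("GG", substr(TINY_MATURE2, 1, 14)))
  seqs <- c(substr(TINY_MATURE1, 1, 14), substr(TINY_MATURE2, 1, 14),
            TINY_TRAILER1)
  fwd <- genome_exclusivity_filter(seqs, fx$genome, fx$genes, pad3 = 10)
  n <- nchar(fx$genome[["chrT"]])
  rc_genome <- c(chrT = revcomp(fx$genome[["chrT"]]))
  rc_genes <- fx$genes
  rc_genes$start <- n - fx$genes$end
  rc_genes$end <- n - fx$genes$start
  rc_genes$strand <- ifelse(fx$genes$strand == "+", "-", "+")
  rc_genes <- validate_trna_genes(rc_genes)
  rev <- genome_exclusivity_filter(seqs, rc_genome, rc_genes, pad3 = 10)
  expect_equal(rev, fwd)
  expect_equal(fwd, c(TRUE, FALSE, TRUE))
})

test_that("alignment TSV round-trips", {
  fx <- tiny_fixture()
  aln <- map_exact(c(substr(TINY_MATURE1, 1, 10), TINY_TRAILER2), fx$ref)
  f <- tempfile(fileext = ".tsv")
  write_alignments(aln, f)
  expect_equal(read_alignments(f), aln)
})
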