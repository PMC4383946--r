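# Hand-built two-gene fixture (one gene per strand) and independent oracles.
# All coordinates are computed from the designed pieces, never hard-coded.

# designed transcripts (5'->3' in transcription orientation)
TINY_MATURE1 <- "GATTACAGATTACAGG"                 # gene 1, plus strand
TINY_TRAILER1 <- "TTCGATTTTA"                      # 10 nt, has a TTTT tract
TINY_MATURE2 <- "CCGGTTAACCGGAATT"                 # gene 2, minus strand
TINY_TRAILER2 <- "AGGTTTTCAA"

tiny_fixture <- function(intergenic = "") {
  left <- "TTGACA"
  mid <- "GGCCAAGGTC"
  block2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(
      paste0(TINY_MATURE2, TINY_TRAILER2))))
  contig <- paste0(left, TINY_MATURE1, TINY_TRAILER1, mid, block2,
                   "ACGTGGCC", intergenic)
  g1_start <- nchar(left)
  g2_start <- nchar(left) + nchar(TINY_MATURE1) + nchar(TINY_TRAILER1) +
    nchar(mid) + nchar(TINY_TRAILER2)
  genes <- data.frame(
    name = c("tiny.trna1", "tiny.trna2"),
    chrom = "chrT",
    start = c(g1_start, g2_start),
    end = c(g1_start + nchar(TINY_MATURE1), g2_start + nchar(TINY_MATURE2)),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  genes <- validate_trna_genes(genes)
  genome <- c(chrT = contig)
  ref <- build_reference(genome, genes, trailer_len = 10)
  list(genome = genome, genes = genes, ref = ref)
}

# brute-force all-positions oracle for exact full-length mapping,
# independent of the package's hashed index
oracle_map <- function(read, ref) {
  rows <- list()
  L <- nchar(read)
  for (i in seq_len(nrow(ref$entries))) {
    for (segment in c("mature_plus_cca", "trailer")) {
      s <- ref$entries[[segment]][i]
      n <- nchar(s)
      if (L > n || L == 0) next
      starts <- 1:(n - L + 1L)
      hit <- which(substring(s, starts, starts + L - 1L) == read)
      for (o in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = read, gene = ref$entries$name[i], segment = segment,
          offset = o - 1L, end_offset = o - 1L + L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(0), gene = character(0),
                      segment = character(0), offset = integer(0),
                      end_offset = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# canonical string form of an alignment set, for set comparison
alignment_key <- function(df) {
  sort(paste(df$sequence, df$gene, df$segment, df$offset, sep = "|"))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random reference with n_entries genes; segments are random strings
random_reference <- function(n_entries, mature_len = 75, trailer_len = 50) {
  entries <- data.frame(
    name = sprintf("rnd.trna%d", seq_len(n_entries)),
    mature_plus_cca = vapply(seq_len(n_entries), function(i)
      paste0(random_dna_str(mature_len), "CCA"), character(1)),
    trailer = vapply(seq_len(n_entries), function(i)
      random_dna_str(trailer_len), character(1)),
    chrom = "chrR", start = 0L, end = 1L, strand = "+",
    stringsAsFactors = FALSE
  )
  structure(list(species = "random", trailer_len = trailer_len,
                 entries = entries), class = "trf_reference")
}

# draw a read: either a true substring of some segment or a random string
random_read <- function(ref, p_positive = 0.6, len_range = c(14, 40)) {
  L <- sample(len_range[1]:len_range[2], 1)
  if (stats::runif(1) < p_positive) {
    i <- sample(nrow(ref$entries), 1)
    s <- ref$entries[[sample(c("mature_plus_cca", "trailer"), 1)]][i]
    if (nchar(s) >= L) {
      o <- sample(nchar(s) - L + 1L, 1)
      return(substr(s, o, o + L - 1L))
    }
  }
  random_dna_str(L)
}
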