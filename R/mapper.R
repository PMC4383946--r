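# Read collapsing, exact full-length placement, genome-exclusivity filter.

#' Collapse a small RNA library to unique sequences with counts
#'
#' Accepts FASTA, FASTQ (qualities ignored) or a 2-column "sequence<TAB>count"
#' file. Reads outside \code{[min_len, max_len]} and reads containing N are
#' excluded from mapping (\code{mappable = FALSE}) but still counted in
#' \code{library_total}, the RPM denominator.
#'
#' @param path input file.
#' @param min_len,max_len mapped-read length bounds (defaults 14 and 40 nt,
#'   the usual small RNA insert range).
#' @param format \code{"auto"} sniffs from the first character / extension.
#' @return list with \code{reads} (data.frame: sequence, count, mappable)
#'   and \code{library_total} (total input reads).
#' @export
collapse_reads <- function(path, min_len = 14L, max_len = 40L,
                           format = c("auto", "fasta", "fastq", "counts")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("reads file not found: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1, 1)
    format <- switch(first, ">" = "fasta", "@" = "fastq", "counts")
  }
  if (format == "counts") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("sequence", "count"),
                             colClasses = c("character", "integer"))
    if (any(tab$count < 1)) stop("counts file: counts must be >= 1")
    seqs <- normalize_sequence(tab$sequence, allow_n = TRUE)
    agg <- tapply(tab$count, seqs, sum)
    reads <- data.frame(sequence = names(agg), count = as.integer(agg),
                        stringsAsFactors = FALSE)
  } else {
    dna <- tryCatch(
      Biostrings::readDNAStringSet(path, format = format),
      error = function(e) stop("failed to parse ", format, " file ", path,
                               ": ", conditionMessage(e)))
    reads <- collapse_sequences(as.character(dna))
  }
  finish_collapse(reads, min_len, max_len)
}

#' Collapse an in-memory vector of read sequences
#'
#' @param seqs character vector, one element per sequenced read.
#' @param counts optional parallel counts (for pre-aggregated input).
#' @return data.frame with \code{sequence} and \code{count}.
#' @export
collapse_sequences <- function(seqs, counts = NULL) {
  seqs <- normalize_sequence(seqs, allow_n = TRUE)
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  agg <- tapply(counts, seqs, sum)
  data.frame(sequence = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE)
}

finish_collapse <- function(reads, min_len, max_len) {
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  len <- nchar(reads$sequence)
  reads$mappable <- len >= min_len & len <= max_len &
    !grepl("N", reads$sequence, fixed = TRUE)
  list(reads = reads, library_total = sum(reads$count))
}

#' Map reads onto a reference by exact full-length matching
#'
#' Every occurrence of each read as an exact substring (overlapping
#' occurrences included) of every entry's mature+CCA and trailer segment is
#' reported: the 100\%-length / 100\%-identity criterion, realized as a
#' deterministic hashed index of all reference substrings at the read
#' lengths present. Output is ordered by entry, then segment
#' (mature_plus_cca before trailer), then offset, then sequence.
#'
#' @param reads data.frame with \code{sequence} and \code{count} (a bare
#'   character vector is also accepted, counts default to 1); rows with
#'   \code{mappable = FALSE} are skipped.
#' @param ref \code{trf_reference}.
#' @return alignments data.frame: sequence, count, gene, segment, offset
#'   (0-based start within the segment), end_offset.
#' @export
map_exact <- function(reads, ref) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, count = 1L, stringsAsFactors = FALSE)
  }
  if (!is.null(reads$mappable)) reads <- reads[reads$mappable, , drop = FALSE]
  empty <- data.frame(sequence = character(0), count = integer(0),
                      gene = character(0), segment = character(0),
                      offset = integer(0), end_offset = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(ref$entries) == 0) return(empty)
  idx <- reference_index(ref, sort(unique(nchar(reads$sequence))))
  if (nrow(idx) == 0) return(empty)
  hit <- idx[idx$sequence %in% reads$sequence, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  res <- data.frame(
    sequence = hit$sequence,
    count = reads$count[match(hit$sequence, reads$sequence)],
    gene = hit$gene,
    segment = hit$segment,
    offset = hit$offset,
    end_offset = hit$offset + nchar(hit$sequence),
    stringsAsFactors = FALSE
  )
  ord <- order(hit$entry_rank, match(hit$segment, c("mature_plus_cca",
                                                    "trailer")),
               hit$offset, hit$sequence)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Enumerate every substring of every reference segment at the given lengths,
# with its position: the exact-match search index. Size is
# O(segment length x number of lengths), small for tRNA-scale references.
reference_index <- function(ref, lengths) {
  rows <- vector("list", nrow(ref$entries) * 2L)
  k <- 0L
  for (i in seq_len(nrow(ref$entries))) {
    for (segment in c("mature_plus_cca", "trailer")) {
      s <- ref$entries[[segment]][i]
      n <- nchar(s)
      Ls <- lengths[lengths <= n & lengths >= 1]
      if (length(Ls) == 0 || n == 0) next
      starts <- unlist(lapply(Ls, function(L) seq_len(n - L + 1L)),
                       use.names = FALSE)
      lens <- rep.int(Ls, n - Ls + 1L)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sequence = substring(s, starts, starts + lens - 1L),
        gene = ref$entries$name[i],
        segment = segment,
        offset = starts - 1L,
        entry_rank = i,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), gene = character(0),
                      segment = character(0), offset = integer(0),
                      entry_rank = integer(0), stringsAsFactors = FALSE)
  }
  out
}

# 0-based half-open genomic intervals covered by each tRNA locus, extended by
# pad3 downstream of the 3' end and pad5 upstream of the 5' end in
# transcription orientation (strand-aware).
padded_loci <- function(genes, pad3, pad5) {
  plus <- genes$strand == "+"
  data.frame(
    chrom = genes$chrom,
    start = pmax(0L, ifelse(plus, genes$start - pad5, genes$start - pad3)),
    end = ifelse(plus, genes$end + pad3, genes$end + pad5),
    stringsAsFactors = FALSE
  )
}

#' Genome-exclusivity filter
#'
#' A read is kept only if every exact occurrence of its sequence (or its
#' reverse complement: both strands are searched) in the genome falls inside
#' a tRNA locus extended by \code{pad3} bases downstream (default: the
#' trailer length, so trailer hits are not counted as outside) and
#' \code{pad5} bases upstream. Reads with any hit outside are dropped as
#' non-tRNA-exclusive; reads hitting several tRNA loci are kept
#' (multi-parent fragments).
#'
#' @param sequences character vector of read sequences (each with at least
#'   one reference alignment).
#' @param genome named character vector from [read_genome()].
#' @param genes \code{trna_genes} table (or a \code{trf_reference}, whose
#'   entry coordinates are then used).
#' @param pad3 downstream pad, default 50 (trailer length).
#' @param pad5 upstream pad, default 0.
#' @return logical vector: \code{TRUE} = keep.
#' @export
genome_exclusivity_filter <- function(sequences, genome, genes,
                                      pad3 = 50L, pad5 = 0L) {
  if (inherits(genes, "trf_reference")) genes <- genes$entries
  loci <- padded_loci(genes, pad3, pad5)
  keep <- rep(TRUE, length(sequences))
  rc <- revcomp(sequences)
  for (chrom in names(genome)) {
    contig <- genome[[chrom]]
    ivs <- loci[loci$chrom == chrom, , drop = FALSE]
    for (strand_seqs in list(sequences, rc)) {
      hits <- stringi::stri_locate_all_fixed(contig, strand_seqs,
                                             overlap = TRUE)
      for (j in seq_along(hits)) {
        if (!keep[j]) next
        m <- hits[[j]]
        m <- m[!is.na(m[, 1]), , drop = FALSE]
        if (nrow(m) == 0) next
        s0 <- m[, 1] - 1L            # 0-based start
        e0 <- m[, 2]                 # half-open end
        inside <- rep(FALSE, nrow(m))
        for (r in seq_len(nrow(ivs))) {
          inside <- inside | (s0 >= ivs$start[r] & e0 <= ivs$end[r])
        }
        if (!all(inside)) keep[j] <- FALSE
      }
    }
  }
  keep
}

#' Map a collapsed library and apply the exclusivity filter
#'
#' Convenience wrapper: [map_exact()] then [genome_exclusivity_filter()] on
#' the distinct mapped sequences. Alignments of dropped reads are removed.
#'
#' @inheritParams map_exact
#' @inheritParams genome_exclusivity_filter
#' @return list: \code{alignments} (filtered), \code{dropped} (character
#'   vector of non-exclusive sequences).
#' @export
map_and_filter <- function(reads, ref, genome, genes = ref,
                           pad3 = ref$trailer_len, pad5 = 0L) {
  aln <- map_exact(reads, ref)
  seqs <- unique(aln$sequence)
  if (length(seqs) == 0) return(list(alignments = aln, dropped = character(0)))
  keep <- genome_exclusivity_filter(seqs, genome, genes, pad3, pad5)
  dropped <- seqs[!keep]
  list(alignments = aln[!(aln$sequence %in% dropped), , drop = FALSE],
       dropped = dropped)
}

#' Write / read an alignment table (TSV)
#'
#' @param alignments alignment data.frame from [map_exact()].
#' @param path TSV file.
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character", "integer", "integer"))
}
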