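# Reference construction: mature tRNA (+CCA) and 3' trailer search space.

#' Normalize a nucleotide string
#'
#' Uppercases, converts RNA U to DNA T. Characters outside \code{A,C,G,T,N}
#' raise an error; \code{N} is tolerated here (mapping excludes such reads
#' later, since exact matching at 100\% identity cannot place them).
#'
#' @param x character vector of sequences.
#' @param allow_n if \code{FALSE}, sequences containing N are also rejected.
#' @return normalized character vector.
#' @export
normalize_sequence <- function(x, allow_n = TRUE) {
  x <- chartr("acgtun", "ACGTTN", toupper(x))
  x <- chartr("U", "T", x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- stringi::stri_detect_regex(x, paste0("[^", alphabet, "]"))
  if (any(bad)) {
    stop("sequence contains characters outside {", alphabet, "}: ",
         substr(x[which(bad)[1]], 1, 40))
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a (multi-contig) genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig, normalized to
#'   uppercase DNA.
#' @export
read_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  g <- as.character(dna)
  # FASTA headers may carry descriptions; contig name is the first word
  names(g) <- sub("\\s.*$", "", names(dna))
  chartr("U", "T", toupper(g))
}

#' Load tRNA gene annotations
#'
#' Reads a BED6 file or a gtRNAdb-style tab-separated export into a
#' \code{trna_genes} table. Internally all coordinates are 0-based half-open;
#' the \code{coord} dialect flag says how to interpret the file
#' (\code{"bed"}: 0-based half-open; \code{"gtrnadb"}: 1-based inclusive).
#'
#' gtRNAdb dialect columns: name, chrom, start, end, strand and optionally
#' intron_starts/intron_ends (comma-separated, same dialect as the
#' gene coordinates). BED6 columns: chrom, start, end, name, score, strand.
#'
#' @param path annotation file.
#' @param coord coordinate dialect, \code{"bed"} or \code{"gtrnadb"}.
#' @return a \code{trna_genes} data.frame with columns \code{name},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} and a list column
#'   \code{introns} (each element a 2-column matrix of 0-based half-open
#'   intron coordinates, possibly 0-row).
#' @export
load_trna_annotation <- function(path, coord = c("bed", "gtrnadb")) {
  coord <- match.arg(coord)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(empty_trna_genes())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (coord == "bed") 6L else 5L
  n_cols <- lengths(fields)
  if (any(n_cols < min_cols)) {
    bad <- which(n_cols < min_cols)[1]
    stop("malformed annotation row at line ", bad, ": expected >= ",
         min_cols, " tab-separated fields, got ", n_cols[bad])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (coord == "bed") {
    genes <- data.frame(
      name   = get(4),
      chrom  = get(1),
      start  = suppressWarnings(as.integer(get(2))),
      end    = suppressWarnings(as.integer(get(3))),
      strand = get(6),
      stringsAsFactors = FALSE
    )
    genes$introns <- replicate(nrow(genes), empty_introns(), simplify = FALSE)
  } else {
    genes <- data.frame(
      name   = get(1),
      chrom  = get(2),
      start  = suppressWarnings(as.integer(get(3))) - 1L,  # 1-based -> 0-based
      end    = suppressWarnings(as.integer(get(4))),
      strand = get(5),
      stringsAsFactors = FALSE
    )
    genes$introns <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 7 || !nzchar(f[6]) || !nzchar(f[7])) return(empty_introns())
      s <- as.integer(strsplit(f[6], ",", fixed = TRUE)[[1]]) - 1L
      e <- as.integer(strsplit(f[7], ",", fixed = TRUE)[[1]])
      cbind(start = s, end = e)
    })
  }
  if (anyNA(genes$start) || anyNA(genes$end)) {
    bad <- which(is.na(genes$start) | is.na(genes$end))[1]
    stop("malformed annotation row at line ", bad, ": non-numeric coordinates")
  }
  validate_trna_genes(genes)
}

empty_introns <- function() cbind(start = integer(0), end = integer(0))

empty_trna_genes <- function() {
  g <- data.frame(name = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), stringsAsFactors = FALSE)
  g$introns <- list()
  class(g) <- c("trna_genes", "data.frame")
  g
}

#' Validate a tRNA gene table
#'
#' Checks strand symbols, coordinate sanity, duplicate names and intron
#' placement; returns the table with class \code{trna_genes}.
#'
#' @param genes data.frame as produced by [load_trna_annotation()].
#' @return validated \code{trna_genes} object.
#' @export
validate_trna_genes <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- which(!(genes$strand %in% c("+", "-")))[1]
    stop("invalid strand '", genes$strand[bad], "' for gene ", genes$name[bad],
         " (must be + or -)")
  }
  if (any(genes$end <= genes$start)) {
    bad <- which(genes$end <= genes$start)[1]
    stop("gene ", genes$name[bad], ": end must exceed start")
  }
  if (anyDuplicated(genes$name)) {
    stop("duplicate gene name: ", genes$name[anyDuplicated(genes$name)])
  }
  if (is.null(genes$introns)) {
    genes$introns <- replicate(nrow(genes), empty_introns(), simplify = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    ivs <- genes$introns[[i]]
    if (nrow(ivs) == 0) next
    if (any(ivs[, 1] <= genes$start[i]) || any(ivs[, 2] >= genes$end[i]) ||
        any(ivs[, 2] <= ivs[, 1])) {
      stop("gene ", genes$name[i], ": introns must lie strictly inside the gene")
    }
  }
  class(genes) <- unique(c("trna_genes", class(genes)))
  genes
}

#' Write tRNA gene annotations
#'
#' Inverse of [load_trna_annotation()]; used for round-trip checks and
#' simulator output.
#'
#' @param genes \code{trna_genes} table.
#' @param path output file.
#' @param coord coordinate dialect to render.
#' @export
write_trna_annotation <- function(genes, path, coord = c("bed", "gtrnadb")) {
  coord <- match.arg(coord)
  if (coord == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes$chrom, genes$start, genes$end, genes$name, genes$strand)
  } else {
    istr <- vapply(genes$introns, function(iv) {
      if (nrow(iv) == 0) return(c("", ""))
      c(paste(iv[, 1] + 1L, collapse = ","), paste(iv[, 2], collapse = ","))
    }, character(2))
    lines <- sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s",
                     genes$name, genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, istr[1, ], istr[2, ])
  }
  writeLines(lines, path)
  invisible(path)
}

slice_genome <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  contig <- genome[[chrom]]
  if (start < 0 || end > nchar(contig)) {
    stop("coordinates [", start, ", ", end, ") exceed contig ", chrom,
         " (length ", nchar(contig), ")")
  }
  substr(contig, start + 1L, end)
}

#' Extract the mature tRNA sequence of one gene
#'
#' Takes the genomic span, splices out annotated introns, and
#' reverse-complements for minus-strand genes so the result reads 5' to 3'
#' in transcription orientation. Does not append CCA; see
#' [build_reference()].
#'
#' @param genome named character vector from [read_genome()].
#' @param gene one row of a \code{trna_genes} table (data.frame or list).
#' @return mature sequence over \{A,C,G,T\}.
#' @export
extract_mature_sequence <- function(genome, gene) {
  gene <- as_gene_row(gene)
  ivs <- gene$introns
  # exonic blocks on the plus strand of the genome
  bounds <- c(gene$start, t(ivs), gene$end)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  blocks <- mapply(function(s, e) slice_genome(genome, gene$chrom, s, e),
                   starts, ends)
  s <- normalize_sequence(paste(blocks, collapse = ""), allow_n = TRUE)
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Extract the 3' trailer of one gene
#'
#' Returns the \code{n} bases immediately 3' of the gene in transcription
#' orientation: genomically downstream of \code{end} for plus-strand genes,
#' the reverse complement of the \code{n} bases before \code{start} for
#' minus-strand genes. Truncated silently (with a message) at contig ends.
#'
#' @param genome named character vector.
#' @param gene one gene row.
#' @param n trailer length, default 50.
#' @return trailer sequence of length \code{<= n}.
#' @export
extract_trailer <- function(genome, gene, n = 50L) {
  stopifnot(n >= 1)
  gene <- as_gene_row(gene)
  contig_len <- nchar(genome[[gene$chrom]])
  if (gene$strand == "+") {
    s <- gene$end
    e <- min(gene$end + n, contig_len)
    out <- slice_genome(genome, gene$chrom, s, e)
  } else {
    s <- max(gene$start - n, 0L)
    out <- revcomp(slice_genome(genome, gene$chrom, s, gene$start))
  }
  if (nchar(out) < n) {
    message("trailer of ", gene$name, " truncated to ", nchar(out),
            " nt at contig boundary")
  }
  normalize_sequence(out, allow_n = TRUE)
}

as_gene_row <- function(gene) {
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1)
    g <- as.list(gene[1, c("name", "chrom", "start", "end", "strand")])
    g$introns <- if (!is.null(gene$introns)) gene$introns[[1]] else empty_introns()
    return(g)
  }
  if (is.null(gene$introns)) gene$introns <- empty_introns()
  gene
}

#' Build the tRF search space for one species
#'
#' One entry per annotated tRNA gene: the mature sequence with the literal
#' string "CCA" appended (the post-transcriptional 3' addition carried by
#' tRF-3s) and the 3' trailer. CCA is always appended; if the genomic 3' end
#' already reads CCA a per-gene warning is emitted (genomically encoded CCA,
#' as in some bacteria, would be duplicated).
#'
#' @param genome named character vector from [read_genome()].
#' @param genes \code{trna_genes} table.
#' @param trailer_len trailer length in nt, default 50.
#' @param species free-text species label.
#' @return a \code{trf_reference}: list with \code{species},
#'   \code{trailer_len} and \code{entries} (data.frame: name,
#'   mature_plus_cca, trailer, chrom, start, end, strand).
#' @export
build_reference <- function(genome, genes, trailer_len = 50L,
                            species = "unspecified") {
  genes <- validate_trna_genes(genes)
  if (nrow(genes) == 0) warning("building an empty reference: no tRNA genes")
  mature <- character(nrow(genes))
  trailer <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    m <- extract_mature_sequence(genome, genes[i, ])
    if (endsWith(m, "CCA")) {
      warning("gene ", genes$name[i],
              ": genomic 3' end already reads CCA; appending anyway")
    }
    mature[i] <- paste0(m, "CCA")
    trailer[i] <- extract_trailer(genome, genes[i, ], n = trailer_len)
  }
  ref <- list(
    species = species,
    trailer_len = as.integer(trailer_len),
    entries = data.frame(
      name = genes$name, mature_plus_cca = mature, trailer = trailer,
      chrom = genes$chrom, start = genes$start, end = genes$end,
      strand = genes$strand, stringsAsFactors = FALSE
    )
  )
  class(ref) <- "trf_reference"
  ref
}

#' @export
print.trf_reference <- function(x, ...) {
  cat("trf_reference:", x$species, "-", nrow(x$entries), "tRNA genes,",
      "trailer", x$trailer_len, "nt\n")
  invisible(x)
}

#' Serialize / load a reference bundle (JSON)
#'
#' @param ref \code{trf_reference}.
#' @param path JSON file.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(
    list(species = ref$species, trailer_len = ref$trailer_len,
         entries = ref$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- list(species = x$species, trailer_len = as.integer(x$trailer_len),
              entries = as.data.frame(x$entries, stringsAsFactors = FALSE))
  class(ref) <- "trf_reference"
  ref
}
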