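# RPM quantification, expression matrix, alignment view, coverage track.

#' Reads per million
#'
#' @param count read count of a fragment.
#' @param library_total total reads in the library (the RPM denominator;
#'   by default the total of the trimmed input library, not only mapped
#'   reads).
#' @return \code{count * 1e6 / library_total}.
#' @export
rpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  count * 1e6 / library_total
}

#' Quantify called tRFs in one library
#'
#' A tRF's count in a library is the collapsed count of its exact sequence;
#' zero when absent.
#'
#' @param trfs tRF table from [call_trfs()].
#' @param reads collapsed reads data.frame (\code{sequence}, \code{count}).
#' @param library_total RPM denominator for the library.
#' @param library_id,source free-text metadata.
#' @return a \code{library_profile}: list with the metadata plus
#'   \code{counts} and \code{rpm} named by \code{trf_id}.
#' @export
quantify_library <- function(trfs, reads, library_total,
                             library_id = "library", source = "") {
  counts <- stats::setNames(reads$count, reads$sequence)[trfs$sequence]
  counts[is.na(counts)] <- 0L
  profile <- list(library_id = library_id, source = source,
                  library_total = library_total,
                  counts = stats::setNames(as.integer(counts), trfs$trf_id),
                  rpm = stats::setNames(rpm(as.numeric(counts), library_total),
                                        trfs$trf_id))
  class(profile) <- "library_profile"
  profile
}

#' Build the tRF x library RPM matrix
#'
#' @param trfs tRF table (defines row universe and order: by trf_id).
#' @param profiles list of \code{library_profile}s (column order preserved).
#' @return numeric matrix, rows = tRF IDs, columns = library IDs; missing
#'   tRFs are 0.
#' @export
build_matrix <- function(trfs, profiles) {
  ids <- trfs$trf_id[order(trfs$trf_number, trfs$trf_id)]
  ids <- unique(ids)
  mat <- matrix(0, nrow = length(ids), ncol = length(profiles),
                dimnames = list(ids,
                                vapply(profiles, `[[`, character(1),
                                       "library_id")))
  for (j in seq_along(profiles)) {
    r <- profiles[[j]]$rpm
    hit <- intersect(names(r), ids)
    mat[hit, j] <- r[hit]
  }
  mat
}

#' Write / read an RPM matrix with a library metadata sidecar
#'
#' TSV renders RPM to 2 decimals; the JSON sidecar keeps full precision and
#' the library metadata.
#'
#' @param mat RPM matrix from [build_matrix()].
#' @param profiles the profiles the matrix was built from.
#' @param path TSV file; the sidecar is \code{<path>.json}.
#' @export
write_matrix <- function(mat, profiles, path) {
  df <- data.frame(trf_id = rownames(mat),
                   format(round(mat, 2), nsmall = 2, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(profiles, function(p) {
    list(library_id = p$library_id, source = p$source,
         library_total = p$library_total,
         rpm = as.list(p$rpm))
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Text alignment view of all reads on one tRNA gene
#'
#' Mirrors the pileup display of a small RNA library on a tRNA: the
#' mature+CCA and trailer sequences on header lines, then each read padded
#' to its offset with its count (and RPM when \code{library_total} is
#' given); dominant reads of passing sites are flagged with \code{*}.
#' Reads are ordered by count descending, then sequence.
#'
#' @param gene gene name.
#' @param alignments alignments (with or without a \code{region} column).
#' @param ref \code{trf_reference}.
#' @param library_total optional RPM denominator.
#' @param threshold dominance threshold used for flagging.
#' @return a single string (lines joined by newline).
#' @export
alignment_view <- function(gene, alignments, ref, library_total = NULL,
                           threshold = 0.80) {
  entry <- ref$entries[ref$entries$name == gene, , drop = FALSE]
  if (nrow(entry) == 0) stop("unknown gene: ", gene)
  aln <- alignments[alignments$gene == gene, , drop = FALSE]
  if (!"region" %in% names(aln)) aln <- assign_region(aln, ref)
  dominant <- unlist(summarize_sites(aln, threshold)$dominant)
  lines <- character(0)
  for (segment in c("mature_plus_cca", "trailer")) {
    seg_aln <- aln[aln$segment == segment, , drop = FALSE]
    lines <- c(lines, sprintf("%s | %s", gene, segment),
               entry[[segment]])
    if (nrow(seg_aln) > 0) {
      seg_aln <- seg_aln[order(-seg_aln$count, seg_aln$sequence), ,
                         drop = FALSE]
      for (i in seq_len(nrow(seg_aln))) {
        annot <- sprintf("(%d reads", seg_aln$count[i])
        if (!is.null(library_total)) {
          annot <- sprintf("%s, %.2f RPM", annot,
                           rpm(seg_aln$count[i], library_total))
        }
        annot <- paste0(annot, ")")
        flag <- if (seg_aln$sequence[i] %in% dominant) " *" else ""
        lines <- c(lines, sprintf("%s%s %s%s",
                                  strrep(" ", seg_aln$offset[i]),
                                  seg_aln$sequence[i], annot, flag))
      }
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Per-base read coverage of one tRNA gene
#'
#' Depth over the concatenation mature+CCA then trailer; position i carries
#' the summed counts of all alignments covering it, the histogram that shows
#' tRF enrichment against the degradation background.
#'
#' @param gene gene name.
#' @param alignments alignment data.frame.
#' @param ref \code{trf_reference}.
#' @return a \code{coverage_track}: list with \code{gene}, \code{depth}
#'   (integer vector), \code{mature_len}.
#' @export
coverage_histogram <- function(gene, alignments, ref) {
  entry <- ref$entries[ref$entries$name == gene, , drop = FALSE]
  if (nrow(entry) == 0) stop("unknown gene: ", gene)
  mature_len <- nchar(entry$mature_plus_cca)
  n <- mature_len + nchar(entry$trailer)
  depth <- integer(n)
  aln <- alignments[alignments$gene == gene, , drop = FALSE]
  for (i in seq_len(nrow(aln))) {
    shift <- if (aln$segment[i] == "trailer") mature_len else 0L
    ix <- (shift + aln$offset[i] + 1L):(shift + aln$end_offset[i])
    depth[ix] <- depth[ix] + aln$count[i]
  }
  track <- list(gene = gene, depth = depth, mature_len = mature_len)
  class(track) <- "coverage_track"
  track
}

#' Write a coverage track as BedGraph-style TSV
#'
#' Columns: gene, 1-based base index, depth.
#'
#' @param track \code{coverage_track}.
#' @param path TSV file.
#' @export
write_coverage <- function(track, path) {
  utils::write.table(
    data.frame(gene = track$gene, base = seq_along(track$depth),
               depth = track$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
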