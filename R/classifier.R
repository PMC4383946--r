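# Positional typing, degradation filtering, subclassing, ID assignment.
#
# A mapped read becomes a tRF candidate only at one of three positions:
#   five_prime  - starts at base 1 of the mature tRNA         -> tRF-5
#   three_prime - ends at the appended CCA (segment 3' end)   -> tRF-3
#   trailer     - starts at base 1 of the 3' trailer          -> tRF-1
# Everything else is "internal" and treated as degradation background.

REGION_LEVELS <- c("five_prime", "three_prime", "trailer", "internal")
TRF_TYPES <- c("tRF-5", "tRF-3", "tRF-1")
REGION_TO_TYPE <- c(five_prime = "tRF-5", three_prime = "tRF-3",
                    trailer = "tRF-1")
ID_BASE <- c("tRF-5" = 5000L, "tRF-3" = 3000L, "tRF-1" = 1000L)

#' Assign the positional region of each alignment
#'
#' A read starting at offset 0 of mature+CCA is \code{five_prime}; a read
#' whose end coincides with the segment end (hence ending in the appended
#' CCA) is \code{three_prime}; a read at offset 0 of the trailer is
#' \code{trailer}; all other placements are \code{internal}. A read spanning
#' the whole mature+CCA satisfies both end rules and is labelled
#' \code{five_prime} (such full-length reads are outside the usual small RNA
#' insert range anyway).
#'
#' @param alignments alignment data.frame from [map_exact()].
#' @param ref \code{trf_reference}.
#' @return the alignments with an added \code{region} column.
#' @export
assign_region <- function(alignments, ref) {
  seg_len <- nchar(ref$entries$mature_plus_cca)
  names(seg_len) <- ref$entries$name
  region <- rep("internal", nrow(alignments))
  mat <- alignments$segment == "mature_plus_cca"
  region[mat & alignments$offset == 0L] <- "five_prime"
  three <- mat & alignments$offset != 0L &
    alignments$end_offset == seg_len[alignments$gene]
  region[three] <- "three_prime"
  region[!mat & alignments$offset == 0L] <- "trailer"
  alignments$region <- region
  alignments
}

#' Dominant reads of one site
#'
#' Implements the enrichment rule that separates genuine tRFs from random
#' degradation: the single most abundant sequence if it carries at least
#' \code{threshold} of the site's reads, else the top two together if they
#' do, else nothing (the site fails). Ties are broken by longer sequence
#' first, then lexicographically.
#'
#' @param counts named integer vector: per-sequence read counts at the site.
#' @param threshold dominant fraction, default 0.80.
#' @return list with \code{reads} (character, length 0-2) and
#'   \code{fraction} (combined fraction of the returned reads).
#' @export
dominant_reads <- function(counts, threshold = 0.80) {
  total <- sum(counts)
  stopifnot(total > 0)
  ord <- order(-counts, -nchar(names(counts)), names(counts))
  counts <- counts[ord]
  if (counts[1] / total >= threshold) {
    return(list(reads = names(counts)[1], fraction = counts[[1]] / total))
  }
  if (length(counts) >= 2 && sum(counts[1:2]) / total >= threshold) {
    return(list(reads = names(counts)[1:2],
                fraction = sum(counts[1:2]) / total))
  }
  list(reads = character(0), fraction = 0)
}

#' Summarize all candidate sites of a library
#'
#' Groups region-positive alignments by (gene, region), applies the
#' dominant-read rule per site, and reports per-site totals.
#'
#' @param alignments alignments with a \code{region} column
#'   (see [assign_region()]).
#' @param threshold dominant fraction, default 0.80.
#' @return data.frame: gene, region, total (site read count),
#'   dominant (list column of sequences), dominant_fraction.
#' @export
summarize_sites <- function(alignments, threshold = 0.80) {
  aln <- alignments[alignments$region != "internal", , drop = FALSE]
  empty <- data.frame(gene = character(0), region = character(0),
                      total = integer(0), dominant_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  empty$dominant <- list()
  if (nrow(aln) == 0) return(empty)
  key <- paste(aln$gene, aln$region, sep = "\r")
  groups <- split(seq_len(nrow(aln)), key)
  rows <- lapply(groups, function(ix) {
    counts <- tapply(aln$count[ix], aln$sequence[ix], sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
    dom <- dominant_reads(counts, threshold)
    out <- data.frame(gene = aln$gene[ix[1]], region = aln$region[ix[1]],
                      total = sum(counts),
                      dominant_fraction = dom$fraction,
                      stringsAsFactors = FALSE)
    out$dominant <- list(dom$reads)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-gene concentration of reads on the three tRF regions
#'
#' The fraction of a gene's mapped read counts that fall on the 5' end,
#' 3' end or trailer start. In clean libraries this exceeds 0.90; the value
#' is an advisory QC metric (genes below \code{flag_below} are flagged, not
#' rejected - only region reads ever become tRFs regardless).
#'
#' @param alignments alignments with a \code{region} column.
#' @param flag_below advisory threshold, default 0.90.
#' @return data.frame: gene, region_count, total_count, concentration,
#'   flagged.
#' @export
region_concentration <- function(alignments, flag_below = 0.90) {
  genes <- unique(alignments$gene)
  on_region <- alignments$region != "internal"
  total <- tapply(alignments$count, alignments$gene, sum)
  reg <- tapply(alignments$count * on_region, alignments$gene, sum)
  conc <- as.numeric(reg[genes] / total[genes])
  data.frame(gene = genes,
             region_count = as.integer(reg[genes]),
             total_count = as.integer(total[genes]),
             concentration = conc,
             flagged = conc < flag_below,
             stringsAsFactors = FALSE)
}

#' Length subclass letter for a tRF
#'
#' tRF-5s cluster at ~15, ~22 and ~31 nt (letters a, b, c; bin edges 18 and
#' 26 nt); tRF-3s at ~18 and ~22 nt (a, b; edge 20 nt). tRF-1 lengths are
#' set by the distance to the Pol III terminator and carry no letter.
#' Letters are only rendered when a parent tRNA yields two or more distinct
#' tRFs of the type (see [call_trfs()]); this helper returns the letter a
#' length would get.
#'
#' @param trf_type one of \code{"tRF-5"}, \code{"tRF-3"}, \code{"tRF-1"}.
#' @param length fragment length in nt.
#' @param edges_5 tRF-5 bin edges, default \code{c(18, 26)}.
#' @param edge_3 tRF-3 bin edge, default 20.
#' @return subclass letter, or \code{""} for tRF-1.
#' @export
assign_subclass <- function(trf_type, length, edges_5 = c(18L, 26L),
                            edge_3 = 20L) {
  stopifnot(length >= 1)
  switch(trf_type,
    "tRF-5" = if (length <= edges_5[1]) "a"
              else if (length <= edges_5[2]) "b" else "c",
    "tRF-3" = if (length <= edge_3) "a" else "b",
    "tRF-1" = "",
    stop("unknown tRF type: ", trf_type))
}

#' Poly-U terminator check for a trailer fragment
#'
#' tRF-1s end within the RNA polymerase III termination signal, an encoded
#' run of >= 4 T. True iff such a run overlaps the trailer window
#' \code{[end_offset - 4, end_offset + 2]} (0-based positions) around the
#' fragment's 3' end. Advisory annotation, never a rejection.
#'
#' @param trailer trailer sequence of the parent gene.
#' @param end_offset 0-based exclusive end of the fragment in the trailer
#'   (= fragment length, since tRF-1s start at offset 0).
#' @return logical.
#' @export
check_terminator <- function(trailer, end_offset) {
  runs <- stringi::stri_locate_all_regex(trailer, "T{4,}")[[1]]
  if (is.na(runs[1, 1])) return(FALSE)
  w_lo <- end_offset - 4L
  w_hi <- end_offset + 2L
  any(runs[, 1] - 1L <= w_hi & runs[, 2] - 1L >= w_lo)
}

#' Create an empty tRF ID registry
#'
#' The registry makes IDs stable across libraries of one species: a
#' sequence keeps its number forever; new sequences take the next number of
#' their series (tRF-5 from 5001, tRF-3 from 3001, tRF-1 from 1001, in
#' discovery order).
#'
#' @param species species label.
#' @return a \code{trf_registry}.
#' @export
new_registry <- function(species = "unspecified") {
  reg <- list(species = species,
              counters = ID_BASE,
              # names: "<type>:<sequence>" -> number
              map = stats::setNames(integer(0), character(0)))
  class(reg) <- "trf_registry"
  reg
}

registry_key <- function(trf_type, sequence) paste0(trf_type, ":", sequence)

#' Assign sequential IDs to tRF records
#'
#' @param records data.frame with \code{trf_type} and \code{sequence}, in
#'   discovery order.
#' @param registry \code{trf_registry}; updated counters and map are
#'   returned alongside.
#' @return list: \code{records} (with \code{trf_number} added),
#'   \code{registry} (updated).
#' @export
assign_ids <- function(records, registry = new_registry()) {
  nums <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    key <- registry_key(records$trf_type[i], records$sequence[i])
    if (key %in% names(registry$map)) {
      nums[i] <- registry$map[[key]]
    } else {
      type <- records$trf_type[i]
      registry$counters[type] <- registry$counters[type] + 1L
      nums[i] <- registry$counters[type]
      if (nums[i] %in% registry$map[startsWith(names(registry$map),
                                               paste0(type, ":"))]) {
        stop("registry integrity error: ID ", nums[i],
             " already bound to a different sequence")
      }
      registry$map[key] <- nums[i]
    }
  }
  records$trf_number <- nums
  list(records = records, registry = registry)
}

#' Call tRFs from filtered alignments
#'
#' The full calling procedure for one library:
#' \enumerate{
#'   \item label each alignment's region ([assign_region()]);
#'   \item per (gene, region) site, apply the dominant-read rule
#'     ([dominant_reads()]); each dominant sequence with at least
#'     \code{min_site_count} reads is a candidate;
#'   \item merge identical (sequence, type) candidates across genes into one
#'     record with a multi-gene parent list;
#'   \item order records deterministically (first parent's position in the
#'     reference, then region 5' / 3' / trailer, then count descending, then
#'     sequence) and assign IDs through the registry;
#'   \item append subclass letters where a parent carries two or more
#'     distinct tRFs of the type; annotate tRF-1s with the poly-U
#'     terminator flag.
#' }
#'
#' @param alignments exclusivity-filtered alignments ([map_and_filter()]).
#' @param ref \code{trf_reference}.
#' @param registry \code{trf_registry}, carried across libraries.
#' @param dominant_threshold site dominance threshold, default 0.80.
#' @param min_site_count minimum reads for a dominant sequence to be called,
#'   default 2 (a singleton cannot be tested against the 80\% rule).
#' @return list: \code{trfs} (data.frame: trf_id, trf_number, trf_type,
#'   subclass, sequence, length, parents, count, terminator),
#'   \code{registry} (updated), \code{sites} (per-site summary),
#'   \code{qc} (per-gene region concentration).
#' @export
call_trfs <- function(alignments, ref, registry = new_registry(),
                      dominant_threshold = 0.80, min_site_count = 2L) {
  if (!"region" %in% names(alignments)) {
    alignments <- assign_region(alignments, ref)
  }
  sites <- summarize_sites(alignments, dominant_threshold)
  qc <- region_concentration(alignments)
  empty <- data.frame(trf_id = character(0), trf_number = integer(0),
                      trf_type = character(0), subclass = character(0),
                      sequence = character(0), length = integer(0),
                      parents = character(0), count = integer(0),
                      terminator = logical(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0) {
    return(list(trfs = empty, registry = registry, sites = sites, qc = qc))
  }

  # per-sequence site counts, for min_site_count and record ordering
  aln_key <- paste(alignments$gene, alignments$region, alignments$sequence,
                   sep = "\r")
  site_count <- tapply(alignments$count, aln_key, sum)

  cand <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    doms <- sites$dominant[[i]]
    if (length(doms) == 0) return(NULL)
    cnt <- as.integer(site_count[paste(sites$gene[i], sites$region[i], doms,
                                       sep = "\r")])
    ok <- cnt >= min_site_count
    if (!any(ok)) return(NULL)
    data.frame(gene = sites$gene[i], region = sites$region[i],
               sequence = doms[ok], count = cnt[ok],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(trfs = empty, registry = registry, sites = sites, qc = qc))
  }
  cand$trf_type <- REGION_TO_TYPE[cand$region]

  # merge identical (sequence, type) across parent genes
  gene_rank <- stats::setNames(seq_len(nrow(ref$entries)), ref$entries$name)
  merge_key <- paste(cand$trf_type, cand$sequence, sep = "\r")
  groups <- split(seq_len(nrow(cand)), merge_key)
  records <- do.call(rbind, lapply(groups, function(ix) {
    parents <- unique(cand$gene[ix])
    parents <- parents[order(gene_rank[parents])]
    data.frame(trf_type = cand$trf_type[ix[1]],
               sequence = cand$sequence[ix[1]],
               length = nchar(cand$sequence[ix[1]]),
               parents = paste(parents, collapse = ","),
               first_parent = gene_rank[parents[1]],
               count = max(cand$count[ix]),
               stringsAsFactors = FALSE)
  }))
  region_rank <- c("tRF-5" = 1L, "tRF-3" = 2L, "tRF-1" = 3L)
  records <- records[order(records$first_parent,
                           region_rank[records$trf_type],
                           -records$count, records$sequence), , drop = FALSE]
  rownames(records) <- NULL

  ids <- assign_ids(records, registry)
  records <- ids$records
  registry <- ids$registry

  # subclass letters: only when >= 2 distinct tRFs of the type share a parent
  parent_list <- strsplit(records$parents, ",", fixed = TRUE)
  records$subclass <- ""
  for (type in c("tRF-5", "tRF-3")) {
    sel <- which(records$trf_type == type)
    if (length(sel) < 2) next
    tab <- table(unlist(parent_list[sel]))
    shared <- names(tab)[tab >= 2]
    for (i in sel) {
      if (any(parent_list[[i]] %in% shared)) {
        records$subclass[i] <- assign_subclass(type, records$length[i])
      }
    }
  }
  records$trf_id <- paste0(records$trf_number, records$subclass)

  # poly-U terminator annotation for trailer fragments
  trailer_by_gene <- stats::setNames(ref$entries$trailer, ref$entries$name)
  records$terminator <- NA
  for (i in which(records$trf_type == "tRF-1")) {
    records$terminator[i] <- any(vapply(parent_list[[i]], function(p) {
      check_terminator(trailer_by_gene[[p]], records$length[i])
    }, logical(1)))
  }

  trfs <- records[, c("trf_id", "trf_number", "trf_type", "subclass",
                      "sequence", "length", "parents", "count", "terminator")]
  list(trfs = trfs, registry = registry, sites = sites, qc = qc)
}

#' Persist / restore an ID registry (JSON)
#'
#' @param registry \code{trf_registry}.
#' @param path JSON file.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(
    list(species = registry$species,
         counters = as.list(registry$counters),
         map = as.list(registry$map)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- list(species = x$species,
              counters = stats::setNames(as.integer(x$counters),
                                         names(x$counters)),
              map = stats::setNames(as.integer(x$map), names(x$map)))
  if (length(reg$map) == 0) reg$map <- stats::setNames(integer(0),
                                                       character(0))
  class(reg) <- "trf_registry"
  reg
}

#' Write a called-tRF table (TSV)
#'
#' @param trfs tRF data.frame from [call_trfs()].
#' @param path TSV file.
#' @export
write_trfs <- function(trfs, path) {
  utils::write.table(trfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trfs
#' @export
read_trfs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character", "character", "integer",
                                   "character", "integer", "logical"))
}
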