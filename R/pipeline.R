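# End-to-end orchestration: collapsed reads -> alignments -> calls -> matrix.

#' Process one library through mapping, filtering and calling
#'
#' @param reads collapsed reads data.frame (with \code{mappable}) or the
#'   list returned by [collapse_reads()] / [simulate_library()].
#' @param ref \code{trf_reference}.
#' @param genome named character vector (for the exclusivity filter).
#' @param registry \code{trf_registry} carried across libraries.
#' @param library_total RPM denominator; taken from \code{reads} when it is
#'   a collapse result.
#' @param library_id,source library metadata.
#' @param dominant_threshold,min_site_count see [call_trfs()].
#' @param pad3,pad5 see [genome_exclusivity_filter()].
#' @return list: \code{trfs}, \code{registry}, \code{profile},
#'   \code{alignments}, \code{dropped}, \code{qc}.
#' @export
process_library <- function(reads, ref, genome, registry = new_registry(),
                            library_total = NULL, library_id = "library",
                            source = "", dominant_threshold = 0.80,
                            min_site_count = 2L,
                            pad3 = ref$trailer_len, pad5 = 0L) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    if (is.null(library_total)) library_total <- reads$library_total
    reads <- reads$reads
  }
  if (is.null(library_total)) library_total <- sum(reads$count)
  mf <- map_and_filter(reads, ref, genome, pad3 = pad3, pad5 = pad5)
  called <- call_trfs(mf$alignments, ref, registry,
                      dominant_threshold = dominant_threshold,
                      min_site_count = min_site_count)
  profile <- quantify_library(called$trfs, reads, library_total,
                              library_id = library_id, source = source)
  list(trfs = called$trfs, registry = called$registry, profile = profile,
       alignments = mf$alignments, dropped = mf$dropped, qc = called$qc)
}

#' Run the full pipeline over several libraries
#'
#' Libraries are processed in the given order (which fixes ID discovery
#' order); the registry accumulates so a sequence keeps one ID across
#' libraries. Profiles are re-quantified against the union tRF table so the
#' matrix covers every tRF in every library.
#'
#' @param libraries named list; each element either a [collapse_reads()] /
#'   [simulate_library()] result or a collapsed reads data.frame.
#' @param ref \code{trf_reference}.
#' @param genome named character vector.
#' @param ... passed to [process_library()].
#' @return list: \code{trfs} (union table), \code{matrix} (RPM),
#'   \code{profiles}, \code{registry}, \code{per_library} (full results).
#' @export
run_pipeline <- function(libraries, ref, genome, ...) {
  registry <- new_registry(ref$species)
  per_library <- vector("list", length(libraries))
  names(per_library) <- names(libraries)
  for (id in names(libraries)) {
    res <- process_library(libraries[[id]], ref, genome, registry,
                           library_id = id, ...)
    registry <- res$registry
    per_library[[id]] <- res
  }
  all_trfs <- do.call(rbind, lapply(per_library, `[[`, "trfs"))
  all_trfs <- all_trfs[!duplicated(paste(all_trfs$trf_type,
                                         all_trfs$trf_number)), ,
                       drop = FALSE]
  all_trfs <- all_trfs[order(all_trfs$trf_number), , drop = FALSE]
  rownames(all_trfs) <- NULL
  profiles <- lapply(names(libraries), function(id) {
    lib <- libraries[[id]]
    reads <- if (is.data.frame(lib)) lib else lib$reads
    total <- if (is.data.frame(lib)) sum(lib$count) else lib$library_total
    quantify_library(all_trfs, reads, total, library_id = id)
  })
  names(profiles) <- names(libraries)
  mat <- build_matrix(all_trfs, profiles)
  list(trfs = all_trfs, matrix = mat, profiles = profiles,
       registry = registry, per_library = per_library)
}
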