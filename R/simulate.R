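# Synthetic genomes, tRNA annotations and small RNA libraries with planted
# tRFs, a degradation-noise model, and ground truth for recovery testing.
#
# The generator states a small, explicit world:
#  - tRNA genes of ~72 nt with 50-nt trailers on random background sequence,
#    alternating strands;
#  - planted fragments at the three canonical positions with set relative
#    weights;
#  - a noise model with two components seen in real pileups: reads that are
#    the planted tRF shortened by 1-3 nt at the 3' end (nucleolytic
#    trimming), and uniform internal fragments (random degradation);
#  - optionally a "background" pool of non-tRNA reads (the bulk of a real
#    small RNA library: miRNAs etc.) that maps nowhere on the reference but
#    inflates the RPM denominator;
#  - optional intergenic decoy copies of planted sequences to exercise the
#    genome-exclusivity filter.

PLANT_REGIONS <- c("five_prime", "three_prime", "trailer")

#' Default planted-tRF layout
#'
#' Six genes: gene 1 carries two tRF-5s (15 and 22 nt, the a/b length
#' subclasses), gene 2 two tRF-3s (18 and 22 nt), genes 3 and 6 a tRF-1
#' each (16 and 20 nt, both ending in an encoded poly-U tract), gene 4 a
#' solitary 31-nt tRF-5, gene 5 a solitary 22-nt tRF-3. Equal weights.
#'
#' @return data.frame: gene (index), region, length, weight.
#' @export
default_planted <- function() {
  data.frame(
    gene   = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L),
    region = c("five_prime", "five_prime", "three_prime", "three_prime",
               "trailer", "five_prime", "three_prime", "trailer"),
    length = c(15L, 22L, 18L, 22L, 16L, 31L, 22L, 20L),
    weight = rep(1, 8),
    stringsAsFactors = FALSE
  )
}

#' Differential-abundance scenario configuration
#'
#' The two-group case-study world: \code{n_per_type} tRFs of each type on
#' separate genes, two libraries per group. Planted weights make tRF-1s a
#' small share of the library over a dominant non-tRNA background pool
#' (weight 80 vs 20 planted, mirroring real small RNA libraries where tRFs
#' are a minor component), so that a 100-1000x tRF-1 induction in group B
#' (applied by [simulate_experiment()] with the returned
#' \code{$induction}) shifts the RPM denominator only mildly.
#'
#' @param seed master seed.
#' @param n_per_type planted tRFs per type, default 10.
#' @param depth reads per library, default 2e5.
#' @return list: \code{cfg} (a \code{sim_config}), \code{induction}
#'   (argument for [simulate_experiment()]).
#' @export
differential_sim_config <- function(seed, n_per_type = 10L, depth = 2e5) {
  n <- 3L * n_per_type
  planted <- data.frame(
    gene = seq_len(n),
    region = rep(c("five_prime", "three_prime", "trailer"),
                 each = n_per_type),
    length = c(rep(c(15L, 22L, 31L), length.out = n_per_type),
               rep(c(18L, 22L), length.out = n_per_type),
               rep(16L:20L, length.out = n_per_type)),
    weight = rep(c(1, 1, 0.005), each = n_per_type),
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(seed, n_genes = n, planted = planted,
                    libraries = data.frame(
                      library_id = c("A1", "A2", "B1", "B2"),
                      group = c("A", "A", "B", "B"),
                      depth = depth),
                    background_weight = 80)
  list(cfg = cfg,
       induction = list(group = "B", trf_type = "tRF-1",
                        fold_range = c(100, 1000)))
}

#' Simulation configuration
#'
#' @param seed master seed; per-library seeds are derived from it.
#' @param n_genes number of tRNA genes.
#' @param gene_len mature tRNA length in nt (~72, typical for tRNAs).
#' @param trailer_len trailer length, default 50.
#' @param planted planted-tRF table (gene index, region, length, weight);
#'   default [default_planted()].
#' @param libraries data.frame: library_id, group, depth (reads).
#' @param noise_fraction fraction of each library that is uniform internal
#'   degradation fragments (14-30 nt), default 0.05.
#' @param trim_fraction fraction of each planted tRF's reads that are 1-3 nt
#'   3'-shortened copies, default 0.10.
#' @param background_weight weight of the non-tRNA read pool, on the same
#'   unnormalized scale as the planted weights (0 = none).
#' @param decoys number of planted sequences additionally copied into
#'   intergenic background.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed, n_genes = 6L, gene_len = 72L, trailer_len = 50L,
                       planted = default_planted(),
                       libraries = data.frame(library_id = "sim1",
                                              group = "A", depth = 2e5),
                       noise_fraction = 0.05, trim_fraction = 0.10,
                       background_weight = 0, decoys = 0L) {
  stopifnot(noise_fraction >= 0, trim_fraction >= 0,
            noise_fraction + trim_fraction < 1,
            all(planted$gene <= n_genes),
            all(planted$region %in% PLANT_REGIONS),
            all(planted$length <= ifelse(planted$region == "trailer",
                                         trailer_len, gene_len)))
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_len = as.integer(gene_len),
              trailer_len = as.integer(trailer_len),
              planted = planted, libraries = libraries,
              noise_fraction = noise_fraction,
              trim_fraction = trim_fraction,
              background_weight = background_weight,
              decoys = as.integer(decoys))
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, tRNA annotation and planted-tRF truth
#'
#' Genes are placed non-overlapping on a single random contig with 40-80 nt
#' spacers, alternating strands (minus-strand genes are stored
#' reverse-complemented, so strand-aware extraction is exercised). For each
#' planted tRF-1 an encoded poly-U (TTTT) tract is written into the trailer
#' ending at the fragment's 3' end. Decoy copies of the first
#' \code{decoys} planted sequences are appended intergenically.
#' Deterministic for a given seed.
#'
#' @param cfg \code{sim_config}.
#' @return list: \code{genome} (named character), \code{genes}
#'   (\code{trna_genes}), \code{ref} (\code{trf_reference}), \code{truth}
#'   (planted table with sequences, expected types and subclasses),
#'   \code{decoy_sequences}.
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed)
  mature <- character(cfg$n_genes)
  trailer <- character(cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    repeat {   # avoid a genomic 3' end that already reads CCA
      mature[g] <- random_dna(cfg$gene_len)
      if (!endsWith(mature[g], "CCA")) break
    }
    trailer[g] <- random_dna(cfg$trailer_len)
  }
  # encode the Pol III terminator under each planted tRF-1 3' end
  for (i in which(cfg$planted$region == "trailer")) {
    g <- cfg$planted$gene[i]
    L <- cfg$planted$length[i]
    substr(trailer[g], L - 3L, L) <- "TTTT"
  }

  # planted read sequences, from the designed transcripts
  planted <- cfg$planted
  planted$sequence <- vapply(seq_len(nrow(planted)), function(i) {
    g <- planted$gene[i]; L <- planted$length[i]
    switch(planted$region[i],
      five_prime  = substr(mature[g], 1L, L),
      three_prime = substr(paste0(mature[g], "CCA"),
                           cfg$gene_len + 3L - L + 1L, cfg$gene_len + 3L),
      trailer     = substr(trailer[g], 1L, L))
  }, character(1))

  # lay out the contig: spacer, gene block, spacer, gene block, ...
  pieces <- character(0)
  pos <- 0L
  gene_start <- integer(cfg$n_genes)
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    spacer <- random_dna(sample(40:80, 1))
    block <- if (strand[g] == "+") {
      paste0(mature[g], trailer[g])
    } else {
      revcomp(paste0(mature[g], trailer[g]))
    }
    pieces <- c(pieces, spacer, block)
    gene_start[g] <- pos + nchar(spacer) +
      if (strand[g] == "-") cfg$trailer_len else 0L
    pos <- pos + nchar(spacer) + nchar(block)
  }
  pieces <- c(pieces, random_dna(60))
  pos <- pos + 60L
  decoy_sequences <- character(0)
  if (cfg$decoys > 0) {
    ix <- seq_len(min(cfg$decoys, nrow(planted)))
    decoy_sequences <- planted$sequence[ix]
    for (s in decoy_sequences) {
      pieces <- c(pieces, s, random_dna(30))
      pos <- pos + nchar(s) + 30L
    }
  }
  genome <- c(chrS = paste(pieces, collapse = ""))

  genes <- data.frame(
    name = sprintf("synth.trna%d", seq_len(cfg$n_genes)),
    chrom = "chrS",
    start = gene_start,
    end = gene_start + cfg$gene_len,
    strand = strand,
    stringsAsFactors = FALSE
  )
  genes$introns <- replicate(cfg$n_genes, empty_introns(), simplify = FALSE)
  genes <- validate_trna_genes(genes)
  ref <- build_reference(genome, genes, trailer_len = cfg$trailer_len,
                         species = "synthetic")

  planted$gene_name <- genes$name[planted$gene]
  planted$trf_type <- REGION_TO_TYPE[planted$region]
  planted$subclass <- ""
  for (type in c("tRF-5", "tRF-3")) {
    sel <- planted$trf_type == type
    shared <- names(which(table(planted$gene[sel]) >= 2))
    hit <- sel & planted$gene %in% as.integer(shared)
    planted$subclass[hit] <- vapply(planted$length[hit], assign_subclass,
                                    character(1), trf_type = type)
  }
  list(genome = genome, genes = genes, ref = ref, truth = planted,
       decoy_sequences = decoy_sequences)
}

# 1-3 nt 3'-shortened copies of a planted fragment (nucleolytic trimming)
trim_variants <- function(sequence) {
  L <- nchar(sequence)
  substr(rep(sequence, 3L), 1L, L - (1:3))
}

#' Simulate one small RNA library
#'
#' Reads are drawn from a multinomial over: each planted fragment (split
#' \code{1 - trim_fraction} full-length / \code{trim_fraction} over its
#' three 3'-trimmed variants), a uniform internal-degradation pool
#' (\code{noise_fraction} of the library), and the non-tRNA background
#' pool. Expected site dominance is therefore at least
#' \code{1 - trim_fraction - noise_fraction} for a solitary planted tRF.
#'
#' @param simref output of [simulate_reference()].
#' @param cfg \code{sim_config}.
#' @param depth number of reads.
#' @param seed seed for this library.
#' @param weights optional override of the planted weight vector (e.g. a
#'   group-specific induction); defaults to \code{cfg$planted$weight}.
#' @return list: \code{reads} (collapsed, with \code{mappable}),
#'   \code{library_total}, \code{truth} (planted per-sequence true counts
#'   plus trim/noise/background totals and the seed).
#' @export
simulate_library <- function(simref, cfg, depth = 2e5, seed = cfg$seed + 1L,
                             weights = NULL) {
  set.seed(seed)
  planted <- simref$truth
  if (is.null(weights)) weights <- planted$weight
  stopifnot(length(weights) == nrow(planted))
  depth <- as.integer(depth)

  w_all <- sum(weights) + cfg$background_weight
  p_planted <- (1 - cfg$noise_fraction) * weights / w_all
  p_bg <- (1 - cfg$noise_fraction) * cfg$background_weight / w_all
  # categories: full_i, trim_i x 3, background, noise
  probs <- c(p_planted * (1 - cfg$trim_fraction),
             rep(p_planted * cfg$trim_fraction / 3, each = 3L),
             p_bg, cfg$noise_fraction)
  counts <- as.integer(stats::rmultinom(1, depth, probs))
  n_p <- nrow(planted)
  full_counts <- counts[seq_len(n_p)]
  trim_counts <- counts[n_p + seq_len(3L * n_p)]
  bg_count <- counts[4L * n_p + 1L]
  noise_count <- counts[4L * n_p + 2L]

  seqs <- c(planted$sequence,
            unlist(lapply(planted$sequence, trim_variants)))
  cnts <- c(full_counts, trim_counts)

  # uniform internal fragments: random gene, length 14-30, strictly inside
  # the mature body (offset >= 1, ending before the mature 3' end)
  if (noise_count > 0) {
    g <- sample.int(cfg$n_genes, noise_count, replace = TRUE)
    len <- sample(14:30, noise_count, replace = TRUE)
    start <- 2L + floor(stats::runif(noise_count) *
                          (cfg$gene_len - len - 2L))
    mature_by_gene <- substr(simref$ref$entries$mature_plus_cca, 1L,
                             nchar(simref$ref$entries$mature_plus_cca) - 3L)
    noise_seqs <- substr(mature_by_gene[g], start, start + len - 1L)
    agg <- tapply(rep(1L, noise_count), noise_seqs, sum)
    seqs <- c(seqs, names(agg))
    cnts <- c(cnts, as.integer(agg))
  }

  # non-tRNA background: random 20-24 nt sequences, essentially all unique
  if (bg_count > 0) {
    len <- sample(20:24, bg_count, replace = TRUE)
    bg_seqs <- character(bg_count)
    for (L in 20:24) {
      ix <- which(len == L)
      if (length(ix) == 0) next
      m <- matrix(sample(c("A", "C", "G", "T"), length(ix) * L,
                         replace = TRUE), ncol = L)
      bg_seqs[ix] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    agg <- tapply(rep(1L, bg_count), bg_seqs, sum)
    seqs <- c(seqs, names(agg))
    cnts <- c(cnts, as.integer(agg))
  }

  keep <- cnts > 0L
  collapsed <- collapse_sequences(seqs[keep], cnts[keep])
  out <- finish_collapse(collapsed, 14L, 40L)

  truth <- planted[, c("sequence", "region", "gene_name", "trf_type",
                       "length", "subclass")]
  truth$count <- full_counts
  list(reads = out$reads, library_total = out$library_total,
       truth = list(planted = truth,
                    trim_count = sum(trim_counts),
                    noise_count = noise_count,
                    background_count = bg_count,
                    depth = depth, seed = seed))
}

#' Simulate a whole multi-library experiment
#'
#' Generates the reference once, then one library per row of
#' \code{cfg$libraries} with seeds \code{cfg$seed + library index}. If
#' \code{induction} is given, planted tRFs of \code{induction$trf_type} are
#' multiplied in weight by per-tRF factors drawn log-uniformly from
#' \code{induction$fold_range} (drawn once, shared by all libraries of
#' \code{induction$group}).
#'
#' @param cfg \code{sim_config}.
#' @param induction optional list(group, trf_type, fold_range).
#' @return list: \code{simref}, \code{libraries} (named list of
#'   [simulate_library()] outputs), \code{induction_factors}.
#' @export
simulate_experiment <- function(cfg, induction = NULL) {
  simref <- simulate_reference(cfg)
  factors <- NULL
  base_w <- cfg$planted$weight
  if (!is.null(induction)) {
    set.seed(cfg$seed + 7919L)
    sel <- simref$truth$trf_type == induction$trf_type
    factors <- rep(1, nrow(cfg$planted))
    lo <- log10(induction$fold_range[1])
    hi <- log10(induction$fold_range[2])
    factors[sel] <- 10^stats::runif(sum(sel), lo, hi)
  }
  libs <- vector("list", nrow(cfg$libraries))
  names(libs) <- cfg$libraries$library_id
  for (j in seq_len(nrow(cfg$libraries))) {
    w <- base_w
    if (!is.null(induction) && cfg$libraries$group[j] == induction$group) {
      w <- base_w * factors
    }
    libs[[j]] <- simulate_library(simref, cfg,
                                  depth = cfg$libraries$depth[j],
                                  seed = cfg$seed + j,
                                  weights = w)
  }
  list(simref = simref, libraries = libs, induction_factors = factors)
}

#' Write simulator outputs to a directory
#'
#' Emits genome.fa, trna.bed, lib_<id>.tsv (collapsed counts),
#' truth_<id>.tsv and sim-manifest.json.
#'
#' @param experiment output of [simulate_experiment()].
#' @param cfg the \code{sim_config} used.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(experiment, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- experiment$simref$genome
  writeLines(c(rbind(paste0(">", names(genome)), unname(genome))),
             file.path(dir, "genome.fa"))
  write_trna_annotation(experiment$simref$genes,
                        file.path(dir, "trna.bed"), coord = "bed")
  for (id in names(experiment$libraries)) {
    lib <- experiment$libraries[[id]]
    utils::write.table(lib$reads[, c("sequence", "count")],
                       file.path(dir, paste0("lib_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(lib$truth$planted,
                       file.path(dir, paste0("truth_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = cfg$seed, n_genes = cfg$n_genes, gene_len = cfg$gene_len,
         trailer_len = cfg$trailer_len,
         noise_fraction = cfg$noise_fraction,
         trim_fraction = cfg$trim_fraction,
         background_weight = cfg$background_weight, decoys = cfg$decoys,
         libraries = cfg$libraries),
    file.path(dir, "sim-manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
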