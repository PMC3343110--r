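#' Analysis parameters
#'
#' Central container for every numeric threshold used by the pipeline.
#' Defaults follow the published repeat-annotation methodology for the two
#' supported probe chemistries: 50-mer bead arrays tolerate 2 mismatches and
#' require a 48 nt repeat overlap; 25-mer arrays tolerate 1 mismatch and
#' require a 24 nt overlap.
#'
#' @param platform One of `"illumina50"`, `"affy25"`, `"generic"`. Sets
#'   `probe_length`, `max_mismatches` and `min_overlap_nt` defaults.
#' @param probe_length Probe length in nt.
#' @param max_mismatches Maximum substitutions tolerated when aligning a probe
#'   to the genome (2 for 50-mers, 1 for 25-mers).
#' @param min_overlap_nt Minimum overlap (nt) between a probe's genomic top hit
#'   and a repeat-masked interval for the probe to be called a repeat probe
#'   (48 for 50-mers, 24 for 25-mers). Also the minimum match count for a
#'   valid top hit.
#' @param fold_threshold Fold-change threshold for calling a probe changed
#'   (inclusive, applied on the log2 scale). 2 by default; 4 for the stricter
#'   calls.
#' @param alpha Adjusted-p significance level for differential calls (strict
#'   `<` by default, see `alpha_inclusive`).
#' @param alpha_inclusive Use `<=` instead of `<` when comparing adjusted p to
#'   `alpha`.
#' @param detection_alpha Detection p-value threshold below which a probe is
#'   called present in a sample.
#' @param ltr_flank_max_gap Maximum distance (nt) between a contig end and a
#'   flanking LTR hit.
#' @param ltr_min_length Minimum genomic length (nt) of an LTR hit considered
#'   when looking for flanks.
#' @param full_length_fraction A contig is approximately full length when its
#'   consensus coverage fraction strictly exceeds this value.
#' @param orf_intact_fraction An ORF is intact in a contig when the covered
#'   fraction of the ORF strictly exceeds this value.
#' @param deletion_cluster_tolerance Breakpoint tolerance (nt) for single-
#'   linkage clustering of recurrent deletions.
#' @param min_deletion_nt Minimum consensus gap length (nt) reported as a
#'   deletion.
#' @param max_cons_overlap Consensus-interval overlap (nt) still regarded as
#'   collinear during contig assembly.
#' @param log_offset Offset added before log2 transform of background-
#'   subtracted bead-array intensities.
#' @param seed Integer seed for any stochastic step.
#'
#' @return An object of class `retro_params` (a named list).
#' @export
#' @examples
#' p <- retro_params("illumina50")
#' p$min_overlap_nt  # 48
retro_params <- function(platform = c("illumina50", "affy25", "generic"),
                         probe_length = NULL,
                         max_mismatches = NULL,
                         min_overlap_nt = NULL,
                         fold_threshold = 2,
                         alpha = 0.01,
                         alpha_inclusive = FALSE,
                         detection_alpha = 0.01,
                         ltr_flank_max_gap = 50,
                         ltr_min_length = 250,
                         full_length_fraction = 0.95,
                         orf_intact_fraction = 0.90,
                         deletion_cluster_tolerance = 10,
                         min_deletion_nt = 50,
                         max_cons_overlap = 20,
                         log_offset = 16,
                         seed = 1L) {
  platform <- match.arg(platform)
  defaults <- switch(platform,
    illumina50 = list(probe_length = 50L, max_mismatches = 2L, min_overlap_nt = 48L),
    affy25     = list(probe_length = 25L, max_mismatches = 1L, min_overlap_nt = 24L),
    generic    = list(probe_length = 50L, max_mismatches = 2L, min_overlap_nt = 48L)
  )
  if (is.null(probe_length)) probe_length <- defaults$probe_length
  if (is.null(max_mismatches)) max_mismatches <- defaults$max_mismatches
  if (is.null(min_overlap_nt)) min_overlap_nt <- defaults$min_overlap_nt

  p <- list(
    platform = platform,
    probe_length = as.integer(probe_length),
    max_mismatches = as.integer(max_mismatches),
    min_overlap_nt = as.integer(min_overlap_nt),
    fold_threshold = fold_threshold,
    alpha = alpha,
    alpha_inclusive = isTRUE(alpha_inclusive),
    detection_alpha = detection_alpha,
    ltr_flank_max_gap = as.integer(ltr_flank_max_gap),
    ltr_min_length = as.integer(ltr_min_length),
    full_length_fraction = full_length_fraction,
    orf_intact_fraction = orf_intact_fraction,
    deletion_cluster_tolerance = as.integer(deletion_cluster_tolerance),
    min_deletion_nt = as.integer(min_deletion_nt),
    max_cons_overlap = as.integer(max_cons_overlap),
    log_offset = log_offset,
    seed = as.integer(seed)
  )
  validate_params(p)
  structure(p, class = "retro_params")
}

validate_params <- function(p) {
  num <- c("fold_threshold", "alpha", "detection_alpha", "full_length_fraction",
           "orf_intact_fraction", "ltr_flank_max_gap", "ltr_min_length",
           "deletion_cluster_tolerance", "min_deletion_nt", "min_overlap_nt",
           "probe_length")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
  }
  if (p$max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  if (p$max_mismatches >= p$probe_length)
    stop("max_mismatches must be smaller than the probe length", call. = FALSE)
  if (p$fold_threshold < 1) stop("fold_threshold must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.retro_params <- function(x, ...) {
  cat("retroarray parameters (", x$platform, ")\n", sep = "")
  cat(sprintf("  alignment: length %d nt, <=%d mismatches, repeat overlap >=%d nt\n",
              x$probe_length, x$max_mismatches, x$min_overlap_nt))
  cat(sprintf("  calls: fold >=%g, adj. p %s %g; detection p < %g\n",
              x$fold_threshold, if (x$alpha_inclusive) "<=" else "<",
              x$alpha, x$detection_alpha))
  cat(sprintf("  contigs: LTR flank <=%d bp, LTR >=%d bp, full length >%g, ORF >%g\n",
              x$ltr_flank_max_gap, x$ltr_min_length,
              x$full_length_fraction, x$orf_intact_fraction))
  invisible(x)
}

# internal: validate a DNA string vector (A/C/G/T/N only)
check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad))
    stop(what, " contains characters outside A/C/G/T/N at entry ",
         which(bad)[1L], call. = FALSE)
  toupper(x)
}
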