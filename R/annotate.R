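#' Classify a probe's top hit against the repeat annotation
#'
#' A probe is a repeat probe when its genomic top hit overlaps a repeat-masked
#' interval by at least `params$min_overlap_nt`. When several intervals
#' qualify, the largest overlap wins (ties broken by genomic position). For
#' platforms whose probes are complementary to the transcript (both supported
#' commercial chemistries), a repeat probe detects sense transcripts when its
#' alignment strand equals the repeat's annotated strand.
#'
#' @param probe_id Probe identifier.
#' @param sequence Probe sequence.
#' @param hit Single-row data.frame from [top_hit()], or `NULL`.
#' @param hit_count Number of qualifying genomic placements.
#' @param repeats Repeat annotation data.frame from [read_rmsk_table()].
#' @param params [retro_params()] object.
#' @param chemistry `"probe_complementary_to_transcript"` (default for the
#'   supported platforms) or `"probe_same_sense_as_transcript"`.
#' @return One-row data.frame: `probe_id`, `sequence`, `is_repeat`,
#'   `detects_sense`, `element`, `family`, `repeat_class`, `overlap_nt`,
#'   `hit_count`, plus the top-hit coordinates.
#' @export
classify_probe <- function(probe_id, sequence, hit, hit_count, repeats, params,
                           chemistry = c("probe_complementary_to_transcript",
                                         "probe_same_sense_as_transcript")) {
  chemistry <- match.arg(chemistry)
  ann <- data.frame(
    probe_id = probe_id, sequence = sequence,
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_, element = NA_character_, family = NA_character_,
    repeat_class = NA_character_, overlap_nt = 0L,
    hit_count = as.integer(hit_count), is_repeat = FALSE,
    detects_sense = NA, stringsAsFactors = FALSE)
  if (is.null(hit)) {
    ann$hit_count <- 0L
    return(ann)
  }
  ann$chrom <- hit$chrom; ann$start <- hit$start; ann$end <- hit$end
  ann$strand <- hit$strand
  cand <- repeats[repeats$chrom == hit$chrom &
                    repeats$start < hit$end & repeats$end > hit$start, ,
                  drop = FALSE]
  if (nrow(cand)) {
    ov <- pmin(cand$end, hit$end) - pmax(cand$start, hit$start)
    best <- order(-ov, cand$start)[1L]
    if (ov[best] >= params$min_overlap_nt) {
      ann$is_repeat <- TRUE
      ann$overlap_nt <- as.integer(ov[best])
      ann$element <- cand$element[best]
      ann$family <- cand$family[best]
      ann$repeat_class <- cand$repeat_class[best]
      same_strand <- hit$strand == cand$strand[best]
      ann$detects_sense <- if (chemistry == "probe_complementary_to_transcript")
        same_strand else !same_strand
    } else {
      ann$overlap_nt <- as.integer(max(ov))
    }
  }
  ann
}

#' Annotate a probe platform against genome and repeat annotation
#'
#' Aligns every probe, picks its top hit under the platform identity cut-off,
#' and classifies it as repeat / non-repeat and sense- / antisense-detecting.
#'
#' @param probes Data.frame with `probe_id` and `sequence` (see
#'   [read_probe_table()]).
#' @param genome [Biostrings::DNAStringSet].
#' @param repeats Repeat annotation from [read_rmsk_table()].
#' @param params [retro_params()].
#' @inheritParams classify_probe
#' @return Data.frame of per-probe annotations (class `retro_annotation`),
#'   one row per input probe, in input order.
#' @export
annotate_platform <- function(probes, genome, repeats, params,
                              chemistry = "probe_complementary_to_transcript") {
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         probes$probe_id[duplicated(probes$probe_id)][1L], call. = FALSE)
  rows <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    aln <- align_probe(probes$sequence[i], genome, params$max_mismatches)
    th <- top_hit(aln, min_matches = params$min_overlap_nt)
    rows[[i]] <- classify_probe(probes$probe_id[i], probes$sequence[i],
                                th$hit, th$hit_count, repeats, params,
                                chemistry)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("retro_annotation", class(out))
  out
}

#' Summarise a platform annotation
#'
#' Platform-level counts: total probes, repeat probes split into sense-
#' detecting (complementary) and antisense, and per-repeat-class probe and
#' element counts.
#'
#' @param annotations Data.frame from [annotate_platform()].
#' @return List with `totals` (named vector) and `by_class` (data.frame).
#' @export
summarize_annotations <- function(annotations) {
  rep_rows <- annotations[which(annotations$is_repeat), , drop = FALSE]
  totals <- c(
    probes = nrow(annotations),
    repeat_probes = nrow(rep_rows),
    complementary = sum(rep_rows$detects_sense, na.rm = TRUE),
    non_complementary = sum(!rep_rows$detects_sense, na.rm = TRUE)
  )
  if (nrow(rep_rows)) {
    by_class <- do.call(rbind, lapply(split(rep_rows, rep_rows$repeat_class),
      function(d) data.frame(repeat_class = d$repeat_class[1L],
                             n_probes = nrow(d),
                             n_elements = length(unique(d$element)),
                             stringsAsFactors = FALSE)))
    rownames(by_class) <- NULL
  } else {
    by_class <- data.frame(repeat_class = character(), n_probes = integer(),
                           n_elements = integer(), stringsAsFactors = FALSE)
  }
  list(totals = totals, by_class = by_class)
}

#' @export
print.retro_annotation <- function(x, ...) {
  s <- summarize_annotations(x)
  cat(sprintf("probe repeat annotation: %d probes, %d repeat probes (%d sense-detecting, %d antisense)\n",
              s$totals["probes"], s$totals["repeat_probes"],
              s$totals["complementary"], s$totals["non_complementary"]))
  if (nrow(s$by_class)) {
    cat("repeat probes by class:\n")
    print(s$by_class, row.names = FALSE)
  }
  invisible(x)
}
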