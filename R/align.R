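#' Align a probe to a genome (exact ungapped, mismatch-tolerant)
#'
#' Finds every ungapped placement of a probe on either strand of a genome with
#' at least `length - max_mismatches` matching bases. The search is complete:
#' no placement at or below the mismatch budget is missed. `N` in a probe (or
#' in the genome) never counts as a match, so a probe containing more than
#' `max_mismatches` `N`s can have no valid placement.
#'
#' Candidate placements are enumerated with a complete shift-or scan and then
#' re-scored by an exact base-match count under the `N`-never-matches rule.
#'
#' @param sequence Probe sequence (character, A/C/G/T/N).
#' @param genome A [Biostrings::DNAStringSet] (e.g. from [read_genome()]).
#' @param max_mismatches Maximum substitutions tolerated.
#' @return Data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `matches`, `probe_length`, `identity`, sorted by descending
#'   `matches` then (chrom, start, strand).
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGTACGTACGT"))
#' align_probe("ACGTACGTACGTACGTACGT", g, max_mismatches = 0)
align_probe <- function(sequence, genome, max_mismatches) {
  sequence <- check_dna(sequence, "probe sequence")
  if (length(sequence) != 1L) stop("align one probe at a time", call. = FALSE)
  if (!length(genome) || sum(Biostrings::width(genome)) == 0L)
    stop("genome is empty", call. = FALSE)
  len <- nchar(sequence)
  n_ns <- nchar(gsub("[^N]", "", sequence))
  if (n_ns > max_mismatches) return(empty_alignments(len))
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  res <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    if (length(subj) < len) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      hits <- Biostrings::matchPattern(pat, subj,
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE, fixed = TRUE)
      if (!length(hits)) next
      starts <- Biostrings::start(hits)
      matches <- vapply(starts, function(s) {
        count_base_matches(as.character(pat),
                           as.character(Biostrings::subseq(subj, s, s + len - 1L)))
      }, integer(1L))
      keep <- matches >= len - max_mismatches
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = starts[keep] - 1L,
        end = starts[keep] - 1L + len, strand = strand,
        matches = matches[keep], probe_length = len,
        identity = matches[keep] / len, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_alignments(len))
  out <- do.call(rbind, res)
  out <- out[order(-out$matches, out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_alignments <- function(len = NA_integer_) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), matches = integer(),
             probe_length = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

# exact base-match count; any N is never a match
count_base_matches <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(av == bv & av != "N")
}

#' Pick the top genomic hit for a probe
#'
#' Returns the alignment with the most matching bases, provided it reaches
#' `min_matches` (the platform identity cut-off, e.g. 48/50). Ties on the
#' match count are broken deterministically by (chrom, start, strand).
#'
#' @param alignments Data.frame from [align_probe()].
#' @param min_matches Minimum matching bases for a hit to qualify.
#' @return List with `hit` (single-row data.frame or `NULL`) and `hit_count`
#'   (number of qualifying placements).
#' @export
top_hit <- function(alignments, min_matches) {
  qual <- alignments[alignments$matches >= min_matches, , drop = FALSE]
  if (!nrow(qual)) return(list(hit = NULL, hit_count = 0L))
  qual <- qual[order(-qual$matches, qual$chrom, qual$start, qual$strand), ,
               drop = FALSE]
  list(hit = qual[1L, , drop = FALSE], hit_count = nrow(qual))
}

#' Count distinct genomic placements of a probe
#'
#' Number of placements with at least `min_matches` matching bases, used to
#' assess how many genomic loci a repeat probe can report on.
#'
#' @inheritParams align_probe
#' @param min_matches Minimum matching bases.
#' @return Integer count.
#' @export
count_genomic_matches <- function(sequence, genome, min_matches) {
  len <- nchar(sequence)
  aln <- align_probe(sequence, genome, max_mismatches = len - min_matches)
  sum(aln$matches >= min_matches)
}

#' In-silico PCR
#'
#' Finds every genomic locus where the forward primer matches one strand and
#' the reverse primer matches the opposite strand with their 3' ends facing
#' inward, and the implied amplicon is no longer than `max_amplicon`.
#' Overlapping amplicons are reported separately.
#'
#' @param forward,reverse Primer sequences (5'->3').
#' @param genome A [Biostrings::DNAStringSet].
#' @param max_amplicon Maximum product length (nt).
#' @param max_mismatches_per_primer Substitutions tolerated per primer site.
#' @return Data.frame with `chrom`, `amp_start`, `amp_end` (0-based half-open),
#'   `strand`, `length`, sorted by position.
#' @export
in_silico_pcr <- function(forward, reverse, genome, max_amplicon,
                          max_mismatches_per_primer = 0L) {
  f <- align_probe(forward, genome, max_mismatches_per_primer)
  r <- align_probe(reverse, genome, max_mismatches_per_primer)
  out <- rbind(
    pair_primer_sites(f[f$strand == "+", ], r[r$strand == "-", ],
                      max_amplicon, "+"),
    pair_primer_sites(r[r$strand == "+", ], f[f$strand == "-", ],
                      max_amplicon, "-")
  )
  if (!nrow(out)) return(out)
  out <- out[order(out$chrom, out$amp_start, out$amp_end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# left: plus-strand sites (3' end points right); right: minus-strand sites
pair_primer_sites <- function(left, right, max_amplicon, strand) {
  empty <- data.frame(chrom = character(), amp_start = integer(),
                      amp_end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (!nrow(left) || !nrow(right)) return(empty)
  res <- list()
  for (i in seq_len(nrow(left))) {
    li <- left[i, ]
    cand <- right[right$chrom == li$chrom &
                    right$start >= li$end &
                    right$end - li$start <= max_amplicon, , drop = FALSE]
    if (!nrow(cand)) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = li$chrom, amp_start = li$start, amp_end = cand$end,
      strand = strand, length = cand$end - li$start,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}
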