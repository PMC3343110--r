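#' Assemble repeat genomic hits into contigs
#'
#' Scans the hits of one repeat element in genomic order and merges adjacent
#' hits into the same contig when they are on the same chromosome and strand,
#' separated by a genomic gap strictly smaller than the consensus length
#' (overlapping or book-ended hits always qualify), and collinear on the
#' consensus: the next hit's consensus interval must begin at or after the
#' running consensus position on the plus strand (mirrored on the minus
#' strand), with up to `max_cons_overlap` nt of slack for the slightly
#' overlapping fragments RepeatMasker emits. Every hit belongs to exactly one
#' contig.
#'
#' @param hits Data.frame of repeat annotation records for a single element
#'   (columns as from [read_rmsk_table()]).
#' @param cons_length Element consensus length (nt). Defaults to the maximum
#'   `cons_length` in `hits`.
#' @param max_cons_overlap Consensus overlap still treated as collinear.
#' @return List of contigs; each contig is a list with `contig_id`, `chrom`,
#'   `span_start`, `span_end`, `strand`, `element`, `cons_length`, `segments`
#'   (the member hit rows in genomic order).
#' @export
assemble_contigs <- function(hits, cons_length = NULL, max_cons_overlap = 20L) {
  if (!nrow(hits)) return(list())
  if (length(unique(hits$element)) != 1L)
    stop("hits must all belong to one element", call. = FALSE)
  if (is.null(cons_length)) cons_length <- max(hits$cons_length)
  hits <- hits[order(hits$chrom, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  groups <- integer(nrow(hits))
  gid <- 1L
  groups[1L] <- gid
  for (i in seq_len(nrow(hits))[-1L]) {
    cur <- hits[i, ]
    prev <- hits[max(which(groups == gid)), ]  # last member of open contig
    if (contig_adjacent(prev, cur, cons_length, max_cons_overlap)) {
      groups[i] <- gid
    } else {
      gid <- gid + 1L
      groups[i] <- gid
    }
  }
  lapply(split(seq_len(nrow(hits)), groups), function(idx) {
    seg <- hits[idx, , drop = FALSE]
    list(contig_id = sprintf("%s_%s_%d", seg$element[1L], seg$chrom[1L],
                             seg$start[1L]),
         chrom = seg$chrom[1L],
         span_start = min(seg$start), span_end = max(seg$end),
         strand = seg$strand[1L], element = seg$element[1L],
         cons_length = cons_length, segments = seg)
  })
}

# adjacency rule between consecutive genomic hits
contig_adjacent <- function(prev, cur, cons_length, max_cons_overlap) {
  if (cur$chrom != prev$chrom || cur$strand != prev$strand) return(FALSE)
  gap <- cur$start - prev$end
  if (gap >= cons_length) return(FALSE)  # strictly less than consensus length
  if (prev$strand == "+") {
    cur$cons_start >= prev$cons_end - max_cons_overlap
  } else {
    # genomic ascent corresponds to consensus descent on the minus strand
    cur$cons_end <= prev$cons_start + max_cons_overlap
  }
}

#' Tabulate contigs
#'
#' @param contigs List from [assemble_contigs()].
#' @return Data.frame with one row per contig (id, span, strand, segment
#'   count, coverage fraction, flags when computed).
#' @export
contig_table <- function(contigs) {
  if (!length(contigs))
    return(data.frame(contig_id = character(), chrom = character(),
                      span_start = integer(), span_end = integer(),
                      strand = character(), n_segments = integer(),
                      coverage_fraction = numeric(), ltr_flanked = logical(),
                      full_length = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(contigs, function(ct) data.frame(
    contig_id = ct$contig_id, chrom = ct$chrom, span_start = ct$span_start,
    span_end = ct$span_end, strand = ct$strand,
    n_segments = nrow(ct$segments),
    coverage_fraction = consensus_coverage(ct)$fraction,
    ltr_flanked = if (is.null(ct$ltr_flanked)) NA else ct$ltr_flanked,
    full_length = if (is.null(ct$full_length)) NA else ct$full_length,
    stringsAsFactors = FALSE, row.names = NULL)))
}

# merge 1-based inclusive intervals given as a 2-column matrix
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L] + 1L) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Consensus coverage of a contig
#'
#' Union of the consensus intervals (1-based inclusive) covered by the
#' contig's segments, and the covered fraction of the consensus. The union is
#' independent of segment order.
#'
#' @param contig A contig from [assemble_contigs()].
#' @return List with `covered` (matrix of merged intervals), `covered_nt`,
#'   `fraction`.
#' @export
consensus_coverage <- function(contig) {
  seg <- contig$segments
  if (is.null(seg) || !nrow(seg))
    return(list(covered = cbind(start = integer(), end = integer()),
                covered_nt = 0L, fraction = 0))
  iv <- cbind(start = seg$cons_start, end = seg$cons_end)
  merged <- merge_intervals(iv)
  covered <- sum(merged[, 2L] - merged[, 1L] + 1L)
  list(covered = merged, covered_nt = covered,
       fraction = covered / contig$cons_length)
}

#' Flag contigs flanked by LTR hits
#'
#' A contig is LTR-flanked when some LTR hit ends within
#' `params$ltr_flank_max_gap` nt upstream of the contig start and another
#' begins within the same distance downstream of the contig end. LTR hits
#' shorter than `params$ltr_min_length` are ignored. LTR orientation is
#' recorded but not required to match the contig strand.
#'
#' @param contigs List from [assemble_contigs()].
#' @param ltr_hits Data.frame of annotation records for the partner LTR
#'   element.
#' @param params [retro_params()].
#' @return `contigs` with `ltr_flanked`, `ltr_upstream_strand`,
#'   `ltr_downstream_strand` set on each contig.
#' @export
find_ltr_flanked <- function(contigs, ltr_hits, params) {
  keep <- ltr_hits[(ltr_hits$end - ltr_hits$start) >= params$ltr_min_length, ,
                   drop = FALSE]
  gap <- params$ltr_flank_max_gap
  lapply(contigs, function(ct) {
    up <- keep[keep$chrom == ct$chrom &
                 keep$end <= ct$span_start &
                 ct$span_start - keep$end <= gap, , drop = FALSE]
    down <- keep[keep$chrom == ct$chrom &
                   keep$start >= ct$span_end &
                   keep$start - ct$span_end <= gap, , drop = FALSE]
    ct$ltr_flanked <- nrow(up) > 0L && nrow(down) > 0L
    ct$ltr_upstream_strand <- if (nrow(up)) up$strand[which.max(up$end)] else NA_character_
    ct$ltr_downstream_strand <- if (nrow(down)) down$strand[which.min(down$start)] else NA_character_
    ct
  })
}

#' Is a contig approximately full length?
#'
#' True when the consensus coverage fraction strictly exceeds
#' `params$full_length_fraction` (default 0.95).
#'
#' @inheritParams find_ltr_flanked
#' @param contig A single contig.
#' @return Logical.
#' @export
classify_full_length <- function(contig, params) {
  consensus_coverage(contig)$fraction > params$full_length_fraction
}

#' Consensus gaps (deletions and truncations) in a contig
#'
#' The complement of the covered consensus union within `[1, cons_length]`,
#' filtered to gaps of at least `params$min_deletion_nt`. Gaps touching a
#' consensus end are flagged `terminal` (truncations), distinct from internal
#' deletions.
#'
#' @inheritParams classify_full_length
#' @return Data.frame with `cons_start`, `cons_end` (1-based inclusive),
#'   `length`, `terminal`.
#' @export
detect_deletions <- function(contig, params) {
  cov <- consensus_coverage(contig)$covered
  L <- contig$cons_length
  empty <- data.frame(cons_start = integer(), cons_end = integer(),
                      length = integer(), terminal = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(cov)) {
    gaps <- data.frame(cons_start = 1L, cons_end = L, length = L,
                       terminal = TRUE, stringsAsFactors = FALSE)
  } else {
    starts <- c(1L, cov[, 2L] + 1L)
    ends <- c(cov[, 1L] - 1L, L)
    keep <- starts <= ends
    gaps <- data.frame(cons_start = starts[keep], cons_end = ends[keep],
                       length = ends[keep] - starts[keep] + 1L,
                       stringsAsFactors = FALSE)
    if (!nrow(gaps)) return(empty)
    gaps$terminal <- gaps$cons_start == 1L | gaps$cons_end == L
  }
  gaps <- gaps[gaps$length >= params$min_deletion_nt, , drop = FALSE]
  rownames(gaps) <- NULL
  gaps
}

#' Cluster recurrent internal deletions across contigs
#'
#' Single-linkage clustering of internal deletions whose start and end
#' breakpoints each differ by at most `params$deletion_cluster_tolerance` nt.
#' Terminal truncations are excluded. The cluster interval is the median of
#' the member breakpoints, and `fraction` is the share of analysed contigs
#' carrying the deletion.
#'
#' @param deletions Data.frame of deletions tagged with a `contig_id` column
#'   (e.g. rbind of [detect_deletions()] outputs).
#' @param n_total_contigs Number of contigs analysed (denominator for
#'   `fraction`).
#' @param params [retro_params()].
#' @return Data.frame with `cons_start`, `cons_end`, `n_contigs`, `fraction`,
#'   sorted by position.
#' @export
cluster_recurrent_deletions <- function(deletions, n_total_contigs, params) {
  del <- deletions[!deletions$terminal, , drop = FALSE]
  empty <- data.frame(cons_start = numeric(), cons_end = numeric(),
                      n_contigs = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(del)) return(empty)
  tol <- params$deletion_cluster_tolerance
  n <- nrow(del)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (abs(del$cons_start[i] - del$cons_start[j]) <= tol &&
        abs(del$cons_end[i] - del$cons_end[j]) <= tol) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(i)
    data.frame(cons_start = stats::median(del$cons_start[i]),
               cons_end = stats::median(del$cons_end[i]),
               n_contigs = length(unique(del$contig_id[i])),
               stringsAsFactors = FALSE)))
  out$fraction <- out$n_contigs / n_total_contigs
  out <- out[order(out$cons_start, out$cons_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is an ORF intact in a contig?
#'
#' True when the covered share of the ORF consensus interval strictly exceeds
#' `params$orf_intact_fraction` (default 0.90).
#'
#' @inheritParams classify_full_length
#' @param orf Length-2 vector: ORF start and end on the consensus (1-based
#'   inclusive).
#' @return Logical.
#' @export
orf_intactness <- function(contig, orf, params) {
  if (orf[1L] < 1L || orf[2L] > contig$cons_length || orf[1L] > orf[2L])
    stop("ORF interval lies outside the consensus", call. = FALSE)
  cov <- consensus_coverage(contig)$covered
  if (!nrow(cov)) return(FALSE)
  inter <- pmin(cov[, 2L], orf[2L]) - pmax(cov[, 1L], orf[1L]) + 1L
  covered <- sum(pmax(inter, 0L))
  covered / (orf[2L] - orf[1L] + 1L) > params$orf_intact_fraction
}

#' Match probes to contigs and classify contigs by responsive probe sets
#'
#' A probe matches a contig when any of its genomic placements lies fully
#' within the contig span widened by one probe length on each side. All
#' qualifying placements are used, not only the top hit, because a repeat
#' probe's top hit is arbitrary among near-identical loci. Each contig is
#' classified by whether it matches only upregulated probes, only unaffected
#' probes, both, or neither.
#'
#' @param placements Data.frame of probe placements (`probe_id`, `chrom`,
#'   `start`, `end`), e.g. all [align_probe()] hits at the identity cut-off.
#' @param contigs List from [assemble_contigs()].
#' @param up_set,unaffected_set Character vectors of probe ids (disjoint).
#' @return Data.frame with `contig_id`, `n_up_probes`, `n_unaffected_probes`,
#'   `class` (one of `only_upregulated`, `only_unaffected`, `both`,
#'   `neither`).
#' @export
match_probes_to_contigs <- function(placements, contigs, up_set,
                                    unaffected_set) {
  if (length(intersect(up_set, unaffected_set)))
    stop("up_set and unaffected_set must be disjoint", call. = FALSE)
  do.call(rbind, lapply(contigs, function(ct) {
    plen <- placements$end - placements$start
    hit <- placements$chrom == ct$chrom &
      placements$start >= ct$span_start - plen &
      placements$end <= ct$span_end + plen
    ids <- unique(placements$probe_id[hit])
    n_up <- length(intersect(ids, up_set))
    n_un <- length(intersect(ids, unaffected_set))
    cls <- if (n_up > 0 && n_un > 0) "both"
      else if (n_up > 0) "only_upregulated"
      else if (n_un > 0) "only_unaffected"
      else "neither"
    data.frame(contig_id = ct$contig_id, n_up_probes = n_up,
               n_unaffected_probes = n_un, class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
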