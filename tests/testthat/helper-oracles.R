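# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths (and Biostrings) wherever they serve as
# a cross-check.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# brute-force Hamming scan at every offset on both strands; N never matches
oracle_hamming_scan <- function(probe, genome_seqs, max_mismatches) {
  L <- nchar(probe)
  res <- list()
  scan_one <- function(chrom, gs, pat, strand) {
    g <- utf8ToInt(gs)
    p <- utf8ToInt(pat)
    n_off <- length(g) - L + 1L
    if (n_off < 1L) return(NULL)
    acc <- integer(n_off)
    N <- utf8ToInt("N")
    for (j in seq_len(L)) {
      gj <- g[j:(j + n_off - 1L)]
      if (p[j] == N) next
      acc <- acc + as.integer(gj == p[j])
    }
    keep <- which(acc >= L - max_mismatches)
    if (!length(keep)) return(NULL)
    data.frame(chrom = chrom, start = keep - 1L, end = keep - 1L + L,
               strand = strand, matches = acc[keep], stringsAsFactors = FALSE)
  }
  for (chrom in names(genome_seqs)) {
    gs <- genome_seqs[[chrom]]
    res[[length(res) + 1L]] <- scan_one(chrom, gs, probe, "+")
    res[[length(res) + 1L]] <- scan_one(chrom, gs, oracle_revcomp(probe), "-")
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), matches = integer(),
                      stringsAsFactors = FALSE))
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided rank-sum p by full enumeration of all C(n, n_a) assignments
oracle_ranksum_exact <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  sums <- apply(combs, 2L, function(i) sum(r[i]))
  p_le <- mean(sums <= obs + 1e-9)
  p_ge <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# independent re-statement of the contig adjacency rule, applied pairwise
oracle_assemble <- function(hits, cons_length, max_cons_overlap = 20L) {
  hits <- hits[order(hits$chrom, hits$start, hits$end), , drop = FALSE]
  n <- nrow(hits)
  grp <- integer(n)
  grp[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    members <- which(grp == grp[i - 1L])
    last <- hits[members[length(members)], ]
    cur <- hits[i, ]
    same_place <- cur$chrom == last$chrom && cur$strand == last$strand
    close_enough <- same_place && (cur$start - last$end) < cons_length
    collinear <- if (!same_place) FALSE else if (last$strand == "+")
      cur$cons_start >= last$cons_end - max_cons_overlap
    else cur$cons_end <= last$cons_start + max_cons_overlap
    grp[i] <- if (close_enough && collinear) grp[i - 1L] else max(grp) + 1L
  }
  split(seq_len(n), grp)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_genome <- function(...) {
  Biostrings::DNAStringSet(unlist(list(...)))
}

# random repeat-hit tables for contig property tests
random_hit_set <- function(n_hits, cons_length = 1000L) {
  chrom <- sample(c("chr1", "chr2"), n_hits, replace = TRUE)
  start <- sort(sample.int(20000L, n_hits))
  width <- sample.int(400L, n_hits) + 50L
  cs <- sample.int(cons_length - 200L, n_hits)
  ce <- pmin(cs + sample.int(300L, n_hits), cons_length)
  d <- data.frame(chrom = chrom, start = start, end = start + width,
                  strand = sample(c("+", "-"), n_hits, replace = TRUE),
                  element = "EL-int", family = "ERVK", repeat_class = "LTR",
                  cons_start = cs, cons_end = ce, cons_length = cons_length,
                  stringsAsFactors = FALSE)
  d[order(d$chrom, d$start, d$end), ]
}

# minimal annotation table in the package's format, built from truth labels
annotation_from_truth <- function(truth) {
  data.frame(probe_id = truth$probe_id, sequence = NA_character_,
             chrom = NA_character_, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, element = truth$element,
             family = truth$family, repeat_class = truth$repeat_class,
             overlap_nt = ifelse(truth$is_repeat, 50L, 0L),
             hit_count = 1L, is_repeat = truth$is_repeat,
             detects_sense = truth$sense, stringsAsFactors = FALSE)
}

# small synthetic probe-truth table for expression-only simulations
null_probe_truth <- function(n_probes, n_repeat = 0L, element = "EL-int") {
  truth <- data.frame(
    probe_id = sprintf("p%05d", seq_len(n_probes)),
    is_repeat = c(rep(TRUE, n_repeat), rep(FALSE, n_probes - n_repeat)),
    element = c(rep(element, n_repeat), rep(NA, n_probes - n_repeat)),
    family = c(rep("ERVK", n_repeat), rep(NA, n_probes - n_repeat)),
    repeat_class = c(rep("LTR", n_repeat), rep(NA, n_probes - n_repeat)),
    sense = c(rep(TRUE, n_repeat), rep(NA, n_probes - n_repeat)),
    stringsAsFactors = FALSE)
  truth
}
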