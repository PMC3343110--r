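hit <- function(chrom = "chr1", start, end, strand = "+", cs, ce,
                cons_length = 900L, element = "EL-int") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             element = element, family = "ERVK", repeat_class = "LTR",
             cons_start = cs, cons_end = ce, cons_length = cons_length,
             stringsAsFactors = FALSE)
}

test_that("collinear nearby hits merge; strand, gap and collinearity break contigs", {
  h <- rbind(hit(start = 1000L, end = 1400L, cs = 1L, ce = 400L),
             hit(start = 1480L, end = 1880L, cs = 500L, ce = 900L))
  ct <- assemble_contigs(h, cons_length = 900L)
  expect_length(ct, 1L)
  expect_equal(ct[[1]]$span_start, 1000L)
  expect_equal(ct[[1]]$span_end, 1880L)
  cov <- consensus_coverage(ct[[1]])
  expect_equal(cov$covered_nt, 801L)
  expect_equal(cov$fraction, 801 / 900)
  # gap exactly the consensus length: strictly "less than" fails
  h2 <- h; h2$start[2] <- 1400L + 900L; h2$end[2] <- h2$start[2] + 400L
  expect_length(assemble_contigs(h2, cons_length = 900L), 2L)
  # opposite strand: new contig
  h3 <- h; h3$strand[2] <- "-"
  expect_length(assemble_contigs(h3, cons_length = 900L), 2L)
  # non-collinear (consensus runs backwards): new contig
  h4 <- rbind(hit(start = 1000L, end = 1400L, cs = 500L, ce = 900L),
              hit(start = 1480L, end = 1880L, cs = 1L, ce = 400L))
  expect_length(assemble_contigs(h4, cons_length = 900L), 2L)
  # single hit: single-segment contig
  expect_length(assemble_contigs(h[1, ], cons_length = 900L), 1L)
  expect_error(assemble_contigs(rbind(h, hit(start = 1L, end = 10L, cs = 1L,
                                             ce = 9L, element = "OTHER"))),
               "one element")
})

test_that("minus-strand contigs require descending consensus along the genome", {
  # consensus descends with genomic position: one minus-strand copy
  h <- rbind(hit(start = 1000L, end = 1400L, strand = "-", cs = 500L, ce = 900L),
             hit(start = 1450L, end = 1850L, strand = "-", cs = 1L, ce = 400L))
  expect_length(assemble_contigs(h, cons_length = 900L), 1L)
  # ascending consensus on the minus strand is not collinear
  h_rev <- h; h_rev$cons_start <- rev(h$cons_start); h_rev$cons_end <- rev(h$cons_end)
  expect_length(assemble_contigs(h_rev, cons_length = 900L), 2L)
})

test_that("assembly agrees with an independent pairwise application of the rules", {
  set.seed(61)
  for (i in 1:40) {
    h <- random_hit_set(sample(2:60, 1))
    got <- assemble_contigs(h, cons_length = 1000L)
    want <- oracle_assemble(h, cons_length = 1000L)
    expect_equal(length(got), length(want))
    got_sizes <- vapply(got, function(ct) nrow(ct$segments), 1L)
    want_sizes <- vapply(want, length, 1L)
    expect_equal(unname(got_sizes), unname(want_sizes))
    # partition: every hit in exactly one contig, reproducing the input
    all_seg <- do.call(rbind, lapply(got, `[[`, "segments"))
    all_seg <- all_seg[order(all_seg$chrom, all_seg$start, all_seg$end), ]
    h_sorted <- h[order(h$chrom, h$start, h$end), ]
    rownames(all_seg) <- rownames(h_sorted) <- NULL
    expect_equal(all_seg, h_sorted)
  }
})

test_that("consensus overlap beyond the collinearity tolerance starts a new contig", {
  h <- rbind(hit(start = 100L, end = 600L, cs = 1L, ce = 500L,
                 cons_length = 1000L),
             hit(start = 610L, end = 1110L, cs = 400L, ce = 900L,
                 cons_length = 1000L))
  expect_length(assemble_contigs(h, cons_length = 1000L), 2L)  # 101 nt overlap
  h$cons_start[2] <- 481L  # 20 nt overlap: tolerated
  expect_length(assemble_contigs(h, cons_length = 1000L), 1L)
})

test_that("consensus coverage arithmetic is inclusive and order-independent", {
  ct <- list(cons_length = 1000L,
             segments = data.frame(cons_start = c(1L, 400L),
                                   cons_end = c(500L, 900L)))
  cov <- consensus_coverage(ct)
  expect_equal(cov$covered_nt, 900L)
  expect_equal(cov$fraction, 0.9)
  ct_rev <- ct; ct_rev$segments <- ct$segments[2:1, ]
  expect_equal(consensus_coverage(ct_rev)$covered_nt, 900L)
  full <- list(cons_length = 700L,
               segments = data.frame(cons_start = 1L, cons_end = 700L))
  expect_equal(consensus_coverage(full)$fraction, 1.0)
  none <- list(cons_length = 700L, segments = data.frame(cons_start = integer(),
                                                         cons_end = integer()))
  expect_equal(consensus_coverage(none)$fraction, 0)
})

test_that("LTR flank detection respects distance and length thresholds", {
  params <- retro_params("illumina50")
  ct <- assemble_contigs(hit(start = 5000L, end = 6000L, cs = 1L, ce = 900L),
                         cons_length = 900L)
  ltr <- function(start, end, strand = "+")
    hit(start = start, end = end, strand = strand, cs = 1L,
        ce = end - start, cons_length = 400L, element = "EL-LTR")
  # 40 bp upstream gap, 10 bp downstream gap: flagged
  flk <- find_ltr_flanked(ct, rbind(ltr(4600L, 4960L), ltr(6010L, 6400L)),
                          params)
  expect_true(flk[[1]]$ltr_flanked)
  expect_equal(flk[[1]]$ltr_upstream_strand, "+")
  # one side at 51 bp: not flagged (strict <= 50)
  far <- find_ltr_flanked(ct, rbind(ltr(4600L, 4949L), ltr(6010L, 6400L)),
                          params)
  expect_false(far[[1]]$ltr_flanked)
  # short LTR hits (< 250 bp) are ignored
  short <- find_ltr_flanked(ct, rbind(ltr(4760L, 4960L), ltr(6010L, 6400L)),
                            params)
  expect_false(short[[1]]$ltr_flanked)
  expect_false(find_ltr_flanked(ct, ltr(10L, 400L), params)[[1]]$ltr_flanked)
})

test_that("full-length and ORF-intactness calls are strict at their boundaries", {
  params <- retro_params("illumina50")
  mk <- function(ce) list(cons_length = 1000L,
                          segments = data.frame(cons_start = 1L, cons_end = ce))
  expect_true(classify_full_length(mk(960L), params))    # 0.96
  expect_false(classify_full_length(mk(950L), params))   # 0.95 exactly
  expect_true(classify_full_length(mk(1000L), params))
  orf <- c(101L, 1100L)  # 1000 nt ORF
  ct <- list(cons_length = 2000L,
             segments = data.frame(cons_start = 101L, cons_end = 1050L))
  expect_true(orf_intactness(ct, orf, params))           # 950/1000
  ct90 <- list(cons_length = 2000L,
               segments = data.frame(cons_start = 101L, cons_end = 1000L))
  expect_false(orf_intactness(ct90, orf, params))        # exactly 0.90
  gone <- list(cons_length = 2000L,
               segments = data.frame(cons_start = 1200L, cons_end = 1900L))
  expect_false(orf_intactness(gone, orf, params))
  expect_error(orf_intactness(ct, c(1L, 3000L), params), "outside")
})

test_that("deletion detection separates internal deletions from truncations", {
  params <- retro_params("illumina50")
  L <- 7000L
  ct <- list(cons_length = L,
             segments = data.frame(cons_start = c(1L, 871L),
                                   cons_end = c(398L, L)))
  d <- detect_deletions(ct, params)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$cons_start, d$cons_end), c(399L, 870L))
  expect_false(d$terminal)
  # full coverage: nothing
  full <- list(cons_length = L, segments = data.frame(cons_start = 1L,
                                                      cons_end = L))
  expect_equal(nrow(detect_deletions(full, params)), 0L)
  # truncated start: terminal gap
  tr <- list(cons_length = 500L,
             segments = data.frame(cons_start = 200L, cons_end = 500L))
  dt <- detect_deletions(tr, params)
  expect_equal(c(dt$cons_start, dt$cons_end), c(1L, 199L))
  expect_true(dt$terminal)
  # sub-threshold gaps are not reported
  small <- list(cons_length = 500L,
                segments = data.frame(cons_start = c(1L, 130L),
                                      cons_end = c(100L, 500L)))
  expect_equal(nrow(detect_deletions(small, params)), 0L)
})

test_that("recurrent deletions cluster within the breakpoint tolerance", {
  params <- retro_params("illumina50")
  dels <- data.frame(cons_start = c(399, 399, 2000), cons_end = c(870, 881, 2500),
                     terminal = FALSE, contig_id = c("c1", "c2", "c3"))
  # end breakpoints 870 vs 881 differ by 11: beyond tolerance 10
  cl10 <- cluster_recurrent_deletions(dels, 6, params)
  expect_equal(nrow(cl10), 3L)
  loose <- retro_params("illumina50", deletion_cluster_tolerance = 11)
  expect_equal(nrow(cluster_recurrent_deletions(dels, 6, loose)), 2L)
  wide <- retro_params("illumina50", deletion_cluster_tolerance = 5)
  expect_equal(nrow(cluster_recurrent_deletions(dels, 6, wide)), 3L)
  # fraction uses all analysed contigs
  two <- data.frame(cons_start = c(399, 401), cons_end = c(870, 872),
                    terminal = FALSE, contig_id = c("c1", "c2"))
  cl <- cluster_recurrent_deletions(two, 6, params)
  expect_equal(cl$n_contigs, 2L)
  expect_equal(cl$fraction, 1 / 3)
  expect_equal(cl$cons_start, 400)
  # terminal truncations never cluster
  term <- data.frame(cons_start = 1, cons_end = 300, terminal = TRUE,
                     contig_id = "c1")
  expect_equal(nrow(cluster_recurrent_deletions(term, 6, params)), 0L)
})

test_that("probe-to-contig matching classifies contigs by responsive probe sets", {
  ct <- assemble_contigs(hit(start = 1000L, end = 2000L, cs = 1L, ce = 900L),
                         cons_length = 900L)
  ct2 <- assemble_contigs(hit(chrom = "chr2", start = 1000L, end = 2000L,
                              cs = 1L, ce = 900L), cons_length = 900L)
  contigs <- c(ct, ct2)
  pl <- data.frame(
    probe_id = c("u1", "u2", "n1", "u1"),
    chrom = c("chr1", "chr1", "chr1", "chr3"),
    start = c(1100L, 1960L, 1500L, 5L),
    end = c(1150L, 2010L, 1550L, 55L), stringsAsFactors = FALSE)
  out <- match_probes_to_contigs(pl, contigs, up_set = c("u1", "u2"),
                                 unaffected_set = "n1")
  expect_equal(out$class, c("both", "neither"))
  expect_equal(out$n_up_probes, c(2L, 0L))
  out2 <- match_probes_to_contigs(pl[1:2, ], contigs, c("u1", "u2"), "n1")
  expect_equal(out2$class, c("only_upregulated", "neither"))
  expect_error(match_probes_to_contigs(pl, contigs, "u1", "u1"), "disjoint")
})
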