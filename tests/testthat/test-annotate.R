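make_rmsk <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, element = r$element,
               family = r$family %||% "ERVK",
               repeat_class = r$repeat_class %||% "LTR",
               cons_start = r$cons_start %||% 1L,
               cons_end = r$cons_end %||% (r$end - r$start),
               cons_length = r$cons_length %||% 7000L,
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

hit_row <- function(chrom = "chr1", start = 100L, end = 150L, strand = "+",
                    matches = 50L) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             matches = matches, probe_length = end - start,
             identity = matches / (end - start), stringsAsFactors = FALSE)
}

test_that("repeat calls require the minimum overlap, strictly", {
  params <- retro_params("illumina50")
  rmsk48 <- make_rmsk(list(chrom = "chr1", start = 102L, end = 700L,
                           strand = "+", element = "MMERVK10C-int"))
  ann <- classify_probe("p1", strrep("A", 50), hit_row(), 1L, rmsk48, params)
  expect_true(ann$is_repeat)        # overlap 48 = threshold, inclusive
  expect_true(ann$detects_sense)    # strands equal, complementary chemistry
  expect_equal(ann$overlap_nt, 48L)
  expect_equal(ann$family, "ERVK")
  rmsk47 <- make_rmsk(list(chrom = "chr1", start = 103L, end = 700L,
                           strand = "+", element = "MMERVK10C-int"))
  ann47 <- classify_probe("p1", strrep("A", 50), hit_row(), 1L, rmsk47, params)
  expect_false(ann47$is_repeat)     # 47 nt misses the 48 nt cut-off
  expect_equal(ann47$overlap_nt, 47L)
  none <- make_rmsk(list(chrom = "chr1", start = 5000L, end = 5600L,
                         strand = "+", element = "X-int"))
  expect_false(classify_probe("p1", strrep("A", 50), hit_row(), 1L, none,
                              params)$is_repeat)
})

test_that("orientation logic follows strand pairing and chemistry", {
  params <- retro_params("illumina50")
  rmsk <- make_rmsk(list(chrom = "chr1", start = 50L, end = 700L,
                         strand = "-", element = "IAPEz-int"))
  same <- classify_probe("p", strrep("A", 50), hit_row(strand = "-"), 1L,
                         rmsk, params)
  expect_true(same$detects_sense)
  opp <- classify_probe("p", strrep("A", 50), hit_row(strand = "+"), 1L,
                        rmsk, params)
  expect_false(opp$detects_sense)
  flipped <- classify_probe("p", strrep("A", 50), hit_row(strand = "+"), 1L,
                            rmsk, params,
                            chemistry = "probe_same_sense_as_transcript")
  expect_true(flipped$detects_sense)
})

test_that("the largest overlap wins, with positional tie-break", {
  params <- retro_params("illumina50")
  rmsk <- make_rmsk(
    list(chrom = "chr1", start = 90L, end = 149L, strand = "+", element = "A-int"),
    list(chrom = "chr1", start = 100L, end = 700L, strand = "+", element = "B-int"))
  ann <- classify_probe("p", strrep("A", 50), hit_row(), 1L, rmsk, params)
  expect_equal(ann$element, "B-int")  # overlap 50 beats 49
  tie <- make_rmsk(
    list(chrom = "chr1", start = 100L, end = 150L, strand = "+", element = "C-int"),
    list(chrom = "chr1", start = 100L, end = 160L, strand = "+", element = "D-int"))
  # equal overlap: first by position wins (same start; stable order)
  ann2 <- classify_probe("p", strrep("A", 50), hit_row(), 1L, tie, params)
  expect_equal(ann2$element, "C-int")
})

test_that("absent top hit yields a non-repeat annotation with zero hits", {
  params <- retro_params("illumina50")
  ann <- classify_probe("p", strrep("A", 50), NULL, 0L, make_rmsk(
    list(chrom = "chr1", start = 0L, end = 700L, strand = "+",
         element = "A-int")), params)
  expect_false(ann$is_repeat)
  expect_equal(ann$hit_count, 0L)
  expect_true(is.na(ann$chrom))
})

test_that("platform annotation recovers planted probes and is deterministic", {
  set.seed(21)
  repeat_core <- random_dna_str(600)
  chr <- paste0(random_dna_str(500), repeat_core, random_dna_str(500))
  g <- make_genome(c(chr1 = chr))
  rmsk <- make_rmsk(list(chrom = "chr1", start = 500L, end = 1100L,
                         strand = "+", element = "SIM-int",
                         cons_start = 1L, cons_end = 600L, cons_length = 600L))
  params <- retro_params("illumina50")
  sense <- substr(repeat_core, 100, 149)
  antisense <- oracle_revcomp(substr(repeat_core, 300, 349))
  background <- substr(chr, 50, 99)
  probes <- data.frame(probe_id = c("s1", "a1", "b1"),
                       sequence = c(sense, antisense, background),
                       stringsAsFactors = FALSE)
  ann <- annotate_platform(probes, g, rmsk, params)
  expect_equal(ann$is_repeat, c(TRUE, TRUE, FALSE))
  expect_equal(ann$detects_sense, c(TRUE, FALSE, NA))
  expect_equal(ann$element, c("SIM-int", "SIM-int", NA))
  # strand symmetry: reverse-complementing a probe flips orientation only
  rc <- data.frame(probe_id = "s1rc", sequence = oracle_revcomp(sense),
                   stringsAsFactors = FALSE)
  ann_rc <- annotate_platform(rc, g, rmsk, params)
  expect_equal(ann_rc$start, ann$start[1L])
  expect_equal(ann_rc$strand, "-")
  expect_false(ann_rc$detects_sense)
  # determinism: byte-identical annotation tables
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_probe_annotation_table(ann, f1)
  write_probe_annotation_table(annotate_platform(probes, g, rmsk, params), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(annotate_platform(rbind(probes, probes[1L, ]), g, rmsk, params),
               "duplicate")
})

test_that("annotation summaries partition the repeat probes", {
  ann <- data.frame(
    probe_id = sprintf("p%d", 1:6), sequence = strrep("A", 50),
    chrom = "chr1", start = 0L, end = 50L, strand = "+",
    element = c("A-int", "A-int", "B-int", NA, NA, "C"),
    family = c("ERVK", "ERVK", "L1", NA, NA, "Alu"),
    repeat_class = c("LTR", "LTR", "LINE", NA, NA, "SINE"),
    overlap_nt = c(50L, 50L, 48L, 0L, 0L, 49L), hit_count = 1L,
    is_repeat = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    detects_sense = c(TRUE, FALSE, TRUE, NA, NA, TRUE),
    stringsAsFactors = FALSE)
  s <- summarize_annotations(ann)
  expect_equal(unname(s$totals["probes"]), 6)
  expect_equal(unname(s$totals["repeat_probes"]), 4)
  expect_equal(unname(s$totals["complementary"] + s$totals["non_complementary"]),
               unname(s$totals["repeat_probes"]))
  expect_equal(sum(s$by_class$n_probes), unname(s$totals["repeat_probes"]))
})
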