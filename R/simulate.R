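#' Describe one synthetic repeat element
#'
#' @param name Element name (internal-region style, e.g. `"SIMERV1-int"`).
#' @param family Repeat family label (e.g. `"ERVK"`).
#' @param repeat_class Repeat class label (e.g. `"LTR"`).
#' @param cons_length Consensus length (nt).
#' @param n_copies Genomic copies to plant.
#' @param substitution_rate Per-nt substitution probability in each copy.
#' @param deletion_specs List of `list(interval = c(start, end), fraction)`:
#'   each deletion is carried by `round(fraction * n_copies)` copies and
#'   splits those copies into collinear fragments.
#' @param ltr_name Name for the partner LTR element.
#' @param ltr_length LTR consensus length (nt).
#' @param ltr_flank Plant flanking LTR copies within 0-10 bp of both ends.
#' @return A named list (one entry of `elements` in [sim_config()]).
#' @export
sim_element <- function(name, family = "ERVK", repeat_class = "LTR",
                        cons_length = 1500L, n_copies = 4L,
                        substitution_rate = 0.02,
                        deletion_specs = list(),
                        ltr_name = paste0(sub("-int$", "", name), "-LTR"),
                        ltr_length = 300L, ltr_flank = TRUE) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1)
  list(name = name, family = family, repeat_class = repeat_class,
       cons_length = as.integer(cons_length), n_copies = as.integer(n_copies),
       substitution_rate = substitution_rate, deletion_specs = deletion_specs,
       ltr_name = ltr_name, ltr_length = as.integer(ltr_length),
       ltr_flank = isTRUE(ltr_flank))
}

# normalise a raw element description (e.g. parsed from YAML) through
# sim_element so every field gets its default; idempotent
as_sim_element <- function(e) {
  if (!is.null(e$deletion_specs))
    e$deletion_specs <- lapply(e$deletion_specs, function(d)
      list(interval = as.integer(unlist(d$interval)), fraction = d$fraction))
  do.call(sim_element, e)
}

#' Simulation configuration
#'
#' The default scenario mirrors the structure of the pipeline's headline
#' analyses at desk scale: eight repeat elements planted in a synthetic
#' genome, one of them spiked with a +2 log2 expression effect on its
#' sense-detecting probes, profiled on 3 case vs 3 control arrays with
#' Gaussian log2 noise (sd 0.25). The first element carries a recurrent
#' internal deletion (consensus 399-870) in a third of its copies.
#'
#' @param seed Integer master seed; the genome, probe and expression
#'   generators derive their streams from it.
#' @param genome_length Total genome length (nt).
#' @param elements List of [sim_element()] descriptions.
#' @param n_non_repeat Number of background (non-repeat) probes.
#' @param per_element_sense,per_element_antisense Repeat probes per element in
#'   each orientation.
#' @param probe_length Probe length (nt).
#' @param n_case,n_control Arrays per condition.
#' @param baseline_mean,baseline_sd Per-probe log2 baseline distribution.
#' @param noise_sd Per-observation Gaussian noise sd (log2).
#' @param spikes List of `list(element, log2_effect)`; effects are added to
#'   case samples of all sense probes of the element.
#' @param detection_dropout_rate Overall expected absent-call rate; the
#'   dropout mass is concentrated on the lowest-baseline decile of probes.
#' @return A list of class `retro_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 220000L,
                       elements = NULL,
                       n_non_repeat = 60L,
                       per_element_sense = 10L,
                       per_element_antisense = 2L,
                       probe_length = 50L,
                       n_case = 3L, n_control = 3L,
                       baseline_mean = 8, baseline_sd = 1.5,
                       noise_sd = 0.25,
                       spikes = list(list(element = "SIMERV2-int",
                                          log2_effect = 2)),
                       detection_dropout_rate = 0.05) {
  if (is.null(elements)) {
    fams <- c("ERVK", "ERVK", "ERV1", "ERV1", "ERVL", "L1", "B2", "ERVK")
    clss <- c("LTR", "LTR", "LTR", "LTR", "LTR", "LINE", "SINE", "LTR")
    elements <- lapply(seq_len(8L), function(i) {
      sim_element(
        name = paste0("SIMERV", i, "-int"),
        family = fams[i], repeat_class = clss[i],
        n_copies = if (i == 1L) 6L else 4L,
        deletion_specs = if (i == 1L)
          list(list(interval = c(399L, 870L), fraction = 1 / 3)) else list(),
        ltr_flank = clss[i] == "LTR")
    })
  }
  elements <- lapply(elements, as_sim_element)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              elements = elements, n_non_repeat = as.integer(n_non_repeat),
              per_element_sense = as.integer(per_element_sense),
              per_element_antisense = as.integer(per_element_antisense),
              probe_length = as.integer(probe_length),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, spikes = spikes,
              detection_dropout_rate = detection_dropout_rate)
  stopifnot(cfg$detection_dropout_rate >= 0, cfg$detection_dropout_rate <= 1,
            all(vapply(elements, function(e) e$cons_length, 1L) > cfg$probe_length))
  class(cfg) <- "retro_sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

substitute_bases <- function(seq, positions) {
  if (!length(positions)) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

#' Simulate a genome with planted repeat copies
#'
#' Builds a random background sequence with each element's copies inserted:
#' copies are mutated at the element substitution rate, carry the configured
#' recurrent deletions (which split a copy into collinear annotation
#' fragments), sit on a random strand, and are optionally flanked by mutated
#' LTR copies within 0-10 bp of both ends. Loci are separated by background
#' spacers longer than any consensus so each planted copy assembles into its
#' own contig. The truth table records every inserted fragment with exact
#' consensus coordinates in the package's rmsk convention.
#'
#' @param config [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet], one chromosome),
#'   `truth` (annotation records data.frame), `consensus` / `ltr_consensus`
#'   (named character vectors), `copy_info` (per-copy fragment coverage and
#'   substitution positions), `background` (data.frame of probe-safe
#'   background intervals), `planted_deletions` (per-element deletion truth).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  els <- config$elements
  consensus <- stats::setNames(
    vapply(els, function(e) random_dna(e$cons_length), character(1L)),
    vapply(els, function(e) e$name, character(1L)))
  ltr_consensus <- stats::setNames(
    vapply(els, function(e) random_dna(e$ltr_length), character(1L)),
    vapply(els, function(e) e$ltr_name, character(1L)))

  # build loci (DNA + per-locus truth rows relative to locus start)
  loci <- list()
  copy_info <- list()
  planted_deletions <- list()
  for (e in els) {
    cons <- consensus[[e$name]]
    del_by_copy <- rep(list(list()), e$n_copies)
    for (spec in e$deletion_specs) {
      k <- round(spec$fraction * e$n_copies)
      for (ci in seq_len(k))
        del_by_copy[[ci]] <- c(del_by_copy[[ci]], list(spec$interval))
      planted_deletions[[length(planted_deletions) + 1L]] <- data.frame(
        element = e$name, cons_start = spec$interval[1L],
        cons_end = spec$interval[2L], n_copies = k, stringsAsFactors = FALSE)
    }
    for (ci in seq_len(e$n_copies)) {
      strand <- sample(c("+", "-"), 1L)
      # covered fragments = complement of this copy's deletions
      dels <- del_by_copy[[ci]]
      frag <- cbind(start = 1L, end = e$cons_length)
      for (d in dels) {
        pieces <- list()
        for (r in seq_len(nrow(frag))) {
          s <- frag[r, 1L]; t <- frag[r, 2L]
          if (d[2L] < s || d[1L] > t) { pieces[[length(pieces) + 1L]] <- c(s, t); next }
          if (d[1L] > s) pieces[[length(pieces) + 1L]] <- c(s, d[1L] - 1L)
          if (d[2L] < t) pieces[[length(pieces) + 1L]] <- c(d[2L] + 1L, t)
        }
        frag <- do.call(rbind, pieces)
      }
      subs <- which(stats::runif(e$cons_length) < e$substitution_rate)
      # keep substitutions on retained sequence only
      keep <- rep(FALSE, e$cons_length)
      for (r in seq_len(nrow(frag))) keep[frag[r, 1L]:frag[r, 2L]] <- TRUE
      subs <- subs[keep[subs]]
      mutated <- substitute_bases(cons, subs)
      frag_seqs <- vapply(seq_len(nrow(frag)), function(r)
        substr(mutated, frag[r, 1L], frag[r, 2L]), character(1L))
      body_fwd <- paste(frag_seqs, collapse = "")
      body <- if (strand == "+") body_fwd else revcomp_chr(body_fwd)
      # fragment truth rows in genomic order within the body
      ord <- if (strand == "+") seq_len(nrow(frag)) else rev(seq_len(nrow(frag)))
      offs <- cumsum(c(0L, (frag[ord, 2L] - frag[ord, 1L] + 1L)))
      body_truth <- do.call(rbind, lapply(seq_along(ord), function(k) {
        r <- ord[k]
        data.frame(rel_start = offs[k], rel_end = offs[k + 1L],
                   strand = strand, element = e$name, family = e$family,
                   repeat_class = e$repeat_class,
                   cons_start = frag[r, 1L], cons_end = frag[r, 2L],
                   cons_length = e$cons_length, stringsAsFactors = FALSE)
      }))
      # optional flanking LTRs
      seq_parts <- body
      truth_parts <- body_truth
      if (e$ltr_flank) {
        mk_ltr <- function() {
          s <- which(stats::runif(e$ltr_length) < e$substitution_rate)
          substitute_bases(ltr_consensus[[e$ltr_name]], s)
        }
        l5 <- mk_ltr(); l3 <- mk_ltr()
        g5 <- sample(0:10, 1L); g3 <- sample(0:10, 1L)
        l5s <- if (strand == "+") l5 else revcomp_chr(l5)
        l3s <- if (strand == "+") l3 else revcomp_chr(l3)
        pre <- paste0(l5s, random_dna(g5))
        shift <- nchar(pre)
        truth_parts$rel_start <- truth_parts$rel_start + shift
        truth_parts$rel_end <- truth_parts$rel_end + shift
        ltr_truth <- data.frame(
          rel_start = c(0L, shift + nchar(body) + g3),
          rel_end = c(e$ltr_length, shift + nchar(body) + g3 + e$ltr_length),
          strand = strand, element = e$ltr_name, family = e$family,
          repeat_class = e$repeat_class, cons_start = 1L,
          cons_end = e$ltr_length, cons_length = e$ltr_length,
          stringsAsFactors = FALSE)
        seq_parts <- paste0(pre, body, random_dna(g3), l3s)
        truth_parts <- rbind(truth_parts, ltr_truth)
      }
      loci[[length(loci) + 1L]] <- list(seq = seq_parts, truth = truth_parts)
      copy_info[[length(copy_info) + 1L]] <- list(
        element = e$name, copy = ci, strand = strand, fragments = frag,
        substitutions = subs)
    }
  }

  total_insert <- sum(vapply(loci, function(l) nchar(l$seq), 1))
  max_cons <- max(vapply(els, function(e) e$cons_length + 2L * e$ltr_length + 22L, 1L))
  n_loci <- length(loci)
  spacer <- floor((config$genome_length - total_insert) / (n_loci + 1L))
  if (spacer < max_cons)
    stop("insertions exceed the genome length: increase genome_length",
         call. = FALSE)
  loci <- sample(loci)  # shuffle locus order along the genome
  pieces <- character(2L * n_loci + 1L)
  truth <- list()
  background <- list()
  pos <- 0L
  pieces[1L] <- random_dna(spacer)
  background[[1L]] <- c(0L, spacer)
  pos <- spacer
  for (i in seq_len(n_loci)) {
    lt <- loci[[i]]$truth
    lt$start <- lt$rel_start + pos
    lt$end <- lt$rel_end + pos
    truth[[i]] <- lt[, c("start", "end", "strand", "element", "family",
                         "repeat_class", "cons_start", "cons_end",
                         "cons_length")]
    pieces[2L * i] <- loci[[i]]$seq
    pos <- pos + nchar(loci[[i]]$seq)
    pieces[2L * i + 1L] <- random_dna(spacer)
    background[[i + 1L]] <- c(pos, pos + spacer)
    pos <- pos + spacer
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(pieces, collapse = ""), "chrS1"))
  truth <- do.call(rbind, truth)
  truth <- data.frame(chrom = "chrS1", truth, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$start), ]
  rownames(truth) <- NULL
  validate_rmsk(truth, "<simulated truth>")
  planted <- if (length(planted_deletions)) do.call(rbind, planted_deletions)
    else data.frame(element = character(), cons_start = integer(),
                    cons_end = integer(), n_copies = integer(),
                    stringsAsFactors = FALSE)
  list(genome = genome, truth = truth, consensus = consensus,
       ltr_consensus = ltr_consensus, copy_info = copy_info,
       background = do.call(rbind, background), planted_deletions = planted,
       config = config)
}

#' Simulate array probes from a planted genome
#'
#' Non-repeat probes are exact background substrings (random strand). Repeat
#' probes are drawn from each element's consensus at footprints that lie
#' entirely inside one planted fragment of some copy with at most
#' `max_mismatches` planted substitutions under the footprint (rejection
#' sampling), so the probe's repeat/element/orientation truth label is
#' unambiguous. Sense probes read the consensus strand; antisense probes are
#' its reverse complement.
#'
#' @param sim Output of [simulate_genome()].
#' @param config [sim_config()] (uses probe counts and length).
#' @param max_mismatches Mismatch budget used for footprint rejection;
#'   defaults to 2 (50-mer rule).
#' @return List with `probes` (data.frame `probe_id`, `sequence`) and `truth`
#'   (data.frame `probe_id`, `is_repeat`, `element`, `family`,
#'   `repeat_class`, `sense`).
#' @export
simulate_probes <- function(sim, config = sim$config, max_mismatches = 2L) {
  set.seed(config$seed + 1000L)
  plen <- config$probe_length
  genome_chr <- as.character(sim$genome[[1L]])
  probes <- list(); truth <- list()
  add_probe <- function(seq, is_repeat, element, family, cls, sense) {
    id <- sprintf("probe_%05d", length(probes) + 1L)
    probes[[length(probes) + 1L]] <<- data.frame(
      probe_id = id, sequence = seq, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      probe_id = id, is_repeat = is_repeat, element = element,
      family = family, repeat_class = cls, sense = sense,
      stringsAsFactors = FALSE)
  }
  # background probes
  bg <- sim$background
  bg <- bg[bg[, 2L] - bg[, 1L] > plen + 2L, , drop = FALSE]
  if (!nrow(bg)) stop("not enough background sequence for probes", call. = FALSE)
  for (i in seq_len(config$n_non_repeat)) {
    r <- bg[sample(nrow(bg), 1L), ]
    s <- sample(seq(r[1L] + 1L, r[2L] - plen), 1L)
    seq <- substr(genome_chr, s + 1L, s + plen)
    if (sample(c(TRUE, FALSE), 1L)) seq <- revcomp_chr(seq)
    add_probe(seq, FALSE, NA_character_, NA_character_, NA_character_, NA)
  }
  # repeat probes from element consensi
  for (e in config$elements) {
    cons <- sim$consensus[[e$name]]
    copies <- Filter(function(ci) ci$element == e$name, sim$copy_info)
    draw_window <- function() {
      for (attempt in 1:200) {
        ci <- copies[[sample(length(copies), 1L)]]
        frag <- ci$fragments
        ok <- which(frag[, 2L] - frag[, 1L] + 1L >= plen)
        if (!length(ok)) next
        r <- ok[sample(length(ok), 1L)]
        s <- sample(seq(frag[r, 1L], frag[r, 2L] - plen + 1L), 1L)
        if (sum(ci$substitutions >= s & ci$substitutions < s + plen) <= max_mismatches)
          return(s)
      }
      stop("could not place a probe with the mismatch budget; lower the substitution rate",
           call. = FALSE)
    }
    for (k in seq_len(config$per_element_sense)) {
      s <- draw_window()
      add_probe(substr(cons, s, s + plen - 1L), TRUE, e$name, e$family,
                e$repeat_class, TRUE)
    }
    for (k in seq_len(config$per_element_antisense)) {
      s <- draw_window()
      add_probe(revcomp_chr(substr(cons, s, s + plen - 1L)), TRUE, e$name,
                e$family, e$repeat_class, FALSE)
    }
  }
  list(probes = do.call(rbind, probes), truth = do.call(rbind, truth))
}

#' Simulate a two-condition expression matrix for the synthetic probes
#'
#' Per-probe log2 baseline drawn once from `N(baseline_mean, baseline_sd^2)`;
#' each observation adds the condition effect (spiked elements' sense probes
#' only, case samples only) and independent Gaussian noise. Detection calls
#' are present everywhere except for dropout concentrated on the
#' lowest-baseline decile of probes.
#'
#' @param probe_truth Truth data.frame from [simulate_probes()].
#' @param config [sim_config()].
#' @return List with `matrix` (log2-scale, probes x samples), `detection`
#'   (logical), `condition_of_sample` (named vector, conditions `"case"` /
#'   `"control"`), `de_truth` (data.frame `probe_id`, `log2_effect`).
#' @export
simulate_expression <- function(probe_truth, config) {
  set.seed(config$seed + 2000L)
  np <- nrow(probe_truth)
  ns <- config$n_case + config$n_control
  samples <- c(sprintf("case_%d", seq_len(config$n_case)),
               sprintf("ctrl_%d", seq_len(config$n_control)))
  cond <- stats::setNames(rep(c("case", "control"),
                              c(config$n_case, config$n_control)), samples)
  effect <- rep(0, np)
  for (sp in config$spikes) {
    hit <- probe_truth$element %in% sp$element & probe_truth$sense %in% TRUE
    effect[hit] <- effect[hit] + sp$log2_effect
  }
  baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
  m <- matrix(baseline, np, ns) +
    outer(effect, as.numeric(cond == "case")) +
    matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
  dimnames(m) <- list(probe_truth$probe_id, samples)
  detection <- matrix(TRUE, np, ns, dimnames = dimnames(m))
  if (config$detection_dropout_rate > 0) {
    low <- baseline <= stats::quantile(baseline, 0.1)
    p_drop <- min(1, config$detection_dropout_rate * 10)
    drop <- matrix(stats::runif(np * ns) < p_drop, np, ns) & low
    detection[drop] <- FALSE
  }
  attr(m, "scale") <- "log2"
  list(matrix = m, detection = detection, condition_of_sample = cond,
       de_truth = data.frame(probe_id = probe_truth$probe_id,
                             log2_effect = effect, stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `rmsk.tsv` (ucsc dialect), `probes.tsv`, `expr.tsv`,
#' `detection.tsv`, `design.tsv` and truth tables under `truth/`.
#'
#' @param sim Output of [simulate_genome()].
#' @param probes Output of [simulate_probes()].
#' @param expr Output of [simulate_expression()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, probes, expr, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_rmsk_ucsc(sim$truth, file.path(outdir, "rmsk.tsv"))
  utils::write.table(probes$probes, file.path(outdir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(expr$matrix, file.path(outdir, "expr.tsv"))
  det <- expr$detection; storage.mode(det) <- "integer"
  write_expression_matrix(det, file.path(outdir, "detection.tsv"))
  utils::write.table(
    data.frame(sample_id = names(expr$condition_of_sample),
               condition = unname(expr$condition_of_sample)),
    file.path(outdir, "design.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(probes$truth, file.path(outdir, "truth", "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$de_truth, file.path(outdir, "truth", "de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$planted_deletions,
                     file.path(outdir, "truth", "deletions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Write annotation records in the ucsc rmsk dialect
#'
#' Inverse of `read_rmsk_table(dialect = "ucsc")`.
#' @param rec Annotation records data.frame.
#' @param path Output path.
#' @export
write_rmsk_ucsc <- function(rec, path) {
  out <- data.frame(
    genoName = rec$chrom, genoStart = rec$start, genoEnd = rec$end,
    strand = rec$strand, repName = rec$element, repClass = rec$repeat_class,
    repFamily = rec$family, repStart = rec$cons_start, repEnd = rec$cons_end,
    repLeft = -(rec$cons_length - rec$cons_end), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rec)
}
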