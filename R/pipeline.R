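#' Run the full repeat-annotation pipeline
#'
#' Orchestrates simulate (optional) -> probe annotation -> preprocessing ->
#' differential expression -> population statistics -> contig assembly ->
#' report, from a single config, writing every stage output plus a run
#' manifest into `outdir`. All outputs are written atomically (temp file +
#' rename) and recorded in the manifest; the manifest is written on success
#' and on failure (recording the failed stage). Re-running with an unchanged
#' config over an existing completed manifest is a no-op unless
#' `force = TRUE`.
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#'   Top-level keys: `seed`; either `simulate: yes` (with optional overrides
#'   under `simulate`) or an `inputs` block with paths `genome`, `rmsk`,
#'   `probes`, `expr`, `detection`, `design`; `params` (arguments to
#'   [retro_params()]); `de` (`case`, `control`); `population`
#'   (`elements`: names to test); `contigs` (`element`, `ltr`).
#' @param outdir Output directory.
#' @param force Re-run even if a completed manifest for the same config
#'   exists.
#' @return List with `status` (0 ok, 2 missing input, 3 invalid parameters),
#'   `manifest` (list), `outputs` (named paths). Failed stages raise no R
#'   error; the status code and manifest record them.
#' @export
run_full <- function(config, outdir, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(cfg)
  manifest_path <- file.path(outdir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (identical(prev$config_hash, cfg_hash) && identical(prev$status, 0L))
      return(list(status = 0L, manifest = prev, outputs = prev$outputs,
                  rerun = FALSE))
  }
  outputs <- list()
  stage <- "init"
  manifest <- list(config_hash = cfg_hash,
                   version = as.character(utils::packageVersion("retroarray")),
                   seed = cfg$seed %||% 1L, status = NA_integer_,
                   failed_stage = NULL, outputs = NULL, input_checksums = NULL)
  finish <- function(status, error = NULL) {
    manifest$status <<- as.integer(status)
    manifest$failed_stage <<- if (status == 0L) NULL else stage
    manifest$error <<- error
    manifest$outputs <<- outputs
    atomic_write(function(p) jsonlite::write_json(
      manifest, p, auto_unbox = TRUE, pretty = TRUE, null = "null"),
      manifest_path)
    list(status = as.integer(status), manifest = manifest, outputs = outputs,
         rerun = TRUE)
  }

  res <- tryCatch({
    stage <- "params"
    params <- do.call(retro_params, c(list(), cfg$params))
    seed <- as.integer(cfg$seed %||% 1L)

    stage <- "inputs"
    if (isTRUE(cfg$simulate) || is.list(cfg$simulate)) {
      sc_args <- if (is.list(cfg$simulate)) cfg$simulate else list()
      sc_args$seed <- seed
      sc <- do.call(sim_config, sc_args)
      sim <- simulate_genome(sc)
      probes <- simulate_probes(sim, sc, max_mismatches = params$max_mismatches)
      expr <- simulate_expression(probes$truth, sc)
      simdir <- file.path(outdir, "sim")
      write_simulation(sim, probes, expr, simdir)
      genome <- sim$genome
      rmsk <- sim$truth
      probe_tab <- probes$probes
      m <- expr$matrix
      detection <- expr$detection
      cond <- expr$condition_of_sample
      outputs$sim <- simdir
    } else {
      inp <- cfg$inputs
      need <- c("genome", "rmsk", "probes", "expr", "design")
      for (f in need) {
        if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
          stop(structure(class = c("retro_missing_input", "error", "condition"),
                         list(message = paste0("missing input: ", f),
                              call = NULL)))
      }
      genome <- read_genome(inp$genome)
      rmsk <- read_rmsk_table(inp$rmsk, dialect = inp$rmsk_dialect %||% "ucsc")
      probe_tab <- read_probe_table(inp$probes)
      m <- read_expression_matrix(inp$expr, scale = inp$expr_scale %||% "log2")
      detection <- if (!is.null(inp$detection) && file.exists(inp$detection)) {
        d <- read_expression_matrix(inp$detection); d > 0
      } else NULL
      cond <- read_design(inp$design)
    }

    stage <- "annotate"
    annot <- annotate_platform(probe_tab, genome, rmsk, params)
    outputs$annot <- write_stage(function(p)
      write_probe_annotation_table(annot, p), outdir, "annot.tsv")
    summ <- summarize_annotations(annot)
    outputs$annot_summary <- write_stage(function(p)
      utils::write.table(summ$by_class, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), outdir, "annot_summary.tsv")

    stage <- "preprocess"
    if (identical(attr(m, "scale"), "raw"))
      m <- log2_transform(m, offset = params$log_offset)
    m <- quantile_normalize(m)
    if (!is.null(detection))
      m <- filter_absent_illumina(m, detection[rownames(m), , drop = FALSE],
                                  params$detection_alpha)
    outputs$norm <- write_stage(function(p) write_expression_matrix(m, p),
                                outdir, "norm.tsv")

    stage <- "de"
    case <- cfg$de$case %||% "case"
    control <- cfg$de$control %||% "control"
    de <- de_analysis(m, cond, case, control, params)
    outputs$de <- write_stage(function(p)
      utils::write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE),
      outdir, "de.tsv")
    elem <- summarize_by_element(de, annot)
    outputs$elements <- write_stage(function(p)
      utils::write.table(elem, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), outdir, "elements.tsv")

    stage <- "population"
    pop_elems <- cfg$population$elements %||%
      unique(stats::na.omit(annot$element[annot$is_repeat]))
    pop <- compare_probe_populations(
      de, annot, lapply(pop_elems, function(e) list(element = e)))
    outputs$poptests <- write_stage(function(p)
      utils::write.table(pop, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), outdir, "poptests.tsv")

    stage <- "contigs"
    ct_el <- cfg$contigs$element %||% NULL
    if (!is.null(ct_el)) {
      hits <- rmsk[rmsk$element == ct_el, , drop = FALSE]
      contigs <- assemble_contigs(hits, max_cons_overlap = params$max_cons_overlap)
      if (!is.null(cfg$contigs$ltr)) {
        ltr_hits <- rmsk[rmsk$element == cfg$contigs$ltr, , drop = FALSE]
        contigs <- find_ltr_flanked(contigs, ltr_hits, params)
      }
      contigs <- lapply(contigs, function(ct) {
        ct$full_length <- classify_full_length(ct, params); ct })
      ctab <- contig_table(contigs)
      outputs$contigs <- write_stage(function(p)
        utils::write.table(ctab, p, sep = "\t", quote = FALSE,
                           row.names = FALSE), outdir, "contigs.tsv")
      dels <- do.call(rbind, lapply(contigs, function(ct) {
        d <- detect_deletions(ct, params)
        if (nrow(d)) d$contig_id <- ct$contig_id
        d
      }))
      clus <- if (!is.null(dels) && nrow(dels))
        cluster_recurrent_deletions(dels, length(contigs), params)
      else data.frame()
      outputs$deletions <- write_stage(function(p)
        utils::write.table(clus, p, sep = "\t", quote = FALSE,
                           row.names = FALSE), outdir, "deletions.tsv")
    }

    stage <- "report"
    rep <- repeat_report(list(contrast = elem))
    outputs$report <- write_stage(function(p) writeLines(rep, p),
                                  outdir, "report.txt")
    finish(0L)
  },
  retro_missing_input = function(e) finish(2L, conditionMessage(e)),
  error = function(e) {
    status <- if (stage %in% c("params")) 3L else 1L
    finish(status, conditionMessage(e))
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

write_stage <- function(writer, outdir, name) {
  atomic_write(writer, file.path(outdir, name))
}

#' Human-readable per-element change report
#'
#' Formats one or more per-element differential summaries (one per contrast)
#' as an up/down/no-change table, with expressed- and changed-probe
#' fractions.
#'
#' @param element_summaries Named list of [summarize_by_element()] outputs.
#' @return Character vector of report lines.
#' @export
repeat_report <- function(element_summaries) {
  if (!length(element_summaries)) stop("no summaries supplied", call. = FALSE)
  elements <- sort(unique(unlist(lapply(element_summaries,
                                        function(s) s$element))))
  lines <- c(paste(c("element", names(element_summaries)), collapse = "\t"))
  for (el in elements) {
    syms <- vapply(element_summaries, function(s) {
      r <- s[s$element == el, , drop = FALSE]
      if (!nrow(r)) return("-")
      if (r$n_up > 0 && r$n_down > 0) "updown"
      else if (r$n_up > 0) "up" else if (r$n_down > 0) "down" else "-"
    }, character(1L))
    lines <- c(lines, paste(c(el, syms), collapse = "\t"))
  }
  for (nm in names(element_summaries)) {
    fr <- attr(element_summaries[[nm]], "fractions")
    if (!is.null(fr) && fr$n_expressed_repeat > 0) {
      lines <- c(lines, sprintf(
        "%s: %d of %d expressed repeat probes changed (%s%%)",
        nm, fr$n_changed_repeat, fr$n_expressed_repeat,
        percent_label(fr$n_changed_repeat, fr$n_expressed_repeat)))
    }
  }
  lines
}
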