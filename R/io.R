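#' Read a repeat annotation table
#'
#' Reads repeat-masked genomic intervals in one of two tab-delimited dialects
#' and returns them in the package's internal convention: genomic coordinates
#' 0-based half-open, consensus coordinates 1-based inclusive with
#' `cons_start <= cons_end` on both strands, rows sorted by (chrom, start).
#'
#' Dialects:
#' \describe{
#'   \item{`"ucsc"`}{Header line with at least the columns `genoName`,
#'     `genoStart`, `genoEnd`, `strand`, `repName`, `repClass`, `repFamily`,
#'     `repStart`, `repEnd`, `repLeft`. `genoStart`/`genoEnd` are 0-based
#'     half-open; `repStart`..`repEnd` is the consensus interval (1-based
#'     inclusive) and `repLeft` the (possibly negative) count of consensus
#'     bases beyond `repEnd`, so `cons_length = repEnd + |repLeft|`.}
#'   \item{`"out"`}{RepeatMasker `.out` format: a 3-line header then
#'     whitespace-delimited columns score, div, del, ins, query, begin, end,
#'     (left), strand (`+` or `C`), repeat, class/family, and three consensus
#'     position columns — `begin end (left)` for `+` rows, `(left) end begin`
#'     for `C` rows. Query coordinates are 1-based inclusive.}
#' }
#'
#' @param path Path to the file.
#' @param dialect `"ucsc"` or `"out"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `element`, `family`, `repeat_class`, `cons_start`, `cons_end`,
#'   `cons_length`.
#' @export
read_rmsk_table <- function(path, dialect = c("ucsc", "out")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- switch(dialect,
    ucsc = read_rmsk_ucsc(path),
    out  = read_rmsk_out(path)
  )
  validate_rmsk(rec, path)
  rec <- rec[order(rec$chrom, rec$start, rec$end), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

read_rmsk_ucsc <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily", "repStart", "repEnd", "repLeft")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ucsc rmsk table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(
    chrom = as.character(tab$genoName),
    start = as.integer(tab$genoStart),
    end = as.integer(tab$genoEnd),
    strand = as.character(tab$strand),
    element = as.character(tab$repName),
    family = as.character(tab$repFamily),
    repeat_class = as.character(tab$repClass),
    cons_start = as.integer(tab$repStart),
    cons_end = as.integer(tab$repEnd),
    cons_length = as.integer(tab$repEnd + abs(tab$repLeft)),
    stringsAsFactors = FALSE
  )
}

read_rmsk_out <- function(path) {
  lines <- readLines(path)
  # .out files carry two header lines plus a blank; tolerate their absence
  body_at <- grep("^\\s*[0-9]+\\s", lines)
  if (!length(body_at)) {
    return(empty_rmsk())
  }
  out <- vector("list", length(body_at))
  for (i in seq_along(body_at)) {
    ln <- body_at[i]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) < 14L)
      stop("malformed RepeatMasker .out row at line ", ln, call. = FALSE)
    strand <- f[9L]
    if (!strand %in% c("+", "C", "-"))
      stop("malformed strand field at line ", ln, call. = FALSE)
    cf <- strsplit(f[11L], "/", fixed = TRUE)[[1L]]
    unparen <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
    r1 <- unparen(f[12L]); r2 <- unparen(f[13L]); r3 <- unparen(f[14L])
    if (anyNA(c(r1, r2, r3)))
      stop("malformed consensus coordinates at line ", ln, call. = FALSE)
    if (strand == "+") {
      cons_start <- r1; cons_end <- r2; cons_length <- r2 + r3
    } else {
      # C rows print (left) end begin
      cons_start <- r3; cons_end <- r2; cons_length <- r2 + r1
    }
    qb <- suppressWarnings(as.integer(f[6L]))
    qe <- suppressWarnings(as.integer(f[7L]))
    if (anyNA(c(qb, qe)))
      stop("malformed query coordinates at line ", ln, call. = FALSE)
    out[[i]] <- data.frame(
      chrom = f[5L], start = qb - 1L, end = qe,
      strand = if (strand == "+") "+" else "-",
      element = f[10L],
      family = if (length(cf) > 1L) cf[2L] else cf[1L],
      repeat_class = cf[1L],
      cons_start = cons_start, cons_end = cons_end,
      cons_length = cons_length,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

empty_rmsk <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), element = character(), family = character(),
             repeat_class = character(), cons_start = integer(),
             cons_end = integer(), cons_length = integer(),
             stringsAsFactors = FALSE)
}

validate_rmsk <- function(rec, path = "<rmsk>") {
  if (!nrow(rec)) return(invisible(rec))
  bad <- which(!(rec$start < rec$end))
  if (length(bad))
    stop(path, ": start >= end in record ", bad[1L], call. = FALSE)
  bad <- which(!(rec$cons_start >= 1L & rec$cons_start <= rec$cons_end &
                   rec$cons_end <= rec$cons_length))
  if (length(bad))
    stop(path, ": inconsistent consensus coordinates in record ", bad[1L],
         call. = FALSE)
  if (any(!rec$strand %in% c("+", "-")))
    stop(path, ": strand must be '+' or '-'", call. = FALSE)
  invisible(rec)
}

#' Write / read a probe repeat-annotation table
#'
#' Tab-delimited, one row per probe, mirroring the published per-platform
#' repeat-probe datasets. Empty string fields are serialised as `"."`;
#' missing numeric fields as `NA`. `write_probe_annotation_table()` and
#' `read_probe_annotation_table()` round-trip losslessly.
#'
#' @param annotations Data.frame as returned by [annotate_platform()].
#' @param path Output (input) path.
#' @return The input invisibly (writer); a data.frame (reader).
#' @export
write_probe_annotation_table <- function(annotations, path) {
  if (!is.data.frame(annotations) || !nrow(annotations))
    stop("annotations must be a non-empty data.frame", call. = FALSE)
  cols <- c("probe_id", "sequence", "chrom", "start", "end", "strand",
            "element", "family", "repeat_class", "overlap_nt", "hit_count",
            "is_repeat", "detects_sense")
  miss <- setdiff(cols, names(annotations))
  if (length(miss))
    stop("annotations missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- annotations[, cols]
  for (f in c("chrom", "strand", "element", "family", "repeat_class"))
    out[[f]] <- ifelse(is.na(out[[f]]) | out[[f]] == "", ".", out[[f]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write annotation table to ", path, call. = FALSE)
  invisible(annotations)
}

#' @rdname write_probe_annotation_table
#' @export
read_probe_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (f in c("chrom", "strand", "element", "family", "repeat_class"))
    tab[[f]][tab[[f]] == "."] <- NA_character_
  tab$is_repeat <- as.logical(tab$is_repeat)
  tab$detects_sense <- as.logical(tab$detects_sense)
  tab
}

#' Read a probe table
#'
#' Accepts either a two-column TSV (`probe_id`, `sequence`; extra columns are
#' kept) or a FASTA file. Sequences are upper-cased and validated against the
#' A/C/G/T/N alphabet; duplicate probe ids are an error.
#'
#' @param path Path to TSV or FASTA.
#' @return Data.frame with `probe_id` and `sequence`.
#' @export
read_probe_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    tab <- data.frame(probe_id = names(ss), sequence = as.character(ss),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "sequence") %in% names(tab)))
      stop("probe TSV must have columns probe_id and sequence", call. = FALSE)
  }
  tab$sequence <- check_dna(tab$sequence, "probe sequence")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe_id: ", tab$probe_id[duplicated(tab$probe_id)][1L],
         call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Read / write an expression matrix
#'
#' TSV with `probe_id` in the first column and one column per sample.
#'
#' @param path File path.
#' @param scale `"raw"` or `"log2"`, recorded as an attribute.
#' @return Numeric matrix (probes x samples) with an attribute `scale`.
#' @export
read_expression_matrix <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  attr(m, "scale") <- scale
  m
}

#' @rdname read_expression_matrix
#' @param m Matrix with probe ids as rownames.
#' @export
write_expression_matrix <- function(m, path) {
  tab <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Read a design table
#'
#' TSV with columns `sample_id` and `condition`.
#' @param path File path.
#' @return Named character vector mapping sample id to condition.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(tab)))
    stop("design must have columns sample_id and condition", call. = FALSE)
  stats::setNames(as.character(tab$condition), as.character(tab$sample_id))
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (!length(g) || sum(Biostrings::width(g)) == 0L)
    stop("genome FASTA is empty", call. = FALSE)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a primer-pair table
#'
#' TSV with columns `name`, `forward`, `reverse`, `max_amplicon`.
#' @param path File path.
#' @return Data.frame of validated primer pairs.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse", "max_amplicon")
  if (!all(need %in% names(tab)))
    stop("primer TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$forward <- check_dna(tab$forward, "forward primer")
  tab$reverse <- check_dna(tab$reverse, "reverse primer")
  bad <- nchar(tab$forward) < 15L | nchar(tab$reverse) < 15L
  if (any(bad))
    stop("primers must be at least 15 nt (pair '", tab$name[bad][1L], "')",
         call. = FALSE)
  bad <- tab$max_amplicon <= nchar(tab$forward) + nchar(tab$reverse)
  if (any(bad))
    stop("max_amplicon must exceed the combined primer length (pair '",
         tab$name[bad][1L], "')", call. = FALSE)
  tab
}
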