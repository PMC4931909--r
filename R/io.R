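#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated RPKM matrix (header row of sample ids, first column
#' gene ids) and validates it against a sample annotation.  Values must be
#' finite and non-negative; gene ids must be unique; every sample column must
#' appear in `sample_info`.  Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @param sample_info tibble with columns `sample`, `condition` and optionally
#'   `replicate`.  `condition` may be a factor whose level order encodes
#'   increasing nominal signal strength; otherwise order of first appearance
#'   is used.
#' @return a tibble with first column `gene_id` and one numeric column per
#'   sample.
#' @examples
#' si <- tibble::tibble(sample = c("s1", "s2"), condition = c("a", "b"))
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "Irf4\t10\t20"), tf)
#' read_expression_table(tf, si)
#' @export
read_expression_table <- function(path, sample_info) {
  check_sample_info(sample_info)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression table needs a gene id column and at least one sample")
  names(raw)[1] <- "gene_id"
  ids <- raw$gene_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samples <- names(raw)[-1]
  missing <- setdiff(samples, sample_info$sample)
  if (length(missing)) {
    abort(paste0("sample(s) in file absent from sample_info: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(gene_id = ids)
  for (s in samples) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) & !is.na(raw[[s]]) | !is.finite(v))
    if (length(bad)) {
      abort(paste0("non-numeric or non-finite value '", raw[[s]][bad[1]],
                   "' at row ", bad[1], " (gene ", ids[bad[1]],
                   "), column ", s))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      abort(paste0("negative expression value ", v[neg[1]], " at row ",
                   neg[1], " (gene ", ids[neg[1]], "), column ", s))
    }
    out[[s]] <- v
  }
  out
}

#' Write an expression table as TSV
#'
#' Inverse of [read_expression_table()]: `read(write(x))` reproduces `x`
#' exactly (field-level equality).
#'
#' @param expr tibble with `gene_id` first column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  expr_to_matrix(expr)  # validates
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a BED-style interval table
#'
#' Parses BED5/BED6 text (columns chrom, start, end, name, score, and an
#' optional strand).  Coordinates are kept 0-based half-open; `start < end` is
#' enforced with the offending line number reported.  With
#' `schema = "peaks"` the score column becomes a normalized tag count column
#' named `tags` and a missing strand defaults to `"+"`.  With
#' `schema = "genes"` six columns are required, strand must be explicit, and
#' the TSS is derived from the strand (`start` for `+`, `end - 1` for `-`).
#'
#' @param path path to a headerless tab-separated BED file.
#' @param schema `"peaks"` (default) or `"genes"`.
#' @return for peaks, a tibble `chrom, start, end, peak_id, tags, strand`;
#'   for genes, a tibble
#'   `gene_id, chrom, tss, strand, gene_start, gene_end`.
#' @export
read_interval_table <- function(path, schema = c("peaks", "genes")) {
  schema <- match.arg(schema)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (schema == "genes") 6L else 5L
  bad <- which(nf < need)
  if (length(bad)) {
    abort(paste0("malformed line ", bad[1], ": expected at least ", need,
                 " tab-separated fields, found ", nf[bad[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  name <- col(4)
  score <- suppressWarnings(as.numeric(col(5)))
  badnum <- which(!is.finite(start) | !is.finite(end) | !is.finite(score))
  if (length(badnum)) {
    abort(paste0("malformed line ", badnum[1], ": non-numeric coordinate or score"))
  }
  badord <- which(start >= end)
  if (length(badord)) {
    abort(paste0("interval start >= end at line ", badord[1],
                 " (", chrom[badord[1]], ":", start[badord[1]], "-",
                 end[badord[1]], "); coordinates are 0-based half-open"))
  }
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, character(1), 6) else rep("+", length(lines))
  if (schema == "genes") {
    if (!all(strand %in% c("+", "-"))) {
      abort("gene annotation requires an explicit '+'/'-' strand in column 6")
    }
    if (anyDuplicated(name)) {
      abort(paste0("duplicate gene id(s): ",
                   paste(unique(name[duplicated(name)]), collapse = ", ")))
    }
    tibble(
      gene_id = name, chrom = chrom,
      tss = ifelse(strand == "+", start, end - 1),
      strand = strand, gene_start = start, gene_end = end
    )
  } else {
    if (!all(strand %in% c("+", "-", "."))) strand[!strand %in% c("+", "-", ".")] <- "+"
    strand[strand == "."] <- "+"
    if (anyDuplicated(name)) {
      abort(paste0("duplicate peak id(s): ",
                   paste(unique(name[duplicated(name)]), collapse = ", ")))
    }
    tibble(chrom = chrom, start = start, end = end,
           peak_id = name, tags = score, strand = strand)
  }
}

#' Write intervals as BED5/BED6
#'
#' Writes a peak table (or gene annotation) back to headerless BED text.
#' Writing, reading and rewriting is byte-identical.
#'
#' @param x a peak tibble (`chrom, start, end, peak_id, tags[, strand]`) or a
#'   gene annotation tibble (`gene_id, chrom, tss, strand, gene_start,
#'   gene_end`).
#' @param path output path.
#' @param strand write a sixth strand column (default `TRUE` when present).
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(x, path, strand = NULL) {
  if ("gene_id" %in% names(x)) {
    check_genes(x)
    df <- data.frame(x$chrom, fmt_num(x$gene_start), fmt_num(x$gene_end),
                     x$gene_id, fmt_num(rep(0, nrow(x))), x$strand)
  } else {
    check_peaks(x)
    has_strand <- "strand" %in% names(x)
    strand <- strand %||% has_strand
    df <- data.frame(x$chrom, fmt_num(x$start), fmt_num(x$end),
                     x$peak_id, fmt_num(x$tags))
    if (strand) df[[6]] <- if (has_strand) x$strand else "+"
  }
  lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

# Locale-independent numeric formatting (decimal point, no sci notation).
fmt_num <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, nsmall = 0,
                drop0trailing = TRUE, justify = "none")
  sub("\\.$", "", out)
}

#' Rescale raw tag counts to tags per ten million
#'
#' Peak tables are assumed to carry already depth-normalized tag counts; this
#' helper performs that normalization when only raw counts are available.
#'
#' @param counts numeric vector of raw tag counts.
#' @param library_size total mapped tags in the library.
#' @return counts rescaled to a ten-million-tag library.
#' @export
tags_per_ten_million <- function(counts, library_size) {
  if (library_size <= 0) abort("library_size must be positive")
  counts / library_size * 1e7
}

#' Write a JSON run manifest
#'
#' Records the parameters, seed and package version of an analysis step so a
#' run can be reproduced exactly.
#'
#' @param path output path.
#' @param step character label for the step.
#' @param parameters named list of parameters.
#' @param seed integer seed used (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, step, parameters = list(), seed = NULL) {
  manifest <- list(
    step = step,
    parameters = parameters,
    seed = seed,
    package = "actisig",
    version = as.character(utils::packageVersion("actisig"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
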