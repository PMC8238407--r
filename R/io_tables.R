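# Reading and writing the pipeline's tabular artifacts. The on-disk contract
# is fixed: UTF-8, tab-separated, one header line, "." decimal separator,
# reals rendered with 6 significant digits. Reports are written atomically
# (temp file + rename) so a failed run never leaves a partial artifact.

#' Construct a gene universe
#'
#' A gene universe is the declared reference gene set (for example, the
#' protein-coding genes of one chromosome) against which detection coverage
#' and missingness are computed. Identifiers are deduplicated preserving first
#' appearance.
#'
#' @param genes Character vector of gene identifiers. Treated as opaque,
#'   case-sensitive strings; no symbol-to-accession mapping is attempted.
#' @param label Free-text description, e.g. `"chr18 protein-coding"`.
#' @return A tibble of class `gene_universe` with one `gene_id` column and a
#'   `label` attribute.
#' @export
#' @examples
#' gene_universe(c("G1", "G2", "G3"), label = "toy")
gene_universe <- function(genes, label = "universe") {
  genes <- as.character(genes)
  if (length(genes) == 0L || any(is.na(genes)) || any(!nzchar(genes))) {
    txc_abort("gene universe identifiers must be non-empty strings.",
              "txc_validation_error")
  }
  out <- tibble(gene_id = unique(genes))
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("gene_universe", class(out))
  out
}

universe_genes <- function(universe) {
  if (inherits(universe, "gene_universe") || is.data.frame(universe)) {
    as.character(universe$gene_id)
  } else {
    as.character(universe)
  }
}

#' Read a per-platform expression table
#'
#' Reads a two-column tab-separated file (`gene_id`, `value`, one header
#' line) holding one platform x sample x batch worth of gene-level expression
#' values in the platform's native unit, and returns it as a long tibble
#' carrying its provenance columns, ready to be row-bound with other
#' platforms and piped into the concordance verbs.
#'
#' Genes absent from the file are simply absent from the table; at detection
#' time they are treated as measured-at-zero (see [detect_genes()]).
#'
#' @param path Path to the TSV file.
#' @param platform Platform tag: `"short_read"`, `"long_read"`, `"qpcr"` or
#'   `"other"`.
#' @param sample Sample label, e.g. `"HepG2"` or `"liver"`.
#' @param batch Batch / campaign label, e.g. `"2017"`.
#' @param unit Free-text unit of the values, e.g. `"RPKM"`.
#' @return A tibble with columns `gene_id`, `value`, `platform`, `sample`,
#'   `batch`, `unit`.
#' @export
read_expression_table <- function(path, platform,
                                  sample = "sample1",
                                  batch = "batch1",
                                  unit = "value") {
  platform <- match.arg(as.character(platform)[1],
                        c("short_read", "long_read", "qpcr", "other"))
  if (!file.exists(path)) {
    txc_abort(paste0("expression table not found: ", path), "txc_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) {
    txc_abort(paste0("empty expression table: ", path), "txc_parse_error")
  }
  rows <- lines[-1]
  lineno <- seq_along(rows) + 1L
  keep <- nzchar(trimws(rows))
  rows <- rows[keep]
  lineno <- lineno[keep]

  fields <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    txc_abort(sprintf("line %d: expected 2 tab-separated columns",
                      lineno[which(nf < 2L)[1]]),
              "txc_parse_error")
  }
  gene_id <- vapply(fields, `[[`, character(1), 1L)
  value_str <- vapply(fields, `[[`, character(1), 2L)
  value <- suppressWarnings(as.numeric(value_str))
  bad <- !is.finite(value)
  if (any(bad)) {
    txc_abort(sprintf("line %d: non-numeric expression value \"%s\"",
                      lineno[which(bad)[1]], value_str[which(bad)[1]]),
              "txc_parse_error")
  }
  if (any(value < 0)) {
    txc_abort(sprintf("line %d: negative expression value",
                      lineno[which(value < 0)[1]]),
              "txc_validation_error")
  }
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    txc_abort(paste0("duplicate gene identifier: ", dup),
              "txc_validation_error")
  }
  tibble(gene_id = gene_id, value = value,
         platform = platform, sample = as.character(sample)[1],
         batch = as.character(batch)[1], unit = as.character(unit)[1])
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: writes the `gene_id` and `value`
#' columns as a two-column TSV with a header line, reals rendered with 6
#' significant digits. Round-tripping reproduces the table to that precision.
#'
#' @param table An expression tibble (needs `gene_id` and `value` columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(is.data.frame(table), all(c("gene_id", "value") %in% names(table)))
  lines <- c("gene_id\tvalue",
             paste(table$gene_id, fmt6(table$value), sep = "\t"))
  write_lines_atomic(lines, path)
  invisible(path)
}

#' Read a gene universe from a list, BED or GFF3 file
#'
#' The format is auto-detected from the file extension (`.bed` -> BED,
#' `.gff`/`.gff3` -> GFF3, anything else -> one identifier per line) and can
#' be overridden with `format`. For BED the identifier is the name column
#' (column 4); for GFF3 it is the `gene_id` (or, failing that, `ID`)
#' attribute of features typed `gene`. Identifiers are deduplicated
#' preserving order.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"list"`, `"bed"` or `"gff3"`.
#' @param label Optional label; defaults to the file name.
#' @return A [gene_universe()] tibble.
#' @export
read_gene_universe <- function(path, format = c("auto", "list", "bed", "gff3"),
                               label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    txc_abort(paste0("gene universe file not found: ", path), "txc_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3", "list")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  genes <- switch(format,
    list = trimws(lines[!startsWith(lines, "#")]),
    bed = {
      rows <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
      fields <- strsplit(rows, "[\t ]+")
      nf <- lengths(fields)
      if (any(nf < 4L)) {
        txc_abort(sprintf(
          "BED line %d has %d columns; at least 4 (incl. name) required",
          which(nf < 4L)[1], min(nf)), "txc_parse_error")
      }
      vapply(fields, `[[`, character(1), 4L)
    },
    gff3 = {
      rows <- lines[!startsWith(lines, "#")]
      fields <- strsplit(rows, "\t", fixed = TRUE)
      fields <- fields[lengths(fields) >= 9L]
      fields <- fields[vapply(fields, `[[`, character(1), 3L) == "gene"]
      vapply(fields, function(f) {
        attrs <- f[[9]]
        m <- regmatches(attrs, regexec("(?:^|;)\\s*gene_id=([^;]+)", attrs))[[1]]
        if (length(m) < 2) {
          m <- regmatches(attrs, regexec("(?:^|;)\\s*ID=([^;]+)", attrs))[[1]]
        }
        if (length(m) < 2) {
          txc_abort(paste0("GFF3 gene feature without gene_id/ID attribute: ",
                           attrs), "txc_parse_error")
        }
        m[[2]]
      }, character(1))
    }
  )
  if (length(genes) == 0L) {
    txc_abort(paste0("no gene identifiers found in ", path),
              "txc_validation_error")
  }
  gene_universe(genes, label = label %||% basename(path))
}

write_lines_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    txc_abort(paste0("cannot write ", path), "txc_io_error")
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt6(col) else as.character(col)
  })
  body <- if (nrow(df) == 0L) character(0) else do.call(paste, c(cols, sep = "\t"))
  write_lines_atomic(c(paste(names(df), collapse = "\t"), body), path)
}

#' Write a concordance report to disk
#'
#' Emits three artifacts into `dir`: `report.json` (machine-readable, keys
#' sorted, reals at 6 significant digits), `cutoff_summary.tsv` (one row per
#' cutoff, the [tidy()] view) and `gene_tiers.tsv` (long per-gene reliability
#' tier table over the universe, tier 0 = undetected). Output is
#' byte-identical across runs given identical input; files are written to a
#' temporary name and renamed so failures leave no partial artifacts.
#'
#' @param report A `concordance_report` from [sweep_concordance()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "concordance_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) txc_abort(paste0("cannot create directory ", dir), "txc_io_error")
  }
  paths <- c(json = file.path(dir, "report.json"),
             summary = file.path(dir, "cutoff_summary.tsv"),
             tiers = file.path(dir, "gene_tiers.tsv"))

  write_lines_atomic(report_json_lines(report), paths[["json"]])
  write_tsv_atomic(tidy(report), paths[["summary"]])
  write_tsv_atomic(gene_tier_table(report), paths[["tiers"]])
  invisible(paths)
}

# Long per-gene tier table over the whole universe (tier 0 = undetected).
gene_tier_table <- function(report) {
  uni <- universe_genes(report$universe)
  purrr::map_dfr(report$cutoffs, function(co) {
    entry <- report$per_cutoff[[cutoff_key(co)]]
    tier <- setNames(rep(0L, length(uni)), uni)
    tier[entry$tiers$gene_id] <- entry$tiers$tier
    tibble(gene_id = uni, cutoff = rep(co, length(uni)),
           tier = as.integer(tier))
  })
}

cutoff_key <- function(cutoff) fmt6(cutoff)

report_json_lines <- function(report) {
  per_cutoff <- lapply(report$per_cutoff, function(e) {
    tan <- e$tanimoto
    list(
      common_all = e$common_all,
      coverage = signif(e$coverage, 6),
      platform_unique = {
        u <- split(e$unique$gene_id, factor(e$unique$set_id,
                                            levels = sort(report$set_info$set_id)))
        lapply(u, I)
      },
      set_counts = as.list(setNames(e$set_counts$n_detected,
                                    e$set_counts$set_id))[
                                      order(e$set_counts$set_id)],
      tanimoto = purrr::pmap(
        list(tan$set_a, tan$set_b, tan$tanimoto, as.character(tan$band),
             tan$degenerate),
        function(a, b, v, band, deg) {
          list(band = band, degenerate = deg, set_a = a, set_b = b,
               value = signif(v, 6))
        }),
      tier_counts = as.list(setNames(e$tier_counts$n,
                                     as.character(e$tier_counts$tier))),
      undetected = I(e$undetected),
      union_size = e$union_size,
      venn = if (is.null(e$venn)) structure(list(), names = character(0))
             else as.list(setNames(e$venn$n_genes, e$venn$region))
    )
  })
  set_info <- report$set_info[order(report$set_info$set_id), ]
  doc <- list(
    comparator = report$comparator,
    cutoffs = per_cutoff,
    sets = purrr::pmap(
      set_info[c("set_id", "platform", "sample", "batch", "unit")],
      function(set_id, platform, sample, batch, unit) {
        list(batch = batch, platform = platform, sample = sample,
             set_id = set_id, unit = unit)
      }),
    universe = list(label = attr(report$universe, "label") %||% "universe",
                    size = length(universe_genes(report$universe)))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  strsplit(as.character(json), "\n", fixed = TRUE)[[1]]
}
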