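# Detection calls: thresholding expression values against a cutoff in each
# platform's native unit. The comparator is explicit because ">" and ">=" give
# different calls exactly at the cutoff, and both semantics are in use.

set_label <- function(platform, sample, batch) {
  paste(platform, sample, batch, sep = ":")
}

# Split a long expression tibble into provenance groups; returns a tibble of
# (set_id, platform, sample, batch, unit) plus a list-column of value
# mappings.
expression_groups <- function(tables) {
  stopifnot(is.data.frame(tables))
  need <- c("gene_id", "value", "platform", "sample", "batch")
  missing <- setdiff(need, names(tables))
  if (length(missing) > 0L) {
    txc_abort(paste0("expression table lacks column(s): ",
                     paste(missing, collapse = ", ")), "txc_validation_error")
  }
  if (!"unit" %in% names(tables)) tables$unit <- "value"
  if (any(!is.finite(tables$value)) || any(tables$value < 0)) {
    txc_abort("expression values must be finite and >= 0.",
              "txc_validation_error")
  }
  grp <- dplyr::distinct(tables, .data$platform, .data$sample, .data$batch,
                         .data$unit)
  grp$set_id <- set_label(grp$platform, grp$sample, grp$batch)
  if (anyDuplicated(grp$set_id)) {
    txc_abort("duplicate (platform, sample, batch) provenance in input tables.",
              "txc_validation_error")
  }
  grp$values <- purrr::pmap(grp[c("platform", "sample", "batch")],
    function(platform, sample, batch) {
      rows <- tables[tables$platform == platform & tables$sample == sample &
                       tables$batch == batch, ]
      if (anyDuplicated(rows$gene_id)) {
        txc_abort(paste0("duplicate gene identifier in table ",
                         set_label(platform, sample, batch)),
                  "txc_validation_error")
      }
      setNames(rows$value, rows$gene_id)
    })
  grp
}

#' Call detected genes at a cutoff
#'
#' Applies one detection threshold to every platform x sample x batch group
#' in a long expression tibble. A gene is called detected when its value
#' satisfies `value > cutoff` (comparator `"strictly_greater"`, the default)
#' or `value >= cutoff` (`"greater_or_equal"`). When a gene universe is
#' supplied, genes absent from a table are treated as measured-at-zero and
#' calls are restricted to universe genes. Cutoff comparison is exact — no
#' epsilon is applied.
#'
#' @param tables Long expression tibble (columns `gene_id`, `value`,
#'   `platform`, `sample`, `batch`, optionally `unit`), e.g. several
#'   [read_expression_table()] results bound together.
#' @param cutoff Single non-negative detection threshold, in each platform's
#'   native unit (no cross-platform normalization is applied).
#' @param comparator `"strictly_greater"` or `"greater_or_equal"`.
#' @param universe Optional [gene_universe()] (or character vector).
#' @return A tibble of detection calls: one row per detected gene with
#'   columns `set_id`, `platform`, `sample`, `batch`, `cutoff`, `comparator`,
#'   `gene_id`.
#' @export
#' @examples
#' tab <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
#'                       value = c(0, 0.05, 2),
#'                       platform = "short_read", sample = "HepG2",
#'                       batch = "b1", unit = "RPKM")
#' detect_genes(tab, cutoff = 0)$gene_id
#' detect_genes(tab, cutoff = 0.1)$gene_id
detect_genes <- function(tables, cutoff, comparator = "strictly_greater",
                         universe = NULL) {
  if (!is_scalar_number(cutoff) || cutoff < 0) {
    txc_abort("`cutoff` must be a single non-negative number.",
              "txc_validation_error")
  }
  assert_comparator(comparator)
  grp <- expression_groups(tables)
  uni <- if (!is.null(universe)) universe_genes(universe)

  purrr::pmap_dfr(
    grp[c("set_id", "platform", "sample", "batch", "values")],
    function(set_id, platform, sample, batch, values) {
      if (!is.null(uni)) {
        v <- setNames(rep(0, length(uni)), uni)
        present <- intersect(names(values), uni)
        v[present] <- values[present]
        values <- v
      }
      hit <- if (comparator == "strictly_greater") values > cutoff
             else values >= cutoff
      genes <- names(values)[hit]
      tibble(set_id = set_id, platform = platform, sample = sample,
             batch = batch, cutoff = cutoff, comparator = comparator,
             gene_id = genes)
    })
}

# Coerce detection calls (tibble with set_id/gene_id, or a named list of
# character vectors) to a named list of gene-id sets, order of first
# appearance preserved.
as_detection_sets <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("set_id", "gene_id") %in% names(x))) {
      txc_abort("detection tibble needs `set_id` and `gene_id` columns.",
                "txc_validation_error")
    }
    if ("cutoff" %in% names(x) && length(unique(x$cutoff)) > 1L) {
      txc_abort("detection calls mix several cutoffs; filter to one first.",
                "txc_validation_error")
    }
    sets <- split(x$gene_id, factor(x$set_id, levels = unique(x$set_id)))
    lapply(sets, unique)
  } else if (is.list(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
      txc_abort("detection sets must be uniquely named.",
                "txc_validation_error")
    }
    lapply(x, function(g) unique(as.character(g)))
  } else {
    txc_abort("cannot interpret input as detection sets.",
              "txc_validation_error")
  }
}
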