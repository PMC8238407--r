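# Cutoff-ladder sweep: the full concordance computation at every cutoff,
# assembled into a single report object, plus replicate-batch concordance.

#' Run the full concordance analysis over a cutoff ladder
#'
#' For each cutoff in the ladder this builds per-platform detection sets,
#' then the exclusive Venn partition, the pairwise Tanimoto matrix with
#' similarity bands, reliability tier counts, platform-unique gene lists,
#' the undetected gene list and the universe coverage, and assembles
#' everything into a `concordance_report`.
#'
#' Detection set sizes, union size and coverage are non-increasing in the
#' cutoff (raising the threshold can only drop calls).
#'
#' @inheritParams detect_genes
#' @param universe A [gene_universe()] (or character vector); required, since
#'   coverage and missingness are computed against it.
#' @param cutoffs Strictly increasing non-negative ladder; defaults to
#'   [default_cutoffs()].
#' @return A `concordance_report`: see [tidy.concordance_report()],
#'   [glance.concordance_report()], [write_report()] and
#'   [autoplot.concordance_report()] for its views.
#' @export
#' @examples
#' tabs <- dplyr::bind_rows(
#'   tibble::tibble(gene_id = c("G1", "G2", "G3"), value = c(2, 0.5, 0),
#'                  platform = "short_read", sample = "s", batch = "b",
#'                  unit = "RPKM"),
#'   tibble::tibble(gene_id = c("G1", "G2", "G3"), value = c(1.5, 0, 0.2),
#'                  platform = "long_read", sample = "s", batch = "b",
#'                  unit = "norm_count"))
#' rep <- sweep_concordance(tabs, gene_universe(c("G1", "G2", "G3", "G4")))
#' tidy(rep)
sweep_concordance <- function(tables, universe,
                              cutoffs = default_cutoffs(),
                              comparator = "strictly_greater") {
  cutoffs <- assert_cutoffs(cutoffs)
  assert_comparator(comparator)
  uni <- universe_genes(universe)
  grp <- expression_groups(tables)
  if (nrow(grp) < 2L) {
    txc_abort("at least two tables with distinct provenance are required.",
              "txc_validation_error")
  }

  per_cutoff <- lapply(cutoffs, function(co) {
    det <- detect_genes(tables, cutoff = co, comparator = comparator,
                        universe = universe)
    sets <- lapply(setNames(grp$set_id, grp$set_id), function(id) {
      unique(det$gene_id[det$set_id == id])
    })
    venn <- if (length(sets) <= 4L) venn_partition(sets) else NULL
    tiers <- reliability_tiers(sets)
    tier_counts <- tibble(
      tier = seq_along(sets),
      n = vapply(seq_along(sets), function(k) sum(tiers$tier == k),
                 integer(1))
    )
    union_genes <- unique(unlist(sets, use.names = FALSE))
    list(
      cutoff = co,
      set_counts = tibble(set_id = grp$set_id,
                          n_detected = lengths(sets)[grp$set_id]),
      venn = venn,
      tanimoto = tanimoto_pairs(sets),
      tiers = tiers,
      tier_counts = tier_counts,
      unique = platform_unique(sets),
      undetected = undetected_genes(sets, universe)$gene_id,
      union_size = length(union_genes),
      common_all = sum(tiers$tier == length(sets)),
      coverage = coverage(sets, universe)
    )
  })
  names(per_cutoff) <- vapply(cutoffs, cutoff_key, character(1))

  structure(
    list(cutoffs = cutoffs, comparator = comparator,
         universe = if (inherits(universe, "gene_universe")) universe
                    else gene_universe(uni),
         set_info = grp[c("set_id", "platform", "sample", "batch", "unit")],
         per_cutoff = per_cutoff),
    class = "concordance_report"
  )
}

#' Concordance between two replicate campaigns
#'
#' Compares the same platform and sample measured in two batches (for
#' example, two sequencing campaigns years apart) by the Tanimoto index of
#' their detection sets at each cutoff of the ladder. Thresholding at 0 is
#' scale-invariant, so pure rescaling between batches leaves the cutoff-0
#' Tanimoto at 1; abundance-dependent drift and independent noise lower it
#' increasingly at higher cutoffs.
#'
#' @param a,b Expression tibbles for the two batches: same platform and
#'   sample, different batch labels.
#' @inheritParams sweep_concordance
#' @param universe Optional [gene_universe()] restricting the calls.
#' @return A tibble of class `replicate_concordance` with columns `cutoff`,
#'   `n_a`, `n_b`, `n_common`, `tanimoto`, `band`, `degenerate`.
#' @export
replicate_concordance <- function(a, b, cutoffs = default_cutoffs(),
                                  comparator = "strictly_greater",
                                  universe = NULL) {
  cutoffs <- assert_cutoffs(cutoffs)
  assert_comparator(comparator)
  ga <- expression_groups(a)
  gb <- expression_groups(b)
  if (nrow(ga) != 1L || nrow(gb) != 1L) {
    txc_abort("each replicate input must hold exactly one table.",
              "txc_validation_error")
  }
  if (ga$platform != gb$platform || ga$sample != gb$sample) {
    txc_abort("replicate tables must share platform and sample.",
              "txc_validation_error")
  }
  if (ga$batch == gb$batch) {
    txc_abort("replicate tables must come from different batches.",
              "txc_validation_error")
  }
  out <- purrr::map_dfr(cutoffs, function(co) {
    da <- detect_genes(a, co, comparator, universe)$gene_id
    db <- detect_genes(b, co, comparator, universe)$gene_id
    n_common <- length(intersect(da, db))
    t <- tanimoto(da, db)
    tibble(cutoff = co, n_a = length(da), n_b = length(db),
           n_common = n_common, tanimoto = t,
           band = classify_similarity(t),
           degenerate = length(da) == 0L && length(db) == 0L)
  })
  class(out) <- c("replicate_concordance", class(out))
  out
}

#' @describeIn sweep_concordance Per-cutoff summary: one row per cutoff with
#'   union size, all-platform intersection, coverage, tier counts, number of
#'   undetected universe genes and the min/mean pairwise Tanimoto.
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) {
  purrr::map_dfr(x$per_cutoff, function(e) {
    row <- tibble(
      cutoff = e$cutoff,
      union_size = e$union_size,
      common_all = e$common_all,
      coverage = e$coverage,
      n_undetected = length(e$undetected),
      min_tanimoto = min(e$tanimoto$tanimoto),
      mean_tanimoto = mean(e$tanimoto$tanimoto)
    )
    tiers <- setNames(as.list(e$tier_counts$n),
                      paste0("n_tier", e$tier_counts$tier))
    dplyr::bind_cols(row, tibble::as_tibble(tiers))
  })
}

#' @describeIn sweep_concordance One-row overview of the whole sweep.
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  s <- tidy(x)
  tibble(
    n_sets = nrow(x$set_info),
    n_cutoffs = length(x$cutoffs),
    universe_size = nrow(x$universe),
    max_coverage = max(s$coverage),
    best_cutoff = s$cutoff[which.max(s$coverage)],
    n_never_detected = length(x$per_cutoff[[cutoff_key(min(x$cutoffs))]]$undetected)
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d detection sets, universe of %d genes\n",
    nrow(x$set_info), nrow(x$universe)))
  cat("sets:", paste(x$set_info$set_id, collapse = ", "), "\n")
  cat(sprintf("comparator: %s\n\n", x$comparator))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  invisible(x)
}
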