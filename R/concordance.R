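# Set-level concordance statistics: Tanimoto similarity with interpretation
# bands, exclusive Venn regions, reliability tiers, platform-unique and
# undetected accounting, and universe coverage.

#' Tanimoto (Jaccard) similarity between two gene sets
#'
#' Computes `|A n B| / (|A| + |B| - |A n B|)`, i.e. intersection over union —
#' the Tanimoto index, identical to the Jaccard index for binary sets. It is
#' symmetric, 1 for identical non-empty sets and 0 for disjoint non-empty
#' sets. When both sets are empty the value is 1 by convention (two
#' platforms that both detect nothing agree perfectly); callers that need to
#' know the value is conventional should use [tanimoto_pairs()], which flags
#' it.
#'
#' @param a,b Character vectors of gene identifiers (duplicates ignored), or
#'   detection tibbles from [detect_genes()] whose `gene_id` column is used.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' tanimoto(c("G1", "G2", "G3"), c("G2", "G3", "G4")) # 2/4 = 0.5
tanimoto <- function(a, b) {
  if (is.data.frame(a)) a <- a$gene_id
  if (is.data.frame(b)) b <- b$gene_id
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  n_common <- length(intersect(a, b))
  denom <- length(a) + length(b) - n_common
  if (denom == 0L) 1.0 else n_common / denom
}

similarity_bands <- c("identical", "weaker", "considerably_different")

#' Interpret a Tanimoto index as a similarity band
#'
#' Maps a Tanimoto value onto the conventional interpretation bands used for
#' comparing transcript sets: `identical` for values in \[0.7, 1\], `weaker`
#' for values in (0.55, 0.7), and `considerably_different` for values of
#' 0.55 and below. The customary verbal bands overlap (1.0–0.7
#' "identical" vs 0.75–0.55 "much weaker"); this function resolves them as
#' the half-open intervals above, honoring the explicit rule that 0.55 and
#' below means the sets differ considerably.
#'
#' @param t Numeric vector of Tanimoto values in \[0, 1\].
#' @return A factor with levels `identical`, `weaker`,
#'   `considerably_different`.
#' @export
#' @examples
#' classify_similarity(c(1, 0.69, 0.55, 0.51))
classify_similarity <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0 | t > 1)) {
    txc_abort("Tanimoto values must lie in [0, 1].", "txc_domain_error")
  }
  band <- ifelse(t >= 0.7, "identical",
                 ifelse(t > 0.55, "weaker", "considerably_different"))
  factor(band, levels = similarity_bands)
}

#' Pairwise Tanimoto matrix over detection sets
#'
#' Computes the Tanimoto index, its similarity band, and set sizes for every
#' unordered pair of detection sets. `degenerate` marks pairs where both
#' sets are empty, whose Tanimoto of 1 is conventional.
#'
#' @param detections Detection calls: a tibble from [detect_genes()] (one
#'   cutoff) or a named list of gene-id character vectors.
#' @return A tibble with columns `set_a`, `set_b`, `n_a`, `n_b`, `n_common`,
#'   `tanimoto`, `band`, `degenerate`.
#' @export
tanimoto_pairs <- function(detections) {
  sets <- as_detection_sets(detections)
  if (length(sets) < 2L) {
    txc_abort("at least two detection sets are required.",
              "txc_validation_error")
  }
  nm <- names(sets)
  idx <- utils::combn(length(sets), 2L)
  purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    n_common <- length(intersect(sets[[i1]], sets[[i2]]))
    t <- tanimoto(sets[[i1]], sets[[i2]])
    tibble(set_a = nm[i1], set_b = nm[i2],
           n_a = length(sets[[i1]]), n_b = length(sets[[i2]]),
           n_common = n_common, tanimoto = t,
           band = classify_similarity(t),
           degenerate = length(sets[[i1]]) == 0L && length(sets[[i2]]) == 0L)
  })
}

venn_region_grid <- function(set_names) {
  k <- length(set_names)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(grid) <- set_names
  # order by subset size, then by set order within size
  grid[order(rowSums(grid), apply(!grid, 1, paste, collapse = "")), ,
       drop = FALSE]
}

#' Exclusive Venn partition of 2-4 detection sets
#'
#' Assigns every gene in the union of the input sets to exactly one of the
#' `2^k - 1` exclusive regions (detected by exactly that subset of sets).
#' All regions are reported, including empty ones, so region counts always
#' sum to the union size.
#'
#' @inheritParams tanimoto_pairs
#' @return A tibble of class `venn_partition` with columns `region`
#'   (e.g. `"A&B"`), `degree` (subset size), `n_genes` and a `genes`
#'   list-column, plus attributes `union_size`, `common_all` and
#'   `set_names`.
#' @export
#' @examples
#' venn_partition(list(A = c("G1", "G2"), B = c("G2", "G3")))
venn_partition <- function(detections) {
  sets <- as_detection_sets(detections)
  if (length(sets) < 2L || length(sets) > 4L) {
    txc_abort("venn_partition() takes 2 to 4 detection sets.",
              "txc_validation_error")
  }
  nm <- names(sets)
  union_genes <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  member <- matrix(member, nrow = length(union_genes), ncol = length(sets),
                   dimnames = list(union_genes, nm))
  key <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))

  grid <- venn_region_grid(nm)
  regions <- unname(apply(grid, 1, function(row) paste(nm[as.logical(row)],
                                                       collapse = "&")))
  out <- tibble(
    region = regions,
    degree = as.integer(rowSums(grid)),
    genes = lapply(regions, function(r) union_genes[key == r])
  )
  out$n_genes <- lengths(out$genes)
  out <- out[c("region", "degree", "n_genes", "genes")]
  attr(out, "union_size") <- length(union_genes)
  attr(out, "common_all") <- unname(out$n_genes[out$degree == length(sets)])
  attr(out, "set_names") <- nm
  class(out) <- c("venn_partition", class(out))
  out
}

#' Reliability tiers: number of platforms detecting each gene
#'
#' The detection of a transcript is treated as the more reliable the more
#' independent technologies registered it. This returns, for every gene in
#' the union of the input sets, its tier: the count of sets containing it.
#' Genes detected by no set are absent from the result.
#'
#' @inheritParams tanimoto_pairs
#' @return A tibble with columns `gene_id` and `tier`, sorted by `gene_id`.
#' @export
reliability_tiers <- function(detections) {
  sets <- as_detection_sets(detections)
  if (length(sets) < 2L) {
    txc_abort("at least two detection sets are required.",
              "txc_validation_error")
  }
  counts <- table(unlist(sets, use.names = FALSE))
  out <- tibble(gene_id = as.character(names(counts)) %||% character(0),
                tier = as.integer(counts))
  if (nrow(out) > 0L) out <- out[order(out$gene_id), ]
  out
}

#' Genes detected by exactly one platform
#'
#' Platform-unique genes — candidate false positives — are the genes detected
#' by one input set and no other; they coincide with the singleton regions of
#' the Venn partition.
#'
#' @inheritParams tanimoto_pairs
#' @return A tibble with columns `set_id` and `gene_id` (zero rows when no
#'   gene is unique to a set).
#' @export
platform_unique <- function(detections) {
  sets <- as_detection_sets(detections)
  if (length(sets) < 2L) {
    txc_abort("at least two detection sets are required.",
              "txc_validation_error")
  }
  tiers <- reliability_tiers(sets)
  singles <- tiers$gene_id[tiers$tier == 1L]
  purrr::map_dfr(names(sets), function(nm) {
    g <- intersect(sets[[nm]], singles)
    tibble(set_id = rep(nm, length(g)), gene_id = g)
  })
}

#' Universe genes not detected by any platform
#'
#' @inheritParams tanimoto_pairs
#' @param universe A [gene_universe()] (or character vector).
#' @return A tibble with one `gene_id` column, in universe order.
#' @export
undetected_genes <- function(detections, universe) {
  sets <- as_detection_sets(detections)
  uni <- universe_genes(universe)
  detected <- unique(unlist(sets, use.names = FALSE))
  tibble(gene_id = uni[!uni %in% detected])
}

#' Fraction of the gene universe detected by at least one platform
#'
#' @inheritParams undetected_genes
#' @return A number in \[0, 1\]: `|union of sets ∩ universe| / |universe|`.
#' @export
coverage <- function(detections, universe) {
  sets <- as_detection_sets(detections)
  uni <- universe_genes(universe)
  if (length(uni) == 0L) {
    txc_abort("gene universe is empty.", "txc_domain_error")
  }
  detected <- unique(unlist(sets, use.names = FALSE))
  sum(uni %in% detected) / length(uni)
}
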