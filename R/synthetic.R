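# Ground-truthed synthetic multi-platform expression data.
#
# The generator produces the statistical structure the concordance analysis
# presumes rather than a read-level simulation: a mostly-expressed gene
# universe with a small silent class, heavy-tailed (log-normal) true
# abundances, platform observation with abundance-dependent dropout and
# multiplicative log-normal noise, rare sub-cutoff false-positive signal on
# silent genes, and abundance-dependent decay between two replicate
# campaigns. Every draw is partitioned into a (seed, platform, batch) stream
# so adding a platform or batch never perturbs another's values.

#' Truth model for the synthetic gene universe
#'
#' @param n_genes Number of genes in the universe (default 275, the size of
#'   a single-chromosome protein-coding gene set).
#' @param silent_fraction Probability that a gene is silent (true abundance
#'   0). The default 2/275 mirrors a universe in which two genes are never
#'   expressed.
#' @param meanlog,sdlog Log-normal parameters of the true abundance
#'   `lambda` (arbitrary copies) of expressed genes.
#' @param seed Integer seed for [generate_truth()].
#' @return A list of class `truth_model`.
#' @export
truth_model <- function(n_genes = 275, silent_fraction = 2 / 275,
                        meanlog = 1.0, sdlog = 2.0, seed = 1L) {
  if (!is_scalar_number(n_genes) || n_genes < 1) {
    txc_abort("`n_genes` must be a positive count.", "txc_domain_error")
  }
  if (!is_scalar_number(silent_fraction) || silent_fraction < 0 ||
      silent_fraction > 1) {
    txc_abort("`silent_fraction` must lie in [0, 1].", "txc_domain_error")
  }
  if (!is_scalar_number(sdlog) || sdlog <= 0) {
    txc_abort("`sdlog` must be positive.", "txc_domain_error")
  }
  structure(list(n_genes = as.integer(n_genes),
                 silent_fraction = silent_fraction,
                 meanlog = meanlog, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "truth_model")
}

#' Platform observation model
#'
#' Describes how one technology turns a true abundance `lambda` into an
#' observed signal: a multiplicative efficiency, log-normal measurement
#' noise, an abundance-dependent dropout probability
#' `d0 * exp(-lambda / lambda0)` (monotone decreasing in `lambda`), and a
#' small false-positive probability that a silent gene yields a spurious
#' signal drawn uniformly from `(0, fp_max]` — i.e. below the first non-zero
#' rung of the default cutoff ladder, where threshold noise concentrates.
#'
#' @param platform `"short_read"`, `"long_read"`, `"qpcr"` or `"other"`.
#' @param efficiency Positive scale mapping `lambda` to expected signal.
#' @param noise_sd_log SD of the measurement noise on the log scale.
#' @param dropout_d0,dropout_lambda0 Dropout parameters `d0` and `lambda0`.
#' @param false_positive_rate Probability a silent gene yields signal; the
#'   default is 0.01 for `long_read` (whose higher per-base error rate makes
#'   spurious gene-level signal more likely) and 0.001 otherwise.
#' @param fp_max Upper bound of the spurious signal magnitude.
#' @param unit Unit label recorded on generated tables; defaults to a
#'   platform-typical unit.
#' @return A list of class `platform_model`.
#' @export
platform_model <- function(platform = c("short_read", "long_read", "qpcr",
                                        "other"),
                           efficiency = 1.0, noise_sd_log = 0.3,
                           dropout_d0 = 0.5, dropout_lambda0 = 1.0,
                           false_positive_rate = NULL, fp_max = 0.1,
                           unit = NULL) {
  platform <- match.arg(platform)
  if (!is_scalar_number(efficiency) || efficiency <= 0) {
    txc_abort("`efficiency` must be positive.", "txc_domain_error")
  }
  if (!is_scalar_number(noise_sd_log) || noise_sd_log < 0) {
    txc_abort("`noise_sd_log` must be >= 0.", "txc_domain_error")
  }
  if (!is_scalar_number(dropout_d0) || dropout_d0 < 0 || dropout_d0 > 1) {
    txc_abort("`dropout_d0` must lie in [0, 1].", "txc_domain_error")
  }
  if (!is_scalar_number(dropout_lambda0) || dropout_lambda0 <= 0) {
    txc_abort("`dropout_lambda0` must be positive.", "txc_domain_error")
  }
  fp <- false_positive_rate %||%
    if (platform == "long_read") 0.01 else 0.001
  if (!is_scalar_number(fp) || fp < 0 || fp > 1) {
    txc_abort("`false_positive_rate` must lie in [0, 1].", "txc_domain_error")
  }
  unit <- unit %||% switch(platform,
                           short_read = "RPKM", long_read = "norm_count",
                           qpcr = "abundance_score", other = "value")
  structure(list(platform = platform, efficiency = efficiency,
                 noise_sd_log = noise_sd_log, dropout_d0 = dropout_d0,
                 dropout_lambda0 = dropout_lambda0,
                 false_positive_rate = fp, fp_max = fp_max, unit = unit),
            class = "platform_model")
}

#' The default three-platform panel
#'
#' Short-read sequencing, long-read sequencing and a qPCR panel with the
#' default observation parameters of [platform_model()]. The platform
#' sensitivities are deliberately generic placeholders, not estimates of any
#' real instrument.
#'
#' @return A named list of three [platform_model()] objects.
#' @export
default_platform_models <- function() {
  list(short_read = platform_model("short_read"),
       long_read = platform_model("long_read"),
       qpcr = platform_model("qpcr"))
}

#' Batch drift model
#'
#' Systematic change between two measurement campaigns of the same sample,
#' modeled as abundance-dependent signal decay: the drifted batch is scaled
#' by `exp(-decay_rate * q_g)` where `q_g` is the rank quantile of the
#' gene's true abundance among expressed genes — so the most abundant
#' transcripts decay the most — plus extra independent log-normal noise.
#' Silent genes stay silent under drift.
#'
#' @param decay_rate Positive decay constant `kappa`.
#' @param extra_noise_sd_log SD of the extra batch noise on the log scale.
#' @return A list of class `batch_drift`.
#' @export
batch_drift <- function(decay_rate = 0.2, extra_noise_sd_log = 0.1) {
  if (!is_scalar_number(decay_rate) || decay_rate < 0) {
    txc_abort("`decay_rate` must be >= 0.", "txc_domain_error")
  }
  if (!is_scalar_number(extra_noise_sd_log) || extra_noise_sd_log < 0) {
    txc_abort("`extra_noise_sd_log` must be >= 0.", "txc_domain_error")
  }
  structure(list(decay_rate = decay_rate,
                 extra_noise_sd_log = extra_noise_sd_log),
            class = "batch_drift")
}

#' Draw per-gene ground truth
#'
#' Generates gene identifiers `G0001...`, flags each gene silent with
#' probability `silent_fraction`, and draws true abundances `lambda` from
#' the model's log-normal for expressed genes (silent genes have
#' `lambda = 0`). Deterministic under the model seed; the caller's RNG state
#' is left untouched.
#'
#' @param model A [truth_model()].
#' @param seed Optional seed overriding `model$seed`.
#' @return A tibble of class `synthetic_truth` with columns `gene_id`,
#'   `lambda`, `expressed`, and the model stored in the `model` attribute.
#' @export
generate_truth <- function(model = truth_model(), seed = NULL) {
  stopifnot(inherits(model, "truth_model"))
  seed <- as.integer(seed %||% model$seed)
  n <- model$n_genes
  out <- with_stream(stream_seed(seed, "truth"), {
    silent <- runif(n) < model$silent_fraction
    lambda <- rep(0, n)
    lambda[!silent] <- rlnorm(sum(!silent), model$meanlog, model$sdlog)
    tibble(gene_id = sprintf("G%04d", seq_len(n)),
           lambda = lambda, expressed = !silent)
  })
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  class(out) <- c("synthetic_truth", class(out))
  out
}

dropout_prob <- function(lambda, pm) {
  pm$dropout_d0 * exp(-lambda / pm$dropout_lambda0)
}

#' Observe a truth table through one platform
#'
#' Realizes one expression table: an expressed gene drops out with
#' probability `d0 * exp(-lambda / lambda0)`, otherwise its observed value
#' is `efficiency * lambda * exp(N(0, noise_sd_log))`, times the drift
#' factor when a [batch_drift()] is supplied; a silent gene yields a
#' spurious value uniform on `(0, fp_max]` with probability
#' `false_positive_rate` and 0 otherwise. Deterministic under
#' `(seed, platform, batch)`; the random stream is keyed on those tags so
#' observing other platforms or batches never changes this table.
#'
#' @param truth A [generate_truth()] tibble.
#' @param pm A [platform_model()].
#' @param seed Integer seed shared by the whole dataset.
#' @param sample,batch Provenance labels for the generated table.
#' @param drift Optional [batch_drift()]; when supplied this batch is the
#'   drifted (later) campaign.
#' @return An expression tibble as from [read_expression_table()].
#' @export
observe_platform <- function(truth, pm, seed = 1L, sample = "sim",
                             batch = "b1", drift = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(pm, "platform_model"))
  n <- nrow(truth)
  lambda <- truth$lambda
  expressed <- truth$expressed

  with_stream(stream_seed(seed, "observe", pm$platform, batch), {
    # fixed draw order per gene, drawn unconditionally, so toggling one
    # model component never shifts the draws of another
    u_drop <- runif(n)
    z_noise <- rnorm(n)
    u_fp <- runif(n)
    u_fp_mag <- runif(n)
    z_drift <- rnorm(n)

    value <- rep(0, n)
    kept <- expressed & u_drop >= dropout_prob(lambda, pm)
    value[kept] <- pm$efficiency * lambda[kept] *
      exp(pm$noise_sd_log * z_noise[kept])

    if (!is.null(drift)) {
      stopifnot(inherits(drift, "batch_drift"))
      q <- rep(0, n)
      q[expressed] <- rank(lambda[expressed], ties.method = "first") /
        sum(expressed)
      value[kept] <- value[kept] * exp(-drift$decay_rate * q[kept]) *
        exp(drift$extra_noise_sd_log * z_drift[kept])
    }

    fp <- !expressed & u_fp < pm$false_positive_rate
    value[fp] <- pm$fp_max * (1 - u_fp_mag[fp])  # uniform on (0, fp_max]

    tibble(gene_id = truth$gene_id, value = value,
           platform = pm$platform, sample = as.character(sample)[1],
           batch = as.character(batch)[1], unit = pm$unit)
  })
}

#' Generate a complete labeled multi-platform dataset
#'
#' Draws one ground truth and observes it through every platform model —
#' and, when a [batch_drift()] is supplied, through a second drifted batch
#' per platform — returning the bound expression tables together with the
#' truth labels and all generating parameters. Byte-identical under the same
#' seed and parameters.
#'
#' @param truth A [truth_model()].
#' @param platforms List of [platform_model()]s (at least two).
#' @param drift Optional [batch_drift()]; adds a second, drifted batch.
#' @param seed Integer seed for the whole dataset.
#' @param sample Sample label.
#' @param batches Labels of the two campaigns; the second is the drifted one.
#' @return A list of class `synthetic_dataset` with elements `tables` (long
#'   expression tibble), `truth`, `universe` ([gene_universe()]), `params`
#'   and `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(seed = 1)
#' dplyr::count(ds$tables, platform)
generate_dataset <- function(truth = truth_model(),
                             platforms = default_platform_models(),
                             drift = NULL, seed = 1L, sample = "HepG2",
                             batches = c("b1", "b2")) {
  if (length(platforms) < 2L) {
    txc_abort("at least two platform models are required.",
              "txc_validation_error")
  }
  tr <- generate_truth(truth, seed = seed)
  tables <- purrr::map_dfr(platforms, function(pm) {
    first <- observe_platform(tr, pm, seed = seed, sample = sample,
                              batch = batches[1], drift = NULL)
    if (is.null(drift)) return(first)
    dplyr::bind_rows(first,
      observe_platform(tr, pm, seed = seed, sample = sample,
                       batch = batches[2], drift = drift))
  })
  structure(
    list(tables = tables, truth = tr,
         universe = gene_universe(tr$gene_id, label = "synthetic universe"),
         params = list(truth = unclass(truth),
                       platforms = lapply(platforms, unclass),
                       drift = if (!is.null(drift)) unclass(drift),
                       sample = sample, batches = batches),
         seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits one expression TSV per platform x batch (named
#' `<platform>_<batch>.tsv`), the truth labels as `truth.tsv`
#' (`gene_id`, `lambda`, `expressed`), the universe as `universe.txt`, and a
#' JSON manifest of all generating parameters. Files are byte-identical
#' across runs with the same seed.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) txc_abort(paste0("cannot create directory ", dir), "txc_io_error")
  }
  grp <- dplyr::distinct(dataset$tables, .data$platform, .data$batch)
  paths <- purrr::pmap_chr(grp, function(platform, batch) {
    p <- file.path(dir, paste0(platform, "_", batch, ".tsv"))
    tab <- dataset$tables[dataset$tables$platform == platform &
                            dataset$tables$batch == batch, ]
    write_expression_table(tab, p)
    p
  })
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv_atomic(
    tibble(gene_id = dataset$truth$gene_id,
           lambda = dataset$truth$lambda,
           expressed = as.integer(dataset$truth$expressed)),
    truth_path)
  uni_path <- file.path(dir, "universe.txt")
  write_lines_atomic(dataset$universe$gene_id, uni_path)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- dataset$params
  manifest$seed <- dataset$seed
  write_lines_atomic(
    strsplit(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE, digits = NA)),
             "\n", fixed = TRUE)[[1]],
    manifest_path)
  invisible(c(paths, truth_path, uni_path, manifest_path))
}
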