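# Within-species strain-diversity analysis on infant-like samples:
# rarefaction, genome counting, bacteriocin presence labelling, and the
# analysis of covariance fit y = b0 + a0*I + b1*x + e.

#' Rarefy a sample's read classifications to a fixed depth
#'
#' Uniform sampling without replacement of exactly `depth` reads,
#' deterministic per (sample, seed). Samples with fewer than `depth` reads are
#' excluded (returns `NULL` with a warning) rather than scaled.
#'
#' @param classification A [classify_reads()] table for one sample.
#' @param depth Target read count (default 1e6).
#' @param seed Integer seed.
#' @return Subsampled classification table with exactly `depth` rows, or
#'   `NULL` when the sample is below depth.
#' @export
rarefy <- function(classification, depth = 1000000L, seed = 1L) {
  stopifnot(depth >= 1L)
  n <- nrow(classification)
  if (n < depth) {
    warning("sample has ", n, " reads, below rarefaction depth ", depth,
            "; excluded")
    return(NULL)
  }
  idx <- withr::with_seed(seed, sample.int(n, depth))
  classification[sort(idx), , drop = FALSE]
}

#' Per-sample strain-diversity records for one species and bacteriocin
#'
#' For each infant-like sample: `y` is the number of distinct genomes of the
#' species with at least one assigned read after rarefaction, `x` is the
#' number of reads assigned to the species per 1 million rarefied reads, and
#' `I` indicates whether the bacteriocin was detected in the sample.
#'
#' @param classifications Named list (by sample) of rarefied
#'   [classify_reads()] tables (entries may be `NULL` for excluded samples).
#' @param species_id Species to analyze (must appear in `taxonomy`).
#' @param taxonomy Taxonomy table (genome_id, species).
#' @param presence Named logical vector: bacteriocin detected per sample; must
#'   cover all samples.
#' @return Data frame: sample_id, y, x, I.
#' @export
diversity_records <- function(classifications, species_id, taxonomy, presence) {
  if (!species_id %in% taxonomy$species)
    stop("species '", species_id, "' absent from taxonomy")
  keep <- !vapply(classifications, is.null, TRUE)
  classifications <- classifications[keep]
  miss <- setdiff(names(classifications), names(presence))
  if (length(miss) > 0L)
    stop("presence labels missing for samples: ", paste(miss, collapse = ", "))
  rows <- lapply(names(classifications), function(sid) {
    cl <- classifications[[sid]]
    in_sp <- !is.na(cl$species) & cl$species == species_id
    data.frame(sample_id = sid,
               y = length(unique(cl$genome[in_sp])),
               x = sum(in_sp) / nrow(cl) * 1e6,
               I = as.integer(presence[[sid]]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(), y = integer(), x = numeric(),
                      I = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Fit the analysis of covariance model y = b0 + a0*I + b1*x + e
#'
#' Ordinary least squares with a two-sided t-test of the bacteriocin-presence
#' effect a0 = 0 versus a0 nonzero. A positive a0 means bacteriocin-positive
#' samples show more genomes (higher within-species diversity) at matched
#' species abundance.
#'
#' @param records Data frame from [diversity_records()] (columns y, x, I);
#'   needs >= 3 records, both indicator levels, and non-constant x.
#' @return Object of class `covariance_fit`: list with `b0`, `a0`, `b1`,
#'   standard errors, `p_a0`, `n`, the underlying `lm` fit, and the two group
#'   regression lines (intercepts differing by a0).
#' @export
fit_covariance_model <- function(records) {
  stopifnot(all(c("y", "x", "I") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 records")
  if (length(unique(records$I)) < 2L)
    stop("degenerate design: all samples have the same bacteriocin indicator")
  if (length(unique(records$x)) < 2L) stop("x is constant")
  fit <- stats::lm(y ~ I + x, data = records)
  if (fit$rank < 3L) stop("rank-deficient design: I and x are collinear")
  # interpolating (zero-residual) designs are legitimate here
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(
    b0 = unname(coef(fit)["(Intercept)"]),
    a0 = unname(coef(fit)["I"]),
    b1 = unname(coef(fit)["x"]),
    se = stats::setNames(sm[, "Std. Error"], c("b0", "a0", "b1")),
    p_a0 = unname(sm["I", "Pr(>|t|)"]),
    n = nrow(records),
    lines = list(
      negative = c(intercept = unname(coef(fit)["(Intercept)"]),
                   slope = unname(coef(fit)["x"])),
      positive = c(intercept = unname(coef(fit)["(Intercept)"] + coef(fit)["I"]),
                   slope = unname(coef(fit)["x"]))),
    fit = fit), class = "covariance_fit")
}

#' @export
print.covariance_fit <- function(x, ...) {
  cat(sprintf(
    "ANCOVA fit (n=%d): y = %.4g + %.4g*I + %.4g*x\n  a0 = %.4g (SE %.3g), p[a0=0] = %.3g\n",
    x$n, x$b0, x$a0, x$b1, x$a0, x$se["a0"], x$p_a0))
  invisible(x)
}

#' Simulate diversity records directly from the covariance model
#'
#' Record-level generator used to study the estimator itself: draws x uniform
#' in `x_range`, I Bernoulli(0.5), and y from the model with Gaussian noise.
#'
#' @param n Number of records.
#' @param b0,a0,b1 Model coefficients.
#' @param sigma Residual standard deviation.
#' @param x_range Range of the abundance covariate (reads per million).
#' @param seed Integer seed.
#' @return Data frame: sample_id, y, x, I.
#' @export
simulate_diversity_records <- function(n, b0 = 1, a0 = 0, b1 = 0.001,
                                       sigma = 1, x_range = c(0, 5000),
                                       seed = 1L) {
  withr::with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    I <- stats::rbinom(n, 1L, 0.5)
    y <- b0 + a0 * I + b1 * x + stats::rnorm(n, 0, sigma)
    data.frame(sample_id = sprintf("r%04d", seq_len(n)), y = y, x = x, I = I,
               stringsAsFactors = FALSE)
  })
}
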