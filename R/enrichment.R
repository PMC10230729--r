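# Age grouping, per-bacteriocin enrichment testing (infant-like vs
# adult-like), FDR correction, prevalence filtering and tiering.

#' Assign samples to age groups and superclasses
#'
#' Groups: infant (age 0-1), child (2-9), adolescent (10-19), adult (20-59),
#' elderly (60-107). The infant group forms the "infant-like" superclass; all
#' other groups are treated as one "adult-like" superclass.
#'
#' @param metadata Data frame with columns `sample_id` and `age` (integer
#'   years in 0-107).
#' @return Data frame: sample_id, age, group, superclass.
#' @export
assign_age_groups <- function(metadata) {
  stopifnot(all(c("sample_id", "age") %in% names(metadata)))
  age <- metadata$age
  bad <- is.na(age) | age < 0 | age > 107 | age != floor(age)
  if (any(bad))
    stop("ages must be integers in [0, 107]; offending samples: ",
         paste(metadata$sample_id[bad], collapse = ", "))
  group <- cut(age, breaks = c(-1, 1, 9, 19, 59, 107),
               labels = c("infant", "child", "adolescent", "adult", "elderly"))
  data.frame(sample_id = metadata$sample_id, age = age,
             group = as.character(group),
             superclass = ifelse(group == "infant", "infant-like", "adult-like"),
             stringsAsFactors = FALSE)
}

#' One-sided Wilcoxon rank-sum test for higher abundance in the first group
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; normal approximation with tie correction and continuity
#' correction otherwise. When every value is identical across both groups the
#' continuity convention gives p = 0.5 (never NaN).
#'
#' @param x Abundances in the group hypothesized to be larger (infant-like).
#' @param y Abundances in the comparison group (adult-like).
#' @return One-sided p-value for `alternative = "greater"`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) return(0.5)
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction; monotone, capped at 1, input order preserved.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`. The Storey option estimates
#'   pi0 from the p-value distribution (lambda = 0.5) and rescales the BH
#'   values; BH is the tested default.
#' @return q-values in the input order (empty input gives empty output).
#' @export
fdr_correct <- function(p_values, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(p_values > lambda) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Assign an enrichment/prevalence tier to one bacteriocin
#'
#' A bacteriocin is `excluded` unless it is significantly enriched
#' (q < `q_threshold`) and present in at least `min_prevalence` of the
#' infant-like samples. Surviving bacteriocins are tiered by infant prevalence:
#' `high` above 0.30, `medium` in the closed interval 0.20-0.30, `low` in
#' 0.10 (inclusive) to 0.20 (exclusive).
#'
#' @param q_value FDR-adjusted q-value of the enrichment test.
#' @param prevalence Fraction of infant-like samples with abundance > 0.
#' @param q_threshold Significance cutoff (default 0.01).
#' @param min_prevalence Minimum infant prevalence (default 0.10).
#' @return One of "high", "medium", "low", "excluded".
#' @export
prevalence_tier <- function(q_value, prevalence, q_threshold = 0.01,
                            min_prevalence = 0.10) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (q_value >= q_threshold || prevalence < min_prevalence) return("excluded")
  if (prevalence > 0.30) return("high")
  if (prevalence >= 0.20) return("medium")
  "low"
}

#' Per-bacteriocin enrichment analysis of an abundance matrix
#'
#' For each bacteriocin, tests whether its gene abundance has a larger
#' expected value in infant-like than adult-like samples (one-sided Wilcoxon
#' rank-sum; zero-abundance samples are included), converts p-values to
#' q-values, computes the fraction of infant-like samples with abundance > 0
#' (prevalence), and assigns a tier.
#'
#' @param abund An [abundance_matrix()] object, or a samples x bacteriocins
#'   numeric matrix of abundances.
#' @param metadata Data frame with `sample_id` and `age` covering all samples.
#' @param q_threshold,min_prevalence Tier parameters, see [prevalence_tier()].
#' @param fdr_method Passed to [fdr_correct()].
#' @return Data frame: bacteriocin, p_value, q_value, infant_prevalence,
#'   mean/sd abundance per superclass, tier; one row per bacteriocin.
#' @export
enrich_bacteriocins <- function(abund, metadata, q_threshold = 0.01,
                                min_prevalence = 0.10, fdr_method = "BH") {
  mat <- if (inherits(abund, "abundance_matrix")) abund$fractions else abund
  stopifnot(is.matrix(mat))
  ages <- assign_age_groups(metadata)
  grp <- ages$superclass[match(rownames(mat), ages$sample_id)]
  if (anyNA(grp)) stop("metadata does not cover all samples in the abundance matrix")
  inf <- grp == "infant-like"
  if (!any(inf) || all(inf))
    stop("need both infant-like and adult-like samples")
  res <- lapply(colnames(mat), function(b) {
    x <- mat[inf, b]; y <- mat[!inf, b]
    data.frame(bacteriocin = b,
               p_value = rank_sum_test(x, y),
               infant_prevalence = mean(x > 0),
               mean_infant = mean(x), sd_infant = stats::sd(x),
               mean_adult = mean(y), sd_adult = stats::sd(y),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- fdr_correct(res$p_value, method = fdr_method)
  res$tier <- mapply(prevalence_tier, res$q_value, res$infant_prevalence,
                     MoreArgs = list(q_threshold = q_threshold,
                                     min_prevalence = min_prevalence))
  res[, c("bacteriocin", "p_value", "q_value", "infant_prevalence",
          "mean_infant", "sd_infant", "mean_adult", "sd_adult", "tier")]
}
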