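#' Construct a replicate expression matrix
#'
#' Container for a gene-by-sample expression matrix with per-sample
#' condition (`WT`/`KO`) and group (cell-type) labels, and optional
#' per-gene, per-group q-values carried over from the source
#' differential-expression analysis.
#'
#' @param values numeric gene-by-sample matrix (non-negative), with
#'   gene rownames and sample colnames.
#' @param condition character vector (one per sample) in `"WT"`/`"KO"`.
#' @param group character vector (one per sample) of group labels.
#' @param qvalues optional numeric gene-by-group matrix of q-values in
#'   \[0, 1\].
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, group, qvalues = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  condition <- as.character(condition)
  group <- as.character(group)
  if (length(condition) != ncol(values) || length(group) != ncol(values)) {
    stop("condition and group must have one label per sample")
  }
  if (any(!condition %in% c("WT", "KO"))) {
    stop("condition labels must be 'WT' or 'KO'")
  }
  if (!is.null(qvalues)) {
    stopifnot(is.matrix(qvalues), !is.null(rownames(qvalues)),
              !is.null(colnames(qvalues)))
    if (any(qvalues < 0 | qvalues > 1, na.rm = TRUE)) {
      stop("q-values must lie in [0, 1]")
    }
  }
  structure(list(values = values,
                 condition = setNames(condition, colnames(values)),
                 group = setNames(group, colnames(values)),
                 qvalues = qvalues),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples; groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}

#' Per-gene fold changes for one cell line / group
#'
#' For the given group, averages replicates to one value per condition
#' and reports the per-gene fold change as mean(KO) / mean(WT).
#' q-values are passed through from the input matrix (they come from
#' the source study's own differential-expression analysis). Genes
#' with WT mean 0 have an undefined fold change and are emitted with
#' `fc = NA` and `fc_defined = FALSE`.
#'
#' @param expr an [expression_matrix()].
#' @param group group label to analyse.
#' @return data.frame of class `de_result` with columns `gene`, `fc`,
#'   `q`, `fc_defined`, and attribute `mode = "linear"`.
#' @export
cellline_de <- function(expr, group) {
  stopifnot(inherits(expr, "expression_matrix"))
  sel <- expr$group == group
  if (!any(sel)) stop("group not present: ", group)
  cond <- expr$condition[sel]
  if (!any(cond == "WT") || !any(cond == "KO")) {
    stop("group '", group, "' needs at least one WT and one KO sample")
  }
  vals <- expr$values[, sel, drop = FALSE]
  wt_mean <- rowMeans(vals[, cond == "WT", drop = FALSE])
  ko_mean <- rowMeans(vals[, cond == "KO", drop = FALSE])
  fc <- ifelse(wt_mean == 0, NA_real_, ko_mean / wt_mean)
  q <- if (!is.null(expr$qvalues) && group %in% colnames(expr$qvalues)) {
    expr$qvalues[rownames(expr$values), group]
  } else {
    rep(NA_real_, nrow(expr$values))
  }
  out <- data.frame(gene = rownames(expr$values), fc = fc, q = unname(q),
                    fc_defined = wt_mean != 0, row.names = NULL)
  structure(out, mode = "linear", class = c("de_result", "data.frame"))
}

#' Observed expression change calls (Eexp) from differential expression
#'
#' Converts per-gene fold changes and q-values into the three-valued
#' observed change `Eexp`: `+1` (up-regulated), `-1` (down-regulated)
#' or `0` (unchanged). A gene is called changed only when its q-value
#' is below `q_cut` *and* its fold change clears the biological
#' threshold `fc_threshold`:
#'
#' * linear mode: `+1` iff `q < q_cut` and `FC >= T`; `-1` iff
#'   `q < q_cut` and `FC <= 1/T` (the reciprocal is the "equivalent"
#'   down-regulation threshold); otherwise `0`. With `T = 1` this
#'   reduces to the sign-only rule `FC > 1` / `FC < 1`.
#' * log10 mode: as above on `log10 FC` against `+/- log10 T`; with
#'   `T = 1` the call is the sign of `log10 FC`.
#'
#' Genes whose fold change is undefined (or `NA` q-value) are placed
#' in the missing set rather than called. `q = q_cut` exactly is
#' treated as not significant (unchanged).
#'
#' @param de a `de_result` from [cellline_de()] or [cohort_de()], or
#'   any data.frame with columns `gene`, `fc` (or `log10_fc`) and `q`.
#' @param q_cut significance cut-off on the q-value (default 0.05).
#' @param fc_threshold biological-change threshold `T >= 1` (default 1,
#'   i.e. direction only). Thresholds are inclusive.
#' @param mode `"linear"` (fold change) or `"log10"` (log10 fold
#'   change); defaults to the `mode` attribute of `de`.
#' @return An object of class `eexp_vector`: named integer vector in
#'   \{-1, 0, +1\} with attribute `missing` (genes without a usable
#'   call).
#' @export
eexp_from_de <- function(de, q_cut = 0.05, fc_threshold = 1,
                         mode = attr(de, "mode")) {
  if (is.null(mode)) mode <- if ("log10_fc" %in% names(de)) "log10" else "linear"
  mode <- match.arg(mode, c("linear", "log10"))
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  fc_col <- if (mode == "linear") "fc" else "log10_fc"
  stopifnot(all(c("gene", fc_col, "q") %in% names(de)))
  fc <- de[[fc_col]]
  q <- de$q
  usable <- !is.na(fc) & !is.na(q)
  if ("fc_defined" %in% names(de)) usable <- usable & de$fc_defined
  sig <- usable & q < q_cut
  if (mode == "linear") {
    up <- sig & if (fc_threshold == 1) fc > 1 else fc >= fc_threshold
    down <- sig & if (fc_threshold == 1) fc < 1 else fc <= 1 / fc_threshold
  } else {
    thr <- log10(fc_threshold)
    up <- sig & if (fc_threshold == 1) fc > 0 else fc >= thr
    down <- sig & if (fc_threshold == 1) fc < 0 else fc <= -thr
  }
  vals <- integer(nrow(de))
  vals[up] <- 1L
  vals[down] <- -1L
  out <- setNames(vals[usable], de$gene[usable])
  structure(out, missing = de$gene[!usable], class = "eexp_vector")
}

#' @export
print.eexp_vector <- function(x, ...) {
  cat(sprintf("eexp_vector: %d up, %d down, %d unchanged (%d missing)\n",
              sum(x == 1L), sum(x == -1L), sum(x == 0L),
              length(attr(x, "missing"))))
  invisible(x)
}

#' Binomial point probability (and optional upper tail)
#'
#' Probability of exactly `k` successes in `n` trials at success
#' probability `p0`: `choose(n, k) p0^k (1-p0)^(n-k)`. This is the
#' point probability (a spreadsheet `BINOM.DIST(..., FALSE)`), *not* a
#' tail probability; it is the significance measure used for correct
#' prediction rates against the 1/3 random baseline. Set
#' `upper_tail = TRUE` for the conventional one-sided test
#' `P(X >= k)`.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 success probability under the null (default 1/3).
#' @param upper_tail if `TRUE` return `P(X >= k)` instead.
#' @return a probability.
#' @examples
#' binom_point_p(15, 28)   # 0.013407744
#' @export
binom_point_p <- function(k, n, p0 = 1 / 3, upper_tail = FALSE) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= k, p0 > 0, p0 < 1)
  if (upper_tail) {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  } else {
    dbinom(k, n, p0)
  }
}

#' Score model predictions against observed changes
#'
#' For every gene present in both the model prediction vector (`Emod`)
#' and the observed change vector (`Eexp`), excluding the criterion
#' gene (it was the perturbation input, not a result) and genes in the
#' missing set, computes the error class `|Emod - Eexp|`: 0 = correct,
#' 1 = one-step ("small") error, 2 = two-step ("large") error. The
#' correct prediction rate is the percentage of error-0 genes, and its
#' significance is the binomial point probability of that many correct
#' calls at the 1/3 random baseline ([binom_point_p()]).
#'
#' As a directionality check, the observed call for the criterion gene
#' must be `-1` (the perturbation removed or lowered it); anything
#' else indicates mis-oriented fold changes and is an error.
#'
#' @param emod an [emod()] result (or named integer vector in
#'   \{-1, 0, 1\}).
#' @param eexp an [eexp_from_de()] result.
#' @param criterion name of the perturbed gene.
#' @param check_direction set `FALSE` to skip the criterion
#'   directionality check (e.g. when the criterion gene is absent from
#'   the expression data).
#' @return An object of class `score_report`: list with `n_evaluated`,
#'   `n_by_error` (named counts for error classes 0/1/2), `rate`
#'   (percent correct), `p_value` (point probability),
#'   `p_upper_tail`, and `excluded` (criterion plus genes missing from
#'   either vector).
#' @export
score_predictions <- function(emod, eexp, criterion,
                              check_direction = TRUE) {
  stopifnot(inherits(eexp, "eexp_vector"), length(criterion) == 1L)
  if (check_direction) {
    if (!criterion %in% names(eexp)) {
      stop("criterion gene '", criterion, "' not present in eexp; ",
           "use check_direction = FALSE if it is absent from the data")
    }
    if (eexp[[criterion]] != -1L) {
      stop("directionality check failed: Eexp[", criterion, "] = ",
           eexp[[criterion]], " but the perturbed gene must be -1")
    }
  }
  emod_v <- unclass(emod)
  shared <- setdiff(intersect(names(emod_v), names(eexp)), criterion)
  shared <- setdiff(shared, attr(emod, "excluded"))
  if (!length(shared)) stop("no shared non-criterion genes to score")
  err <- abs(emod_v[shared] - unclass(eexp)[shared])
  n_by_error <- setNames(as.integer(table(factor(err, levels = 0:2))),
                         c("correct", "small_error", "large_error"))
  n <- length(shared)
  k <- n_by_error[["correct"]]
  excluded <- sort(unique(c(criterion, attr(emod, "excluded"),
                            setdiff(names(emod_v), names(eexp)),
                            attr(eexp, "missing"))))
  structure(list(n_evaluated = n, n_by_error = n_by_error,
                 rate = 100 * k / n,
                 p_value = binom_point_p(k, n, 1 / 3),
                 p_upper_tail = binom_point_p(k, n, 1 / 3, upper_tail = TRUE),
                 excluded = excluded),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "score_report: %d genes evaluated; %d correct (%.2f%%), %d small / %d large errors; p = %.3g\n",
    x$n_evaluated, x$n_by_error[["correct"]], x$rate,
    x$n_by_error[["small_error"]], x$n_by_error[["large_error"]], x$p_value))
  invisible(x)
}

#' Correlation between knockdown level and prediction accuracy
#'
#' Pearson correlation of per-group focal-gene fold changes (the
#' residual level of the perturbed gene, measuring knockdown depth)
#' against per-group correct prediction rates, with the coefficient of
#' determination and a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param fc_focal numeric vector of focal-gene fold changes, one per
#'   group.
#' @param rates numeric vector of correct prediction rates (same
#'   length).
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
knockdown_correlation <- function(fc_focal, rates) {
  if (length(fc_focal) != length(rates)) stop("input lengths differ")
  n <- length(fc_focal)
  if (n < 3) stop("need at least 3 groups")
  if (var(fc_focal) == 0 || var(rates) == 0) stop("zero variance in input")
  r <- stats::cor(fc_focal, rates)
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, r_squared = r^2, p_value = p, n = n)
}

#' Split a patient cohort by a focal gene's expression
#'
#' Stratifies patients into "High" (strictly above the threshold) and
#' "Low" (at or below) groups, where the threshold is the mean,
#' median, upper quartile or lower quartile of the focal gene's values
#' (z-scores or expression units). Quartiles use linear interpolation
#' (`stats::quantile` type 7, the common spreadsheet convention) by
#' default; the convention is switchable.
#'
#' @param cohort numeric patient-by-gene matrix with patient rownames
#'   and gene colnames.
#' @param focal_gene gene to stratify on.
#' @param statistic `"mean"`, `"median"`, `"upper_quartile"` or
#'   `"lower_quartile"`.
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return list with `high` and `low` (patient ID vectors, together
#'   covering the cohort) and `threshold`.
#' @export
split_cohort <- function(cohort, focal_gene,
                         statistic = c("mean", "median", "upper_quartile",
                                       "lower_quartile"),
                         quantile_type = 7) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(cohort), !is.null(rownames(cohort)))
  if (!focal_gene %in% colnames(cohort)) {
    stop("focal gene not in cohort: ", focal_gene)
  }
  if (nrow(cohort) < 2) stop("need at least 2 patients")
  x <- cohort[, focal_gene]
  threshold <- switch(statistic,
                      mean = mean(x),
                      median = median(x),
                      upper_quartile = quantile(x, 0.75, type = quantile_type,
                                                names = FALSE),
                      lower_quartile = quantile(x, 0.25, type = quantile_type,
                                                names = FALSE))
  high <- rownames(cohort)[x > threshold]
  low <- rownames(cohort)[x <= threshold]
  if (!length(high) || !length(low)) {
    stop("degenerate split: one group is empty (constant focal-gene values?)")
  }
  list(high = high, low = low, threshold = unname(threshold))
}

#' Low-versus-High differential expression for a stratified cohort
#'
#' Per-gene log10 fold change of Low-group mean over High-group mean,
#' with q-values from a Welch two-sample t-test on log-transformed
#' values, Benjamini-Hochberg adjusted across genes. The orientation
#' (Low over High) makes the focal splitting gene come out negative,
#' matching the directionality convention of the observed-change
#' calls. This is a generic two-group surrogate for portal-specific
#' comparison tools; externally computed differential-expression
#' tables (with their own q-values) can be supplied to
#' [eexp_from_de()] directly instead.
#'
#' Genes whose group means are not strictly positive have an undefined
#' log fold change and are emitted with `fc_defined = FALSE`.
#'
#' @param cohort numeric patient-by-gene matrix (expression units,
#'   positive for genes to be called).
#' @param high,low disjoint patient ID vectors from [split_cohort()].
#' @return data.frame of class `de_result` with columns `gene`,
#'   `log10_fc`, `q`, `fc_defined`, attribute `mode = "log10"`.
#' @export
cohort_de <- function(cohort, high, low) {
  stopifnot(is.matrix(cohort), length(high) >= 2, length(low) >= 2)
  if (length(intersect(high, low))) stop("high and low groups overlap")
  bad <- setdiff(c(high, low), rownames(cohort))
  if (length(bad)) stop("unknown patient ID(s): ", paste(head(bad, 5), collapse = ", "))
  genes <- colnames(cohort)
  hi <- cohort[high, , drop = FALSE]
  lo <- cohort[low, , drop = FALSE]
  mean_hi <- colMeans(hi)
  mean_lo <- colMeans(lo)
  defined <- mean_hi > 0 & mean_lo > 0 & apply(hi > 0, 2, all) & apply(lo > 0, 2, all)
  log10_fc <- ifelse(defined, log10(mean_lo / mean_hi), NA_real_)
  p <- vapply(seq_along(genes), function(j) {
    if (!defined[[j]]) return(NA_real_)
    a <- log10(lo[, j]); b <- log10(hi[, j])
    if (sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      t.test(a, b)$p.value
    }
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, log10_fc = unname(log10_fc), q = unname(q),
                    fc_defined = unname(defined), row.names = NULL)
  structure(out, mode = "log10", class = c("de_result", "data.frame"))
}
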