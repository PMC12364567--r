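# Statistical kernel: Jaccard-Tanimoto coefficient with an exact
# hypergeometric significance test, error-normalized fold change (ENFC),
# coefficient-of-variation summaries, and the nonparametric two-group test
# used for abundance comparisons.

#' Jaccard-Tanimoto coefficient of two presence lists
#'
#' J = |A n B| / |A u B| over two aligned logical vectors. When both lists
#' are empty the union is empty and J is defined as 1 (identical lists),
#' with a warning.
#'
#' @param x,y Logical vectors of equal length, aligned by variable.
#' @return J in [0, 1].
#' @export
jaccard <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y)) stop("presence lists differ in length")
  uni <- sum(x | y)
  if (uni == 0L) {
    warning("both presence lists empty; J defined as 1", call. = FALSE)
    return(1)
  }
  sum(x & y) / uni
}

#' Jaccard-Tanimoto coefficient with significance
#'
#' Tests whether two presence lists are more different than expected by
#' chance. The null model reassigns each list's "present" labels uniformly
#' at random across the variable universe, preserving each list's total
#' count; the intersection size is then hypergeometric, and since J is a
#' strictly increasing function of the intersection size (at fixed totals),
#' the dissimilarity-tail p-value is the exact hypergeometric probability of
#' an intersection no larger than observed. The Monte-Carlo method resamples
#' placements with a seeded RNG and reports (count(J_null <= J_obs) + 1) /
#' (n_null + 1).
#'
#' @param x,y Logical presence vectors over a common, aligned universe.
#' @param method "exact" (closed-form hypergeometric tail) or
#'   "monte-carlo".
#' @param alternative "dissimilar" (one-sided, small p means the lists are
#'   more different than chance; the convention used in traffic
#'   comparisons) or "two.sided" (doubled smaller tail, capped at 1).
#' @param n_null Monte-Carlo replicate count (>= 100).
#' @param seed Optional integer seed for the Monte-Carlo method.
#' @return A \code{jtc_result}: list with \code{jaccard}, \code{p_value},
#'   \code{method}, \code{n_null} (NA for exact).
#' @export
jtc_pvalue <- function(x, y, method = c("exact", "monte-carlo"),
                       alternative = c("dissimilar", "two.sided"),
                       n_null = 10000L, seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y)) stop("presence lists differ in length")
  n <- length(x); k1 <- sum(x); k2 <- sum(y); m_obs <- sum(x & y)
  j_obs <- if (k1 + k2 == 0L) {
    warning("both presence lists empty; J defined as 1", call. = FALSE)
    1
  } else m_obs / (k1 + k2 - m_obs)

  if (method == "exact") {
    # X ~ Hypergeometric(n; k1, k2); J(m) = m / (k1 + k2 - m) is increasing
    lower <- stats::phyper(m_obs, k1, n - k1, k2)
    upper <- 1 - stats::phyper(m_obs - 1, k1, n - k1, k2)
    p <- switch(alternative,
                dissimilar = lower,
                two.sided = min(1, 2 * min(lower, upper)))
    res <- list(jaccard = j_obs, p_value = p, method = "exact",
                n_null = NA_integer_)
  } else {
    if (n_null < 100L) stop("monte-carlo needs n_null >= 100")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    # resample both lists' present labels across the universe, keeping totals
    m_null <- if (k1 == 0L || k2 == 0L) rep(0L, n_null) else
      vapply(seq_len(n_null), function(i) {
        xs <- sample.int(n, k1)
        ys <- sample.int(n, k2)
        sum(xs %in% ys)
      }, integer(1))
    j_null <- ifelse(k1 + k2 - m_null == 0L, 1, m_null / (k1 + k2 - m_null))
    lower <- (sum(j_null <= j_obs) + 1) / (n_null + 1)
    upper <- (sum(j_null >= j_obs) + 1) / (n_null + 1)
    p <- switch(alternative,
                dissimilar = lower,
                two.sided = min(1, 2 * min(lower, upper)))
    res <- list(jaccard = j_obs, p_value = p, method = "monte-carlo",
                n_null = as.integer(n_null))
  }
  class(res) <- "jtc_result"
  res
}

#' @export
print.jtc_result <- function(x, ...) {
  cat("J = ", signif(x$jaccard, 4), ", p = ", format_pvalue(x$p_value),
      " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Error-normalized fold change
#'
#' ENFC summarises a between-group difference on a scale normalised by the
#' measurement spread: ENFC = ln(FC) / sqrt((s1/m1)^2 + (s0/m0)^2) with
#' FC = m1/m0 and s the sample standard deviation — the log fold change in
#' units of its propagated relative error. ENFC is antisymmetric under
#' swapping the groups and zero when the means are equal.
#'
#' @param m1,m0 Group means (group 1 vs reference group 0); must be > 0 for
#'   a calculable record.
#' @param s1,s0 Group standard deviations; at least one must be > 0.
#' @return A one-row data.frame: fold_change, enfc, calculable.
#' @export
enfc <- function(m1, s1, m0, s0) {
  bad <- is.na(m1) || is.na(m0) || m1 <= 0 || m0 <= 0 ||
    ((is.na(s1) || s1 == 0) && (is.na(s0) || s0 == 0))
  if (bad)
    return(data.frame(fold_change = NA_real_, enfc = NA_real_,
                      calculable = FALSE))
  r1 <- if (is.na(s1)) 0 else s1 / m1
  r0 <- if (is.na(s0)) 0 else s0 / m0
  fc <- m1 / m0
  data.frame(fold_change = fc, enfc = log(fc) / sqrt(r1^2 + r0^2),
             calculable = TRUE)
}

#' Per-variable ENFC between two phenotypes within each compartment
#'
#' @param table An [abundance_table()].
#' @param design A [study_design()].
#' @param phenotypes Length-2 character vector; first element is group 1,
#'   second the reference.
#' @param na_as_zero Treat missing values as zero rather than excluding
#'   them from means. Default FALSE.
#' @return A data.frame: compartment, variable, mean1, sd1, n1, mean0, sd0,
#'   n0, fold_change, enfc, calculable. Incalculable records (a zero or
#'   undetected mean, or both spreads zero) are flagged, not dropped.
#' @export
enfc_table <- function(table, design, phenotypes, na_as_zero = FALSE) {
  stopifnot(inherits(table, "abundance_table"), length(phenotypes) == 2L)
  comps <- sort(unique(design$compartment))
  vars <- colnames(table$values)
  rows <- list()
  for (cm in comps) {
    grab <- function(p) {
      ids <- design$sample_id[design$phenotype == p & design$compartment == cm]
      v <- table$values[match(ids, table$samples), , drop = FALSE]
      if (na_as_zero) v[is.na(v)] <- 0
      v
    }
    v1 <- grab(phenotypes[1L]); v0 <- grab(phenotypes[2L])
    for (vn in vars) {
      a <- v1[, vn]; a <- a[!is.na(a)]
      b <- v0[, vn]; b <- b[!is.na(b)]
      e <- enfc(mean(a), stats::sd(a), mean(b), stats::sd(b))
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = cm, variable = vn,
        mean1 = if (length(a)) mean(a) else NA_real_,
        sd1 = if (length(a) > 1L) stats::sd(a) else NA_real_,
        n1 = length(a),
        mean0 = if (length(b)) mean(b) else NA_real_,
        sd0 = if (length(b) > 1L) stats::sd(b) else NA_real_,
        n0 = length(b),
        fold_change = e$fold_change, enfc = e$enfc,
        calculable = e$calculable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient-of-variation summary per phenotype
#'
#' Per-variable CV (sample SD / mean, in percent) within each phenotype,
#' the mean CV across variables per phenotype, and the mean absolute
#' between-phenotype difference of per-variable means expressed as percent
#' of the across-phenotype mean (the "mean difference between groups"
#' summary).
#'
#' @param values Numeric matrix, samples x variables.
#' @param phenotype Character vector, one label per row; exactly two
#'   distinct labels.
#' @return A list: \code{per_variable} (data.frame variable, phenotype,
#'   mean, sd, cv_pct), \code{mean_cv} (named numeric per phenotype),
#'   \code{mean_between_diff_pct}.
#' @export
cv_summary <- function(values, phenotype) {
  values <- as.matrix(values)
  phenos <- sort(unique(phenotype))
  if (length(phenos) != 2L) stop("cv_summary needs exactly two phenotypes")
  per <- list()
  means <- list()
  for (p in phenos) {
    v <- values[phenotype == p, , drop = FALSE]
    if (nrow(v) < 2L) stop("phenotype '", p, "' has fewer than 2 samples")
    mu <- colMeans(v, na.rm = TRUE)
    sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
    cv <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
    per[[p]] <- data.frame(variable = colnames(values), phenotype = p,
                           mean = mu, sd = sdv, cv_pct = cv,
                           stringsAsFactors = FALSE, row.names = NULL)
    means[[p]] <- mu
  }
  per_variable <- do.call(rbind, per)
  rownames(per_variable) <- NULL
  mean_cv <- vapply(phenos, function(p) mean(per[[p]]$cv_pct, na.rm = TRUE),
                    numeric(1))
  mid <- (means[[1L]] + means[[2L]]) / 2
  diff_pct <- ifelse(mid == 0, NA_real_,
                     100 * abs(means[[1L]] - means[[2L]]) / mid)
  list(per_variable = per_variable, mean_cv = mean_cv,
       mean_between_diff_pct = mean(diff_pct, na.rm = TRUE))
}

#' Nonparametric two-group abundance test
#'
#' Two-sided Wilcoxon rank-sum test, the standard two-group choice for
#' data assumed unequally distributed and heteroscedastic. Exact null
#' distribution when the combined sample size is below 20 and there are no
#' ties; normal approximation with continuity correction otherwise. When
#' every value across both groups is tied the test is uninformative and
#' p = 1 is returned with a warning.
#'
#' @param values1,values2 Numeric vectors (>= 3 values each).
#' @return List with \code{p_value} and \code{tier} (see [p_tier()]).
#' @export
group_test <- function(values1, values2) {
  values1 <- values1[!is.na(values1)]; values2 <- values2[!is.na(values2)]
  if (length(values1) < 3L || length(values2) < 3L)
    stop("group_test needs >= 3 values per group")
  all_vals <- c(values1, values2)
  if (length(unique(all_vals)) == 1L) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(list(p_value = 1, tier = p_tier(1)))
  }
  exact <- length(all_vals) < 20L && !anyDuplicated(all_vals)
  p <- suppressWarnings(
    stats::wilcox.test(values1, values2, exact = exact,
                       correct = !exact)$p.value)
  list(p_value = p, tier = p_tier(p))
}

#' Significance tier annotation
#'
#' Maps a p-value to the tier glyphs used on composition plots:
#' "****" < 0.0001, "***" < 0.001, "**" < 0.01, "+" < 0.05, "*" < 0.1,
#' otherwise "".
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
p_tier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "+" else if (pi < 0.1) "*" else ""
  }, character(1))
}

#' Display floor for p-values
#'
#' P-values below 2.2e-16 (double-precision display floor) are reported as
#' the floor; [format_pvalue()] prints them as "<2.2e-16".
#'
#' @param p Numeric vector.
#' @return Numeric vector, floored at 2.2e-16.
#' @export
p_floor <- function(p) pmax(p, 2.2e-16)

#' @rdname p_floor
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 2.2e-16, "<2.2e-16", format(signif(p, 3))))
}
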