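# Fatty-acid composition stage: per-sample mol% normalization and grouped
# comparison tables with propagated error bars and significance tiers.
# The lipid-fraction split (PL vs TG) is an input label; fractionation
# happens upstream of this package.

#' Normalize per-sample fatty-acid amounts to mol%
#'
#' Each sample's species amounts are rescaled to molar percentages of the
#' sample total, so every sample sums to 100 and an overall scale change in
#' one sample (e.g. injected amount) cancels.
#'
#' @param amounts Numeric matrix or data.frame, samples x FA species;
#'   non-negative. Row names (or a leading \code{sample_id} column) identify
#'   samples.
#' @return Numeric matrix of mol% with the same dimnames; samples whose
#'   total is zero are dropped with a warning.
#' @export
normalize_mol_percent <- function(amounts) {
  if (is.data.frame(amounts)) {
    if (names(amounts)[1L] == "sample_id") {
      rn <- amounts$sample_id
      amounts <- as.matrix(amounts[, -1L, drop = FALSE])
      rownames(amounts) <- rn
    } else amounts <- as.matrix(amounts)
  }
  storage.mode(amounts) <- "double"
  if (any(amounts < 0, na.rm = TRUE)) stop("negative FA amount")
  totals <- rowSums(amounts, na.rm = TRUE)
  zero <- totals == 0
  if (any(zero)) {
    warning("dropping sample(s) with zero FA total: ",
            paste(rownames(amounts)[zero], collapse = ", "), call. = FALSE)
    amounts <- amounts[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  100 * amounts / totals
}

#' Grouped fatty-acid composition summary
#'
#' Per-species group means of mol%, propagated error bars, and a
#' nonparametric two-group test with tier annotation — the tabular form of
#' a sexed FA-composition bar plot.
#'
#' The default error bar is the standard error of the mean of per-sample
#' mol% within the group. With \code{error = "propagated"} the bar instead
#' propagates the per-sample quotient (species / total) by the delta
#' method, adding the relative error of the sample total in quadrature.
#'
#' @param molpct Matrix from [normalize_mol_percent()] (samples x species).
#' @param group Character vector, one label per sample; exactly two groups,
#'   >= 3 samples each.
#' @param error "sem" (default) or "propagated".
#' @param totals Per-sample pre-normalization totals (raw amount scale),
#'   required for \code{error = "propagated"}; their relative SEM is added
#'   in quadrature (quotient rule for the normalization divide).
#' @return A data.frame: species, mean per group, error per group,
#'   p_value, p_adj (Benjamini-Hochberg), tier. Species entirely absent
#'   from one group get mean 0 there and no test (NA p).
#' @export
group_fa_summary <- function(molpct, group, error = c("sem", "propagated"),
                             totals = NULL) {
  error <- match.arg(error)
  molpct <- as.matrix(molpct)
  groups <- sort(unique(group))
  if (length(groups) != 2L) stop("need exactly two groups")
  if (any(table(group) < 3L)) stop("need >= 3 samples per group")
  if (error == "propagated" && (is.null(totals) || length(totals) != nrow(molpct)))
    stop("error = 'propagated' needs per-sample pre-normalization totals")
  g1 <- molpct[group == groups[1L], , drop = FALSE]
  g2 <- molpct[group == groups[2L], , drop = FALSE]

  err_of <- function(g, tot) {
    sem <- apply(g, 2L, stats::sd, na.rm = TRUE) / sqrt(nrow(g))
    if (error == "sem") return(sem)
    # quotient rule: relative SEM of the sample totals in quadrature
    rel_tot <- stats::sd(tot) / (sqrt(length(tot)) * mean(tot))
    mu <- colMeans(g, na.rm = TRUE)
    sqrt(sem^2 + (mu * rel_tot)^2)
  }
  t1 <- if (is.null(totals)) NULL else totals[group == groups[1L]]
  t2 <- if (is.null(totals)) NULL else totals[group == groups[2L]]

  species <- colnames(molpct)
  p <- vapply(species, function(s) {
    a <- g1[, s]; b <- g2[, s]
    if (all(is.na(a) | a == 0) || all(is.na(b) | b == 0)) return(NA_real_)
    group_test(a, b)$p_value
  }, numeric(1))
  out <- data.frame(
    species = species,
    mean1 = colMeans(g1, na.rm = TRUE), err1 = err_of(g1, t1),
    mean2 = colMeans(g2, na.rm = TRUE), err2 = err_of(g2, t2),
    p_value = unname(p), stringsAsFactors = FALSE, row.names = NULL)
  out$mean1[is.na(out$mean1)] <- 0
  out$mean2[is.na(out$mean2)] <- 0
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$tier <- p_tier(out$p_value)
  names(out)[2:5] <- c(paste0("mean_", groups[1L]), paste0("err_", groups[1L]),
                       paste0("mean_", groups[2L]), paste0("err_", groups[2L]))
  attr(out, "groups") <- groups
  out
}
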