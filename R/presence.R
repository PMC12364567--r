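# Presence calling: a variable is present in a (phenotype, compartment)
# group when a sufficient fraction of that group's samples record a signal
# strictly greater than zero. The default occupancy threshold is 0.66,
# taken literally, so 2 of 3 samples (0.667) passes. Missing values count
# as not detected; the denominator is always the full group size.

#' Call per-group presence from signal occupancy
#'
#' For every (phenotype, compartment) group and every variable, computes the
#' occupancy (fraction of the group's samples with signal > 0) and calls the
#' variable present when occupancy >= \code{threshold}.
#'
#' @param table An [abundance_table()].
#' @param design A [study_design()]; every sample in the design must exist
#'   in the table. Samples in the table but not the design are ignored.
#' @param threshold Occupancy threshold in (0, 1]; default 0.66.
#' @return A \code{presence_matrix}: list with \code{present} and
#'   \code{occupancy}, both 3-d arrays indexed (phenotype, compartment,
#'   variable); \code{phenotypes}, \code{compartments}, \code{variables}
#'   (canonical names); \code{group_n} (matrix of group sizes); and
#'   \code{threshold}.
#' @export
call_presence <- function(table, design, threshold = 0.66) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  missing_samples <- setdiff(design$sample_id, table$samples)
  if (length(missing_samples) > 0L)
    stop("design sample(s) absent from table: ",
         paste(missing_samples, collapse = ", "))

  phenos <- sort(unique(design$phenotype))
  comps <- sort(unique(design$compartment))
  vars <- colnames(table$values)

  occ <- array(NA_real_, dim = c(length(phenos), length(comps), length(vars)),
               dimnames = list(phenotype = phenos, compartment = comps,
                               variable = vars))
  n_mat <- matrix(0L, length(phenos), length(comps),
                  dimnames = list(phenos, comps))
  for (p in phenos) {
    for (cm in comps) {
      ids <- design$sample_id[design$phenotype == p & design$compartment == cm]
      n_mat[p, cm] <- length(ids)
      if (length(ids) == 0L) next
      vals <- table$values[match(ids, table$samples), , drop = FALSE]
      detected <- !is.na(vals) & vals > 0
      occ[p, cm, ] <- colSums(detected) / length(ids)
    }
  }
  if (any(n_mat == 0L))
    stop("empty (phenotype, compartment) group(s): ",
         paste(apply(which(n_mat == 0L, arr.ind = TRUE), 1L, function(ij)
           paste0("(", phenos[ij[1L]], ", ", comps[ij[2L]], ")")),
           collapse = ", "))

  structure(list(present = occ >= threshold, occupancy = occ,
                 phenotypes = phenos, compartments = comps, variables = vars,
                 group_n = n_mat, threshold = threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", length(x$phenotypes), " phenotypes x ",
      length(x$compartments), " compartments x ", length(x$variables),
      " variables (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Long-format view of a presence matrix
#'
#' @param presence A \code{presence_matrix}.
#' @return A data.frame with columns phenotype, compartment, variable,
#'   occupancy, present, ordered deterministically.
#' @export
presence_long <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  grid <- expand.grid(phenotype = presence$phenotypes,
                      compartment = presence$compartments,
                      variable = presence$variables,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$occupancy <- as.vector(presence$occupancy)
  grid$present <- as.vector(presence$present)
  grid <- grid[order(grid$phenotype, grid$compartment, grid$variable), ]
  rownames(grid) <- NULL
  grid
}

#' Presence pattern of one variable for one phenotype
#'
#' @param presence A \code{presence_matrix}.
#' @param phenotype Phenotype label.
#' @param variable Canonical variable name.
#' @return Character vector of compartments where the variable is present.
#' @export
presence_pattern <- function(presence, phenotype, variable) {
  stopifnot(inherits(presence, "presence_matrix"))
  pr <- presence$present[phenotype, , variable]
  presence$compartments[pr]
}
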