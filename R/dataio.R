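# Input containers: wide abundance table, sample design, compartment network.
# Missing cells and explicit zeros both mean "not detected" for presence
# calling; quantitative stages exclude missing values from means by default.

#' Construct a compartment network
#'
#' A compartment network is a simple undirected graph: nodes are metabolic
#' compartments (tissues and fluids), edges are metabolic adjacencies along
#' which lipids are exchanged directly (e.g. serum-liver).
#'
#' @param nodes Character vector of compartment labels (unique, case
#'   sensitive).
#' @param edges A two-column matrix or data.frame of node labels, or a list
#'   of length-2 character vectors. Self-loops and duplicate edges (in either
#'   orientation) are errors.
#' @return A \code{compartment_network} object.
#' @export
compartment_network <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels in network")
  if (length(nodes) == 0L) stop("network needs at least one node")
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, as.character))
  if (is.null(edges) || length(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have exactly two endpoints")
    storage.mode(em) <- "character"
  }
  bad <- setdiff(as.vector(em), nodes)
  if (length(bad) > 0L)
    stop("edge references unknown node(s): ", paste(bad, collapse = ", "))
  if (any(em[, 1L] == em[, 2L]))
    stop("self-loop edge: ", em[which(em[, 1L] == em[, 2L])[1L], 1L])
  key <- apply(em, 1L, function(e) paste(sort(e), collapse = "\r"))
  if (anyDuplicated(key))
    stop("duplicated edge: ",
         gsub("\r", "-", key[duplicated(key)][1L], fixed = TRUE))
  # canonical order: endpoints sorted within edge, edges sorted
  if (nrow(em) > 0L) {
    em <- matrix(t(apply(em, 1L, sort)), ncol = 2L)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  colnames(em) <- c("from", "to")
  structure(list(nodes = nodes, edges = em), class = "compartment_network")
}

#' @export
print.compartment_network <- function(x, ...) {
  cat("<compartment_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Test whether two compartments are metabolically adjacent
#' @param network A \code{compartment_network}.
#' @param a,b Node labels.
#' @return Logical scalar.
#' @export
has_edge <- function(network, a, b) {
  stopifnot(inherits(network, "compartment_network"))
  e <- sort(c(a, b))
  any(network$edges[, 1L] == e[1L] & network$edges[, 2L] == e[2L])
}

#' Edge labels of a network
#' @param network A \code{compartment_network}.
#' @return Character vector "a|b" with endpoints in sorted order.
#' @export
edge_labels <- function(network) {
  if (nrow(network$edges) == 0L) return(character())
  paste(network$edges[, 1L], network$edges[, 2L], sep = "|")
}

#' Read a compartment network from JSON
#'
#' Expects \code{{"nodes": [...], "edges": [[a,b], ...]}}.
#'
#' @param path Path to a JSON file.
#' @return A [compartment_network()].
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$nodes)) stop("network JSON lacks a 'nodes' array")
  edges <- obj$edges
  if (is.null(edges) || length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  compartment_network(obj$nodes, edges)
}

#' Write a compartment network to JSON
#' @param network A \code{compartment_network}.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "compartment_network"))
  edges <- lapply(seq_len(nrow(network$edges)),
                  function(i) unname(network$edges[i, ]))
  jsonlite::write_json(list(nodes = network$nodes, edges = edges), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Default mouse-study compartment network
#'
#' A nine-compartment star: serum as the circulating hub connected to liver,
#' spleen, kidney, heart, brain, vastus muscle, BAT and WAT. This is an
#' explicit synthetic stand-in for the mouse compartment map (whose published
#' form is graphical); analyses accept any user-supplied network.
#'
#' @return A [compartment_network()].
#' @export
default_compartment_network <- function() {
  tissues <- c("liver", "spleen", "kidney", "heart", "brain",
               "vastus muscle", "BAT", "WAT")
  compartment_network(c("serum", tissues), cbind("serum", tissues))
}

#' Read a wide abundance table
#'
#' First column: sample id; remaining headers: shorthand lipid names.
#' Values are non-negative signal intensities in arbitrary units; empty
#' cells are missing. Negative values are a hard error naming the cell.
#' Headers that fail lipid-name parsing are kept (as opaque variables) and
#' reported in the \code{unparseable} attribute-like field.
#'
#' @param path CSV or TSV file path.
#' @param dialect "auto" (sniff delimiter from the header line), "csv" or
#'   "tsv".
#' @return An \code{abundance_table}: list with \code{samples} (character),
#'   \code{variables} (data.frame from [parse_lipid_names()]), \code{values}
#'   (numeric matrix, samples x variables) and \code{unparseable}
#'   (character vector of offending headers).
#' @export
read_abundance_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    hdr <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", hdr)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("abundance table needs a sample-id column plus >= 1 variable")
  abundance_table(samples = as.character(df[[1L]]),
                  values = as.matrix(df[, -1L, drop = FALSE]))
}

#' Construct an abundance table from a matrix
#'
#' @param samples Character vector of sample ids (unique).
#' @param values Numeric matrix, one row per sample, lipid names as column
#'   names. Values must be >= 0 or NA.
#' @return An \code{abundance_table} (see [read_abundance_table()]).
#' @export
abundance_table <- function(samples, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(samples) != nrow(values))
    stop("sample ids and value rows differ in length")
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("variable names missing or duplicated")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative intensity at sample '", samples[neg[1L, 1L]],
         "', variable '", colnames(values)[neg[1L, 2L]], "'")
  vars <- parse_lipid_names(colnames(values))
  unparseable <- colnames(values)[!vars$parseable]
  if (length(unparseable) > 0L)
    warning("unparseable variable name(s): ",
            paste(unparseable, collapse = ", "), call. = FALSE)
  colnames(values) <- vars$name  # canonical formatting where parseable
  rownames(values) <- samples
  structure(list(samples = samples, variables = vars, values = values,
                 unparseable = unparseable),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", length(x$samples), " samples x ",
      nrow(x$variables), " variables\n", sep = "")
  invisible(x)
}

#' Write an abundance table as CSV
#' @param table An \code{abundance_table}.
#' @param path Output path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = table$samples, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a study design
#'
#' Maps samples to (phenotype, compartment) and optional numeric covariates.
#'
#' @param sample_id Character vector.
#' @param phenotype Character vector (e.g. "male"/"female").
#' @param compartment Character vector of compartment labels.
#' @param covariates Optional data.frame of numeric covariates (e.g. BMI).
#' @return A \code{study_design} data.frame.
#' @export
study_design <- function(sample_id, phenotype, compartment, covariates = NULL) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in design")
  df <- data.frame(sample_id = as.character(sample_id),
                   phenotype = as.character(phenotype),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(df))
    df <- cbind(df, covariates)
  }
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read a study design CSV
#'
#' Columns: sample_id, phenotype, compartment, then optional numeric
#' covariates.
#' @param path CSV path.
#' @return A [study_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "compartment")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  covs <- df[setdiff(names(df), need)]
  study_design(df$sample_id, df$phenotype, df$compartment,
               if (ncol(covs) > 0L) covs else NULL)
}

#' Cross-validate abundance table, design and network
#'
#' Checks that every design sample exists in the table, every design
#' compartment is a network node, and reports per-(phenotype, compartment)
#' sample counts.
#'
#' @param table An \code{abundance_table}.
#' @param design A \code{study_design}.
#' @param network A \code{compartment_network}.
#' @return A list with \code{counts} (data.frame phenotype, compartment, n)
#'   and \code{n_samples}, \code{n_variables}.
#' @export
validate_design <- function(table, design, network) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(network, "compartment_network"))
  missing_samples <- setdiff(design$sample_id, table$samples)
  if (length(missing_samples) > 0L)
    stop("design sample(s) absent from abundance table: ",
         paste(missing_samples, collapse = ", "))
  bad_comp <- setdiff(unique(design$compartment), network$nodes)
  if (length(bad_comp) > 0L)
    stop("design compartment(s) absent from network: ",
         paste(bad_comp, collapse = ", "))
  counts <- as.data.frame(table(phenotype = design$phenotype,
                                compartment = design$compartment),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n"
  counts <- counts[counts$n > 0L, , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_samples = length(table$samples),
       n_variables = nrow(table$variables))
}
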