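# Switch Analysis: classify each variable's spatial presence pattern over
# the compartment network, per phenotype.
#
# Type taxonomy (a partition of non-empty patterns):
#   A       present in every network node ("throughout the whole system")
#   U       present in exactly one compartment (isolated)
#   B       present in exactly two metabolically adjacent compartments
#   N2      present in exactly two non-adjacent compartments
#   PARTIAL present in more than two but not all compartments
#   ABSENT  empty pattern
# PARTIAL variables are additionally enrolled in every per-edge B-set whose
# both endpoints they occupy (the edge-pie criterion is edge-local), while
# the global count table keeps PARTIAL separate so the labels stay a
# partition. A-type variables are excluded from edge sets by default since
# they are tabulated separately as ubiquitous.

.switch_labels <- c("A", "U", "B", "N2", "PARTIAL", "ABSENT")

#' Classify a presence pattern over a compartment network
#'
#' @param pattern Character vector of compartments where a variable is
#'   present (possibly empty).
#' @param network A [compartment_network()].
#' @return A single label: "A", "U", "B", "N2", "PARTIAL" or "ABSENT".
#' @seealso [pattern_edges()] for the adjacent pairs a pattern spans.
#' @export
classify_pattern <- function(pattern, network) {
  stopifnot(inherits(network, "compartment_network"))
  pattern <- unique(as.character(pattern))
  unknown <- setdiff(pattern, network$nodes)
  if (length(unknown) > 0L)
    stop("pattern contains unknown compartment(s): ",
         paste(unknown, collapse = ", "))
  k <- length(pattern)
  if (k == 0L) return("ABSENT")
  if (k == length(network$nodes)) return("A")
  if (k == 1L) return("U")
  if (k == 2L)
    return(if (has_edge(network, pattern[1L], pattern[2L])) "B" else "N2")
  "PARTIAL"
}

#' Adjacent compartment pairs spanned by a pattern
#'
#' @param pattern Character vector of compartments.
#' @param network A [compartment_network()].
#' @return Character vector of edge labels "a|b" (sorted endpoints) for
#'   every network edge with both endpoints in the pattern.
#' @export
pattern_edges <- function(pattern, network) {
  stopifnot(inherits(network, "compartment_network"))
  if (nrow(network$edges) == 0L) return(character())
  hit <- network$edges[, 1L] %in% pattern & network$edges[, 2L] %in% pattern
  edge_labels(network)[hit]
}

#' Run the Switch Analysis
#'
#' Classifies every variable's presence pattern per phenotype and localizes
#' it on the network: per-node U-sets (isolated variables), per-edge B-sets
#' (variables present in both endpoints of an adjacency), N2 pairs, and the
#' ubiquitous A-set. Also emits the per-variable traffic table and the
#' per-class x type count table (the machine-readable form of a traffic
#' plot with its inset table).
#'
#' @param presence A [call_presence()] result.
#' @param network A [compartment_network()]; its nodes must cover the
#'   presence compartments.
#' @param include_a_in_edges Logical; enroll A-type variables in per-edge
#'   B-sets. Default FALSE (ubiquitous lipids are tabulated separately).
#' @param group_dg_with_tg Logical; count DG variables as class TG in the
#'   count table (DG species arising from in-source fragmentation of TGs
#'   travel with the TG class in traffic plots). Default FALSE; the
#'   triglyceride traffic driver turns it on.
#' @return A \code{traffic_result}: list with \code{traffic} (data.frame:
#'   phenotype, variable, class, label, compartments, edges), \code{a_set},
#'   \code{u_sets} (per phenotype, per node), \code{edge_sets} (per
#'   phenotype, per edge), \code{n2_sets} (per phenotype, per unordered
#'   non-adjacent pair), \code{counts} (class x label x phenotype table),
#'   \code{network}, \code{phenotypes}.
#' @export
switch_analysis <- function(presence, network,
                            include_a_in_edges = FALSE,
                            group_dg_with_tg = FALSE) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(network, "compartment_network"))
  bad <- setdiff(presence$compartments, network$nodes)
  if (length(bad) > 0L)
    stop("presence compartment(s) not in network: ", paste(bad, collapse = ", "))

  phenos <- presence$phenotypes
  vars <- sort(presence$variables)
  vinfo <- parse_lipid_names(vars)
  cls <- ifelse(vinfo$parseable, vinfo$class_code, "unknown")
  if (group_dg_with_tg) cls[cls == "DG"] <- "TG"
  names(cls) <- vars

  rows <- vector("list", length(phenos) * length(vars))
  u_sets <- edge_sets <- n2_sets <- a_set <- list()
  i <- 0L
  for (p in phenos) {
    u_sets[[p]] <- stats::setNames(
      lapply(network$nodes, function(n) character()), network$nodes)
    edge_sets[[p]] <- stats::setNames(
      lapply(edge_labels(network), function(e) character()), edge_labels(network))
    n2_sets[[p]] <- list()
    a_set[[p]] <- character()
    if (!any(presence$present[p, , ]))
      warning("phenotype '", p, "' has no present variables", call. = FALSE)
    for (v in vars) {
      pat <- presence$compartments[presence$present[p, , v]]
      lab <- classify_pattern(pat, network)
      spans <- pattern_edges(pat, network)
      if (lab == "U") {
        u_sets[[p]][[pat]] <- c(u_sets[[p]][[pat]], v)
      } else if (lab == "A") {
        a_set[[p]] <- c(a_set[[p]], v)
      } else if (lab == "N2") {
        key <- paste(sort(pat), collapse = "|")
        n2_sets[[p]][[key]] <- c(n2_sets[[p]][[key]], v)
      }
      if (lab %in% c("B", "PARTIAL") || (lab == "A" && include_a_in_edges))
        for (e in spans)
          edge_sets[[p]][[e]] <- c(edge_sets[[p]][[e]], v)
      i <- i + 1L
      rows[[i]] <- data.frame(
        phenotype = p, variable = v, class = unname(cls[v]), label = lab,
        compartments = paste(sort(pat), collapse = ";"),
        edges = paste(spans, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  traffic <- do.call(rbind, rows)

  counts <- table(class = traffic$class,
                  label = factor(traffic$label, levels = .switch_labels),
                  phenotype = traffic$phenotype)

  structure(list(traffic = traffic, a_set = a_set, u_sets = u_sets,
                 edge_sets = edge_sets, n2_sets = n2_sets, counts = counts,
                 network = network, phenotypes = phenos),
            class = "traffic_result")
}

#' @export
print.traffic_result <- function(x, ...) {
  cat("<traffic_result> ", length(unique(x$traffic$variable)), " variables, ",
      "phenotypes: ", paste(x$phenotypes, collapse = ", "), "\n", sep = "")
  tab <- table(x$traffic$phenotype, x$traffic$label)
  print(tab)
  invisible(x)
}

#' Type-count inset table
#'
#' Number of variables of each type per phenotype (optionally per lipid
#' class) — the machine-readable twin of a traffic plot's inset table.
#'
#' @param result A \code{traffic_result}.
#' @param by_class Logical; split counts by lipid class.
#' @return A data.frame.
#' @export
traffic_counts <- function(result, by_class = FALSE) {
  stopifnot(inherits(result, "traffic_result"))
  tr <- result$traffic
  if (by_class) {
    df <- as.data.frame(table(class = tr$class, phenotype = tr$phenotype,
                              label = factor(tr$label, levels = .switch_labels)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table(phenotype = tr$phenotype,
                              label = factor(tr$label, levels = .switch_labels)),
                        stringsAsFactors = FALSE)
  }
  names(df)[names(df) == "Freq"] <- "n"
  df
}

.compare_sets <- function(s1, s2) {
  list(shared = sort(intersect(s1, s2)),
       only1 = sort(setdiff(s1, s2)),
       only2 = sort(setdiff(s2, s1)))
}

#' Compare the traffic of two phenotypes
#'
#' For every network node (U-sets), every edge (edge B-sets) and the global
#' presence lists, splits the variables into shared / unique-to-1 /
#' unique-to-2 and attaches the Jaccard-Tanimoto coefficient with its exact
#' p-value over the common variable universe.
#'
#' @param result A \code{traffic_result} holding both phenotypes, or a
#'   two-element list of single-phenotype results over the same network.
#' @param phenotypes Length-2 character vector; defaults to the result's
#'   first two phenotypes.
#' @return A \code{traffic_comparison}: data.frame with one row per scope
#'   (scope_type in global/node/edge, scope label, n_shared, n_only1,
#'   n_only2, jaccard, p_value) plus a \code{sets} list carrying the
#'   underlying memberships.
#' @export
compare_phenotypes <- function(result, phenotypes = NULL) {
  stopifnot(inherits(result, "traffic_result"))
  if (is.null(phenotypes)) phenotypes <- result$phenotypes[1:2]
  if (length(phenotypes) != 2L || !all(phenotypes %in% result$phenotypes))
    stop("need exactly two phenotypes present in the traffic result")
  p1 <- phenotypes[1L]; p2 <- phenotypes[2L]
  universe <- sort(unique(result$traffic$variable))

  scopes <- list()
  sets <- list()
  add_scope <- function(type, label, s1, s2) {
    cmp <- .compare_sets(s1, s2)
    # empty-vs-empty scopes fall back to the documented J = 1 convention;
    # the per-call warning is redundant inside a whole-network sweep
    jt <- suppressWarnings(
      jtc_pvalue(universe %in% s1, universe %in% s2, method = "exact"))
    scopes[[length(scopes) + 1L]] <<- data.frame(
      scope_type = type, scope = label,
      n_shared = length(cmp$shared), n_only1 = length(cmp$only1),
      n_only2 = length(cmp$only2), jaccard = jt$jaccard,
      p_value = jt$p_value, stringsAsFactors = FALSE)
    sets[[paste(type, label, sep = ":")]] <<- cmp
  }

  tr <- result$traffic
  glob1 <- tr$variable[tr$phenotype == p1 & tr$label != "ABSENT"]
  glob2 <- tr$variable[tr$phenotype == p2 & tr$label != "ABSENT"]
  add_scope("global", "all", glob1, glob2)
  for (n in result$network$nodes)
    add_scope("node", n, result$u_sets[[p1]][[n]], result$u_sets[[p2]][[n]])
  for (e in edge_labels(result$network))
    add_scope("edge", e, result$edge_sets[[p1]][[e]], result$edge_sets[[p2]][[e]])

  out <- do.call(rbind, scopes)
  structure(list(table = out, sets = sets, phenotypes = phenotypes,
                 network = result$network),
            class = "traffic_comparison")
}

#' @export
print.traffic_comparison <- function(x, ...) {
  cat("<traffic_comparison> ", x$phenotypes[1L], " vs ", x$phenotypes[2L],
      "\n", sep = "")
  print(utils::head(x$table, 12L))
  invisible(x)
}
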