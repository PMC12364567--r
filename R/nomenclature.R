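# Shorthand lipid nomenclature: CLASS[modifier](C:D[/C:D...]).
# Class codes seen on the platforms this package targets; anything else is
# accepted but flagged (vendor exports routinely carry extra codes).
.known_classes <- c(
  "PC", "PE", "PI", "PS", "PA", "PG", "LPC", "LPE", "LPA", "SM", "Cer",
  "CE", "MG", "DG", "TG", "FA"
)

#' Parse a shorthand lipid name
#'
#' Parses names such as \code{"PC(34:2)"}, \code{"TG(17:0/17:0/17:0)"},
#' \code{"PC-O(33:2)"} (ether lipid) or \code{"TGox(53:3)"} (oxidized
#' species) into a structured record. Both the \code{"PC-O"} and
#' \code{"PC O-"} ether dialects are accepted; the canonical output dialect
#' (see [format_lipid_name()]) is \code{"PC-O(C:D)"}.
#'
#' @param name A single lipid name string.
#' @return An object of class \code{lipid_name}: a list with fields
#'   \code{class_code}, \code{ether} (logical), \code{oxidized} (logical),
#'   \code{total_carbons}, \code{total_double_bonds}, \code{chains} (integer
#'   matrix with columns \code{carbons}, \code{double_bonds}, or \code{NULL}
#'   when the name gives only totals) and \code{known} (logical; \code{FALSE}
#'   for class codes outside the recognised set).
#' @details Total carbons must be at least the total double-bond count; when
#'   chains are given, the totals are their sums. Unknown class codes parse
#'   with a warning rather than an error so that pipelines run on
#'   heterogeneous vendor exports.
#' @examples
#' parse_lipid_name("PC(34:2)")
#' parse_lipid_name("TG(17:0/17:0/17:0)")$total_carbons # 51
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("lipid name must be a single non-empty string")
  name <- trimws(name)

  m <- regmatches(name, regexec("^(.*?)\\(([^()]*)\\)$", name))[[1]]
  if (length(m) == 0L)
    stop("malformed lipid name (no parenthesized composition): '", name, "'")
  head <- trimws(m[2]); comp <- m[3]
  if (!nzchar(head))
    stop("malformed lipid name (empty class code): '", name, "'")

  ether <- FALSE; oxid <- FALSE
  # ether dialects: "PC-O", "PC O-"; oxidized: "TGox", "TGoxo"
  if (grepl("(-O|\\sO-?)$", head)) {
    ether <- TRUE
    head <- sub("(-O|\\sO-?)$", "", head)
  } else if (grepl("(ox|oxo)$", head) && nchar(head) > 2L) {
    oxid <- TRUE
    head <- sub("(oxo|ox)$", "", head)
  }
  head <- trimws(head)
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", head))
    stop("malformed class code '", head, "' in '", name, "'")
  known <- head %in% .known_classes
  if (!known)
    warning("unknown lipid class code '", head, "' in '", name, "'",
            call. = FALSE)

  chains <- .parse_composition(comp, name)
  if (nrow(chains) == 1L) {
    totals <- chains[1L, ]
    chains_out <- NULL
  } else {
    totals <- as.integer(colSums(chains))
    chains_out <- chains
  }
  if (totals[1L] < totals[2L])
    stop("total carbons (", totals[1L], ") < total double bonds (",
         totals[2L], ") in '", name, "'")

  structure(
    list(class_code = head, ether = ether, oxidized = oxid,
         total_carbons = unname(totals[1L]),
         total_double_bonds = unname(totals[2L]),
         chains = chains_out, known = known),
    class = "lipid_name"
  )
}

# "34:2" or "17:0/17:0/17:0" -> integer matrix (carbons, double_bonds)
.parse_composition <- function(comp, name) {
  parts <- trimws(strsplit(comp, "/", fixed = TRUE)[[1]])
  if (length(parts) == 0L || any(!nzchar(parts)))
    stop("malformed composition '", comp, "' in '", name, "'")
  out <- matrix(0L, nrow = length(parts), ncol = 2L,
                dimnames = list(NULL, c("carbons", "double_bonds")))
  for (i in seq_along(parts)) {
    cd <- regmatches(parts[i], regexec("^([0-9]+):([0-9]+)$", parts[i]))[[1]]
    if (length(cd) == 0L)
      stop("malformed carbon:double-bond token '", parts[i], "' in '",
           name, "'")
    cc <- as.integer(cd[2]); dd <- as.integer(cd[3])
    if (cc < dd)
      stop("chain '", parts[i], "' has more double bonds than carbons in '",
           name, "'")
    out[i, ] <- c(cc, dd)
  }
  out
}

#' Format a parsed lipid name canonically
#'
#' Inverse of [parse_lipid_name()]: \code{parse_lipid_name(format_lipid_name(x))}
#' reproduces \code{x}. The ether modifier is printed as \code{"-O"}, the
#' oxidized modifier as \code{"ox"}; sn-resolved chains are printed as
#' \code{C:D/C:D/...}, otherwise totals as \code{C:D}.
#'
#' @param lipid A \code{lipid_name} object.
#' @return A single string.
#' @export
format_lipid_name <- function(lipid) {
  stopifnot(inherits(lipid, "lipid_name"))
  mod <- if (lipid$ether) "-O" else if (lipid$oxidized) "ox" else ""
  comp <- if (is.null(lipid$chains)) {
    paste0(lipid$total_carbons, ":", lipid$total_double_bonds)
  } else {
    paste(paste0(lipid$chains[, 1L], ":", lipid$chains[, 2L]), collapse = "/")
  }
  paste0(lipid$class_code, mod, "(", comp, ")")
}

#' @export
print.lipid_name <- function(x, ...) {
  cat("<lipid_name> ", format_lipid_name(x),
      if (!x$known) "  [unknown class]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.lipid_name <- function(x, ...) format_lipid_name(x)

#' Expand compact multi-species lipid notation
#'
#' Expands the compact notations \code{"TG(48:0, 48:1, 48:2)"} (comma list)
#' and \code{"TG(54:3-6)"} (double-bond range; ASCII hyphen, en dash and
#' minus sign all accepted) into one [parse_lipid_name()] record per species.
#' A plain single-species name passes through as a singleton list.
#'
#' @param text A single string in compact notation.
#' @return A list of \code{lipid_name} objects.
#' @examples
#' length(expand_compact_list("TG(54:3-6)")) # 4
#' @export
expand_compact_list <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("expected a single non-empty string")
  m <- regmatches(text, regexec("^(.*?)\\(([^()]*)\\)$", text))[[1]]
  if (length(m) == 0L)
    stop("malformed compact lipid list: '", text, "'")
  prefix <- trimws(m[2]); body <- m[3]
  if (grepl("[(,]", prefix))
    stop("mixed class prefixes inside one parenthesis: '", text, "'")
  items <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  if (any(grepl("\\(", items)))
    stop("mixed class prefixes inside one parenthesis: '", text, "'")
  out <- list()
  for (it in items) {
    it <- gsub("−|–", "-", it)  # minus sign / en dash -> hyphen
    rng <- regmatches(it, regexec("^([0-9]+):([0-9]+)-([0-9]+)$", it))[[1]]
    if (length(rng) > 0L) {
      cc <- rng[2]; d0 <- as.integer(rng[3]); d1 <- as.integer(rng[4])
      if (d1 < d0) stop("descending double-bond range '", it, "'")
      comps <- paste0(cc, ":", d0:d1)
    } else {
      comps <- it
    }
    for (cmp in comps)
      out[[length(out) + 1L]] <- parse_lipid_name(paste0(prefix, "(", cmp, ")"))
  }
  out
}

#' Parse a vector of lipid column headers
#'
#' Vectorised, non-throwing front end to [parse_lipid_name()] used on table
#' headers: malformed names and unknown class codes are collected rather than
#' raised, so a whole header row can be validated in one pass.
#'
#' @param names Character vector of column headers.
#' @return A data.frame with one row per header: \code{name} (canonical
#'   formatting where parseable, input otherwise), \code{class_code},
#'   \code{ether}, \code{oxidized}, \code{total_carbons},
#'   \code{total_double_bonds}, \code{parseable}, \code{known}.
#' @export
parse_lipid_names <- function(names) {
  rows <- lapply(names, function(nm) {
    p <- tryCatch(suppressWarnings(parse_lipid_name(nm)), error = function(e) NULL)
    if (is.null(p)) {
      data.frame(name = nm, class_code = NA_character_, ether = NA,
                 oxidized = NA, total_carbons = NA_integer_,
                 total_double_bonds = NA_integer_, parseable = FALSE,
                 known = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(name = format_lipid_name(p), class_code = p$class_code,
                 ether = p$ether, oxidized = p$oxidized,
                 total_carbons = p$total_carbons,
                 total_double_bonds = p$total_double_bonds, parseable = TRUE,
                 known = p$known, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
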