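#' Read and write Newick timetrees
#'
#' Thin, validating wrappers around ape's Newick support. `read_newick()`
#' accepts either a file path or a literal Newick string, checks the
#' string for balanced parentheses before parsing (reporting the character
#' offset of the first imbalance), and validates the result as a rooted
#' timetree with unique tip labels and non-negative branch lengths (My).
#' `write_newick()` serialises with enough digits that a round trip
#' preserves branch lengths to well below 1e-9 My.
#'
#' @param x a file path, or a string containing a Newick description
#'   (anything holding a `;`).
#' @return `read_newick()`: an ape `phylo`; `write_newick()`: the Newick
#'   string, invisibly if written to a file.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(tr)
#' @export
read_newick <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    stop("'x' must be a single path or Newick string", call. = FALSE)
  }
  txt <- if (grepl(";", x, fixed = TRUE)) x else {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  check_newick_syntax(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  check_timetree(tree)
  tree
}

# Balanced-parenthesis scan with character positions, ignoring quoted labels.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at character ", i,
             call. = FALSE)
      }
    }
  }
  if (quoted) stop("malformed Newick: unterminated quoted label",
                   call. = FALSE)
  if (depth > 0L) {
    stop("malformed Newick: ", depth, " unmatched '(' by character ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree an ape `phylo` timetree.
#' @param path optional output file; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  check_timetree(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Shared TSV reader: header, tab-separated, '#' comment lines ignored.
read_tsv_strict <- function(path, required) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read trait observations from a long-format TSV
#'
#' Expects columns `taxon`, `metric`, `value`; `#`-prefixed comment lines
#' are ignored and an empty `value` cell means missing. Duplicate
#' (taxon, metric) rows are an error rather than silently collapsed.
#'
#' @param path TSV file.
#' @return a named list with one named numeric vector per metric
#'   (`NA` = missing), suitable for [complexity_through_time()].
#' @export
read_trait_table <- function(path) {
  df <- read_tsv_strict(path, c("taxon", "metric", "value"))
  df$value <- as.numeric(df$value)
  dup <- duplicated(df[, c("taxon", "metric")])
  if (any(dup)) {
    stop("duplicate taxon/metric row(s): ",
         paste(unique(paste(df$taxon[dup], df$metric[dup], sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$metric), function(d) {
    v <- d$value
    names(v) <- d$taxon
    v
  })
  out[unique(df$metric)]
}

#' Read posterior node-age summaries from a TSV
#'
#' Expects columns `label`, `mean_ga`, `hpd_older_ga`, `hpd_younger_ga`
#' (ages in Ga). Each row is validated by [node_estimate()].
#'
#' @param path TSV file.
#' @return a named list of `node_estimate` objects.
#' @export
read_node_estimates <- function(path) {
  df <- read_tsv_strict(path, c("label", "mean_ga", "hpd_older_ga",
                                "hpd_younger_ga"))
  if (anyDuplicated(df$label)) {
    stop("duplicate node label(s) in ", basename(path), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    node_estimate(df$label[i], df$mean_ga[i], df$hpd_older_ga[i],
                  df$hpd_younger_ga[i])
  })
  names(out) <- df$label
  out
}

#' Read fossil minimum ages from a TSV
#'
#' Expects columns `name`, `min_age_ga`.
#'
#' @param path TSV file.
#' @return a named list of `fossil_evidence` objects.
#' @export
read_fossils <- function(path) {
  df <- read_tsv_strict(path, c("name", "min_age_ga"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    fossil_evidence(df$name[i], df$min_age_ga[i])
  })
  names(out) <- df$name
  out
}

#' Read a table of published node ages from a TSV
#'
#' Expects columns `node_label`, `age_ga`, `year`, `relaxed_clock` (0/1),
#' `source_id`, `topology_id`; `#` comment lines are ignored.
#'
#' @param path TSV file.
#' @return a `published_times` table (see [published_times()]).
#' @export
read_published_times <- function(path) {
  df <- read_tsv_strict(path, c("node_label", "age_ga", "year",
                                "relaxed_clock", "source_id", "topology_id"))
  published_times(df$node_label, df$age_ga, df$year,
                  as.logical(as.integer(df$relaxed_clock)),
                  df$source_id, df$topology_id)
}

#' Read literature-screening rules from a YAML file
#'
#' Recognised keys mirror [filter_rules()]: `min_year`,
#' `require_relaxed_clock`, `fossil_minima` (a mapping node label -> Ga)
#' and `drop_redundant`; omitted keys take the defaults.
#'
#' @param path YAML file.
#' @return a `filter_rules` object.
#' @export
read_filter_rules <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("min_year", "require_relaxed_clock", "fossil_minima",
             "drop_redundant")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown rule key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- filter_rules()
  args <- utils::modifyList(unclass(defaults), y)
  do.call(filter_rules, args)
}

#' Write a data frame as a plain TSV
#'
#' Deterministic tab-separated output (no quoting, no row names) used for
#' per-node complexity tables and curves.
#'
#' @param df a data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
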