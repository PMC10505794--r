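#' Construct a table of published node-age estimates
#'
#' A `published_times` table holds one row per literature estimate of a
#' node age, in the style of a TimeTree divergence-time search: the node it
#' dates, the point estimate in Ga, the publication year, whether the study
#' used a relaxed molecular clock, and identifiers for the study and for the
#' published tree (so that repeat reports of the same tree can be
#' recognised as redundant).
#'
#' @param node_label character, the named divergence each estimate dates.
#' @param age numeric, point estimate in Ga; must be positive.
#' @param year integer publication year; must be after 1900.
#' @param relaxed_clock logical, whether a relaxed clock was used.
#' @param source_id character study identifier.
#' @param topology_id character identifier of the published tree.
#' @return a `data.frame` of class `published_times`.
#' @seealso [filter_published_times()], [simulate_published_times()]
#' @examples
#' published_times("LUCA", c(4.29, 4.33), c(2018, 2021), TRUE,
#'                 c("s1", "s2"), c("t1", "t2"))
#' @export
published_times <- function(node_label, age, year, relaxed_clock,
                            source_id, topology_id) {
  out <- data.frame(
    node_label = as.character(node_label),
    age = as.numeric(age),
    year = as.integer(year),
    relaxed_clock = as.logical(relaxed_clock),
    source_id = as.character(source_id),
    topology_id = as.character(topology_id),
    stringsAsFactors = FALSE
  )
  validate_published_times(out)
}

validate_published_times <- function(x) {
  need <- c("node_label", "age", "year", "relaxed_clock",
            "source_id", "topology_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("published times table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$age)) || any(x$age <= 0)) {
    stop("published ages must be positive and finite (Ga)", call. = FALSE)
  }
  if (any(is.na(x$year)) || any(x$year <= 1900)) {
    stop("publication years must be integers after 1900", call. = FALSE)
  }
  if (any(is.na(x$relaxed_clock))) {
    stop("relaxed_clock must be TRUE or FALSE for every record", call. = FALSE)
  }
  class(x) <- c("published_times", "data.frame")
  x
}

#' Literature-screening rules for published node ages
#'
#' Encodes the screening applied to a collection of published divergence
#' times before a consensus calibration is formed: drop estimates published
#' before `min_year` (older studies predate modern methods and datasets),
#' drop strict-clock estimates when `require_relaxed_clock`, drop estimates
#' that conflict with a fossil minimum at a listed node (by default the
#' 0.89 Ga minimum implied by a putative 890-My-old fossil sponge for the
#' Metazoa crown and its ancestral nodes), and drop redundant records —
#' repeat publications of the same tree by the same study for the same node
#' — keeping the most recent.
#'
#' @param min_year integer; earliest admissible publication year.
#' @param require_relaxed_clock logical; drop strict-clock estimates?
#' @param fossil_minima named numeric vector, node label -> minimum age (Ga).
#'   Applies only to the listed labels; estimates strictly younger than the
#'   minimum are dropped.
#' @param drop_redundant logical; deduplicate on
#'   (source_id, topology_id, node_label), keeping the most recent year?
#' @return a list of class `filter_rules`.
#' @examples
#' filter_rules(min_year = 2005)
#' @export
filter_rules <- function(min_year = 2000,
                         require_relaxed_clock = TRUE,
                         fossil_minima = c("Metazoa-crown-and-ancestors" = 0.89),
                         drop_redundant = TRUE) {
  fossil_minima <- unlist(fossil_minima)
  if (length(fossil_minima) &&
      (is.null(names(fossil_minima)) || any(!nzchar(names(fossil_minima))))) {
    stop("'fossil_minima' must be a named vector (node label -> Ga)",
         call. = FALSE)
  }
  if (any(fossil_minima <= 0)) {
    stop("fossil minima must be positive (Ga)", call. = FALSE)
  }
  structure(
    list(min_year = as.integer(min_year),
         require_relaxed_clock = isTRUE(require_relaxed_clock),
         fossil_minima = fossil_minima,
         drop_redundant = isTRUE(drop_redundant)),
    class = "filter_rules"
  )
}

#' Screen published node ages against literature-quality rules
#'
#' Applies, in order: the publication-year cutoff, the relaxed-clock
#' requirement, fossil-minimum consistency at the nodes listed in
#' `rules$fossil_minima`, and redundancy removal (at most one record per
#' `(source_id, topology_id, node_label)`, keeping the most recent year;
#' ties keep the first record). Input order is preserved among survivors.
#' An empty result is legal; the filter is idempotent.
#'
#' @param records a `published_times` table (see [published_times()]).
#' @param rules a `filter_rules` object.
#' @return the surviving rows, still a `published_times` table.
#' @examples
#' x <- published_times("LUCA", c(4.3, 4.2), c(1999, 2015), TRUE,
#'                      c("a", "b"), c("t1", "t2"))
#' filter_published_times(x) # drops the 1999 record
#' @export
filter_published_times <- function(records, rules = filter_rules()) {
  records <- validate_published_times(as.data.frame(records))
  if (!inherits(rules, "filter_rules")) {
    stop("'rules' must be built with filter_rules()", call. = FALSE)
  }
  keep <- records$year >= rules$min_year
  if (rules$require_relaxed_clock) keep <- keep & records$relaxed_clock
  if (length(rules$fossil_minima)) {
    hit <- match(records$node_label, names(rules$fossil_minima))
    constrained <- !is.na(hit)
    keep[constrained] <-
      keep[constrained] &
      records$age[constrained] >= rules$fossil_minima[hit[constrained]]
  }
  out <- records[keep, , drop = FALSE]
  if (rules$drop_redundant && nrow(out) > 1L) {
    key <- paste(out$source_id, out$topology_id, out$node_label, sep = "\r")
    best <- tapply(seq_len(nrow(out)), key, function(i) {
      i[which.max(out$year[i])]
    })
    out <- out[sort(unname(unlist(best))), , drop = FALSE]
  }
  rownames(out) <- NULL
  validate_published_times(out)
}

# Oldest defensible age: the age of the Earth (Ga).
.EARTH_AGE_GA <- 4.567

#' Consensus calibration from a sample of published node ages
#'
#' Summarises the filtered published estimates of one node as a uniform
#' calibration density whose bounds are the two-sided `confidence`-level
#' confidence interval of the mean published age, using Student-t quantiles:
#' `mean +/- t((1 + confidence)/2, n - 1) * sd / sqrt(n)`. Student-t rather
#' than normal quantiles are used because per-node study counts are small
#' (typically 2–28). Bounds are clamped to the physically meaningful range
#' `[0, 4.567]` Ga (the age of the Earth) with a warning when clamping
#' occurs.
#'
#' @param node_label character, the node being calibrated.
#' @param ages numeric vector of published ages in Ga; at least two.
#' @param confidence confidence level in (0, 1); default 0.99.
#' @return an object of class `consensus_calibration`: a list with
#'   `node_label`, `older`, `younger` (Ga), `n_studies`, `mean_age`.
#' @examples
#' consensus_calibration("LUCA", c(4.28, 4.30, 4.33))
#' @export
consensus_calibration <- function(node_label, ages, confidence = 0.99) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L) {
    stop("consensus calibration for '", node_label,
         "' needs at least 2 published ages (insufficient studies)",
         call. = FALSE)
  }
  if (any(!is.finite(ages)) || any(ages <= 0)) {
    stop("published ages must be positive and finite (Ga)", call. = FALSE)
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must lie in (0, 1)", call. = FALSE)
  }
  n <- length(ages)
  m <- mean(ages)
  half <- qt((1 + confidence) / 2, df = n - 1L) * sd(ages) / sqrt(n)
  older <- m + half
  younger <- m - half
  if (older > .EARTH_AGE_GA || younger < 0) {
    warning("consensus interval for '", node_label,
            "' exceeds [0, ", .EARTH_AGE_GA, "] Ga; bounds clamped",
            call. = FALSE)
    older <- min(older, .EARTH_AGE_GA)
    younger <- max(younger, 0)
  }
  structure(
    list(node_label = as.character(node_label),
         older = older, younger = younger,
         n_studies = n, mean_age = m),
    class = "consensus_calibration"
  )
}

#' @export
print.consensus_calibration <- function(x, ...) {
  cat(sprintf("Consensus calibration: %s\n", x$node_label))
  cat(sprintf("  uniform(%.2f, %.2f) Ga  (mean %.2f, n = %d studies)\n",
              x$younger, x$older, x$mean_age, x$n_studies))
  invisible(x)
}

#' Consensus calibrations for every node in a published-times table
#'
#' Convenience pipeline: screen `times` with `rules`, then build one
#' [consensus_calibration()] per node label with at least two surviving
#' estimates. Nodes left with fewer than two estimates are dropped with a
#' warning, since no dispersion of the mean can be estimated for them.
#'
#' @param times a `published_times` table.
#' @param rules a `filter_rules` object.
#' @param confidence confidence level passed through; default 0.99.
#' @return a list of `consensus_calibration` objects, in first-appearance
#'   order of the surviving node labels.
#' @export
consensus_calibrations <- function(times, rules = filter_rules(),
                                   confidence = 0.99) {
  kept <- filter_published_times(times, rules)
  labs <- unique(kept$node_label)
  out <- list()
  for (lab in labs) {
    ages <- kept$age[kept$node_label == lab]
    if (length(ages) < 2L) {
      warning("node '", lab, "' has fewer than 2 estimates after filtering; ",
              "no consensus calibration emitted", call. = FALSE)
      next
    }
    out[[lab]] <- consensus_calibration(lab, ages, confidence)
  }
  out
}

#' Serialise consensus calibrations
#'
#' Two dialects: `"tsv"` writes a tab-separated table with the familiar
#' calibration-table layout (node, older and younger boundary in Ga to two
#' decimals, number of studies); `"mrbayes-uniform"` writes one uniform
#' calibration statement per node,
#' `calibrate <node> = uniform(<younger>, <older>);`, ready to paste into a
#' dating configuration block. [parse_calibration_table()] inverts both.
#'
#' @param calibrations non-empty list of `consensus_calibration` objects.
#' @param dialect `"tsv"` or `"mrbayes-uniform"`.
#' @param digits decimal places used for the bounds; default 2, matching
#'   conventional reporting in Ga.
#' @return a single character string.
#' @examples
#' cal <- consensus_calibration("LUCA", c(4.28, 4.30, 4.32))
#' cat(emit_calibration_table(list(cal), "tsv"))
#' @export
emit_calibration_table <- function(calibrations,
                                   dialect = c("tsv", "mrbayes-uniform"),
                                   digits = 2) {
  dialect <- match.arg(dialect)
  if (!length(calibrations)) {
    stop("no calibrations to emit", call. = FALSE)
  }
  if (inherits(calibrations, "consensus_calibration")) {
    calibrations <- list(calibrations)
  }
  ok <- vapply(calibrations, inherits, logical(1), "consensus_calibration")
  if (!all(ok)) {
    stop("all entries must be consensus_calibration objects", call. = FALSE)
  }
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  if (dialect == "tsv") {
    header <- "node\tolder_ga\tyounger_ga\tn_studies"
    rows <- vapply(calibrations, function(cal) {
      paste(cal$node_label, fmt(cal$older), fmt(cal$younger), cal$n_studies,
            sep = "\t")
    }, character(1))
    paste0(paste(c(header, rows), collapse = "\n"), "\n")
  } else {
    rows <- vapply(calibrations, function(cal) {
      sprintf("calibrate %s = uniform(%s, %s);",
              cal$node_label, fmt(cal$younger), fmt(cal$older))
    }, character(1))
    paste0(paste(rows, collapse = "\n"), "\n")
  }
}

#' @rdname emit_calibration_table
#' @param text output of [emit_calibration_table()].
#' @return for `parse_calibration_table()`, a list of
#'   `consensus_calibration` objects (with `mean_age` set to the interval
#'   midpoint, the only summary the serialised form retains; `n_studies` is
#'   `NA` for the MrBayes dialect, which does not carry it).
#' @export
parse_calibration_table <- function(text,
                                    dialect = c("tsv", "mrbayes-uniform")) {
  dialect <- match.arg(dialect)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (dialect == "tsv") {
    if (length(lines) < 2L) {
      stop("calibration TSV has no data rows", call. = FALSE)
    }
    df <- read.table(text = text, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      structure(
        list(node_label = df$node[i],
             older = df$older_ga[i], younger = df$younger_ga[i],
             n_studies = as.integer(df$n_studies[i]),
             mean_age = (df$older_ga[i] + df$younger_ga[i]) / 2),
        class = "consensus_calibration"
      )
    })
  } else {
    pat <- "^calibrate (.+) = uniform\\(([-0-9.eE]+), ([-0-9.eE]+)\\);$"
    bad <- !grepl(pat, lines)
    if (any(bad)) {
      stop("unparseable calibration statement: ", lines[which(bad)[1]],
           call. = FALSE)
    }
    lapply(lines, function(ln) {
      m <- regmatches(ln, regexec(pat, ln))[[1]]
      younger <- as.numeric(m[3]); older <- as.numeric(m[4])
      structure(
        list(node_label = m[2], older = older, younger = younger,
             n_studies = NA_integer_, mean_age = (older + younger) / 2),
        class = "consensus_calibration"
      )
    })
  }
}
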