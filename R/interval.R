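#' Posterior summary of a dated divergence
#'
#' Holds the posterior mean and 95\% highest-posterior-density (HPD) limits
#' of a node age, as printed in a dating study — e.g. the divergence of
#' eukaryotes from their last bacterial common ancestor (LBCA-K), from
#' their last archaeal common ancestor (LACA-K), or the eukaryote crown
#' node (LECA).
#'
#' @param label node name.
#' @param mean posterior mean age (Ga).
#' @param hpd_older,hpd_younger older and younger 95\% HPD limits (Ga);
#'   must bracket the mean and be positive.
#' @return an object of class `node_estimate`.
#' @examples
#' node_estimate("LECA", 1.65, 1.79, 1.45)
#' @export
node_estimate <- function(label, mean, hpd_older, hpd_younger) {
  if (!(hpd_older >= mean && mean >= hpd_younger && hpd_younger > 0)) {
    stop("node estimate '", label,
         "' must satisfy hpd_older >= mean >= hpd_younger > 0",
         call. = FALSE)
  }
  structure(list(label = as.character(label), mean = as.numeric(mean),
                 hpd_older = as.numeric(hpd_older),
                 hpd_younger = as.numeric(hpd_younger)),
            class = "node_estimate")
}

#' @export
print.node_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f (%.2f-%.2f) Ga\n",
              x$label, x$mean, x$hpd_older, x$hpd_younger))
  invisible(x)
}

#' Fossil evidence with a minimum age
#'
#' @param name fossil (or fossil assemblage) name.
#' @param min_age minimum age in Ga; must be positive.
#' @return an object of class `fossil_evidence`.
#' @examples
#' fossil_evidence("earliest uncontested eukaryotes", 1.62)
#' @export
fossil_evidence <- function(name, min_age) {
  if (!is.numeric(min_age) || min_age <= 0) {
    stop("fossil minimum age must be positive (Ga)", call. = FALSE)
  }
  structure(list(name = as.character(name), min_age = as.numeric(min_age)),
            class = "fossil_evidence")
}

#' An ordered deep-time interval
#'
#' @param older,younger bounds in Ga; `older` must exceed `younger`.
#' @param mode `"conservative"` or `"core"`.
#' @return an object of class `time_interval`.
#' @examples
#' time_interval(2.19, 1.45, "conservative")
#' @export
time_interval <- function(older, younger, mode = c("conservative", "core")) {
  mode <- match.arg(mode)
  if (!(older > younger)) {
    stop("interval bounds crossed or degenerate: older (", older,
         ") must exceed younger (", younger, ")", call. = FALSE)
  }
  structure(list(older = as.numeric(older), younger = as.numeric(younger),
                 mode = mode),
            class = "time_interval")
}

#' @export
print.time_interval <- function(x, ...) {
  cat(sprintf("%s interval: %.2f-%.2f Ga (width %.2f Ga)\n",
              x$mode, x$older, x$younger, x$older - x$younger))
  invisible(x)
}

#' The Great Oxidation Event as core and conservative intervals
#'
#' Defaults follow the geochemical proxy literature: a core interval of
#' 2.43–2.22 Ga from the consensus of environmental proxy dates, and a
#' conservative envelope of 3.01–1.77 Ga once confidence intervals on the
#' proxies (nonzero I/(Ca+Mg) at the old end, redox-sensitive detrital
#' minerals at the young end) are admitted. Supplied as configuration so
#' alternative proxy sets can be used.
#'
#' @param core_older,core_younger core bounds (Ga).
#' @param conservative_older,conservative_younger conservative bounds (Ga).
#' @return an object of class `goe_interval`.
#' @examples
#' goe_interval()
#' @export
goe_interval <- function(core_older = 2.43, core_younger = 2.22,
                         conservative_older = 3.01,
                         conservative_younger = 1.77) {
  ok <- conservative_older >= core_older &&
    core_older > core_younger &&
    core_younger >= conservative_younger
  if (!ok) {
    stop("GOE bounds must satisfy conservative_older >= core_older > ",
         "core_younger >= conservative_younger", call. = FALSE)
  }
  structure(list(core_older = core_older, core_younger = core_younger,
                 conservative_older = conservative_older,
                 conservative_younger = conservative_younger),
            class = "goe_interval")
}

#' Older boundary of the eukaryogenesis interval
#'
#' If eukaryogenesis resulted from an archaeal host acquiring a bacterial
#' endosymbiont, both partners' divergences from their closest living
#' relatives predate the fusion, so the *younger* of the two divergences is
#' the tightest defensible older limit. The node with the younger posterior
#' mean is selected; `mode = "conservative"` returns its older 95\% HPD
#' limit (avoiding false precision), `mode = "core"` returns its posterior
#' mean.
#'
#' @param lbcak,lacak `node_estimate`s for the bacterial- and
#'   archaeal-relative divergences.
#' @param mode `"conservative"` or `"core"`.
#' @return the boundary age in Ga.
#' @examples
#' lb <- node_estimate("LBCA-K", 2.04, 2.19, 1.89)
#' la <- node_estimate("LACA-K", 2.58, 2.74, 2.38)
#' older_boundary(lb, la, "conservative") # 2.19
#' older_boundary(lb, la, "core")         # 2.04
#' @export
older_boundary <- function(lbcak, lacak, mode = c("conservative", "core")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lbcak, "node_estimate"), inherits(lacak, "node_estimate"))
  pick <- if (lbcak$mean <= lacak$mean) lbcak else lacak
  if (mode == "conservative") pick$hpd_older else pick$mean
}

#' Younger boundary of the eukaryogenesis interval
#'
#' Eukaryogenesis must have concluded by the eukaryote crown node (LECA),
#' so LECA bounds the interval from below. `mode = "conservative"` returns
#' LECA's younger 95\% HPD limit; `mode = "core"` returns its older HPD
#' limit (the probable lower edge of the interval). With
#' `include_fossil = TRUE`, unambiguous eukaryotic fossils older than the
#' phylogenetic value tighten the boundary to the oldest fossil minimum.
#' Fossil inclusion defaults off: the headline intervals exclude the
#' 1.62 Ga fossil and use it only as an after-the-fact test via
#' [fossil_margin()].
#'
#' @param leca `node_estimate` for LECA.
#' @param fossils list of `fossil_evidence` objects (may be empty).
#' @param mode `"conservative"` or `"core"`.
#' @param include_fossil take the max over fossils and the phylogenetic
#'   value? Default `FALSE`.
#' @return the boundary age in Ga.
#' @examples
#' le <- node_estimate("LECA", 1.65, 1.79, 1.45)
#' younger_boundary(le, mode = "conservative")                 # 1.45
#' younger_boundary(le, mode = "core")                         # 1.79
#' younger_boundary(le, list(fossil_evidence("euk", 1.62)),
#'                  "conservative", include_fossil = TRUE)     # 1.62
#' @export
younger_boundary <- function(leca, fossils = list(),
                             mode = c("conservative", "core"),
                             include_fossil = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(leca, "node_estimate"))
  if (inherits(fossils, "fossil_evidence")) fossils <- list(fossils)
  value <- if (mode == "conservative") leca$hpd_younger else leca$hpd_older
  if (include_fossil && length(fossils)) {
    mins <- vapply(fossils, function(f) {
      stopifnot(inherits(f, "fossil_evidence"))
      f$min_age
    }, numeric(1))
    value <- max(value, mins)
  }
  value
}

#' Assemble the eukaryogenesis interval
#'
#' Composes [older_boundary()] and [younger_boundary()] into a
#' [time_interval()]. Crossed bounds (older <= younger) signal inconsistent
#' inputs and raise an error.
#'
#' @inheritParams older_boundary
#' @inheritParams younger_boundary
#' @return a `time_interval`.
#' @examples
#' lb <- node_estimate("LBCA-K", 2.04, 2.19, 1.89)
#' la <- node_estimate("LACA-K", 2.58, 2.74, 2.38)
#' le <- node_estimate("LECA", 1.65, 1.79, 1.45)
#' eukaryogenesis_interval(lb, la, le, mode = "conservative") # 2.19-1.45 Ga
#' eukaryogenesis_interval(lb, la, le, mode = "core")         # 2.04-1.79 Ga
#' @export
eukaryogenesis_interval <- function(lbcak, lacak, leca, fossils = list(),
                                    mode = c("conservative", "core"),
                                    include_fossil = FALSE) {
  mode <- match.arg(mode)
  older <- older_boundary(lbcak, lacak, mode)
  younger <- younger_boundary(leca, fossils, mode, include_fossil)
  if (older <= younger) {
    stop("inconsistent inputs: older boundary (", older,
         " Ga) does not exceed younger boundary (", younger, " Ga)",
         call. = FALSE)
  }
  time_interval(older, younger, mode)
}

#' Position of a fossil relative to an interval's younger bound
#'
#' `delta = fossil$min_age - interval$younger`: positive when the fossil is
#' older than the younger boundary (the fossil pre-dates the bound),
#' negative when it falls outside the interval on the young side. `inside`
#' reports whether the fossil minimum lies within the interval.
#'
#' @param interval a `time_interval`.
#' @param fossil a `fossil_evidence`.
#' @return a list with `delta` (Ga) and `inside` (logical).
#' @examples
#' cons <- time_interval(2.19, 1.45, "conservative")
#' fossil_margin(cons, fossil_evidence("euk", 1.62)) # delta 0.17, inside
#' @export
fossil_margin <- function(interval, fossil) {
  stopifnot(inherits(interval, "time_interval"),
            inherits(fossil, "fossil_evidence"))
  delta <- fossil$min_age - interval$younger
  inside <- fossil$min_age >= interval$younger &&
    fossil$min_age <= interval$older
  list(delta = delta, inside = inside)
}

#' Width of a time interval
#'
#' @param interval a `time_interval`.
#' @return `older - younger`, in Ga.
#' @examples
#' interval_width(time_interval(2.10, 0.91)) # 1.19
#' @export
interval_width <- function(interval) {
  stopifnot(inherits(interval, "time_interval"))
  interval$older - interval$younger
}

#' Fractional shortening of one interval width relative to another
#'
#' @param new_width,old_width widths in Ga; `old_width` must be positive.
#' @return `1 - new_width / old_width`; negative when the new interval is
#'   wider.
#' @examples
#' percent_shorter(0.74, 1.19) # ~0.378
#' @export
percent_shorter <- function(new_width, old_width) {
  if (!is.numeric(old_width) || old_width <= 0) {
    stop("'old_width' must be positive", call. = FALSE)
  }
  1 - new_width / old_width
}

#' Gap between the end of the GOE and the onset of an interval
#'
#' Expresses the lag between the close of the Great Oxidation Event (its
#' core younger bound) and the older bound of an interval as a fraction of
#' all time elapsed since the GOE ended:
#' `max(0, goe$core_younger - interval$older) / goe$core_younger`. Zero
#' when the interval overlaps or pre-dates the end of the GOE.
#'
#' @param goe a `goe_interval`.
#' @param interval a `time_interval`.
#' @return a fraction in `[0, 1]`.
#' @examples
#' goe_gap_fraction(goe_interval(), time_interval(2.04, 1.79, "core"))
#' @export
goe_gap_fraction <- function(goe, interval) {
  stopifnot(inherits(goe, "goe_interval"), inherits(interval, "time_interval"))
  max(0, goe$core_younger - interval$older) / goe$core_younger
}

#' Full interval report
#'
#' Runs the interval construction for one mode and gathers the derived
#' diagnostics into a single list, ready for JSON serialisation with
#' [write_interval_report()].
#'
#' @inheritParams eukaryogenesis_interval
#' @param goe a `goe_interval`; default [goe_interval()].
#' @return a list: `mode`, `older`, `younger`, `width` (Ga),
#'   `fossil_margins` (one entry per fossil with `name`, `min_age`,
#'   `delta`, `inside`) and `goe_gap_fraction`.
#' @export
interval_report <- function(lbcak, lacak, leca, fossils = list(),
                            mode = c("conservative", "core"),
                            include_fossil = FALSE,
                            goe = goe_interval()) {
  mode <- match.arg(mode)
  if (inherits(fossils, "fossil_evidence")) fossils <- list(fossils)
  iv <- eukaryogenesis_interval(lbcak, lacak, leca, fossils, mode,
                                include_fossil)
  margins <- lapply(fossils, function(f) {
    fm <- fossil_margin(iv, f)
    list(name = f$name, min_age = f$min_age,
         delta = fm$delta, inside = fm$inside)
  })
  list(mode = mode,
       older = iv$older,
       younger = iv$younger,
       width = interval_width(iv),
       fossil_margins = margins,
       goe_gap_fraction = goe_gap_fraction(goe, iv))
}

#' @rdname interval_report
#' @param report output of `interval_report()`.
#' @param path file to write; JSON is returned invisibly as a string too.
#' @export
write_interval_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(as.character(json))
}
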