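#' Value-set constants for a target instrument
#'
#' Preference-based index instruments have a bounded, discontinuous support:
#' a ceiling at 1 (full health / full capability), a tariff-specific floor,
#' and -- for the EQ-5D family -- a "gap" between 1 and the next-best
#' attainable index value inside which no observation can occur. A
#' `value_set` object records these anchors and constrains every likelihood,
#' prediction and simulation in the package.
#'
#' The built-in anchors are those of the English tariffs: EQ-5D-3L floor
#' -0.594 with next-best value 0.883; EQ-5D-5L floor -0.285 with next-best
#' value 0.951; ICECAP-O on \[0, 1\] with no gap. The feasible set is
#' `{ceiling}` together with the closed interval `[floor, gap_lower]`; the
#' open interval `(gap_lower, ceiling)` is unobservable.
#'
#' @param instrument one of `"eq5d3l"`, `"eq5d5l"`, `"icecapo"` (case
#'   insensitive), or an existing `value_set` object (returned unchanged).
#' @return An object of class `value_set`: a list with elements
#'   `instrument`, `floor`, `ceiling`, `gap_lower` and `has_gap`.
#' @examples
#' value_set("eq5d3l")
#' is_feasible(c(1, 0.95, -0.6), value_set("eq5d3l"))
#' @seealso [is_feasible()], [value_set_spec()], [read_value_sets()]
#' @export
value_set <- function(instrument) {
  if (inherits(instrument, "value_set")) return(instrument)
  if (!is.character(instrument) || length(instrument) != 1L)
    stop("'instrument' must be a single instrument id or a value_set object")
  id <- tolower(instrument)
  anchors <- .value_set_anchors()
  if (!id %in% names(anchors))
    stop("unsupported instrument '", instrument, "'; supported: ",
         paste(names(anchors), collapse = ", "))
  a <- anchors[[id]]
  value_set_spec(floor = a[["floor"]], gap_lower = a[["gap_lower"]],
                 ceiling = a[["ceiling"]], instrument = id)
}

.value_set_anchors <- function() {
  list(
    eq5d3l  = c(floor = -0.594, gap_lower = 0.883, ceiling = 1),
    eq5d5l  = c(floor = -0.285, gap_lower = 0.951, ceiling = 1),
    icecapo = c(floor = 0,      gap_lower = 1,     ceiling = 1)
  )
}

#' Construct a value-set specification from explicit anchors
#'
#' Builds a `value_set` from arbitrary anchors, for alternative tariffs or
#' for pushing the bounds far away so that censoring is inactive (the
#' uncensored normal-regression limit).
#'
#' @param floor lowest attainable index value.
#' @param gap_lower largest attainable value strictly below the ceiling
#'   (equal to `ceiling` when the instrument has no gap).
#' @param ceiling maximum attainable index value (1 for the built-ins).
#' @param instrument optional identifier carried along for labelling.
#' @return An object of class `value_set`.
#' @export
value_set_spec <- function(floor, gap_lower, ceiling = 1,
                           instrument = "custom") {
  stopifnot(is.numeric(floor), is.numeric(gap_lower), is.numeric(ceiling),
            length(floor) == 1L, length(gap_lower) == 1L,
            length(ceiling) == 1L)
  if (!(floor < gap_lower && gap_lower <= ceiling))
    stop("value set requires floor < gap_lower <= ceiling")
  structure(list(instrument = instrument,
                 floor = unname(floor),
                 ceiling = unname(ceiling),
                 gap_lower = unname(gap_lower),
                 has_gap = gap_lower < ceiling),
            class = "value_set")
}

#' @export
print.value_set <- function(x, ...) {
  cat("Value set:", x$instrument, "\n")
  cat(sprintf("  feasible: {%g} U [%g, %g]%s\n", x$ceiling, x$floor,
              x$gap_lower,
              if (x$has_gap)
                sprintf("   (open gap (%g, %g))", x$gap_lower, x$ceiling)
              else "   (no gap)"))
  invisible(x)
}

#' Feasibility of index values under a value set
#'
#' A value is feasible iff it equals the ceiling or lies in
#' `[floor, gap_lower]`. Values inside the open gap, below the floor or
#' above the ceiling are infeasible.
#'
#' @param y numeric vector of index values (finite).
#' @param spec a [value_set()] object or instrument id.
#' @return Logical vector of the same length as `y`.
#' @export
is_feasible <- function(y, spec) {
  spec <- value_set(spec)
  stopifnot(is.numeric(y))
  if (any(!is.finite(y))) stop("'y' must be finite")
  y == spec$ceiling | (y >= spec$floor & y <= spec$gap_lower)
}

#' Read value-set anchors from a key-value configuration file
#'
#' Allows alternative tariffs to be swapped in without code changes. The
#' file holds one `key = value` pair per line, keys of the form
#' `<instrument>.<anchor>` with anchors `floor`, `gap_lower` and optionally
#' `ceiling` (default 1); `#` starts a comment. A template with the
#' built-in English anchors ships at
#' `system.file("extdata", "value_sets.conf", package = "utilmap")`.
#'
#' @param path path to the configuration file.
#' @return Named list of `value_set` objects, one per instrument found.
#' @export
read_value_sets <- function(path) {
  kv <- read_keyvalue(path)
  ids <- unique(sub("\\..*$", "", names(kv)))
  out <- lapply(ids, function(id) {
    get1 <- function(anchor, default = NULL) {
      key <- paste0(id, ".", anchor)
      if (key %in% names(kv)) as.numeric(kv[[key]])
      else if (!is.null(default)) default
      else stop("value-set config missing key '", key, "'")
    }
    value_set_spec(floor = get1("floor"), gap_lower = get1("gap_lower"),
                   ceiling = get1("ceiling", 1), instrument = id)
  })
  names(out) <- ids
  out
}
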