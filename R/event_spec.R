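#' Define the event set for a subtype-and-stage model
#'
#' An event is a (biomarker, severity level) pair. In the z-score model each
#' biomarker contributes one event per z threshold (default z = 2, 5, 10,
#' roughly mild/moderate/severe abnormality relative to controls). In the
#' ordinal model each region contributes one event per severity-score step
#' (score 1..K-1; score 0 is the pre-event state). A model stage is a position
#' along a permutation of all events; stage 0 means no event has occurred.
#'
#' @param biomarkers character vector of biomarker/region names.
#' @param pathology character vector, one of \code{"amyloid"} or \code{"tau"}
#'   per biomarker (recycled if length 1).
#' @param levels numeric vector of z thresholds (z-score model) or the number
#'   of score levels K (ordinal model, giving events at scores 1..K-1). May be
#'   a list with one vector per biomarker.
#' @param kind \code{"zscore"} or \code{"ordinal"}.
#' @param z_max per-biomarker terminal z value anchoring the trajectory at the
#'   final stage; default is the top event level + 5 (z-score model only).
#' @return An object of class \code{event_spec}: the canonical event table
#'   (one row per event), per-biomarker levels, and pathology classes.
#' @export
event_spec <- function(biomarkers, pathology = "amyloid",
                       levels = c(2, 5, 10), kind = c("zscore", "ordinal"),
                       z_max = NULL) {
  kind <- match.arg(kind)
  B <- length(biomarkers)
  if (B == 0L) stop("at least one biomarker is required")
  if (anyDuplicated(biomarkers)) stop("duplicate biomarker names")
  pathology <- rep_len(pathology, B)
  if (!all(pathology %in% c("amyloid", "tau")))
    stop("pathology must be 'amyloid' or 'tau'")
  names(pathology) <- biomarkers

  if (kind == "ordinal" && length(levels) == 1L && !is.list(levels)) {
    # interpret scalar as K score levels -> events at scores 1..K-1
    levels <- seq_len(levels - 1L)
  }
  if (!is.list(levels)) levels <- rep(list(as.numeric(levels)), B)
  if (length(levels) != B) stop("levels must match number of biomarkers")
  names(levels) <- biomarkers
  for (b in biomarkers) {
    lv <- levels[[b]]
    if (length(lv) == 0L || any(diff(lv) <= 0))
      stop("event levels must be strictly increasing for biomarker ", b)
  }

  if (kind == "zscore") {
    if (is.null(z_max)) z_max <- vapply(levels, function(l) max(l) + 5, 0)
    z_max <- rep_len(z_max, B)
    names(z_max) <- biomarkers
    for (b in biomarkers)
      if (z_max[[b]] <= max(levels[[b]]))
        stop("z_max must exceed the top event level for biomarker ", b)
  } else z_max <- NULL

  events <- do.call(rbind, lapply(seq_len(B), function(i) {
    lv <- unname(levels[[i]])
    data.frame(biomarker = unname(biomarkers[i]),
               level_index = seq_along(lv),
               value = lv,
               pathology = unname(pathology[i]),
               stringsAsFactors = FALSE)
  }))
  events$event_id <- seq_len(nrow(events))
  events$label <- paste0(events$biomarker, ":", events$value)

  structure(list(kind = kind, biomarkers = biomarkers,
                 pathology = pathology, levels = levels, z_max = z_max,
                 events = events, n_events = nrow(events)),
            class = "event_spec")
}

#' @export
print.event_spec <- function(x, ...) {
  cat("Event specification (", x$kind, " model)\n", sep = "")
  cat("  ", length(x$biomarkers), " biomarkers, ", x$n_events, " events\n",
      sep = "")
  for (b in x$biomarkers)
    cat("  ", b, " [", x$pathology[[b]], "]: ",
        paste(x$levels[[b]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Check a sequence (integer permutation of event ids, position -> event) is
# valid: a permutation respecting within-biomarker level order.
is_valid_sequence <- function(spec, sequence) {
  if (length(sequence) != spec$n_events) return(FALSE)
  if (!setequal(sequence, seq_len(spec$n_events))) return(FALSE)
  pos <- order(sequence)  # pos[event_id] = position
  for (b in spec$biomarkers) {
    ids <- spec$events$event_id[spec$events$biomarker == b]
    if (length(ids) > 1L && any(diff(pos[ids]) <= 0)) return(FALSE)
  }
  TRUE
}

# Random valid permutation: random order, then sort each biomarker's events
# among their own positions by level.
random_sequence <- function(spec) {
  seqn <- sample(spec$n_events)
  pos <- order(seqn)
  for (b in spec$biomarkers) {
    ids <- spec$events$event_id[spec$events$biomarker == b]
    if (length(ids) > 1L) {
      p <- sort(pos[ids])
      seqn[p] <- ids
    }
  }
  seqn
}

# Positions (1..N) of each event under a sequence: pos[event_id] = position
event_positions <- function(sequence) order(sequence)

# Bounds for relocating the event at position `from`: valid insertion
# positions keep within-biomarker level order. Returns c(lo, hi) inclusive
# on the N-length sequence after removal+reinsertion.
relocation_bounds <- function(spec, sequence, from) {
  ev <- sequence[from]
  b <- spec$events$biomarker[ev]
  lvl <- spec$events$level_index[ev]
  ids <- spec$events$event_id[spec$events$biomarker == b]
  prev <- ids[match(lvl - 1L, spec$events$level_index[ids])]
  nxt <- ids[match(lvl + 1L, spec$events$level_index[ids])]
  # Work on the reduced sequence (event removed): insertion slot i places the
  # event before the i-th element of the reduced sequence.
  red <- sequence[-from]
  lo <- 1L; hi <- length(red) + 1L
  if (!is.na(prev)) lo <- which(red == prev) + 1L
  if (!is.na(nxt)) hi <- which(red == nxt)
  c(lo, hi)
}

# Move event at position `from` to insertion slot `to` (1..N) in the reduced
# sequence; returns the new sequence.
relocate_event <- function(sequence, from, to) {
  ev <- sequence[from]
  red <- sequence[-from]
  append(red, ev, after = to - 1L)
}
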