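#' Map a global Braak stage to a regional tau severity score
#'
#' Braak stages 0..VI are grouped into four regional tau severity scores,
#' with the grouping depending on the region class. Medial temporal lobe
#' (MTL) regions (entorhinal cortex, hippocampus) tolerate Braak 0/I/II as
#' normal age-related tau: 0/I/II -> 0, III/IV -> 1 (mild), V -> 2
#' (moderate), VI -> 3 (severe). Neocortical regions, which become abnormal
#' at later Braak stages, group 0/I/II/III -> 0, IV -> 1, V -> 2, VI -> 3.
#'
#' @param braak_label Braak stage: 0..6 or "0","I".."VI".
#' @param region_class \code{"MTL"} or \code{"neocortical"}.
#' @return integer severity score 0..3.
#' @export
map_braak <- function(braak_label, region_class = c("MTL", "neocortical")) {
  region_class <- match.arg(region_class)
  roman <- c("0", "I", "II", "III", "IV", "V", "VI")
  lab <- as.character(braak_label)
  idx <- match(toupper(lab), roman)
  num <- suppressWarnings(as.integer(lab))
  idx[is.na(idx) & !is.na(num) & num >= 0 & num <= 6] <-
    num[is.na(idx) & !is.na(num) & num >= 0 & num <= 6] + 1L
  if (any(is.na(idx)))
    stop("unknown Braak label(s): ",
         paste(unique(lab[is.na(idx)]), collapse = ", "))
  stage <- idx - 1L  # numeric 0..6
  if (region_class == "MTL")
    ifelse(stage <= 2L, 0L, ifelse(stage <= 4L, 1L,
                                   ifelse(stage == 5L, 2L, 3L)))
  else
    ifelse(stage <= 3L, 0L, ifelse(stage == 4L, 1L,
                                   ifelse(stage == 5L, 2L, 3L)))
}

#' Map a global CERAD rating to an amyloid severity score
#'
#' CERAD neuritic plaque ratings are used directly as four severity scores:
#' no AD -> 0, possible -> 1, probable -> 2, definite -> 3.
#'
#' @param cerad_label rating; matching is case-insensitive on the leading
#'   word ("no", "possible", "probable", "definite").
#' @return integer severity score 0..3.
#' @export
map_cerad <- function(cerad_label) {
  key <- tolower(sub("\\s.*$", "", trimws(as.character(cerad_label))))
  score <- match(key, c("no", "possible", "probable", "definite")) - 1L
  if (any(is.na(score)))
    stop("unknown CERAD label(s): ",
         paste(unique(cerad_label[is.na(score)]), collapse = ", "))
  score
}

# Gaussian KDE density evaluated at x given training points and bandwidth.
gauss_kde <- function(x, train, h) {
  vapply(x, function(xx) mean(stats::dnorm(xx, train, h)), 0)
}

scott_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) s <- max(abs(x), 1) * 1e-3
  s * n^(-1 / 5)
}

#' Fit a per-region KDE severity mixture
#'
#' Fits one Gaussian-kernel density per severity score level to the
#' continuous measures of subjects carrying that score, yielding the mixture
#' p(x | score = k, region) used to convert measures into score
#' probabilities. Bandwidths follow Scott's rule per level. Levels with
#' fewer than \code{min_count} training subjects are merged into the
#' adjacent level with the larger count for density fitting only; the score
#' retains its identity through the shared density.
#'
#' @param measures numeric vector of (residualized) measures.
#' @param scores integer severity scores 0..K-1, one per measure.
#' @param region region identifier (used in messages and stored).
#' @param K number of score levels (default \code{max(scores) + 1}).
#' @param min_count minimum training subjects per fitted density.
#' @return object of class \code{kde_mixture}.
#' @export
fit_kde_mixture <- function(measures, scores, region = "region",
                            K = NULL, min_count = 5L) {
  ok <- !is.na(measures) & !is.na(scores)
  measures <- measures[ok]; scores <- as.integer(scores[ok])
  if (is.null(K)) K <- max(scores) + 1L
  if (K < 2L) stop("need at least two score levels")
  counts <- tabulate(scores + 1L, K)
  # merge sparse levels into adjacent groups until all groups reach
  # min_count; groups are contiguous runs of score levels sharing a density
  group <- seq_len(K)
  repeat {
    gsizes <- tapply(counts, group, sum)
    small <- names(gsizes)[gsizes < min_count]
    if (!length(small)) break
    g <- as.integer(small[1])
    gs <- sort(unique(group))
    pos <- match(g, gs)
    neighbours <- c(if (pos > 1) gs[pos - 1], if (pos < length(gs))
      gs[pos + 1])
    if (!length(neighbours))
      stop("region ", region, ": level group ", g - 1L,
           " has fewer than ", min_count, " subjects and no neighbour ",
           "to merge with")
    sizes <- gsizes[as.character(neighbours)]
    target <- neighbours[which.max(sizes)]
    group[group == g] <- target
  }
  densities <- vector("list", K)
  bandwidths <- numeric(K)
  for (k in seq_len(K)) {
    members <- which(group == group[k]) - 1L  # score levels sharing density
    train <- measures[scores %in% members]
    h <- scott_bandwidth(train)
    densities[[k]] <- list(train = train, h = h)
    bandwidths[k] <- h
  }
  structure(list(region = region, K = K, densities = densities,
                 counts = counts, groups = group,
                 bandwidths = bandwidths, min_count = min_count),
            class = "kde_mixture")
}

#' Evaluate the K severity densities of a mixture
#'
#' @param mixture a \code{\link{fit_kde_mixture}} object.
#' @param x numeric vector of measures.
#' @return length(x) x K matrix of densities p(x | score = k).
#' @export
kde_density <- function(mixture, x) {
  out <- sapply(mixture$densities, function(d) gauss_kde(x, d$train, d$h))
  matrix(out, nrow = length(x), ncol = mixture$K)
}

#' @export
print.kde_mixture <- function(x, ...) {
  cat("KDE severity mixture for region '", x$region, "': K = ", x$K,
      ", level counts: ", paste(x$counts, collapse = "/"), "\n", sep = "")
  if (any(x$groups != seq_len(x$K)))
    cat("  (sparse levels merged; density groups: ",
        paste(x$groups, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Severity score probabilities from KDE mixtures
#'
#' Converts continuous measures into per-subject, per-region severity score
#' probabilities by normalizing the fitted severity densities:
#' P(score k) = p(m | k, region) / sum_k' p(m | k', region). Densities below
#' 1e-300 are floored before normalizing; if every level underflows the
#' subject receives a uniform 1/K row (with a warning), keeping the
#' normalizing denominator away from zero.
#'
#' @param measures n x R matrix of measures (columns named by region).
#' @param mixtures list of \code{\link{fit_kde_mixture}} objects, one per
#'   column of \code{measures}.
#' @return n x R x K probability array; every (subject, region) slice sums
#'   to 1. Region pathology classes may be attached by
#'   \code{\link{assemble_ordinal_input}}.
#' @export
score_probabilities <- function(measures, mixtures) {
  if (is.null(dim(measures)))
    measures <- matrix(measures, ncol = 1)
  R <- ncol(measures)
  if (length(mixtures) != R)
    stop("need one mixture per region (", R, " regions, ",
         length(mixtures), " mixtures)")
  if (any(is.na(measures))) {
    bad <- which(apply(is.na(measures), 1, any))
    stop("NaN/NA measures for subject row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  K <- mixtures[[1]]$K
  n <- nrow(measures)
  out <- array(0, dim = c(n, R, K),
               dimnames = list(rownames(measures), colnames(measures),
                               paste0("score", 0:(K - 1L))))
  floored <- 0L
  for (r in seq_len(R)) {
    d <- kde_density(mixtures[[r]], measures[, r])
    d <- pmax(d, 1e-300)
    all_floor <- apply(d <= 1e-300, 1, all)
    if (any(all_floor)) {
      d[all_floor, ] <- 1 / K
      floored <- floored + sum(all_floor)
    }
    out[, r, ] <- d / rowSums(d)
  }
  if (floored > 0L)
    warning(floored, " (subject, region) pairs underflowed all severity ",
            "densities; assigned uniform 1/K scores")
  out
}

#' Combine amyloid and tau score tensors for the ordinal model
#'
#' Concatenates two score-probability tensors (same subjects, disjoint
#' region sets) along the region axis, retaining the pathology class of each
#' region so that downstream early-window derivation can distinguish
#' amyloid from tau events.
#'
#' @param amyloid_tensor,tau_tensor n x R x K arrays from
#'   \code{\link{score_probabilities}}; \code{tau_tensor} may be NULL.
#' @return n x (Ra+Rt) x K array with attribute \code{"pathology"}.
#' @export
assemble_ordinal_input <- function(amyloid_tensor, tau_tensor = NULL) {
  if (is.null(tau_tensor)) {
    attr(amyloid_tensor, "pathology") <-
      rep("amyloid", dim(amyloid_tensor)[2])
    return(amyloid_tensor)
  }
  da <- dim(amyloid_tensor); dt <- dim(tau_tensor)
  if (da[1] != dt[1]) stop("subject mismatch between tensors")
  if (da[3] != dt[3]) stop("score-level mismatch between tensors")
  sa <- dimnames(amyloid_tensor)[[1]]; st <- dimnames(tau_tensor)[[1]]
  if (!is.null(sa) && !is.null(st) && !identical(sa, st))
    stop("subject mismatch between tensors")
  out <- array(0, dim = c(da[1], da[2] + dt[2], da[3]),
               dimnames = list(sa,
                               c(dimnames(amyloid_tensor)[[2]],
                                 dimnames(tau_tensor)[[2]]),
                               dimnames(amyloid_tensor)[[3]]))
  out[, seq_len(da[2]), ] <- amyloid_tensor
  out[, da[2] + seq_len(dt[2]), ] <- tau_tensor
  attr(out, "pathology") <- c(rep("amyloid", da[2]), rep("tau", dt[2]))
  out
}

#' Build an ordinal event spec from a score tensor
#'
#' @param tensor array from \code{\link{assemble_ordinal_input}} (or
#'   \code{\link{score_probabilities}}) with region dimnames and a
#'   \code{"pathology"} attribute.
#' @return an \code{\link{event_spec}} of kind \code{"ordinal"} with K-1
#'   events per region.
#' @export
event_spec_from_tensor <- function(tensor) {
  regions <- dimnames(tensor)[[2]]
  if (is.null(regions)) regions <- paste0("R", seq_len(dim(tensor)[2]))
  pathology <- attr(tensor, "pathology")
  if (is.null(pathology)) pathology <- rep("amyloid", length(regions))
  event_spec(regions, pathology, levels = dim(tensor)[3], kind = "ordinal")
}
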