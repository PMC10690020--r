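#' Construct a subtype-and-stage model from known sequences
#'
#' Builds a \code{sustain} model object directly from given event sequences
#' and fractions, without fitting — e.g. to stage subjects under a
#' ground-truth ordering or to reconstruct a serialized model.
#'
#' @param spec an \code{\link{event_spec}}.
#' @param sequences list of event-id permutations, one per subtype.
#' @param fractions subtype mixture fractions (default uniform).
#' @param sigma per-biomarker sd (z-score model).
#' @return object of class \code{sustain} (without MCMC samples beyond the
#'   given sequences).
#' @export
sustain_model <- function(spec, sequences, fractions = NULL, sigma = 1) {
  if (!is.list(sequences)) sequences <- list(sequences)
  for (s in sequences)
    if (!is_valid_sequence(spec, s))
      stop("invalid event sequence")
  C <- length(sequences)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  stopifnot(length(fractions) == C, abs(sum(fractions) - 1) < 1e-8)
  structure(list(kind = spec$kind, spec = spec, n_subtypes = C,
                 sequences = sequences, fractions = fractions,
                 samples = lapply(sequences, function(s)
                   matrix(s, nrow = 1)),
                 loglik = NA_real_, loglik_by_C = NA_real_,
                 sigma = sigma, n = NA_integer_,
                 config = list(), seed = NULL),
            class = "sustain")
}

#' Assign subjects to subtypes and stages
#'
#' Computes the joint posterior over (subtype, stage) for each subject,
#' proportional to the subtype fraction times the stage likelihood (uniform
#' stage prior). MAP assignments break ties toward the lower stage, then the
#' lower subtype index. Subjects whose MAP stage is 0 are flagged stage-zero
#' and given subtype label \code{"none"} (at stage 0 no event has occurred,
#' so the subtype is unidentifiable).
#'
#' @param model a fitted \code{\link{fit_sustain}} object.
#' @param data z-score matrix or score-probability array with the model's
#'   biomarkers.
#' @param subject_id optional subject identifiers (defaults to rownames or
#'   1..n).
#' @return object of class \code{sustain_placement}: a data.frame with
#'   \code{subject_id}, \code{map_subtype} (integer, NA at stage zero),
#'   \code{subtype_label}, \code{map_stage}, \code{stage_zero},
#'   \code{entropy} (posterior entropy, nats), plus the full posterior array
#'   (subjects x subtypes x stages) as attribute \code{"posterior"}.
#' @export
assign_subjects <- function(model, data, subject_id = NULL) {
  spec <- model$spec
  if (spec$kind == "zscore") {
    if (!all(spec$biomarkers %in% colnames(data)))
      stop("data is missing model biomarkers: ",
           paste(setdiff(spec$biomarkers, colnames(data)), collapse = ", "))
    data <- data[, spec$biomarkers, drop = FALSE]
  } else {
    if (dim(data)[2] != length(spec$biomarkers))
      stop("data region axis does not match model spec")
  }
  n <- data_n(data)
  if (is.null(subject_id))
    subject_id <- if (!is.null(rownames(data))) rownames(data)
                  else as.character(seq_len(n))
  C <- model$n_subtypes
  N <- spec$n_events
  post <- array(0, dim = c(n, C, N + 1L))
  for (c in seq_len(C)) {
    ll <- stage_loglik_matrix(data, spec, model$sequences[[c]], model$sigma)
    post[, c, ] <- log(model$fractions[c]) + ll
  }
  # normalize over (subtype, stage) jointly
  flat <- matrix(post, n, C * (N + 1L))
  m <- apply(flat, 1, max)
  p <- exp(flat - m)
  p <- p / rowSums(p)
  post <- array(p, dim = c(n, C, N + 1L))

  map_subtype <- integer(n); map_stage <- integer(n)
  for (j in seq_len(n)) {
    pj <- post[j, , , drop = FALSE]
    best <- -Inf; bc <- 1L; bs <- 0L
    for (s in 0:N) for (c in seq_len(C)) {
      v <- post[j, c, s + 1L]
      if (v > best + 1e-12) { best <- v; bc <- c; bs <- s }
      # ties resolved by loop order: lower stage first, then lower subtype
    }
    map_subtype[j] <- bc; map_stage[j] <- bs
  }
  stage_zero <- map_stage == 0L
  entropy <- apply(p, 1, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
  labels <- ifelse(stage_zero, "none", paste0("S", map_subtype))
  out <- data.frame(subject_id = subject_id,
                    map_subtype = ifelse(stage_zero, NA_integer_,
                                         map_subtype),
                    subtype_label = labels,
                    map_stage = map_stage,
                    stage_zero = stage_zero,
                    entropy = entropy,
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  class(out) <- c("sustain_placement", "data.frame")
  out
}

#' Positional variance diagram
#'
#' Empirical frequency with which each event occupies each sequence position
#' across MCMC samples: an events x positions matrix whose rows each sum
#' to 1. This is the standard visualization of ordering uncertainty in
#' event-based models.
#'
#' @param samples matrix of sequence samples (one sequence per row,
#'   position -> event id), e.g. \code{model$samples[[c]]}.
#' @param spec optional \code{\link{event_spec}} used to label rows.
#' @return N x N matrix of frequencies; rows are events, columns positions.
#' @export
positional_variance <- function(samples, spec = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  if (nrow(samples) == 0) stop("no sequence samples")
  N <- ncol(samples)
  pvd <- matrix(0, N, N)
  for (i in seq_len(nrow(samples)))
    pvd[cbind(samples[i, ], seq_len(N))] <- pvd[cbind(samples[i, ],
                                                      seq_len(N))] + 1
  pvd <- pvd / nrow(samples)
  if (!is.null(spec)) rownames(pvd) <- spec$events$label
  colnames(pvd) <- paste0("pos", seq_len(N))
  pvd
}
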