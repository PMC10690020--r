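# Sequence fitting: greedy ascent over event relocations, then Metropolis
# MCMC with the same relocation proposal. Both operate on the total (possibly
# responsibility-weighted) log marginal likelihood, via a precomputed
# likelihood context (ll_context) so candidate sequences are cheap to score.

# One greedy pass: for each event in random order, try all valid insertion
# slots and keep the best. Repeats until no improvement. Total log-likelihood
# is non-decreasing across iterations by construction.
greedy_ascent <- function(ctx, sequence, weights = NULL, max_passes = 50L) {
  ll <- ctx_total(ctx, sequence, weights)
  N <- ctx$spec$n_events
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (from in sample(N)) {
      bounds <- relocation_bounds(ctx$spec, sequence, from)
      best_ll <- ll; best_seq <- NULL
      for (to in seq.int(bounds[1], bounds[2])) {
        cand <- relocate_event(sequence, from, to)
        if (identical(cand, sequence)) next
        cand_ll <- ctx_total(ctx, cand, weights)
        if (cand_ll > best_ll + 1e-12) {
          best_ll <- cand_ll; best_seq <- cand
        }
      }
      if (!is.null(best_seq)) {
        sequence <- best_seq; ll <- best_ll; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = sequence, loglik = ll)
}

# Metropolis MCMC over sequences. Proposal: relocate one uniformly chosen
# event to a uniformly chosen valid slot. Returns thinned post-burn-in
# samples and the best sequence visited.
sequence_mcmc <- function(ctx, sequence, weights = NULL,
                          n_iter = 1e5, burn_in = 1e4, thin = 25L) {
  ll <- ctx_total(ctx, sequence, weights)
  best_seq <- sequence; best_ll <- ll
  N <- ctx$spec$n_events
  keep <- if (n_iter > burn_in)
    seq.int(burn_in + 1L, n_iter, by = thin) else integer(0)
  samples <- matrix(NA_integer_, length(keep), N)
  k <- 0L
  for (it in seq_len(n_iter)) {
    from <- sample.int(N, 1L)
    bounds <- relocation_bounds(ctx$spec, sequence, from)
    to <- if (bounds[1] >= bounds[2]) bounds[1]
          else sample.int(bounds[2] - bounds[1] + 1L, 1L) + bounds[1] - 1L
    cand <- relocate_event(sequence, from, to)
    if (!identical(cand, sequence)) {
      cand_ll <- ctx_total(ctx, cand, weights)
      if (log(stats::runif(1)) < cand_ll - ll) {
        sequence <- cand; ll <- cand_ll
        if (ll > best_ll) { best_ll <- ll; best_seq <- sequence }
      }
    }
    if (k < length(keep) && it == keep[k + 1L]) {
      k <- k + 1L
      samples[k, ] <- sequence
    }
  }
  list(best_sequence = best_seq, best_loglik = best_ll, samples = samples)
}

fit_single_ctx <- function(ctx, n_restarts = 25L,
                           mcmc = list(n_iter = 1e5, burn_in = 1e4),
                           weights = NULL, init = NULL) {
  thin <- if (is.null(mcmc$thin)) 25L else mcmc$thin
  best <- NULL
  starts <- replicate(n_restarts, random_sequence(ctx$spec),
                      simplify = FALSE)
  if (!is.null(init)) starts <- c(list(init), starts)
  if (!length(starts)) starts <- list(random_sequence(ctx$spec))
  for (s0 in starts) {
    g <- greedy_ascent(ctx, s0, weights)
    if (is.null(best) || g$loglik > best$loglik) best <- g
  }
  samples <- matrix(best$sequence, nrow = 1)
  if (!is.null(mcmc$n_iter) && mcmc$n_iter > 0) {
    mc <- sequence_mcmc(ctx, best$sequence, weights,
                        n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                        thin = thin)
    if (mc$best_loglik > best$loglik)
      best <- list(sequence = mc$best_sequence, loglik = mc$best_loglik)
    if (nrow(mc$samples) > 0) samples <- mc$samples
  }
  list(sequence = best$sequence, loglik = best$loglik, samples = samples)
}

#' Fit a single event sequence (one subtype)
#'
#' Greedy ascent (relocation-based hill climbing on the total log marginal
#' likelihood) from random valid permutations, followed by Metropolis MCMC
#' over sequences. The MAP sequence is the highest-likelihood sequence seen
#' across restarts and MCMC.
#'
#' @param data z-score matrix or score-probability array (see
#'   \code{\link{subject_marginal}}).
#' @param spec an \code{\link{event_spec}}.
#' @param n_restarts number of random greedy restarts.
#' @param mcmc list with \code{n_iter}, \code{burn_in} and optional
#'   \code{thin}; set \code{n_iter = 0} to skip MCMC (e.g. inside
#'   cross-validation).
#' @param sigma per-biomarker sd (z-score model).
#' @param weights optional per-subject weights (EM responsibilities).
#' @param seed integer seed; the fit is deterministic given data and seed.
#' @param init optional starting sequence (warm start) added to the
#'   restarts.
#' @return list with \code{sequence} (MAP), \code{loglik}, \code{samples}
#'   (thinned post-burn-in MCMC draws, one sequence per row).
#' @export
fit_single_subtype <- function(data, spec, n_restarts = 25L,
                               mcmc = list(n_iter = 1e5, burn_in = 1e4),
                               sigma = 1, weights = NULL, seed = NULL,
                               init = NULL) {
  if (data_n(data) < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  ctx <- ll_context(data, spec, sigma)
  fit_single_ctx(ctx, n_restarts, mcmc, weights, init)
}

# Mixture log-likelihood of all subjects under sequences/fractions:
# per-subject log sum_c f_c * marginal_c(j).
mixture_loglik_ctx <- function(ctx, sequences, fractions) {
  C <- length(sequences)
  LJ <- matrix(0, ctx$n, C)
  for (c in seq_len(C))
    LJ[, c] <- log(fractions[c]) + ctx_log_marginal(ctx, sequences[[c]])
  m <- LJ[cbind(seq_len(nrow(LJ)), max.col(LJ, ties.method = "first"))]
  per_subject <- m + log(rowSums(exp(LJ - m)))
  list(total = sum(per_subject), log_joint = LJ, per_subject = per_subject)
}

# EM refinement of a C-subtype model from initial sequences: alternate soft
# (or hard) responsibilities, weighted per-subtype sequence refits (warm
# started), and fraction updates, until the total log-likelihood improves
# by less than tol.
em_refine <- function(ctx, sequences, fractions = NULL,
                      tol = 1e-3, max_iter = 25L, frac_floor = 1e-3,
                      hard = FALSE) {
  C <- length(sequences)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  ml <- mixture_loglik_ctx(ctx, sequences, fractions)
  trace <- ml$total
  for (it in seq_len(max_iter)) {
    resp <- exp(ml$log_joint - ml$per_subject)
    if (hard) {
      hard_c <- max.col(resp, ties.method = "first")
      resp <- matrix(0, nrow(resp), C)
      resp[cbind(seq_len(nrow(resp)), hard_c)] <- 1
    }
    for (c in seq_len(C)) {
      g <- greedy_ascent(ctx, sequences[[c]], weights = resp[, c])
      sequences[[c]] <- g$sequence
    }
    fractions <- colMeans(resp)
    fractions <- pmax(fractions, frac_floor)
    fractions <- fractions / sum(fractions)
    ml <- mixture_loglik_ctx(ctx, sequences, fractions)
    trace <- c(trace, ml$total)
    if (ml$total - trace[length(trace) - 1L] < tol) break
  }
  list(sequences = sequences, fractions = fractions, loglik = ml$total,
       log_joint = ml$log_joint, per_subject = ml$per_subject,
       trace = trace)
}

#' Fit a subtype-and-stage model
#'
#' Fits C subtypes, each a maximum a posteriori event sequence with a
#' mixture fraction, by hierarchical construction: the C-subtype solution is
#' initialized by splitting each subtype of the (C-1)-subtype solution in
#' turn (random halves of its hard-assigned members, each half refit),
#' keeping the best-likelihood split after EM refinement (alternating soft
#' subject-to-subtype responsibilities, per-subtype sequence refits and
#' fraction updates until the total log-likelihood improves by less than
#' \code{tol}). MCMC sequence samples are then drawn per subtype on the
#' final hard assignment.
#'
#' @param data n x B z-score matrix (kind \code{"zscore"}) or n x R x K
#'   score probability array (kind \code{"ordinal"}).
#' @param spec an \code{\link{event_spec}} matching the data.
#' @param n_subtypes number of subtypes C.
#' @param n_restarts greedy restarts for the base (single-sequence) fits.
#' @param mcmc list(n_iter, burn_in, thin) for per-subtype MCMC.
#' @param sigma per-biomarker sd (z-score model).
#' @param n_splits random split attempts per parent subtype.
#' @param min_members minimum hard-assigned members per subtype; splits
#'   that collapse a subtype below this are rejected.
#' @param tol EM convergence tolerance on total log-likelihood.
#' @param hard_assignment use hard (classification) EM instead of soft.
#' @param seed integer seed; fits are deterministic given data and seed.
#' @return object of class \code{sustain}: MAP \code{sequences} (list),
#'   \code{fractions}, MCMC \code{samples} per subtype, total
#'   \code{loglik}, the \code{spec}, and the fitting configuration.
#' @seealso \code{\link{assign_subjects}}, \code{\link{positional_variance}},
#'   \code{\link{cross_validate_cvic}}
#' @export
fit_sustain <- function(data, spec, n_subtypes = 1L, n_restarts = 25L,
                        mcmc = list(n_iter = 1e5, burn_in = 1e4),
                        sigma = 1, n_splits = 3L, min_members = 5L,
                        tol = 1e-3, hard_assignment = FALSE, seed = NULL) {
  if (n_subtypes < 1L) stop("n_subtypes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ctx <- ll_context(data, spec, sigma)
  n <- ctx$n

  base <- fit_single_ctx(ctx, n_restarts, mcmc = list(n_iter = 0))
  sequences <- list(base$sequence)
  fractions <- 1
  loglik <- base$loglik
  loglik_by_C <- c(loglik)

  C <- 1L
  while (C < n_subtypes) {
    ml <- mixture_loglik_ctx(ctx, sequences, fractions)
    hard_c <- max.col(exp(ml$log_joint - ml$per_subject),
                      ties.method = "first")
    best_cand <- NULL
    for (parent in seq_len(C)) {
      members <- which(hard_c == parent)
      if (length(members) < 2L * min_members) next
      for (try in seq_len(n_splits)) {
        half <- sample(members, floor(length(members) / 2))
        other <- setdiff(members, half)
        if (length(half) < min_members || length(other) < min_members)
          next
        f1 <- fit_single_ctx(ctx_subset(ctx, half),
                             n_restarts = max(2L, n_restarts %/% 4L),
                             mcmc = list(n_iter = 0))
        f2 <- fit_single_ctx(ctx_subset(ctx, other),
                             n_restarts = max(2L, n_restarts %/% 4L),
                             mcmc = list(n_iter = 0))
        cand_seqs <- c(sequences[-parent],
                       list(f1$sequence, f2$sequence))
        em <- em_refine(ctx, cand_seqs, tol = tol,
                        hard = hard_assignment)
        post_hard <- max.col(exp(em$log_joint - em$per_subject),
                             ties.method = "first")
        if (min(tabulate(post_hard, length(cand_seqs))) < min_members)
          next
        if (is.null(best_cand) || em$loglik > best_cand$loglik)
          best_cand <- em
      }
    }
    if (is.null(best_cand))
      stop("no valid split found when growing from ", C, " to ", C + 1L,
           " subtypes (all candidate subtypes collapsed below ",
           "min_members)")
    sequences <- best_cand$sequences
    fractions <- best_cand$fractions
    loglik <- best_cand$loglik
    C <- C + 1L
    loglik_by_C <- c(loglik_by_C, loglik)
  }

  # MCMC per subtype on the final hard assignment
  ml <- mixture_loglik_ctx(ctx, sequences, fractions)
  hard_c <- max.col(exp(ml$log_joint - ml$per_subject),
                    ties.method = "first")
  samples <- vector("list", C)
  for (c in seq_len(C)) {
    members <- which(hard_c == c)
    if (length(members) < 2L) members <- seq_len(n)
    if (!is.null(mcmc$n_iter) && mcmc$n_iter > 0) {
      sub <- ctx_subset(ctx, members)
      mc <- sequence_mcmc(sub, sequences[[c]],
                          n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                          thin = if (is.null(mcmc$thin)) 25L
                                 else mcmc$thin)
      samples[[c]] <- mc$samples
      if (mc$best_loglik > ctx_total(sub, sequences[[c]]))
        sequences[[c]] <- mc$best_sequence
    } else samples[[c]] <- matrix(sequences[[c]], nrow = 1)
  }
  ml <- mixture_loglik_ctx(ctx, sequences, fractions)

  structure(list(kind = spec$kind, spec = spec, n_subtypes = C,
                 sequences = sequences, fractions = fractions,
                 samples = samples, loglik = ml$total,
                 loglik_by_C = loglik_by_C, sigma = sigma, n = n,
                 config = list(n_restarts = n_restarts, mcmc = mcmc,
                               n_splits = n_splits,
                               min_members = min_members, tol = tol,
                               hard_assignment = hard_assignment),
                 seed = seed),
            class = "sustain")
}

#' Cross-validated information criterion over the number of subtypes
#'
#' For each candidate number of subtypes C, fits the model on all folds but
#' one and evaluates held-out subjects' log marginal likelihood under the
#' fitted mixture. CVIC(C) = -2 * sum of held-out log-likelihoods; lower is
#' better. Folds are a simple random partition under the given seed.
#'
#' @param data,spec,sigma as in \code{\link{fit_sustain}}.
#' @param max_subtypes largest C to evaluate.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and fits.
#' @param ... further fitting arguments passed to \code{\link{fit_sustain}}
#'   (e.g. \code{n_restarts}, \code{mcmc}).
#' @return data.frame with columns \code{n_subtypes} and \code{cvic}.
#' @export
cross_validate_cvic <- function(data, spec, max_subtypes = 3L, n_folds = 10L,
                                sigma = 1, seed = NULL, ...) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  n <- data_n(data)
  if (n < n_folds) stop("fewer subjects than folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  ctx <- ll_context(data, spec, sigma)
  heldout_ll <- numeric(max_subtypes)
  for (f in seq_len(n_folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    if (length(train) < 2L) stop("fold too small to fit")
    test_ctx <- ctx_subset(ctx, test)
    prev <- NULL
    for (C in seq_len(max_subtypes)) {
      # a C-subtype model the training fold cannot support (every split
      # collapses below min_members) contributes its (C-1)-subtype fit:
      # no held-out improvement, rather than a hard failure
      fit <- tryCatch(
        fit_sustain(data_subset(data, train), spec, n_subtypes = C,
                    sigma = sigma, mcmc = list(n_iter = 0), ...),
        error = function(e) {
          if (is.null(prev)) stop(e)
          warning("fold ", f, ", C = ", C, ": ", conditionMessage(e),
                  "; carrying forward the ", C - 1L, "-subtype fit")
          prev
        })
      ml <- mixture_loglik_ctx(test_ctx, fit$sequences, fit$fractions)
      heldout_ll[C] <- heldout_ll[C] + ml$total
      prev <- fit
    }
  }
  data.frame(n_subtypes = seq_len(max_subtypes), cvic = -2 * heldout_ll)
}
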