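#' Expected z-score trajectory value
#'
#' Each biomarker follows a piecewise-linear trajectory in model stage,
#' anchored at (stage 0, z = 0), at (position of each of its events, the
#' event's z level) and at (stage N, z_max). The trajectory is strictly
#' increasing in stage, so every stage has a distinct expected biomarker
#' profile.
#'
#' @param spec an \code{\link{event_spec}} of kind \code{"zscore"}.
#' @param sequence integer permutation of event ids (position -> event).
#' @param stage integer vector of stages in 0..N.
#' @param biomarker biomarker name.
#' @return expected z value(s) at the requested stage(s).
#' @export
expected_zscore <- function(spec, sequence, stage, biomarker) {
  stopifnot(spec$kind == "zscore")
  if (any(stage < 0 | stage > spec$n_events))
    stop("stage out of range 0..", spec$n_events)
  E <- trajectory_matrix(spec, sequence)
  unname(E[biomarker, stage + 1L])
}

# B x (N+1) matrix of expected z values per biomarker (rows) and stage
# 0..N (columns). The terminal (stage N, z_max) anchor is dropped when the
# biomarker's last event already sits at position N.
trajectory_matrix <- function(spec, sequence) {
  N <- spec$n_events
  pos <- order(sequence)
  st <- 0:N
  E <- matrix(0, nrow = length(spec$biomarkers), ncol = N + 1L,
              dimnames = list(spec$biomarkers, NULL))
  for (i in seq_along(spec$biomarkers)) {
    b <- spec$biomarkers[i]
    sel <- spec$events$biomarker == b
    xs <- c(0, pos[spec$events$event_id[sel]])
    ys <- c(0, spec$events$value[sel])
    if (xs[length(xs)] < N) {
      xs <- c(xs, N)
      ys <- c(ys, spec$z_max[[b]])
    }
    seg <- findInterval(st, xs, rightmost.closed = TRUE)
    slope <- diff(ys) / diff(xs)
    E[i, ] <- ys[seg] + (st - xs[seg]) * c(slope, 0)[seg]
    E[i, N + 1L] <- ys[length(ys)]
  }
  E
}

#' Stage likelihood of a z-score profile
#'
#' Density of one subject's biomarker z-scores at a given stage of a
#' sequence: independent Gaussians centred on the expected trajectory values,
#' with unit standard deviation by default (inputs are control-standardized).
#'
#' @param z_row named numeric vector of z-scores (one per biomarker).
#' @param spec,sequence model definition as in \code{\link{expected_zscore}}.
#' @param stage integer stage in 0..N.
#' @param sigma per-biomarker standard deviation (default 1).
#' @return the likelihood (density) value.
#' @export
zscore_stage_likelihood <- function(z_row, spec, sequence, stage, sigma = 1) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  Z <- matrix(z_row[spec$biomarkers], nrow = 1,
              dimnames = list(NULL, spec$biomarkers))
  ll <- zscore_loglik_matrix(Z, spec, sequence, sigma)
  exp(ll[1, stage + 1L])
}

# n x (N+1) matrix of per-subject log stage likelihoods for z-score data.
# Z: n x B matrix with columns in spec$biomarkers order.
zscore_loglik_matrix <- function(Z, spec, sequence, sigma = 1) {
  B <- length(spec$biomarkers)
  sigma <- rep_len(sigma, B)
  E <- trajectory_matrix(spec, sequence)
  Zs <- sweep(Z, 2, sigma, "/")
  Es <- E / sigma
  cst <- -0.5 * B * log(2 * pi) - sum(log(sigma))
  # ||z - e||^2 = ||z||^2 - 2 z.e + ||e||^2, expanded via one matmul
  cross <- Zs %*% Es
  zz <- rowSums(Zs^2)
  ee <- colSums(Es^2)
  cst - 0.5 * (outer(zz, ee, "+") - 2 * cross)
}

#' Stage likelihood of an ordinal severity-score profile
#'
#' For the ordinal model, a subject contributes per-region probabilities over
#' severity scores 0..K-1. At stage s of a sequence, region j is expected to
#' have reached score s_j(s) = the number of that region's events at
#' positions <= s; the stage likelihood is the product over regions of the
#' subject's probability for that score.
#'
#' @param prob_row regions x K matrix of score probabilities (rows sum to 1).
#' @param spec an \code{\link{event_spec}} of kind \code{"ordinal"}.
#' @param sequence integer permutation of event ids.
#' @param stage integer stage in 0..N.
#' @return the likelihood value.
#' @export
ordinal_stage_likelihood <- function(prob_row, spec, sequence, stage) {
  if (any(prob_row < 0) || any(abs(rowSums(prob_row) - 1) > 1e-6))
    stop("malformed probability row: each region must sum to 1")
  P <- array(prob_row, dim = c(1, nrow(prob_row), ncol(prob_row)))
  ll <- ordinal_loglik_matrix(P, spec, sequence)
  exp(ll[1, stage + 1L])
}

# Score index (0-based) of each region at each stage: R x (N+1) matrix.
stage_scores <- function(spec, sequence) {
  N <- spec$n_events
  R <- length(spec$biomarkers)
  S <- matrix(0L, R, N + 1L, dimnames = list(spec$biomarkers, NULL))
  for (p in seq_len(N)) {
    ev <- sequence[p]
    r <- match(spec$events$biomarker[ev], spec$biomarkers)
    S[, p + 1L] <- S[, p]
    S[r, p + 1L] <- spec$events$level_index[ev]
  }
  S
}

# n x (N+1) log stage likelihoods for ordinal data.
# P: n x R x K array of score probabilities.
ordinal_loglik_matrix <- function(P, spec, sequence) {
  n <- dim(P)[1]; R <- dim(P)[2]; K <- dim(P)[3]
  LP <- matrix(log(pmax(P, 1e-300)), n, R * K)  # column (k-1)*R + r
  S <- stage_scores(spec, sequence)
  N <- spec$n_events
  out <- matrix(0, n, N + 1L)
  cols0 <- seq_len(R)  # score-0 columns
  out[, 1L] <- rowSums(LP[, cols0, drop = FALSE])
  for (s in seq_len(N)) {
    # only one region's score changes from stage s-1 to s
    ev <- sequence[s]
    r <- match(spec$events$biomarker[ev], spec$biomarkers)
    k_old <- S[r, s]; k_new <- S[r, s + 1L]
    out[, s + 1L] <- out[, s] - LP[, k_old * R + r] + LP[, k_new * R + r]
  }
  out
}

# Dispatch: log stage-likelihood matrix for either model kind.
stage_loglik_matrix <- function(data, spec, sequence, sigma = 1) {
  if (spec$kind == "zscore") zscore_loglik_matrix(data, spec, sequence, sigma)
  else ordinal_loglik_matrix(data, spec, sequence)
}

# Precomputed likelihood context: everything that does not depend on the
# sequence, so greedy ascent / MCMC / EM evaluate candidate sequences with
# minimal per-call work.
ll_context <- function(data, spec, sigma = 1) {
  if (spec$kind == "zscore") {
    B <- length(spec$biomarkers)
    sigma <- rep_len(sigma, B)
    Zs <- sweep(data[, spec$biomarkers, drop = FALSE], 2, sigma, "/")
    list(kind = "zscore", spec = spec, sigma = sigma, Zs = Zs,
         zz = rowSums(Zs^2),
         cst = -0.5 * B * log(2 * pi) - sum(log(sigma)),
         n = nrow(data))
  } else {
    n <- dim(data)[1]; R <- dim(data)[2]; K <- dim(data)[3]
    list(kind = "ordinal", spec = spec,
         LP = matrix(log(pmax(data, 1e-300)), n, R * K),
         R = R, K = K, n = n)
  }
}

ctx_subset <- function(ctx, idx) {
  ctx$n <- length(idx)
  if (ctx$kind == "zscore") {
    ctx$Zs <- ctx$Zs[idx, , drop = FALSE]
    ctx$zz <- ctx$zz[idx]
  } else {
    ctx$LP <- ctx$LP[idx, , drop = FALSE]
  }
  ctx
}

# n x (N+1) log stage-likelihood matrix from a context.
ctx_loglik_matrix <- function(ctx, sequence) {
  spec <- ctx$spec
  if (ctx$kind == "zscore") {
    Es <- trajectory_matrix(spec, sequence) / ctx$sigma
    ctx$cst - 0.5 * (outer(ctx$zz, colSums(Es^2), "+") - 2 * ctx$Zs %*% Es)
  } else {
    S <- stage_scores(spec, sequence)
    N <- spec$n_events
    R <- ctx$R
    out <- matrix(0, ctx$n, N + 1L)
    out[, 1L] <- rowSums(ctx$LP[, seq_len(R), drop = FALSE])
    bm_idx <- match(spec$events$biomarker, spec$biomarkers)
    for (s in seq_len(N)) {
      ev <- sequence[s]
      r <- bm_idx[ev]
      out[, s + 1L] <- out[, s] - ctx$LP[, S[r, s] * R + r] +
        ctx$LP[, S[r, s + 1L] * R + r]
    }
    out
  }
}

ctx_log_marginal <- function(ctx, sequence) {
  log_row_mean_exp(ctx_loglik_matrix(ctx, sequence))
}

ctx_total <- function(ctx, sequence, weights = NULL) {
  lm <- ctx_log_marginal(ctx, sequence)
  if (is.null(weights)) sum(lm) else sum(weights * lm)
}

#' Marginal likelihood of subjects under a sequence
#'
#' Averages the stage likelihood over stages 0..N with a uniform stage prior.
#'
#' @param data n x B z-score matrix (z-score model) or n x R x K probability
#'   array (ordinal model).
#' @param spec an \code{\link{event_spec}}.
#' @param sequence integer permutation of event ids.
#' @param sigma per-biomarker sd (z-score model only).
#' @return numeric vector of per-subject marginal likelihoods.
#' @export
subject_marginal <- function(data, spec, sequence, sigma = 1) {
  exp(subject_log_marginal(data, spec, sequence, sigma))
}

# log mean_s exp(ll[, s]) rowwise, numerically stable
log_row_mean_exp <- function(ll) {
  m <- ll[cbind(seq_len(nrow(ll)), max.col(ll, ties.method = "first"))]
  m + log(rowMeans(exp(ll - m)))
}

subject_log_marginal <- function(data, spec, sequence, sigma = 1) {
  log_row_mean_exp(stage_loglik_matrix(data, spec, sequence, sigma))
}

# Weighted total log marginal likelihood (weights = EM responsibilities).
total_log_marginal <- function(data, spec, sequence, sigma = 1,
                               weights = NULL) {
  lm <- subject_log_marginal(data, spec, sequence, sigma)
  if (is.null(weights)) sum(lm) else sum(weights * lm)
}

# Number of subjects in a data object of either kind.
data_n <- function(data) if (is.matrix(data)) nrow(data) else dim(data)[1]

# Subset subjects.
data_subset <- function(data, idx) {
  if (is.matrix(data)) data[idx, , drop = FALSE]
  else data[idx, , , drop = FALSE]
}
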