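# S3 methods for fitted sustain models.

#' @export
print.sustain <- function(x, ...) {
  cat("Subtype-and-stage model (", x$kind, "), ", x$n_subtypes,
      " subtype(s), ", x$spec$n_events, " events, n = ", x$n, "\n", sep = "")
  cat("Total log-likelihood: ", format(x$loglik, digits = 6), "\n", sep = "")
  for (c in seq_len(x$n_subtypes)) {
    cat("Subtype ", c, " (fraction ", sprintf("%.3f", x$fractions[c]),
        "):\n  ", sep = "")
    cat(paste(x$spec$events$label[x$sequences[[c]]], collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.sustain <- function(object, ...) {
  pvds <- lapply(seq_len(object$n_subtypes), function(c)
    positional_variance(object$samples[[c]], object$spec))
  # mean position uncertainty per subtype: average row entropy of the PVD
  unc <- vapply(pvds, function(P) {
    mean(apply(P, 1, function(r) { r <- r[r > 0]; -sum(r * log(r)) }))
  }, 0)
  out <- list(model = object, pvds = pvds, position_entropy = unc)
  class(out) <- "summary.sustain"
  out
}

#' @export
print.summary.sustain <- function(x, ...) {
  print(x$model)
  cat("\nMean event-position entropy (nats) per subtype:\n")
  print(round(x$position_entropy, 3))
  invisible(x)
}

#' @export
coef.sustain <- function(object, ...) {
  data.frame(subtype = rep(seq_len(object$n_subtypes),
                           each = object$spec$n_events),
             position = rep(seq_len(object$spec$n_events),
                            object$n_subtypes),
             event = unlist(lapply(object$sequences, function(s)
               object$spec$events$label[s])),
             fraction = rep(object$fractions, each = object$spec$n_events),
             stringsAsFactors = FALSE)
}

#' @export
logLik.sustain <- function(object, ...) {
  # free parameters: per-subtype sequence (N ranks) + C-1 fractions
  val <- object$loglik
  attr(val, "df") <- object$n_subtypes * object$spec$n_events +
    (object$n_subtypes - 1L)
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' Predict subtype and stage for new subjects
#'
#' @param object fitted \code{\link{fit_sustain}} model.
#' @param newdata z-score matrix or score-probability array.
#' @param ... unused.
#' @return a \code{sustain_placement} (see \code{\link{assign_subjects}}).
#' @export
predict.sustain <- function(object, newdata, ...) {
  assign_subjects(object, newdata)
}

#' Plot positional variance diagrams
#'
#' Heatmap of the positional variance diagram of each subtype, events ordered
#' by their MAP position.
#'
#' @param x fitted model.
#' @param subtypes which subtypes to plot.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.sustain <- function(x, subtypes = seq_len(x$n_subtypes), ...) {
  old <- graphics::par(mfrow = c(1, length(subtypes)),
                       mar = c(4, 8, 2, 1))
  on.exit(graphics::par(old))
  for (c in subtypes) {
    pvd <- positional_variance(x$samples[[c]], x$spec)
    ord <- x$sequences[[c]]  # event at each position, MAP order
    m <- pvd[ord, , drop = FALSE]
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                    z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                    xlab = "model stage", ylab = "", yaxt = "n",
                    main = sprintf("Subtype %d (f = %.2f)", c,
                                   x$fractions[c]), ...)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

#' Simulate z-score data from a fitted model
#'
#' Draws subjects from the fitted mixture: subtype ~ fractions, stage uniform
#' over 0..N, biomarker values Gaussian around the expected trajectory.
#' Only available for z-score models.
#'
#' @param object fitted model of kind \code{"zscore"}.
#' @param nsim number of subjects.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return matrix of simulated z-scores with attributes \code{"subtype"} and
#'   \code{"stage"}.
#' @export
simulate.sustain <- function(object, nsim = 100, seed = NULL, ...) {
  if (object$kind != "zscore")
    stop("simulate is only implemented for z-score models")
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  N <- spec$n_events
  subtype <- sample.int(object$n_subtypes, nsim, replace = TRUE,
                        prob = object$fractions)
  stage <- sample.int(N + 1L, nsim, replace = TRUE) - 1L
  Z <- matrix(0, nsim, length(spec$biomarkers),
              dimnames = list(NULL, spec$biomarkers))
  for (c in seq_len(object$n_subtypes)) {
    idx <- which(subtype == c)
    if (!length(idx)) next
    E <- trajectory_matrix(spec, object$sequences[[c]])
    Z[idx, ] <- t(E[, stage[idx] + 1L, drop = FALSE]) +
      matrix(stats::rnorm(length(idx) * ncol(Z), sd = object$sigma),
             length(idx), ncol(Z))
  }
  attr(Z, "subtype") <- subtype
  attr(Z, "stage") <- stage
  Z
}
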