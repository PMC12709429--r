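# The beta-weighted ELBO: closed-form diagonal-Gaussian KL, token
# reconstruction negative log-likelihood, and the beta schedule.
#
# Reduction convention: the reconstruction NLL is summed over the tokens of
# a sequence and averaged over molecules; the KL is summed over latent
# dimensions and averaged over molecules. With beta in [5e-05, 1e-04] a
# per-token-mean reconstruction would make the KL term numerically
# irrelevant; sum-over-tokens keeps the printed beta range meaningful.

#' Closed-form KL divergence to the standard Gaussian prior
#'
#' KL( N(mu, diag(sigma^2)) || N(0, I) ) =
#' sum_d 0.5 (mu_d^2 + sigma_d^2 - 1 - ln sigma_d^2), evaluated per molecule
#' and averaged over the batch (or returned per molecule).
#'
#' @param dist a \code{LatentDistribution}.
#' @param reduce "mean" (batch average, default) or "none" (per molecule).
#' @return scalar, or numeric vector with \code{reduce = "none"}.
#' @examples
#' d <- new("LatentDistribution", mu = matrix(1), logSigma = matrix(0))
#' klDivergence(d)   # 0.5
#' @export
klDivergence <- function(dist, reduce = c("mean", "none")) {
  stopifnot(is(dist, "LatentDistribution"))
  reduce <- match.arg(reduce)
  mu <- dist@mu; ls <- dist@logSigma
  if (!all(is.finite(mu)) || !all(is.finite(ls)))
    stop("non-finite posterior parameters")
  per <- rowSums(0.5 * (mu^2 + exp(2 * ls) - 1 - 2 * ls))
  if (reduce == "mean") mean(per) else per
}

#' Token reconstruction negative log-likelihood
#'
#' Negative log softmax probability of each target token, summed over the
#' non-pad positions of a sequence and averaged over the batch. Logits must
#' be aligned one step ahead of the targets, as produced by
#' [decodeTeacherForced()]: \code{logits[b, t, ]} predicts
#' \code{targets[b, t + 1]}. Pad positions contribute zero.
#'
#' @param logits numeric array (B, T-1, vocabSize).
#' @param targets B x T integer matrix of BOS-led token ids.
#' @param reduce "mean" (batch average) or "none" (per molecule).
#' @return scalar NLL (or per-molecule vector).
#' @export
reconstructionNLL <- function(logits, targets, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(is.array(logits), length(dim(logits)) == 3L, is.matrix(targets))
  B <- dim(logits)[1]; Tm1 <- dim(logits)[2]
  if (B != nrow(targets) || Tm1 != ncol(targets) - 1L)
    stop("logits (", B, ",", Tm1, ",.) do not align with targets (",
         nrow(targets), ",", ncol(targets), "): expected T-1 positions")
  tgt <- targets[, -1, drop = FALSE]
  per <- numeric(B)
  for (b in seq_len(B)) {
    L <- matrix(logits[b, , ], nrow = Tm1)
    m <- apply(L, 1L, max)
    lse <- m + log(rowSums(exp(L - m)))
    nll <- lse - L[cbind(seq_len(Tm1), tgt[b, ])]
    keep <- tgt[b, ] != .PAD_ID
    per[b] <- sum(nll[keep])
  }
  if (reduce == "mean") mean(per) else per
}

#' Evaluate the beta schedule at a step
#'
#' Monotonic mode interpolates linearly from \code{betaLow} at step 0 to
#' \code{betaHigh} at the final step. Cyclical mode splits the horizon into
#' \code{nCycles} equal cycles, each a linear ramp from \code{betaLow}
#' towards \code{betaHigh} that resets to \code{betaLow} at every cycle
#' boundary (the endpoint step returns \code{betaHigh}).
#'
#' @param schedule a \code{BetaSchedule}.
#' @param step integer step in [0, totalSteps].
#' @return the beta weight at that step.
#' @examples
#' betaAt(betaSchedule("monotonic", totalSteps = 99), 0)    # 5e-05
#' betaAt(betaSchedule("monotonic", totalSteps = 99), 99)   # 1e-04
#' @export
betaAt <- function(schedule, step) {
  stopifnot(is(schedule, "BetaSchedule"))
  if (length(step) != 1L || step < 0 || step > schedule@totalSteps)
    stop("step must lie in [0, ", schedule@totalSteps, "]")
  lo <- schedule@betaLow; hi <- schedule@betaHigh
  if (step == schedule@totalSteps) return(hi)
  if (schedule@mode == "monotonic") {
    lo + (hi - lo) * step / schedule@totalSteps
  } else {
    cycleLen <- schedule@totalSteps / schedule@nCycles
    pos <- step %% cycleLen
    lo + (hi - lo) * pos / cycleLen
  }
}

#' LossBreakdown: the assembled objective
#'
#' total = beta * kl + recon; all four components are recorded so training
#' logs can show the KL/reconstruction balance under the beta schedule.
#'
#' @slot kl KL divergence term (batch mean).
#' @slot recon reconstruction NLL term (batch mean).
#' @slot beta the KL weight applied.
#' @slot total the combined loss.
#' @export
setClass("LossBreakdown",
  representation(kl = "numeric", recon = "numeric",
                 beta = "numeric", total = "numeric"))

setValidity("LossBreakdown", function(object) {
  msgs <- character(0)
  if (abs(object@total - (object@beta * object@kl + object@recon)) >
      1e-8 * max(1, abs(object@total)))
    msgs <- c(msgs, "total must equal beta * kl + recon")
  if (object@kl < 0) msgs <- c(msgs, "kl must be >= 0")
  if (object@recon < 0) msgs <- c(msgs, "recon must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: total %.6f = %.3g * kl %.6f + recon %.6f\n",
              object@total, object@beta, object@kl, object@recon))
})

#' Assemble the total loss
#'
#' @param kl KL divergence (batch mean, non-negative).
#' @param recon reconstruction NLL (batch mean, non-negative).
#' @param beta the KL weight.
#' @return a \code{LossBreakdown} with total = beta * kl + recon.
#' @examples
#' totalLoss(2, 3, 0.5)   # total 4
#' @export
totalLoss <- function(kl, recon, beta) {
  stopifnot(is.finite(kl), is.finite(recon), is.finite(beta))
  new("LossBreakdown", kl = as.numeric(kl), recon = as.numeric(recon),
      beta = as.numeric(beta), total = as.numeric(beta * kl + recon))
}
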