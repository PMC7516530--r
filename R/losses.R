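#' Classification, entropy and adversarial loss primitives
#'
#' These are the closed-form pieces of the training objective.  All
#' logarithms are natural.
#'
#' `classifier_loss()` is the mean source-domain cross-entropy
#' `-log p[y]`; `prediction_entropy()` is `H(p) = -sum_c p_c log p_c` (with
#' `0 log 0 := 0`); `entropy_weight()` is the transferability weight
#' `w(H) = 1 + exp(-H)`, which lies in `(1, 2]` and decreases with
#' uncertainty; `discriminator_loss()` is the weighted binary cross-entropy
#' of the domain discriminator (source scores pushed to 1, target to 0),
#' averaged within each domain and summed; `total_loss()` is the minimax
#' objective `L_c - lambda * L_d`; `lr_schedule()` is the inverse-decay
#' learning rate `alpha0 * (1 + u * tau)^(-beta)` with training progress
#' `tau` in `[0, 1]`.
#'
#' @param p class-probability matrix `(C x n)` (columns are examples) or a
#'   single probability vector.
#' @param y integer labels in `1..C`, one per column of `p`.
#' @return a scalar.
#' @export
classifier_loss <- function(p, y) {
  p <- as.matrix(p)
  y <- as.integer(y)
  if (length(y) != ncol(p)) stop("one label per example required")
  mean(-log(p[cbind(y, seq_along(y))]))
}

#' @rdname classifier_loss
#' @export
prediction_entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 2L, prediction_entropy))
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' @rdname classifier_loss
#' @param H entropy value(s) from [prediction_entropy()].
#' @export
entropy_weight <- function(H) 1 + exp(-H)

#' @rdname classifier_loss
#' @param scores_s,scores_t discriminator outputs in `(0, 1)` for the source
#'   and target batches.
#' @param weights_s,weights_t per-example weights (all 1 for the unweighted
#'   variant).
#' @export
discriminator_loss <- function(scores_s, scores_t,
                               weights_s = rep(1, length(scores_s)),
                               weights_t = rep(1, length(scores_t))) {
  if (any(scores_s <= 0 | scores_s >= 1) || any(scores_t <= 0 | scores_t >= 1))
    stop("discriminator scores must lie strictly in (0, 1)")
  mean(-weights_s * log(scores_s)) + mean(-weights_t * log(1 - scores_t))
}

#' @rdname classifier_loss
#' @param L_c,L_d classifier and discriminator loss values.
#' @param lambda adversarial trade-off in `[0, 1]`.
#' @export
total_loss <- function(L_c, L_d, lambda) L_c - lambda * L_d

#' @rdname classifier_loss
#' @param tau training progress in `[0, 1]`.
#' @param alpha0,u,beta schedule parameters.
#' @export
lr_schedule <- function(tau, alpha0 = 0.01, u = 10, beta = 0.75) {
  alpha0 * (1 + u * tau)^(-beta)
}
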