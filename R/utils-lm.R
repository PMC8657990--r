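# Coefficient standard errors and R^2 computed directly from the lm QR
# decomposition. summary.lm() warns on exactly noiseless data ("essentially
# perfect fit"), which is the normal situation for deterministic synthetic
# traces here, so we avoid it.
lm_coef_se <- function(fit) {
  s2 <- sum(fit$residuals^2) / fit$df.residual
  unscaled <- diag(chol2inv(qr.R(fit$qr)))
  se <- numeric(length(unscaled))
  se[fit$qr$pivot] <- sqrt(pmax(unscaled, 0) * s2)
  stats::setNames(se, names(stats::coef(fit)))
}

lm_r_squared <- function(fit) {
  y <- fit$residuals + fit$fitted.values
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(fit$residuals^2) / tss
}
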