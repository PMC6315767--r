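#' Variable importance in projection (VIP), split into predictive and
#' orthogonal parts
#'
#' For each feature, importance is the squared component weight averaged over
#' components with weights proportional to the component's explained sum of
#' squares, scaled so that the mean squared VIP over features is exactly 1.
#' With a single predictive component the predictive part reduces to
#' `VIPpred_j = sqrt(m) * |w_j|` (`m` features, `|w| = 1`), so
#' `mean(VIPpred^2) = 1` identically. The orthogonal part weights each
#' orthogonal component by its explained X-variation; the total combines the
#' predictive and orthogonal sums of squares. Features whose orthogonal
#' importance exceeds their predictive importance vary within rather than
#' between groups and are flagged downstream as not biomarker-relevant.
#'
#' @param model a fitted [oplsda()] model.
#' @return data.frame with `feature_id`, `vip_pred`, `vip_ortho`,
#'   `vip_total` and `vip_ratio` (= pred/ortho, `Inf` when the orthogonal
#'   part is zero).
#' @export
vip <- function(model) {
  if (!inherits(model, "oplsda")) stop("vip() needs a fitted oplsda model")
  m <- length(model$weights)
  w2 <- model$weights^2
  vip_pred <- sqrt(m * w2)
  k <- model$n_ortho
  if (k > 0) {
    sso <- model$ss_ortho
    Wo2 <- model$ortho_weights^2
    ortho_num <- c(Wo2 %*% sso)
    vip_ortho <- sqrt(m * ortho_num / sum(sso))
    tot <- (w2 * model$ss_pred + ortho_num) / (model$ss_pred + sum(sso))
    vip_total <- sqrt(m * tot)
  } else {
    vip_ortho <- rep(0, m)
    vip_total <- vip_pred
  }
  ratio <- ifelse(vip_ortho == 0, Inf, vip_pred / vip_ortho)
  data.frame(feature_id = model$feature_id,
             vip_pred = unname(vip_pred), vip_ortho = unname(vip_ortho),
             vip_total = unname(vip_total), vip_ratio = unname(ratio),
             stringsAsFactors = FALSE)
}
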