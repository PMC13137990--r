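#' Distribution-of-fitness-effects configuration
#'
#' Nonsynonymous selection coefficients are drawn from a negative gamma
#' distribution (`s = -rgamma(shape, mean = dfe_mean)`); synonymous
#' mutations are neutral (`s = 0`). Dominance follows the threshold rule:
#' `h = 0` for `s < h_threshold` (recessive when strongly deleterious) and
#' `h = 0.25` otherwise. The nonsynonymous:synonymous draw ratio defaults
#' to 2.31:1.
#'
#' @param shape gamma shape (default 0.186, the human nonsynonymous DFE
#'   convention).
#' @param mean_s mean selection coefficient magnitude (default 0.01314).
#' @param nonsyn_ratio nonsynonymous:synonymous ratio (default 2.31).
#' @param h_threshold dominance threshold on s (default -0.01).
#' @param h_strong,h_weak dominance below / at-or-above the threshold.
#' @return list of class `dfe_config`.
#' @export
dfe_config <- function(shape = 0.186, mean_s = 0.01314,
                       nonsyn_ratio = 2.31, h_threshold = -0.01,
                       h_strong = 0, h_weak = 0.25) {
  stopifnot(shape > 0, mean_s > 0, nonsyn_ratio > 0)
  structure(list(shape = shape, mean_s = mean_s,
                 nonsyn_ratio = nonsyn_ratio, h_threshold = h_threshold,
                 h_strong = h_strong, h_weak = h_weak),
            class = "dfe_config")
}

#' Classify selection-coefficient strength
#'
#' Threshold classes for deleterious mutations: strong `s <= -0.01`,
#' moderate `-0.01 < s <= -0.001`, weak `-0.001 < s <= -0.00001`; effects
#' closer to zero (including `s = 0`) are neutral. Positive `s` is an
#' error.
#'
#' @param s numeric vector of selection coefficients (`<= 0`).
#' @return character vector in `{"strong", "moderate", "weak",
#'   "neutral"}`.
#' @export
classify_strength <- function(s) {
  if (any(s > 0)) stop("selection coefficients must be <= 0")
  ifelse(s <= -0.01, "strong",
         ifelse(s <= -0.001, "moderate",
                ifelse(s <= -0.00001, "weak", "neutral")))
}

#' Draw new mutations
#'
#' Each mutation is nonsynonymous with probability `ratio/(ratio+1)`
#' (2.31/3.31 under the default), in which case `s` is a negative gamma
#' draw with `h` from the threshold rule; synonymous mutations have
#' `s = 0`. Uses the current RNG stream.
#'
#' @param n number of mutations.
#' @param dfe a [dfe_config()].
#' @return data.frame with `type`, `s`, `h`, `strength_class`.
#' @export
draw_mutation <- function(n, dfe = dfe_config()) {
  nonsyn <- runif(n) < dfe$nonsyn_ratio / (dfe$nonsyn_ratio + 1)
  s <- numeric(n)
  k <- sum(nonsyn)
  if (k) s[nonsyn] <- -rgamma(k, shape = dfe$shape,
                              scale = dfe$mean_s / dfe$shape)
  h <- ifelse(s < dfe$h_threshold, dfe$h_strong, dfe$h_weak)
  data.frame(type = ifelse(nonsyn, "nonsynonymous", "synonymous"),
             s = s, h = h, strength_class = classify_strength(s),
             stringsAsFactors = FALSE)
}
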