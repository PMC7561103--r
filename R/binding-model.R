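#' Statistical weight of single-site occupancy
#'
#' The statistical (Boltzmann) weight of one transcription complex bound to a
#' single CSL site is `alpha = conc / kd_nM`, the ratio of the free complex
#' concentration to its single-site dissociation constant. It is the natural
#' variable of the two-site binding polynomial `1 + 2*alpha + C*alpha^2`.
#'
#' @param conc Complex concentration in nM (vectorised, each `>= 0`).
#' @param kd_nM Single-site dissociation constant in nM (`> 0`).
#' @return Numeric vector of dimensionless statistical weights.
#' @examples
#' statistical_weight(c(2.5, 40, 640), kd_nM = 40)
#' @export
statistical_weight <- function(conc, kd_nM) {
  check_scalar_positive(kd_nM, "kd_nM")
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    rlang::abort("`conc` must be finite and nonnegative.",
                 class = "emsacoop_validation_error")
  }
  conc / kd_nM
}

#' Occupancy probabilities of a fully competent two-site probe
#'
#' Probabilities that a probe with two equivalent sites carries 0, 1 or 2
#' complexes at equilibrium. The four microstates (empty, site A, site B,
#' both) have Boltzmann weights `1, alpha, alpha, C*alpha^2`, giving the
#' binding polynomial `Z = 1 + 2*alpha + C*alpha^2` and
#' `(P0, P1, P2) = (1, 2*alpha, C*alpha^2) / Z`.
#' `C = 1` means independent sites; `C > 1` positive cooperativity (the
#' second site binds more tightly, `Kd2 = Kd/C`); `C < 1` negative.
#'
#' @param alpha Statistical weight(s), nonnegative (see
#'   [statistical_weight()]).
#' @param C Cooperativity factor, strictly positive scalar.
#' @return A tibble with columns `alpha`, `p0`, `p1`, `p2`; rows sum to 1.
#' @examples
#' occupancy_pure(alpha = 1, C = 5)
#' @export
occupancy_pure <- function(alpha, C) {
  occupancy_mixture(alpha, C = C, f = 1)
}

#' Occupancy probabilities with a partially competent probe population
#'
#' Extends [occupancy_pure()] to a probe population in which only a fraction
#' `f` can bind two complexes while the remaining `1 - f` binds at most one
#' (a one-site probe with polynomial `1 + 2*alpha`). This accounts for the
#' single-shift band never being depleted at saturating protein:
#' \deqn{P_0 = \frac{f}{1+2\alpha+C\alpha^2} + \frac{1-f}{1+2\alpha},\quad
#'       P_1 = \frac{2\alpha f}{1+2\alpha+C\alpha^2} +
#'             \frac{2\alpha(1-f)}{1+2\alpha},\quad
#'       P_2 = \frac{C\alpha^2 f}{1+2\alpha+C\alpha^2}.}
#'
#' `alpha = 0` returns exactly `(1, 0, 0)` without evaluating `C*alpha^2`.
#'
#' @inheritParams occupancy_pure
#' @param f Fraction of probes competent to bind two complexes, in `[0, 1]`.
#' @return A tibble with columns `alpha`, `p0`, `p1`, `p2`; rows sum to 1.
#' @examples
#' occupancy_mixture(alpha = c(0, 1), C = 5, f = 0.85)
#' @export
occupancy_mixture <- function(alpha, C, f) {
  check_alpha(alpha)
  check_scalar_positive(C, "C")
  check_fraction(f, "f")
  p <- occupancy_probs(alpha, C, f)
  tibble::tibble(alpha = alpha, p0 = p[, 1L], p1 = p[, 2L], p2 = p[, 3L])
}

# bare-matrix kernel shared by the fit residuals and the tibble wrappers;
# alpha assumed validated. Column order (p0, p1, p2).
occupancy_probs <- function(alpha, C, f) {
  d1 <- 1 + 2 * alpha
  d2 <- d1 + C * alpha^2
  p0 <- f / d2 + (1 - f) / d1
  p1 <- 2 * alpha * (f / d2 + (1 - f) / d1)
  p2 <- f * C * alpha^2 / d2
  zero <- alpha == 0
  if (any(zero)) {
    p0[zero] <- 1
    p1[zero] <- 0
    p2[zero] <- 0
  }
  cbind(p0, p1, p2, deparse.level = 0)
}

#' Mean number of sites filled
#'
#' The average occupancy `P1 + 2*P2` of the mixture model, in `[0, 2]`.
#' It increases monotonically with `alpha` and saturates at `1 + f`: the
#' incompetent fraction contributes at most one bound complex.
#'
#' @inheritParams occupancy_mixture
#' @return Numeric vector of mean occupancies, same length as `alpha`.
#' @examples
#' mean_sites_filled(alpha = c(0.1, 1, 100), C = 5, f = 0.85)
#' @export
mean_sites_filled <- function(alpha, C, f) {
  check_alpha(alpha)
  check_scalar_positive(C, "C")
  check_fraction(f, "f")
  p <- occupancy_probs(alpha, C, f)
  unname(p[, 2L] + 2 * p[, 3L])
}

#' Dissociation constant of the second site
#'
#' Cooperativity rescales the second-site dissociation constant:
#' `Kd2 = Kd / C`. With `C = 5` the second complex binds five-fold more
#' tightly once the first site is occupied.
#'
#' @param kd_nM First-site dissociation constant, nM, `> 0`.
#' @param C Cooperativity factor, `> 0`.
#' @return Second-site dissociation constant in nM.
#' @examples
#' second_site_kd(kd_nM = 40, C = 5)
#' @export
second_site_kd <- function(kd_nM, C) {
  check_scalar_positive(kd_nM, "kd_nM")
  check_scalar_positive(C, "C")
  kd_nM / C
}

#' Binding-model parameter triple
#'
#' Validates and packages the three fitted parameters: the single-site
#' dissociation constant `kd_nM`, the cooperativity factor `C`, and the
#' two-complex-competent probe fraction `f`.
#'
#' @param kd_nM Dissociation constant in nM, `> 0`.
#' @param C Cooperativity factor, `> 0`.
#' @param f Competent fraction in `[0, 1]`.
#' @return A one-row tibble with columns `kd_nM`, `C`, `f` and the derived
#'   `kd2_nM = kd_nM / C`.
#' @examples
#' model_params(kd_nM = 40, C = 5, f = 0.85)
#' @export
model_params <- function(kd_nM, C, f) {
  check_scalar_positive(kd_nM, "kd_nM")
  check_scalar_positive(C, "C")
  check_fraction(f, "f")
  tibble::tibble(kd_nM = kd_nM, C = C, f = f, kd2_nM = kd_nM / C)
}

# ---- argument checks ------------------------------------------------------

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a single finite positive number.", name),
                 class = "emsacoop_validation_error")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a single number in [0, 1].", name),
                 class = "emsacoop_validation_error")
  }
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha < 0)) {
    rlang::abort("`alpha` must be finite and nonnegative.",
                 class = "emsacoop_validation_error")
  }
  invisible(alpha)
}
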