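#' Cholesky factors of the genetic and environmental covariance matrices
#'
#' True breeding values are sampled as `L r` with `L L' = G`, and
#' environmental deviations as `C r` with `C C' = R`, where `r` is a vector
#' of independent standard-normal draws. A zero matrix (degenerate
#' configurations in tests) yields a zero factor.
#'
#' @param panel A [trait_panel()], or a list with matrices `G` and `R`.
#' @return List with lower-triangular factors `L` and `C`.
#' @export
chol_factors <- function(panel) {
  list(L = chol_lower(panel$G), C = chol_lower(panel$R))
}

chol_lower <- function(M) {
  if (all(M == 0)) return(M * 0)
  t(chol(M))
}

#' Sample base-population true breeding values
#'
#' Draws `n` i.i.d. multivariate-normal TBV vectors with mean zero and
#' covariance `G` via `L r` with standard-normal `r`. All randomness comes
#' from the current R random stream; seed it for reproducibility.
#'
#' @param n Number of animals.
#' @param factors Result of [chol_factors()].
#' @return `n x n_traits` matrix of TBVs in trait units.
#' @export
sample_base_tbv <- function(n, factors) {
  t <- ncol(factors$L)
  r <- matrix(rnorm(n * t), n, t)
  tbv <- r %*% t(factors$L)
  colnames(tbv) <- colnames(factors$L)
  tbv
}

#' Sample offspring true breeding values (parent average + Mendelian sampling)
#'
#' The offspring TBV is the parent average plus a Mendelian-sampling
#' deviation with covariance `0.5 (1 - (F_sire + F_dam) / 2) G`, shrunk by
#' parental inbreeding. The default `scale = "sqrt"` applies the factor
#' `sqrt(0.5 (1 - Fbar))` to `L r` so that the deviation *variance* is
#' `0.5 (1 - Fbar) G`, the standard quantitative-genetics result;
#' `scale = "linear"` instead multiplies `L r` by `0.5 (1 - Fbar)` directly,
#' which shrinks the deviation variance to `0.25 (1 - Fbar)^2 G` and is kept
#' only as a sensitivity switch.
#'
#' @param tbv_sire,tbv_dam Parent TBVs: matrices (`n x n_traits`) or single
#'   vectors.
#' @param f_sire,f_dam Parent inbreeding coefficients in `[0, 1]` (recycled).
#' @param factors Result of [chol_factors()].
#' @param scale `"sqrt"` (default) or `"linear"`, see Details.
#' @return Matrix of offspring TBVs, one row per offspring.
#' @export
sample_offspring_tbv <- function(tbv_sire, tbv_dam, f_sire, f_dam, factors,
                                 scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  if (is.vector(tbv_sire)) tbv_sire <- matrix(tbv_sire, nrow = 1)
  if (is.vector(tbv_dam)) tbv_dam <- matrix(tbv_dam, nrow = 1)
  n <- nrow(tbv_sire)
  stopifnot(nrow(tbv_dam) == n)
  if (any(f_sire < 0 | f_sire > 1 | f_dam < 0 | f_dam > 1)) {
    stop("inbreeding coefficients must lie in [0, 1]")
  }
  fbar <- (rep_len(f_sire, n) + rep_len(f_dam, n)) / 2
  k <- if (scale == "sqrt") sqrt(0.5 * (1 - fbar)) else 0.5 * (1 - fbar)
  t <- ncol(factors$L)
  dev <- (matrix(rnorm(n * t), n, t) %*% t(factors$L)) * k
  0.5 * (tbv_sire + tbv_dam) + dev
}

#' Recording mask for one animal
#'
#' Which traits can ever be observed on an animal, given the recording rules:
#' both-sexes traits on every candidate, female-only traits on females, and
#' cull-only traits on candidates culled without having been selected.
#'
#' @param panel A [trait_panel()].
#' @param sex `"M"` or `"F"`.
#' @param culled Whether the animal was culled as an unselected candidate.
#' @return Logical vector over panel traits.
#' @export
recording_mask <- function(panel, sex, culled = FALSE) {
  rec <- panel$traits$sex_recording
  rec == "both_sexes" |
    (rec == "female_only" & sex == "F") |
    (rec == "cull_only" & culled)
}

#' Sample a phenotype record
#'
#' `obs = tbv + C r`: the full environmental deviation is drawn once, and
#' the recording mask determines which components are observable.
#'
#' @param tbv TBV vector of the animal.
#' @param factors Result of [chol_factors()].
#' @param panel A [trait_panel()].
#' @param sex `"M"` or `"F"`.
#' @param culled Whether cull-only traits are (or will become) observable.
#' @return Tibble with columns `trait`, `value` (NA when masked) and
#'   `observed`.
#' @export
sample_phenotype <- function(tbv, factors, panel, sex, culled = FALSE) {
  obs <- drop(sample_environment(1, factors)) + tbv
  mask <- recording_mask(panel, sex, culled)
  tibble::tibble(
    trait = panel$traits$code,
    value = ifelse(mask, obs, NA_real_),
    observed = mask
  )
}

#' Sample environmental deviations
#'
#' Draws `n` i.i.d. environmental deviation vectors with mean zero and
#' covariance `R` via `C r`.
#'
#' @inheritParams sample_base_tbv
#' @return `n x n_traits` matrix of deviations in trait units.
#' @export
sample_environment <- function(n, factors) {
  t <- ncol(factors$C)
  r <- matrix(rnorm(n * t), n, t)
  e <- r %*% t(factors$C)
  colnames(e) <- colnames(factors$C)
  e
}
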