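#' Economic values of the breeding goals
#'
#' @param panel A [trait_panel()].
#' @return Long tibble with columns `goal`, `trait` and `value` (EUR per
#'   trait unit). Traits with zero economic value stay in the table: they
#'   contribute nothing to the aggregate genotype but remain in the BLUP
#'   model as correlated information.
#' @export
breeding_goals <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  g <- panel$goals
  tibble::tibble(
    goal = rep(colnames(g), each = nrow(g)),
    trait = rep(rownames(g), times = ncol(g)),
    value = as.numeric(g)
  )
}

#' Economic-value vector of one breeding goal
#'
#' @param panel A [trait_panel()].
#' @param goal Goal name (e.g. `"curOBG"`) or a numeric vector of length
#'   equal to the number of panel traits (returned unchanged, named).
#' @return Named numeric vector in panel trait order.
#' @export
goal_vector <- function(panel, goal) {
  stopifnot(inherits(panel, "trait_panel"))
  if (is.numeric(goal)) {
    if (length(goal) != nrow(panel$traits)) {
      stop("economic-value vector must have one entry per panel trait")
    }
    return(setNames(as.numeric(goal), panel$traits$code))
  }
  k <- match(goal, colnames(panel$goals))
  if (is.na(k)) {
    stop("unknown breeding goal '", goal, "'; available: ",
         paste(colnames(panel$goals), collapse = ", "))
  }
  panel$goals[, k]
}

#' Aggregate genotype of an animal under a breeding goal
#'
#' The aggregate genotype H is the dot product of the economic values with
#' the animal's (true or estimated) breeding values, i.e. its genetic merit
#' expressed in EUR.
#'
#' @param values Economic-value vector (EUR per trait unit), e.g. from
#'   [goal_vector()].
#' @param tbv Breeding-value vector in the same trait order and units.
#' @return Scalar EUR value.
#' @export
aggregate_genotype <- function(values, tbv) {
  if (length(values) != length(tbv)) {
    stop("economic values and breeding values differ in length")
  }
  sum(values * tbv)
}

#' Genetic covariance between two aggregate genotypes
#'
#' `cov(H1, H2) = v1' G v2`, the standard selection-index quantity.
#'
#' @param panel A [trait_panel()].
#' @param goal1,goal2 Goal names or economic-value vectors.
#' @return Covariance in EUR^2.
#' @export
goal_covariance <- function(panel, goal1, goal2) {
  v1 <- goal_vector(panel, goal1)
  v2 <- goal_vector(panel, goal2)
  drop(v1 %*% panel$G %*% v2)
}

#' Genetic correlation between two breeding goals
#'
#' `v1' G v2 / sqrt((v1' G v1) (v2' G v2))` — the correlation between the
#' aggregate genotypes defined by two economic-value vectors on the same
#' trait panel.
#'
#' @inheritParams goal_covariance
#' @return Correlation in `[-1, 1]`.
#' @export
goal_correlation <- function(panel, goal1, goal2) {
  v1 <- goal_covariance(panel, goal1, goal1)
  v2 <- goal_covariance(panel, goal2, goal2)
  if (v1 <= 0 || v2 <= 0) {
    stop("goal variance is zero; correlation undefined")
  }
  goal_covariance(panel, goal1, goal2) / sqrt(v1 * v2)
}

#' All pairwise correlations between the panel's breeding goals
#'
#' @param panel A [trait_panel()].
#' @return Tibble with one row per goal and one column per goal, carrying the
#'   full symmetric correlation matrix of the aggregate genotypes.
#' @examples
#' goal_correlation_table(trait_panel())
#' @export
goal_correlation_table <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  gs <- colnames(panel$goals)
  cv <- crossprod(panel$goals, panel$G %*% panel$goals)
  cr <- stats::cov2cor(cv)
  dplyr::bind_cols(tibble::tibble(goal = gs), tibble::as_tibble(cr))
}
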