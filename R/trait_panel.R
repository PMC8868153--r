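#' Load the ten-trait genetic parameter panel
#'
#' Reads the panel of trait definitions (variances, recording rules),
#' genetic and phenotypic correlations, and economic values of the four
#' breeding goals, and assembles the genetic (`G`), phenotypic (`P`) and
#' environmental (`R`) covariance matrices. The environmental covariance is
#' derived on the covariance scale as `R = P - G`; environmental correlations
#' are never supplied directly. `G` and `R` are validated (and, if necessary,
#' minimally repaired) to be symmetric positive definite so that their
#' Cholesky factors exist for sampling.
#'
#' @param file Path to a YAML parameter file. Defaults to the packaged file
#'   that carries the Danish dam-line parameter set the simulator is built
#'   around.
#' @param max_adjust Maximum absolute change of any correlation allowed
#'   during positive-definite repair before the load aborts (default 0.05).
#'
#' @return An object of class `trait_panel`: a list with
#'   \describe{
#'     \item{traits}{tibble of trait definitions (code, unit, recording rule,
#'       additive/phenotypic/environmental variance, heritability)}
#'     \item{genetic_corr, phenotypic_corr}{10 x 10 correlation matrices}
#'     \item{G, P, R}{covariance matrices in trait-unit products}
#'     \item{goals}{matrix of economic values (traits x goals, EUR per unit)}
#'     \item{pd_report}{tibble describing any positive-definite repair}
#'   }
#' @examples
#' panel <- trait_panel()
#' heritability(panel)
#' @export
trait_panel <- function(file = NULL, max_adjust = 0.05) {
  if (is.null(file)) {
    file <- system.file("extdata", "trait_parameters.yaml", package = "orgpigsim")
  }
  raw <- yaml::read_yaml(file)

  traits <- dplyr::bind_rows(lapply(raw$traits, tibble::as_tibble))
  traits <- dplyr::rename(traits,
    sa2 = "additive_variance", sp2 = "phenotypic_variance",
    se2 = "environmental_variance", h2 = "heritability"
  )
  n <- nrow(traits)
  codes <- traits$code
  if (anyDuplicated(codes)) stop("duplicated trait codes in parameter file")
  ok_rec <- c("both_sexes", "female_only", "cull_only")
  if (!all(traits$sex_recording %in% ok_rec)) {
    stop("sex_recording must be one of: ", paste(ok_rec, collapse = ", "))
  }
  if (any(traits$sa2 <= 0) || any(traits$se2 <= 0)) {
    stop("additive and environmental variances must be strictly positive")
  }
  rel_gap <- abs(traits$sa2 + traits$se2 - traits$sp2) / traits$sp2
  if (any(rel_gap > 1e-9)) {
    stop("inconsistent variances for ", paste(codes[rel_gap > 1e-9], collapse = ", "),
         ": additive + environmental must equal phenotypic")
  }
  h2_calc <- traits$sa2 / traits$sp2
  bad_h2 <- abs(round(h2_calc, 2) - traits$h2) > 1e-9
  if (any(bad_h2)) {
    stop("recomputed heritability disagrees with the tabulated diagonal for ",
         paste(codes[bad_h2], collapse = ", "))
  }

  rg <- corr_from_triplets(raw$genetic_correlations, codes, "genetic")
  rp <- corr_from_triplets(raw$phenotypic_correlations, codes, "phenotypic")

  G <- rg * tcrossprod(sqrt(traits$sa2))
  P <- rp * tcrossprod(sqrt(traits$sp2))
  R <- P - G
  dimnames(G) <- dimnames(P) <- dimnames(R) <- list(codes, codes)

  fixG <- ensure_positive_definite(G, "G", max_adjust = max_adjust)
  fixR <- ensure_positive_definite(R, "R", max_adjust = max_adjust)
  pd_report <- tibble::tibble(
    matrix = c("G", "R"),
    repaired = c(fixG$repaired, fixR$repaired),
    max_correlation_change = c(fixG$max_change, fixR$max_change)
  )

  goals_raw <- raw$economic_values
  goals <- vapply(goals_raw, function(g) {
    miss <- setdiff(codes, names(g))
    if (length(miss)) stop("economic values missing for trait(s): ",
                           paste(miss, collapse = ", "))
    as.numeric(unlist(g)[codes])
  }, numeric(n))
  rownames(goals) <- codes

  structure(
    list(
      traits = traits,
      genetic_corr = rg, phenotypic_corr = rp,
      G = fixG$matrix, P = P, R = fixR$matrix,
      goals = goals,
      pd_report = pd_report,
      source = file
    ),
    class = "trait_panel"
  )
}

corr_from_triplets <- function(triplets, codes, what) {
  n <- length(codes)
  m <- diag(1, n)
  dimnames(m) <- list(codes, codes)
  for (tr in triplets) {
    i <- match(tr[[1]], codes)
    j <- match(tr[[2]], codes)
    r <- as.numeric(tr[[3]])
    if (is.na(i) || is.na(j)) {
      stop("unknown trait in ", what, " correlation entry: ",
           tr[[1]], "/", tr[[2]])
    }
    if (r < -1 || r > 1) {
      stop(what, " correlation for ", tr[[1]], "-", tr[[2]],
           " outside [-1, 1]: ", r)
    }
    m[i, j] <- r
    m[j, i] <- r
  }
  m
}

#' Validate (and minimally repair) a covariance matrix to positive definite
#'
#' Covariance matrices assembled from rounded published correlations can be
#' indefinite. If `M` admits a Cholesky factor it is returned unchanged;
#' otherwise it is projected to the nearest correlation matrix on the
#' correlation scale ([Matrix::nearPD()] with variances preserved), and the
#' largest absolute correlation change is reported. A repair that moves any
#' correlation by more than `max_adjust` aborts, since the repaired matrix
#' would no longer represent the tabulated architecture.
#'
#' @param M Symmetric matrix with strictly positive diagonal.
#' @param label Name used in messages.
#' @param max_adjust Abort threshold for the largest correlation change.
#' @return List with elements `matrix` (positive definite), `repaired`
#'   (logical) and `max_change` (largest absolute correlation adjustment).
#' @export
ensure_positive_definite <- function(M, label = "matrix", max_adjust = 0.05) {
  if (!isSymmetric(unname(M), tol = 1e-8)) {
    stop(label, " must be symmetric")
  }
  if (any(diag(M) <= 0)) stop(label, " must have a strictly positive diagonal")
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch) && min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0) {
    return(list(matrix = M, repaired = FALSE, max_change = 0))
  }
  s <- sqrt(diag(M))
  corr <- M / tcrossprod(s)
  near <- Matrix::nearPD(corr, corr = TRUE, keepDiag = TRUE,
                         posd.tol = 1e-8, maxit = 500)
  corr_new <- as.matrix(near$mat)
  max_change <- max(abs(corr_new - corr))
  if (max_change > max_adjust) {
    stop("positive-definite repair of ", label, " changes a correlation by ",
         signif(max_change, 3), " (> ", max_adjust,
         "); refusing to simulate an architecture that far from the input")
  }
  M_new <- corr_new * tcrossprod(s)
  dimnames(M_new) <- dimnames(M)
  list(matrix = M_new, repaired = TRUE, max_change = max_change)
}

#' Heritabilities of the panel traits
#'
#' @param panel A [trait_panel()].
#' @return Tibble with columns `trait` and `h2` (= additive / phenotypic
#'   variance).
#' @export
heritability <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  tibble::tibble(trait = panel$traits$code,
                 h2 = panel$traits$sa2 / panel$traits$sp2)
}

#' Environmental covariance between two traits
#'
#' The environmental covariance is defined by difference,
#' `R[i, j] = P[i, j] - G[i, j]`, because only genetic and phenotypic
#' correlations are tabulated.
#'
#' @param panel A [trait_panel()].
#' @param i,j Trait codes or indices.
#' @return Covariance in the product of the two traits' units.
#' @export
environmental_covariance <- function(panel, i, j) {
  stopifnot(inherits(panel, "trait_panel"))
  i <- trait_index(panel, i)
  j <- trait_index(panel, j)
  panel$P[i, j] - panel$G[i, j]
}

trait_index <- function(panel, i) {
  if (is.character(i)) {
    k <- match(i, panel$traits$code)
    if (anyNA(k)) stop("unknown trait: ", paste(i[is.na(k)], collapse = ", "))
    return(k)
  }
  i <- as.integer(i)
  if (any(i < 1 | i > nrow(panel$traits))) stop("trait index out of range")
  i
}

#' @export
print.trait_panel <- function(x, ...) {
  cat("<trait_panel> ", nrow(x$traits), " traits, ",
      ncol(x$goals), " breeding goals\n", sep = "")
  print(x$traits)
  rep_needed <- x$pd_report$repaired
  if (any(rep_needed)) {
    cat("positive-definite repair applied to:",
        paste(x$pd_report$matrix[rep_needed], collapse = ", "), "\n")
  } else {
    cat("G and R positive definite as assembled (no repair)\n")
  }
  invisible(x)
}
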