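#' Assemble the mixed-model equations for multivariate pedigree BLUP
#'
#' Builds Henderson's mixed-model equations for the multi-trait animal model
#' `y = Xb + Za + e` with fixed time-step effects per trait, additive genetic
#' effects with covariance `G (x) A`, and residuals with covariance `R (x) I`.
#' Missing traits are handled exactly: each animal's residual contribution
#' uses the inverse of the observed-trait submatrix of `R` for its missing
#' pattern, so any pattern of recorded traits is permitted.
#'
#' @param ped Pedigree data frame ([as_pedigree()]); every record animal must
#'   be present, and every pedigree animal receives equations (records or
#'   not).
#' @param records Long tibble of observations with columns `id`, `trait`
#'   (code or index), `value`, and `step` (the time step defining the fixed
#'   contemporary-group level for that trait).
#' @param panel A [trait_panel()] (or any list with `traits`, `G`, `R`).
#' @param f Optional precomputed inbreeding coefficients.
#' @return An object of class `mme_system`: sparse symmetric coefficient
#'   matrix `C`, right-hand side `rhs`, the fixed-level map, and dimensions.
#' @export
assemble_mme <- function(ped, records, panel, f = NULL) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  codes <- panel$traits$code
  nt <- length(codes)

  need <- c("id", "trait", "value", "step")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  tr <- if (is.character(records$trait)) {
    match(records$trait, codes)
  } else {
    as.integer(records$trait)
  }
  if (anyNA(tr) || any(tr < 1 | tr > nt)) stop("unknown trait in records")
  aid <- as.integer(records$id)
  if (any(aid < 1 | aid > n)) stop("record for animal not in pedigree")
  val <- as.numeric(records$value)
  if (anyNA(val)) stop("records must not contain NA; omit unobserved traits")
  step <- as.integer(records$step)
  if (anyDuplicated(paste(aid, tr))) {
    stop("at most one record per animal and trait")
  }

  ord <- order(aid, tr)
  aid <- aid[ord]; tr <- tr[ord]; val <- val[ord]; step <- step[ord]

  # fixed-effect levels: one per (trait, time step) with data
  fl <- factor(paste(tr, step, sep = ":"))
  nf <- nlevels(fl)
  lev_col <- as.integer(fl)
  lev_parts <- do.call(rbind, strsplit(levels(fl), ":", fixed = TRUE))
  lev_map <- tibble::tibble(
    col = seq_len(nf),
    trait = codes[as.integer(lev_parts[, 1])],
    step = as.integer(lev_parts[, 2])
  )

  acol0 <- function(a, t) nf + (a - 1L) * nt + t # solution column of (animal, trait)

  # group animals by missing pattern
  by_animal <- split(seq_along(aid), aid)
  pat_key <- vapply(by_animal, function(ix) paste(tr[ix], collapse = ","),
                    character(1))
  jj <- ii <- list()
  xs <- list()
  rhs_idx <- list()
  rhs_val <- list()
  k <- 0L
  for (key in unique(pat_key)) {
    rows_list <- by_animal[pat_key == key]
    p <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    m <- length(p)
    Rinv <- solve(panel$R[p, p, drop = FALSE])
    g <- length(rows_list)
    idx <- unlist(rows_list, use.names = FALSE)
    a_g <- aid[idx][seq(1, length(idx), by = m)]
    vals <- matrix(val[idx], nrow = g, ncol = m, byrow = TRUE)
    levs <- matrix(lev_col[idx], nrow = g, ncol = m, byrow = TRUE)
    for (t1 in seq_len(m)) {
      ac1 <- acol0(a_g, p[t1])
      for (t2 in seq_len(m)) {
        w <- Rinv[t1, t2]
        if (w == 0) next
        ac2 <- acol0(a_g, p[t2])
        k <- k + 1L
        ii[[k]] <- c(ac1, levs[, t1], levs[, t1], ac1)
        jj[[k]] <- c(ac2, levs[, t2], ac2, levs[, t2])
        xs[[k]] <- rep(w, 4L * g)
      }
    }
    vw <- vals %*% Rinv
    for (t in seq_len(m)) {
      k <- k + 1L
      ii[[k]] <- integer(0); jj[[k]] <- integer(0); xs[[k]] <- numeric(0)
      rhs_idx[[length(rhs_idx) + 1L]] <- c(acol0(a_g, p[t]), levs[, t])
      rhs_val[[length(rhs_val) + 1L]] <- rep(vw[, t], 2L)
    }
  }

  # genetic part: Ginv kronecker Ainv, animal-major ordering
  Ginv <- chol2inv(chol(panel$G))
  Ainv <- a_inverse(ped, f = f)
  K <- Matrix::kronecker(Ainv, Matrix::Matrix(Ginv, sparse = TRUE))
  Kt <- as(as(K, "generalMatrix"), "TsparseMatrix")

  ntot <- nf + n * nt
  ii <- c(unlist(ii, use.names = FALSE), Kt@i + 1L + nf)
  jj <- c(unlist(jj, use.names = FALSE), Kt@j + 1L + nf)
  xs <- c(unlist(xs, use.names = FALSE), Kt@x)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(ntot, ntot))
  C <- Matrix::forceSymmetric(C)

  rhs <- numeric(ntot)
  if (length(rhs_idx)) {
    idx <- unlist(rhs_idx, use.names = FALSE)
    vv <- unlist(rhs_val, use.names = FALSE)
    agg <- rowsum(vv, idx)
    rhs[as.integer(rownames(agg))] <- agg[, 1]
  }

  structure(
    list(C = C, rhs = rhs, n_fixed = nf, n_animals = n, n_traits = nt,
         trait_codes = codes, levels = lev_map, n_records = length(val)),
    class = "mme_system"
  )
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky factorization (CHOLMOD via the Matrix package,
#' fill-reducing permutation). The relative residual of the normal equations
#' is checked against `tol`; failure to reach it is an error.
#'
#' @param sys An [assemble_mme()] system.
#' @param tol Relative residual tolerance (default 1e-8).
#' @return An object of class `blup_fit`: matrix `ebv` (animals x traits),
#'   tibble `fixed` of time-step effect estimates, and solver diagnostics.
#' @export
solve_mme <- function(sys, tol = 1e-8) {
  stopifnot(inherits(sys, "mme_system"))
  C <- sys$C
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    # near-singular fixed block (e.g. confounded levels): tiny ridge retry
    C <- C + Matrix::Diagonal(nrow(C), 1e-8 * mean(Matrix::diag(C)))
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  }
  sol <- as.numeric(Matrix::solve(ch, sys$rhs))
  num <- sqrt(sum(as.numeric(sys$C %*% sol - sys$rhs)^2))
  den <- max(sqrt(sum(sys$rhs^2)), 1e-300)
  res <- if (all(sys$rhs == 0)) num else num / den
  if (!is.finite(res) || res > tol) {
    stop("mixed-model solve did not reach tolerance (relative residual ",
         signif(res, 3), " > ", tol, ")")
  }
  nf <- sys$n_fixed
  ebv <- matrix(sol[nf + seq_len(sys$n_animals * sys$n_traits)],
                ncol = sys$n_traits, byrow = TRUE)
  colnames(ebv) <- sys$trait_codes
  fixed <- sys$levels
  fixed$estimate <- sol[seq_len(nf)]
  structure(
    list(ebv = ebv, fixed = fixed,
         diagnostics = tibble::tibble(
           n_equations = length(sol), n_records = sys$n_records,
           relative_residual = res, method = "sparse Cholesky (CHOLMOD)"
         )),
    class = "blup_fit"
  )
}

#' Per-animal selection-index values under a breeding goal
#'
#' The index is the aggregate genotype of the *estimated* breeding values:
#' the dot product of the goal's economic values with each animal's EBV
#' vector.
#'
#' @param fit A [solve_mme()] fit.
#' @param values Economic-value vector in trait order (see [goal_vector()]).
#' @return Tibble with columns `id` and `index` (EUR).
#' @export
selection_index <- function(fit, values) {
  stopifnot(inherits(fit, "blup_fit"))
  if (length(values) != ncol(fit$ebv)) {
    stop("economic values do not match the number of traits")
  }
  tibble::tibble(id = seq_len(nrow(fit$ebv)),
                 index = as.numeric(fit$ebv %*% values))
}

#' @method tidy blup_fit
#' @export
tidy.blup_fit <- function(x, ...) {
  tibble::tibble(
    id = rep(seq_len(nrow(x$ebv)), times = ncol(x$ebv)),
    trait = rep(colnames(x$ebv), each = nrow(x$ebv)),
    ebv = as.numeric(x$ebv)
  )
}

#' @method glance blup_fit
#' @export
glance.blup_fit <- function(x, ...) x$diagnostics

#' @export
print.blup_fit <- function(x, ...) {
  cat("<blup_fit> ", nrow(x$ebv), " animals x ", ncol(x$ebv), " traits; ",
      x$diagnostics$n_records, " records; relative residual ",
      signif(x$diagnostics$relative_residual, 3), "\n", sep = "")
  invisible(x)
}
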