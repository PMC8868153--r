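#' Validate a pedigree table
#'
#' A pedigree is a plain data frame with integer columns `id`, `sire`, `dam`
#' (0 or `NA` = unknown parent). Ids must be contiguous `1..n` in row order
#' and parents must precede their offspring, which also guarantees the
#' pedigree is acyclic. Extra columns (sex, line, birth step, ...) pass
#' through untouched.
#'
#' @param ped Data frame with at least `id`, `sire`, `dam`.
#' @return The validated pedigree as a tibble, unknown parents coded 0.
#' @export
as_pedigree <- function(ped) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  ped <- tibble::as_tibble(ped)
  ped$id <- as.integer(ped$id)
  ped$sire <- as.integer(ifelse(is.na(ped$sire), 0L, ped$sire))
  ped$dam <- as.integer(ifelse(is.na(ped$dam), 0L, ped$dam))
  n <- nrow(ped)
  if (!identical(ped$id, seq_len(n))) {
    stop("pedigree ids must be contiguous 1..n in row order")
  }
  if (any(ped$sire > ped$id) || any(ped$dam > ped$id) ||
      any(ped$sire == ped$id & ped$sire > 0) ||
      any(ped$dam == ped$id & ped$dam > 0)) {
    stop("every parent must be listed before its offspring")
  }
  ped
}

#' Pedigree inbreeding coefficients
#'
#' Exact coefficients by the Meuwissen-Luo tabular scheme (compiled);
#' founders and animals with an unknown parent get `F = 0` (unknown parents
#' are treated as draws from the unrelated, non-inbred base population).
#'
#' @param ped Pedigree data frame (see [as_pedigree()]).
#' @return Tibble with columns `id` and `f`.
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  f <- ped_inbreeding_cpp(ped$sire, ped$dam, numeric(0))
  tibble::tibble(id = ped$id, f = f)
}

# Mendelian-sampling variances d_i given parent inbreeding:
# both parents known 0.5 - 0.25(Fs + Fd); one known 0.75 - 0.25 Fp; none 1.
mendelian_d <- function(sire, dam, f) {
  fs <- ifelse(sire > 0, f[pmax(sire, 1)], 0)
  fd <- ifelse(dam > 0, f[pmax(dam, 1)], 0)
  both <- sire > 0 & dam > 0
  one <- xor(sire > 0, dam > 0)
  d <- rep(1, length(sire))
  d[both] <- 0.5 - 0.25 * (fs[both] + fd[both])
  d[one] <- 0.75 - 0.25 * (fs + fd)[one]
  d
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: each animal contributes
#' `1/d_i` to its own diagonal and `-1/(2 d_i)` / `1/(4 d_i)` terms linking
#' it to its known parents, with `d_i` the Mendelian-sampling variance.
#'
#' @param ped Pedigree data frame.
#' @param f Optional precomputed inbreeding coefficients (in id order);
#'   computed with [inbreeding()] when missing.
#' @return Sparse symmetric matrix (class from the Matrix package).
#' @export
a_inverse <- function(ped, f = NULL) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)$f
  stopifnot(length(f) == n)
  d <- mendelian_d(ped$sire, ped$dam, f)
  alpha <- 1 / d

  i <- ped$id
  s <- ped$sire
  dm <- ped$dam
  has_s <- s > 0
  has_d <- dm > 0

  ii <- c(i, i[has_s], s[has_s], i[has_d], dm[has_d],
          s[has_s & has_d], dm[has_s & has_d])
  jj <- c(i, s[has_s], i[has_s], dm[has_d], i[has_d],
          dm[has_s & has_d], s[has_s & has_d])
  xx <- c(alpha,
          rep(-alpha[has_s] / 2, 2),
          rep(-alpha[has_d] / 2, 2),
          rep(alpha[has_s & has_d] / 4, 2))
  # parent-parent diagonal contributions
  ii <- c(ii, s[has_s], dm[has_d])
  jj <- c(jj, s[has_s], dm[has_d])
  xx <- c(xx, alpha[has_s] / 4, alpha[has_d] / 4)

  Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  )
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Intended for small pedigrees (oracles, fixtures, diagnostics); refuses
#' pedigrees beyond 2000 animals.
#'
#' @param ped Pedigree data frame.
#' @return Dense `n x n` matrix with `A[i, i] = 1 + F_i`.
#' @export
a_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (n > 2000) stop("a_matrix is for small pedigrees (n <= 2000)")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aij <- 0
        if (s > 0) aij <- aij + 0.5 * A[s, j]
        if (d > 0) aij <- aij + 0.5 * A[d, j]
        A[i, j] <- aij
        A[j, i] <- aij
      }
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

#' Numerator relationship between two animals
#'
#' @param ped Pedigree data frame (small; uses the tabular method).
#' @param i,j Animal ids.
#' @return The additive relationship `a_ij`; `a_ii = 1 + F_i`.
#' @export
relationship <- function(ped, i, j) {
  ped <- as_pedigree(ped)
  i <- as.integer(i)
  j <- as.integer(j)
  if (i < 1 || i > nrow(ped) || j < 1 || j > nrow(ped)) {
    stop("unknown animal id")
  }
  a_matrix(ped)[i, j]
}

#' Deterministic toy pedigrees for tests and examples
#'
#' @param kind `"trio"` (two founders and one offspring),
#'   `"full_sib_mating"` (offspring of full sibs, `F = 0.25`), or
#'   `"random_n"` (random pedigree over `n` animals: 5 founders, later
#'   animals with parents drawn among predecessors).
#' @param n Size for `"random_n"`.
#' @param seed Seed for `"random_n"`.
#' @return Pedigree tibble.
#' @export
make_toy_pedigree <- function(kind = c("trio", "full_sib_mating", "random_n"),
                              n = 30, seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    trio = tibble::tibble(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L)),
    full_sib_mating = tibble::tibble(
      id = 1:5,
      sire = c(0L, 0L, 1L, 1L, 3L),
      dam = c(0L, 0L, 2L, 2L, 4L)
    ),
    random_n = {
      stopifnot(n >= 6)
      withr_seed <- function(expr) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
        expr
      }
      withr_seed({
        sire <- integer(n)
        dam <- integer(n)
        for (i in 6:n) {
          p <- sample(seq_len(i - 1), 2)
          sire[i] <- p[1]
          dam[i] <- p[2]
        }
        tibble::tibble(id = seq_len(n), sire = sire, dam = dam)
      })
    }
  )
}
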