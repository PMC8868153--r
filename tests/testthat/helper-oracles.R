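# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package: recursive kinship instead of
# Meuwissen-Luo, dense matrix algebra instead of sparse Henderson rules.

# Recursive-kinship matrix (path-counting equivalent): K[i, j] is the kinship
# phi(i, j); the numerator relationship is 2 * K and F_i = 2 * K[i, i] - 1.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        kij <- 0
        if (s > 0) kij <- kij + 0.5 * K[s, j]
        if (d > 0) kij <- kij + 0.5 * K[d, j]
        K[i, j] <- kij
        K[j, i] <- kij
      }
    }
    K[i, i] <- 0.5 * (1 + if (s > 0 && d > 0) K[s, d] else 0)
  }
  K
}

inbreeding_oracle <- function(ped) 2 * diag(kinship_oracle(ped)) - 1

a_matrix_oracle <- function(ped) 2 * kinship_oracle(ped)

# Dense mixed-model solve, assembled from first principles: one scalar row
# per observed animal-trait, block-diagonal residual covariance over each
# animal's observed-trait pattern, additive prior kron(solve(A), solve(G))
# in animal-major order, fixed levels one per (trait, step) in the same
# lexicographic order the package uses.
dense_mme_oracle <- function(ped, records, G, R) {
  n <- nrow(ped)
  nt <- nrow(G)
  records <- records[order(records$id, records$trait), ]
  lev <- factor(paste(records$trait, records$step, sep = ":"))
  nf <- nlevels(lev)
  lev_col <- as.integer(lev)

  nobs <- nrow(records)
  W <- matrix(0, nobs, nf + n * nt)
  V <- matrix(0, nobs, nobs)
  for (r in seq_len(nobs)) {
    W[r, lev_col[r]] <- 1
    W[r, nf + (records$id[r] - 1) * nt + records$trait[r]] <- 1
  }
  for (a in unique(records$id)) {
    rows <- which(records$id == a)
    V[rows, rows] <- R[records$trait[rows], records$trait[rows]]
  }
  Vinv <- solve(V)
  prior <- kronecker(solve(a_matrix_oracle(ped)), solve(G))
  C <- t(W) %*% Vinv %*% W
  C[(nf + 1):(nf + n * nt), (nf + 1):(nf + n * nt)] <-
    C[(nf + 1):(nf + n * nt), (nf + 1):(nf + n * nt)] + prior
  rhs <- t(W) %*% Vinv %*% records$value
  sol <- solve(C, rhs)
  list(
    ebv = matrix(sol[(nf + 1):(nf + n * nt)], ncol = nt, byrow = TRUE),
    fixed = sol[seq_len(nf)],
    C = C
  )
}

# Tiny single-trait panel for dimension/limit tests.
mini_panel <- function(sa2 = 1, se2 = 1, n_traits = 1) {
  G <- diag(sa2, n_traits)
  R <- diag(se2, n_traits)
  codes <- paste0("T", seq_len(n_traits))
  dimnames(G) <- dimnames(R) <- list(codes, codes)
  list(
    traits = tibble::tibble(
      code = codes, unit = "u", sex_recording = "both_sexes",
      sa2 = diag(G), sp2 = diag(G) + diag(R), se2 = diag(R)
    ),
    G = G, R = R, P = G + R
  )
}

# Random pedigree + multi-trait records with random missing patterns,
# reproducible; used for dense-oracle comparisons.
random_blup_fixture <- function(n_animals, panel, seed, n_steps = 3,
                                p_obs = 0.7) {
  set.seed(seed)
  ped <- make_toy_pedigree("random_n", n = n_animals, seed = seed)
  nt <- nrow(panel$G)
  rec <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    obs <- which(runif(nt) < p_obs)
    if (!length(obs)) return(NULL)
    data.frame(id = a, trait = obs,
               value = rnorm(length(obs), sd = sqrt(diag(panel$P)[obs])),
               step = sample.int(n_steps, 1))
  }))
  list(ped = ped, records = tibble::as_tibble(rec))
}
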