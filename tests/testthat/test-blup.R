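panel <- trait_panel()

test_that("system dimensions follow records and pedigree", {
  mp <- mini_panel()
  ped <- tibble::tibble(id = 1L, sire = 0L, dam = 0L)
  rec <- tibble::tibble(id = 1L, trait = 1L, value = 2.5, step = 1L)
  sys <- assemble_mme(ped, rec, mp)
  expect_equal(nrow(sys$C), 2) # one fixed level + one animal equation
  expect_equal(sys$n_fixed, 1)
  fit <- solve_mme(sys)
  expect_equal(nrow(fit$ebv), 1)
})

test_that("a trio system matches the hand-assembled dense equations", {
  ped <- make_toy_pedigree("trio")
  rec <- tibble::tibble(id = c(1L, 2L, 3L, 3L),
                        trait = c(1L, 1L, 1L, 2L),
                        value = c(12, -5, 30, 40),
                        step = c(1L, 1L, 2L, 2L))
  oracle <- dense_mme_oracle(ped, rec, panel$G, panel$R)
  sys <- assemble_mme(ped, rec, panel)
  expect_equal(as.matrix(sys$C), unname(oracle$C), tolerance = 1e-8,
               ignore_attr = TRUE)
  fit <- solve_mme(sys)
  expect_equal(unname(fit$ebv), oracle$ebv, tolerance = 1e-6)
  expect_equal(fit$fixed$estimate, drop(oracle$fixed), tolerance = 1e-6)
})

test_that("missing traits use the observed-submatrix residual inverse", {
  ped <- tibble::tibble(id = 1L, sire = 0L, dam = 0L)
  obs <- setdiff(seq_len(10), which(panel$traits$code == "LP5"))
  rec <- tibble::tibble(id = 1L, trait = obs, value = rnorm(9), step = 1L)
  sys <- assemble_mme(ped, rec, panel)
  # the animal-by-animal residual block must equal solve(R[obs, obs])
  acols <- sys$n_fixed + obs
  blk <- as.matrix(sys$C[acols, acols]) -
    chol2inv(chol(panel$G))[obs, obs] # subtract the genetic prior
  expect_equal(blk, unname(solve(panel$R[obs, obs])), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("solutions match dense solves on multi-trait fixtures", {
  mp3 <- list(
    traits = tibble::tibble(code = c("A", "B", "C"), unit = "u",
                            sex_recording = "both_sexes"),
    G = matrix(c(4, 1, 0.5, 1, 2, -0.3, 0.5, -0.3, 1), 3, 3),
    R = matrix(c(6, -1, 0, -1, 5, 1, 0, 1, 3), 3, 3)
  )
  mp3$P <- mp3$G + mp3$R
  for (seed in c(11, 23)) {
    fx <- random_blup_fixture(40, mp3, seed = seed)
    oracle <- dense_mme_oracle(fx$ped, fx$records, mp3$G, mp3$R)
    fit <- solve_mme(assemble_mme(fx$ped, fx$records, mp3))
    expect_equal(unname(fit$ebv), oracle$ebv, tolerance = 1e-6)
  }
})

test_that("a record-free non-parent gets the parent-average EBV", {
  ped <- tibble::tibble(id = 1:5,
                        sire = c(0L, 0L, 0L, 0L, 1L),
                        dam = c(0L, 0L, 0L, 0L, 2L))
  set.seed(8)
  rec <- tidyr::expand_grid(id = 1:4, trait = 1:10)
  rec$value <- rnorm(nrow(rec), sd = sqrt(panel$traits$sp2[rec$trait]))
  rec$step <- 1L
  fit <- solve_mme(assemble_mme(ped, rec, panel))
  expect_equal(fit$ebv[5, ], (fit$ebv[1, ] + fit$ebv[2, ]) / 2,
               tolerance = 1e-8)
  expect_gt(max(abs(fit$ebv[1, ])), 0) # the identity is not vacuous
})

test_that("EBVs vanish in the no-heritability limit", {
  mp <- mini_panel(sa2 = 1e-9, se2 = 1)
  ped <- make_toy_pedigree("trio")
  rec <- tibble::tibble(id = 1:3, trait = 1L, value = c(10, -4, 6),
                        step = c(1L, 1L, 2L))
  fit <- solve_mme(assemble_mme(ped, rec, mp))
  expect_true(all(abs(fit$ebv) < 1e-6))
})

test_that("solutions are invariant to record ordering", {
  fx <- random_blup_fixture(25, panel, seed = 31)
  fit1 <- solve_mme(assemble_mme(fx$ped, fx$records, panel))
  shuffled <- fx$records[sample.int(nrow(fx$records)), ]
  fit2 <- solve_mme(assemble_mme(fx$ped, shuffled, panel))
  expect_equal(fit1$ebv, fit2$ebv, tolerance = 1e-10)
})

test_that("selection index prices EBVs linearly", {
  fx <- random_blup_fixture(15, panel, seed = 41)
  fit <- solve_mme(assemble_mme(fx$ped, fx$records, panel))
  v <- goal_vector(panel, "curOBG")
  idx <- selection_index(fit, v)
  expect_equal(idx$index, as.numeric(fit$ebv %*% v))
  fit0 <- fit
  fit0$ebv <- fit$ebv * 0
  expect_equal(selection_index(fit0, v)$index, rep(0, 15))
  fit2 <- fit
  fit2$ebv <- fit$ebv * 2
  expect_equal(selection_index(fit2, v)$index, 2 * idx$index)
  # a single-trait EBV of -0.01 on feed efficiency under curOBG
  ebv_fe <- matrix(0, 1, 10, dimnames = list(NULL, panel$traits$code))
  ebv_fe[1, "FE"] <- -0.01
  fit_fe <- structure(list(ebv = ebv_fe), class = "blup_fit")
  expect_equal(selection_index(fit_fe, v)$index, 0.29333)
})

test_that("record validation rejects malformed input", {
  ped <- make_toy_pedigree("trio")
  expect_error(assemble_mme(ped, tibble::tibble(id = 9L, trait = 1L,
                                                value = 1, step = 1L), panel),
               "not in pedigree")
  expect_error(assemble_mme(ped, tibble::tibble(id = 1L, trait = 99L,
                                                value = 1, step = 1L), panel),
               "unknown trait")
  expect_error(assemble_mme(ped, tibble::tibble(id = c(1L, 1L), trait = 1L,
                                                value = 1:2, step = 1L), panel),
               "one record")
})
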