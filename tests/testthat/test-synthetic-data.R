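test_that("the generator is deterministic and study-shaped", {
  d1 <- simulate_dataset(synth_config(seed = 101))
  d2 <- simulate_dataset(synth_config(seed = 101))
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$tree$edge.length, d2$tree$edge.length)

  expect_equal(ape::Ntip(d1$tree), 38L)
  expect_equal(sum(d1$traits$status == "extant"), 25L)
  expect_equal(sum(d1$traits$status == "extinct"), 13L)
  expect_setequal(as.character(unique(d1$traits$locomotion)),
                  LOCOMOTOR_LEVELS)
  # fossil tips within the Eocene-Miocene window
  ages <- d1$truth$tip_ages[d1$traits$status == "extinct"]
  expect_true(all(ages >= 5 & ages <= 50))
  # age bins contain the true ages
  bins <- d1$age_bins[match(names(ages), d1$age_bins$tip), ]
  expect_true(all(ages <= bins$FAD_early & ages >= bins$FAD_late))
  # the trait-table invariants hold by construction (validator passed)
  expect_s3_class(d1$traits, "trait_table")
  expect_equal(sum(is.na(d1$traits$petrosal_lobule_volume)), 1L)
})

test_that("byte-identical files come from the same seed", {
  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(simulate_dataset(synth_config(seed = 7)), dir1)
  write_dataset(simulate_dataset(synth_config(seed = 7)), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("tiny transition rates leave the true map nearly constant", {
  # per-pair rate 2.5e-4 = total leaving rate 1e-3 per Myr
  n_few <- 0L
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    ds <- simulate_dataset(synth_config(seed = 300 + r, q_true = 2.5e-4,
                                        require_all_categories = FALSE))
    if (ds$truth$locomotion_changes <= 2) n_few <- n_few + 1L
  }
  expect_gte(n_few / n_rep, 0.9)
})

test_that("the small fixture supports its oracle computations", {
  fx <- fixture_small()
  expect_equal(ape::Ntip(fx$tree), 6L)
  # shared-path matrix against the hand-derived values
  C <- shared_path_matrix(fx$tree)
  expect_equal(C["A", "B"], 8)   # MRCA(A,B) at height 5 + 3
  expect_equal(C["A", "C"], 5)
  expect_equal(C["A", "E"], 0)
  expect_equal(C["E", "F"], 6)
  expect_equal(unname(diag(C)), rep(10, 6))
  expect_equal(C, brute_shared_paths(fx$tree))
  # enumeration oracle on its 2 locomotor groups
  p_asym <- fp_ksample(fx$traits$body_mass, fx$groups)$p
  p_exact <- fp_exact_pvalue(fx$traits$body_mass, fx$groups)
  expect_lt(abs(p_asym - p_exact), 0.05)
  # GLS intercept by explicit inversion
  y <- log10(fx$traits$endocranial_volume)
  ones <- matrix(1, 6, 1)
  beta <- solve(t(ones) %*% solve(C) %*% ones, t(ones) %*% solve(C) %*% y)
  expect_equal(unname(gls_fit(y, ones, C)$coefficients),
               as.numeric(beta), tolerance = 1e-10)
})

test_that("noise-free datasets have a deterministic allometric slope", {
  zero_off <- c(arboreal = 0, fossorial = 0, glider = 0,
                scansorial = 0, terrestrial = 0)
  slopes <- vapply(1:5, function(r) {
    ds <- simulate_dataset(synth_config(seed = 500 + r, resid_sd = 0,
                                        loco_offsets = zero_off))
    tab <- ds$traits[match(ds$tree$tip.label, ds$traits$species), ]
    y <- log10(tab$endocranial_volume)
    X <- cbind(1, log10(tab$body_mass))
    unname(gls_fit(y, X, shared_path_matrix(ds$tree))$coefficients[2])
  }, 0)
  expect_lt(max(abs(slopes - 0.57)), 1e-8)
  expect_equal(stats::var(slopes), 0, tolerance = 1e-16)
})
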