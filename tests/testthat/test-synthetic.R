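test_that("chi-1 build/measure round-trip holds over a dense grid", {
  # 5-degree grid across the full circle (open at -180)
  grid <- seq(-175, 180, by = 5)
  rebuilt <- vapply(grid, function(chi) {
    chi1_angles(build_his_residue(chi))$chi1
  }, numeric(1))
  expect_equal(rebuilt, grid, tolerance = 1e-6)
  # bin edge lands exactly and classifies as trans under the default bins
  edge <- chi1_angles(build_his_residue(120))$chi1
  expect_equal(edge, 120, tolerance = 1e-6)
  expect_identical(classify_rotamer(edge), "trans")
})

test_that("place_atom honours bond length, angle and torsion", {
  set.seed(505)
  for (i in 1:20) {
    a <- rnorm(3); b <- a + rnorm(3); c0 <- b + rnorm(3)
    bond <- runif(1, 1, 2); angle <- runif(1, 60, 150)
    torsion <- runif(1, -179, 180)
    d <- tryCatch(place_atom(a, b, c0, bond, angle, torsion),
                  error = function(e) NULL)
    if (is.null(d)) next
    expect_equal(sqrt(sum((d - c0)^2)), bond, tolerance = 1e-9)
    v1 <- b - c0; v2 <- d - c0
    got_angle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(got_angle, angle, tolerance = 1e-6)
    expect_equal(dihedral_angle(a, b, c0, d), torsion, tolerance = 1e-6)
  }
})

test_that("built structures are valid survey inputs with the declared content", {
  path <- tempfile(fileext = ".pdb")
  build_structure(list(A = -60, B = 180), ph = 7.5, path = path,
                  sulfate = list(chain = "A", distance = 3.2))
  s <- read_structure(path)
  calls <- assign_rotamers(s, 260)
  calls <- annotate_anion_coordination(s, calls)
  expect_equal(nrow(calls), 2)
  expect_identical(calls$rotamer[calls$chain == "A"], "gauche-")
  expect_identical(calls$rotamer[calls$chain == "B"], "trans")
  expect_true(calls$anion_coordinated[calls$chain == "A"])
  expect_false(calls$anion_coordinated[calls$chain == "B"])
  expect_equal(s$metadata$crystallization_ph, 7.5)

  # 8 subunits, four of each label -> distinct concordance, 4/4 counts
  path8 <- tempfile(fileext = ".pdb")
  chains <- as.list(c(rep(-60, 4), rep(180, 4)))
  names(chains) <- LETTERS[1:8]
  build_structure(chains, ph = 7.5, path = path8)
  calls8 <- assign_rotamers(read_structure(path8), 260)
  expect_equal(sum(calls8$rotamer == "gauche-"), 4)
  expect_equal(sum(calls8$rotamer == "trans"), 4)
  expect_identical(dimer_concordance(calls8), "distinct")
})

test_that("the manifest-profile generator agrees with its own bookkeeping", {
  dir <- tempfile()
  manifest <- hiska_manifest()
  truth <- simulate_survey_structures(manifest, dir, seed = 99)
  expect_equal(nrow(truth), nrow(manifest))
  expect_setequal(unique(truth$pdb_id), unique(manifest$pdb_id))
  # every generated chi-1 classifies as the label it was drawn for
  expect_identical(classify_rotamer(truth$chi1), truth$rotamer)
  # the survey over the generated files equals the generated tally exactly
  survey <- compile_survey(manifest, mode = "coordinates",
                           structures_dir = dir)
  expect_equal(unname(survey$counts["gauche-"]),
               sum(truth$rotamer == "gauche-"))
  expect_equal(unname(survey$counts["trans"]),
               sum(truth$rotamer == "trans"))
  expect_false(survey$partial)
})

test_that("generator output is reproducible under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- simulate_survey_structures(hiska_manifest(), d1, seed = 7)
  t2 <- simulate_survey_structures(hiska_manifest(), d2, seed = 7)
  expect_equal(t1$chi1, t2$chi1)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(purrr::map_chr(f1, ~ paste(readLines(.x),
                                                     collapse = "\n"))),
                   unname(purrr::map_chr(f2, ~ paste(readLines(.x),
                                                     collapse = "\n"))))
  # decay simulator: bitwise-identical under the same seed
  s1 <- simulate_decay(10, sigma = 0.05, reps = 5, seed = 11)
  s2 <- simulate_decay(10, sigma = 0.05, reps = 5, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_decay(10, sigma = 0.05, reps = 5, seed = 12)
  expect_false(identical(s1$signal, s3$signal))
})

test_that("noise-free decay simulation is the exact exponential", {
  tc <- simulate_decay(10, sigma = 0)
  expect_equal(tc$signal, 100 * exp(-log(2) * tc$time / 10))
  f <- suppressWarnings(fit_decay(tc))
  expect_equal(f$half_life, 10, tolerance = 1e-9)
})
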