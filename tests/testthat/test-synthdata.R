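test_that("Yule trees have the right shape and are reproducible", {
  tr2 <- simulate_tree(2, seed = 1L)
  expect_identical(ape::Ntip(tr2), 2L)
  tr <- simulate_tree(50, seed = 7L)
  expect_identical(ape::Ntip(tr), 50L)
  expect_identical(tr$Nnode, 49L)
  expect_identical(sort(tr$tip.label), sort(paste0("s", 1:50)))
  expect_identical(ape::write.tree(simulate_tree(50, seed = 7L)),
                   ape::write.tree(tr))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("gene content evolution respects rates and stationarity", {
  tr <- simulate_tree(30, seed = 3L)
  frozen <- evolve_gene_content(tr, 10L, gain = 0, loss = 0, root_prob = 1,
                                seed = 1L)
  expect_true(all(frozen == 1L))
  # long branches: presence frequency approaches gain / (gain + loss)
  long <- tr; long$edge.length <- long$edge.length * 100
  m <- evolve_gene_content(long, 200L, gain = 0.3, loss = 0.7, seed = 2L)
  expect_lt(abs(mean(m) - 0.3), 0.05)
  expect_identical(
    unclass(evolve_gene_content(tr, 20L, gain = .4, loss = .6, seed = 5L)),
    unclass(evolve_gene_content(tr, 20L, gain = .4, loss = .6, seed = 5L)))
})

test_that("phenotype assignment follows the causal threshold and noise", {
  m <- ortholog_matrix(matrix(c(1L, 0L, 1L, 0L), 4, 1),
                       paste0("s", 1:4), "f1")
  ph <- assign_phenotypes(m, "f1", threshold = 1L, noise = 0, seed = 1L)
  expect_identical(ph$label, unname(ifelse(m[, 1] == 1L, "positive", "negative")))
  expect_error(assign_phenotypes(m, "f1", noise = 0.5), "noise")
  expect_error(assign_phenotypes(m, "nope"), "causal ids")
  big <- ortholog_matrix(matrix(1L, 500, 1), paste0("s", 1:500), "f1")
  ph2 <- assign_phenotypes(big, "f1", threshold = 1L, noise = 0.1, seed = 2L)
  flip_rate <- mean(ph2$label == "negative")
  expect_lt(abs(flip_rate - 0.1), 0.03)
})

test_that("proteome generation mirrors presence and mutation arithmetic", {
  st <- simulate_sc_study(sim_config(n_strains = 12L, n_families = 15L,
                                     n_causal = 3L, threshold = 2L,
                                     seq_len = 60L, seed = 5L))
  pr0 <- generate_proteomes(st$matrix, seq_len = 60L, mutation_rate = 0,
                            seed = 9L)
  for (f in colnames(st$matrix)[1:5]) {
    msa <- pr0$msas[[f]]
    if (length(msa) >= 2) expect_identical(length(unique(msa)), 1L)
  }
  # a strain lacking family f carries no f protein
  absent <- which(unclass(st$matrix) == 0L, arr.ind = TRUE)[1, ]
  s <- rownames(st$matrix)[absent[1]]; f <- colnames(st$matrix)[absent[2]]
  expect_false(any(startsWith(names(pr0$proteomes[[s]]), paste0(f, "|"))))
  # pairwise identity ~ 1 - 2 * rate * 19/20 at low rates
  pr <- generate_proteomes(st$matrix, seq_len = 60L, mutation_rate = 0.05,
                           seed = 11L)
  idents <- unlist(lapply(pr$msas, function(msa) {
    if (length(msa) < 2) return(NULL)
    a <- strsplit(msa[1], "")[[1]]
    vapply(msa[-1], function(s) mean(a == strsplit(s, "")[[1]]), 0)
  }))
  expected <- 1 - 2 * 0.05 * (19 / 20) + (0.05 * 19 / 20)^2
  expect_lt(abs(mean(idents) - expected), 0.015)
})

test_that("survey generator hits its Spearman target", {
  r1 <- generate_survey_records(n = 100, target_rho = 1, seed = 1L)
  expect_equal(spearman_correlation(r1$depth, r1$score)$rho, 1.0)
  r0 <- generate_survey_records(n = 450, target_rho = 0, seed = 2L)
  expect_lt(abs(spearman_correlation(r0$depth, r0$score)$rho), 0.15)
  r <- generate_survey_records(n = 450, target_rho = 0.41, seed = 3L)
  expect_lt(abs(spearman_correlation(r$depth, r$score)$rho - 0.41), 0.1)
  expect_identical(generate_survey_records(n = 50, seed = 4L),
                   generate_survey_records(n = 50, seed = 4L))
  expect_true(all(r$depth >= 0 & r$depth <= 4000))
  expect_true(all(r$score >= 0 & r$score <= 1))
})

test_that("goniometer forward model closes the loop with spot detection", {
  sp <- generate_goniometer_spectrum(d = 440, noise = 0, seed = 1L)
  spots <- detect_diffraction_spots(sp, prominence = 5)
  expect_gt(nrow(spots), 3)
  step <- diff(sp$wavelengths[1:2])
  for (k in seq_len(nrow(spots))) {
    lams <- c(predict_spot_wavelength(440, -45, spots$theta_out[k], -1L),
              predict_spot_wavelength(440, -45, spots$theta_out[k], 1L))
    expect_lte(min(abs(spots$lambda_peak[k] - lams), na.rm = TRUE), step)
  }
  fit <- fit_lattice_constant(spots, theta_in = -45, orders = c(-1L, 1L))
  expect_lt(abs(fit$d - 440), 2)
  # all diffraction wavelengths outside the grid: empty spot set
  tiny <- generate_goniometer_spectrum(d = 150, noise = 0, seed = 2L)
  expect_identical(nrow(detect_diffraction_spots(tiny)), 0L)
  expect_equal(generate_goniometer_spectrum(d = 400, noise = .05, seed = 3L),
               generate_goniometer_spectrum(d = 400, noise = .05, seed = 3L))
})

test_that("the simulated study is reproducible and internally consistent", {
  a <- simulate_sc_study(sim_config(n_strains = 20L, n_families = 25L,
                                    n_causal = 5L, threshold = 3L,
                                    seq_len = 30L, seed = 13L))
  b <- simulate_sc_study(sim_config(n_strains = 20L, n_families = 25L,
                                    n_causal = 5L, threshold = 3L,
                                    seq_len = 30L, seed = 13L))
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$phenotypes$label, b$phenotypes$label)
  expect_identical(a$proteomes, b$proteomes)
  # every proteome entry corresponds to a presence in the matrix
  for (s in rownames(a$matrix)) {
    fams <- sub("\\|.*", "", names(a$proteomes[[s]]))
    expect_identical(sort(fams), sort(colnames(a$matrix)[a$matrix[s, ] == 1L]))
  }
})
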