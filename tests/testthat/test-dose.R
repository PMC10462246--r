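test_that("absorbed dose converts hours once and sums source contributions", {
  ph <- phantom("p", 1000, data.frame(region = "Organ", mass_g = 10,
                                      is_source = TRUE, is_target = TRUE))
  sv <- svalue_matrix(data.frame(target = "Organ", source = "Organ",
                                 svalue_Gy_per_Bq_s = 5e-15), ph)
  rep1 <- absorbed_dose(c(Organ = 2), sv)
  expect_equal(unname(rep1$d), 2 * 3600 * 5e-15, tolerance = 1e-12)

  expect_equal(unname(absorbed_dose(c(Organ = 0), sv)$d), 0)
  expect_error(absorbed_dose(c(Spleen = 1), sv), "Spleen",
               class = "predose_validation_error")
})

test_that("dose reports are linear in the TIAC vector and conserve breakdowns", {
  ph <- toy_human()
  sv <- toy_svalues(ph)
  set.seed(9)
  for (k in 1:5) {
    a1 <- setNames(runif(length(sv$sources), 0, 10), sv$sources)
    a2 <- setNames(runif(length(sv$sources), 0, 10), sv$sources)
    r1 <- absorbed_dose(a1, sv)
    r2 <- absorbed_dose(a2, sv)
    r12 <- absorbed_dose(a1 + a2, sv)
    expect_equal(r12$d, r1$d + r2$d, tolerance = 1e-12)
    expect_equal(absorbed_dose(3.7 * a1, sv)$d, 3.7 * r1$d, tolerance = 1e-12)
    # per-source contributions sum to each target's total
    expect_equal(rowSums(r1$contributions), r1$d, tolerance = 1e-12)
    # per-radiation-type partition also conserves the total
    expect_equal(rowSums(r1$by_type), r1$d, tolerance = 1e-12)
  }
})

test_that("equivalent dose weights the per-radiation-type partition by wR", {
  ph <- toy_human()
  sv <- toy_svalues(ph)
  tiacs <- setNames(c(2, 1, 0.5, 1.5, 8), sv$sources)
  rep_ <- absorbed_dose(tiacs, sv, phantom = ph)
  # unit weights leave the absorbed dose unchanged
  w1 <- tissue_weights(wR = c(beta = 1, photon = 1))
  expect_equal(equivalent_dose(rep_, w1)$h, rep_$d, tolerance = 1e-12)

  # single radiation type with wR = 20
  ph1 <- phantom("p", 1000, data.frame(region = "Organ", mass_g = 10,
                                       is_source = TRUE, is_target = TRUE))
  sva <- svalue_matrix(data.frame(target = "Organ", source = "Organ",
                                  svalue_Gy_per_Bq_s = 1e-12 / 3600,
                                  radiation_type = "alpha"), ph1)
  ra <- absorbed_dose(c(Organ = 1), sva)
  ha <- equivalent_dose(ra, tissue_weights(wR = c(alpha = 20)))$h
  expect_equal(unname(ha), 2e-11, tolerance = 1e-12)

  # mixture 0.7 at wR = 1 plus 0.3 at wR = 20 gives h = 6.7 d
  nuc <- radionuclide("mix", 10, 1e-14,
                      components = data.frame(radiation_type = c("beta", "alpha"),
                                              dose_fraction = c(0.7, 0.3)))
  svt <- svalue_matrix(data.frame(target = "Organ", source = "Organ",
                                  svalue_Gy_per_Bq_s = 5e-15), ph1)
  rmix <- absorbed_dose(c(Organ = 2), svt, nuclide = nuc)
  hmix <- equivalent_dose(rmix, tissue_weights(wR = c(beta = 1, alpha = 20)))
  expect_equal(unname(hmix$h), unname(6.7 * rmix$d), tolerance = 1e-12)
  expect_error(equivalent_dose(rmix, tissue_weights(wR = c(beta = 1))),
               "alpha", class = "predose_validation_error")
})

test_that("effective dose is the tissue-weighted sex average, humans only", {
  ph <- phantom("p", 70000,
                data.frame(region = c("A", "B"), mass_g = c(100, 200),
                           is_source = TRUE, is_target = TRUE),
                species = "human")
  mk_rep <- function(h) {
    sv <- suppressWarnings(
      svalue_matrix(data.frame(target = c("A", "B"), source = c("A", "B"),
                               svalue_Gy_per_Bq_s = 1e-15), ph))
    r <- absorbed_dose(c(A = 1, B = 1), sv, phantom = ph)
    r$h <- h
    r
  }
  w <- tissue_weights(wT = c(A = 0.5, B = 0.5),
                      wR = c(total = 1))
  male <- mk_rep(c(A = 1e-11, B = 3e-11))
  female <- mk_rep(c(A = 2e-11, B = 4e-11))
  e <- effective_dose(male, female, w)
  expect_equal(e$e_Sv_per_Bq, 2.5e-11, tolerance = 1e-12)
  # symmetric under sex swap
  expect_equal(effective_dose(female, male, w)$e_Sv_per_Bq, e$e_Sv_per_Bq)
  # identical reports collapse to sum wT h
  expect_equal(effective_dose(male, male, w)$e_Sv_per_Bq,
               sum(0.5 * male$h), tolerance = 1e-12)
  # per-tissue contributions sum to e
  expect_equal(sum(e$contributions$contribution_Sv_per_Bq), e$e_Sv_per_Bq,
               tolerance = 1e-12)
  # zero weights zero the coefficient
  w0 <- suppressWarnings(tissue_weights(wT = c(A = 0, B = 0)))
  expect_equal(effective_dose(male, female, w0)$e_Sv_per_Bq, 0)

  wmiss <- suppressWarnings(tissue_weights(wT = c(A = 0.5, C = 0.5)))
  expect_error(effective_dose(male, female, wmiss), "C",
               class = "predose_validation_error")

  phm <- phantom("m", 25, data.frame(region = "A", mass_g = 1,
                                     is_source = TRUE, is_target = TRUE),
                 species = "mouse")
  svm <- svalue_matrix(data.frame(target = "A", source = "A",
                                  svalue_Gy_per_Bq_s = 1e-13), phm)
  rm_ <- absorbed_dose(c(A = 1), svm, phantom = phm)
  rm_$h <- c(A = 1e-11)
  expect_error(effective_dose(rm_, rm_, w), "human",
               class = "predose_validation_error")
})

test_that("RBE weighting parallels wR but with free units", {
  ph1 <- phantom("p", 1000, data.frame(region = "Organ", mass_g = 10,
                                       is_source = TRUE, is_target = TRUE))
  sva <- svalue_matrix(data.frame(target = "Organ", source = "Organ",
                                  svalue_Gy_per_Bq_s = 1e-12 / 3600,
                                  radiation_type = "alpha"), ph1)
  r <- absorbed_dose(c(Organ = 1), sva)
  expect_equal(unname(rbe_weighted_dose(r, c(alpha = 1))$d_rbe), unname(r$d))
  expect_equal(unname(rbe_weighted_dose(r, c(alpha = 5))$d_rbe), 5e-12,
               tolerance = 1e-12)

  nuc <- radionuclide("mix", 10, 1e-14,
                      components = data.frame(radiation_type = c("alpha", "beta"),
                                              dose_fraction = c(0.9, 0.1)))
  svt <- svalue_matrix(data.frame(target = "Organ", source = "Organ",
                                  svalue_Gy_per_Bq_s = 5e-15), ph1)
  rmix <- absorbed_dose(c(Organ = 2), svt, nuclide = nuc)
  out <- rbe_weighted_dose(rmix, c(alpha = 5, beta = 1), unit = "Gy-Eq")
  expect_equal(unname(out$d_rbe), unname(4.6 * rmix$d), tolerance = 1e-12)
  expect_equal(out$rbe_unit, "Gy-Eq")
  expect_error(rbe_weighted_dose(rmix, c(alpha = -1, beta = 1)),
               class = "predose_validation_error")
})

test_that("self-dose sanity check approximates local absorption", {
  nuc <- radionuclide("np", 100, 1.6e-14)
  chk <- self_dose_check(1, 10, nuc)
  expect_equal(chk$d_approx_Gy_per_Bq, 3600 * 1.6e-14 / 0.01, tolerance = 1e-12)
  expect_false(chk$flagged)

  # pure-photon emitter: check skipped with a notice
  phot <- radionuclide("ph", 100, 0)
  expect_message(chk0 <- self_dose_check(1, 10, phot), "skipped")
  expect_true(chk0$skipped)
  expect_equal(chk0$d_approx_Gy_per_Bq, 0)

  # S(self) constructed as delta_np / M makes the ratio exactly 1
  m_g <- 10
  s_local <- nuc$delta_np_J / (m_g / 1000)
  d_soft <- 2 * 3600 * s_local
  chk1 <- self_dose_check(2, m_g, nuc, reported_d = d_soft)
  expect_equal(chk1$ratio, 1, tolerance = 1e-12)
  expect_false(chk1$flagged)

  expect_warning(chk2 <- self_dose_check(2, m_g, nuc, reported_d = d_soft / 10),
                 class = "predose_self_dose")
  expect_true(chk2$flagged)
})
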