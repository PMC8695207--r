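test_that("continuous banding honours inclusive edges, symmetry and sd = 0", {
  bands <- c(1.5, 1.0, 0.5, -1.0)
  # exactly at a band edge takes the better score ("within" is inclusive)
  expect_equal(score_continuous(10 + 1 * 2, 10, 2, bands)$score, 1.5)
  expect_equal(score_continuous(10 + 2 * 2, 10, 2, bands)$score, 1.0)
  expect_equal(score_continuous(10 + 3 * 2, 10, 2, bands)$score, 0.5)
  expect_equal(score_continuous(10 + 3.0001 * 2, 10, 2, bands)$score, -1.0)
  # symmetry about the mean for arbitrary displacements
  for (d in c(0.3, 1.7, 2.9, 5)) {
    expect_identical(score_continuous(10 + d, 10, 2, bands),
                     score_continuous(10 - d, 10, 2, bands))
  }
  # degenerate reference: sd = 0
  expect_equal(score_continuous(10, 10, 0, bands)$score, 1.5)
  expect_equal(score_continuous(10.001, 10, 0, bands)$score, -1.0)
  expect_error(score_continuous(1, 0, -1, bands), class = "hl_score_error")
})

test_that("band index is non-decreasing in |value - mean|", {
  bands <- c(1.5, 1.0, 0.5, -1.0)
  z <- seq(0, 5, by = 0.01)
  idx <- match(score_continuous(10 + z * 2, 10, 2, bands)$band,
               c("within_1sd", "within_2sd", "within_3sd", "beyond_3sd"))
  expect_true(all(diff(idx) >= 0))
})

test_that("discrete offsets look up the printed cells, catch-all beyond +/-2", {
  rules <- default_rules()
  fc <- rules$discrete_offsets["formal_charge74", ]
  expect_equal(score_discrete(2, 0, fc)$score, -3.0)
  expect_equal(score_discrete(-1, 0, fc)$score, 2.0)
  expect_equal(score_discrete(3, 0, fc)$score, -1.0)  # beyond +2: catch-all
  hbd <- rules$discrete_offsets["hbd74", ]
  expect_equal(score_discrete(0, 0, hbd)$score, 1.5)
  rb <- rules$discrete_offsets["rotatable_bonds", ]
  expect_equal(score_discrete(9, 5, rb)$score, -1.0)
  expect_identical(score_discrete(7, 5, rb)$offset, "+2")
})

test_that("the H-bond acceptor NA cells follow the selected policy", {
  mirrored <- default_rules("mirrored")$discrete_offsets["hba74", ]
  strict <- default_rules("strict")$discrete_offsets["hba74", ]
  expect_equal(score_discrete(1, 2, mirrored)$score, 1.0)
  expect_equal(score_discrete(0, 2, mirrored)$score, 0.5)
  expect_equal(score_discrete(1, 2, strict)$score, -1.0)
  expect_equal(score_discrete(0, 2, strict)$score, -1.0)
  # above-mode cells agree between policies
  expect_equal(score_discrete(3, 2, mirrored)$score,
               score_discrete(3, 2, strict)$score)
})

test_that("score_compound totals equal the sum of independent per-descriptor calls", {
  ref <- published_reference()
  rules <- default_rules()
  set.seed(202)
  for (i in 1:25) {
    d <- at_reference(
      molar_mass = runif(1, 50, 900), aromatic_pct = runif(1, 0, 100),
      psa = runif(1, 0, 250), logd74 = runif(1, -6, 12),
      logs = runif(1, -9, 2), logp = runif(1, -4, 10),
      rotatable_bonds = sample(0:15, 1), hba74 = sample(0:10, 1),
      hbd74 = sample(0:8, 1), formal_charge74 = sample(-3:3, 1))
    br <- score_compound(d, ref, rules)
    manual <- sum(vapply(continuous_descriptors(), function(nm)
      score_continuous(d[[nm]], ref$continuous[nm, "mean"],
                       ref$continuous[nm, "sd"],
                       rules$continuous_bands[nm, ])$score, numeric(1))) +
      sum(vapply(discrete_descriptors(), function(nm)
        score_discrete(d[[nm]], ref$modes[[nm]],
                       rules$discrete_offsets[nm, ])$score, numeric(1)))
    expect_equal(br$total, manual)
    expect_equal(br$total, sum(br$per_descriptor$score))
    expect_gte(br$total, -12); expect_lte(br$total, 18)
  }
})

test_that("totals are exact half-point arithmetic with no float drift", {
  br <- score_compound(at_reference(logp = 2.9 + 1.5 * 2.5), # band 3: 1.0
                       published_reference())
  expect_identical(br$total * 2, round(br$total * 2))
  expect_equal(br$total, 16)
})

test_that("scoring refuses incomplete descriptor sets without partial totals", {
  x <- at_reference(); x$psa <- NULL
  expect_error(score_compound(x), "psa", class = "hl_descriptor_error")
})

test_that("rule-set extremes follow the per-descriptor maxima and minima", {
  expect_equal(max_score(default_rules()), 18)
  expect_equal(min_score(default_rules()), -12)
  # de-weighting log P to the standard bands lowers the maximum by 1.5
  rules <- default_rules()
  cb <- rules$continuous_bands
  cb["logp", ] <- c(1.5, 1.0, 0.5, -1.0)
  expect_equal(max_score(herblike:::new_hl_rules(cb, rules$discrete_offsets)),
               16.5)
  # all-zero rules
  zero <- herblike:::new_hl_rules(cb * 0, rules$discrete_offsets * 0)
  expect_equal(max_score(zero), 0)
  expect_equal(min_score(zero), 0)
})

test_that("ranking sorts by total then id, thresholds with >=, and keeps rejects", {
  fx <- worked_fixture()
  fx$expected_total <- NULL
  broken <- fx[1, ]; broken$compound_id <- "HLX-BROKEN"; broken$psa <- NA
  res <- rank_library(rbind(fx, broken), published_reference(),
                      default_rules(), threshold = 14)
  expect_equal(res$ranked$compound_id[1], "HLX-MAX")
  # tie pair ordered lexicographically
  tie <- res$ranked[res$ranked$total == 15.5, "compound_id"]
  expect_identical(tie, c("HLX-TIE-A", "HLX-TIE-B"))
  expect_identical(res$ranked$rank, seq_len(nrow(res$ranked)))
  # threshold is inclusive: the 14.0 compound is shortlisted
  expect_equal(res$shortlist$count, 4L)
  expect_true("HLX-LOGP3SD" %in% res$shortlist$ids)
  expect_equal(res$rejects$compound_id, "HLX-BROKEN")
})

test_that("a single compound at the reference point ranks first with 18 points", {
  one <- as.data.frame(c(list(compound_id = "REF"), at_reference()))
  res <- predict(published_reference(), one)
  expect_equal(res$ranked$total, 18)
  expect_equal(res$ranked$rank, 1L)
})

test_that("custom rules round-trip through YAML and alter scoring as written", {
  rules <- default_rules()
  cb <- rules$continuous_bands
  cb["logp", ] <- c(1.5, 1.0, 0.5, -1.0)
  custom <- herblike:::new_hl_rules(cb, rules$discrete_offsets, "mirrored")
  path <- tempfile(fileext = ".yaml")
  write_rules(custom, path)
  back <- read_rules(path)
  expect_equal(back$continuous_bands, custom$continuous_bands)
  expect_equal(back$discrete_offsets, custom$discrete_offsets)
  expect_equal(score_compound(at_reference(), rules = back)$total, 16.5)
  # non-half-point scores are refused
  cb["logp", 1] <- 1.23
  expect_error(herblike:::new_hl_rules(cb, rules$discrete_offsets),
               class = "hl_rules_error")
})
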