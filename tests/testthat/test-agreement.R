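test_that("paired differences follow their definitions and symmetries", {
  ref <- c(110, 100); oth <- c(90, 100)
  pd <- paired_differences(ref, oth)
  expect_equal(pd$mean_diff, 10)
  expect_equal(pd$mean_rel_pct, 10)   # (20% + 0%) / 2
  # identical measurements give all-zero summaries
  z <- paired_differences(ref, ref)
  expect_equal(unlist(z), c(mean_diff = 0, sd_diff = 0,
                            mean_rel_pct = 0, sd_rel_pct = 0))
  # swapping reference and other negates the means exactly
  sw <- paired_differences(oth, ref)
  expect_equal(sw$mean_diff, -pd$mean_diff)
  expect_equal(sw$mean_rel_pct, -pd$mean_rel_pct)
  expect_equal(sw$sd_diff, pd$sd_diff)
  expect_error(paired_differences(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(paired_differences(110, 90), "at least 2")
  expect_error(paired_differences(c(1, 2), c(-1, 2)), "pair 1")
})

test_that("paired differences match an independent recomputation", {
  set.seed(15)
  ref <- stats::runif(10, 300, 900)
  oth <- ref + stats::rnorm(10, 5, 20)
  got <- paired_differences(ref, oth)
  want <- paired_differences_oracle(ref, oth)
  for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
})

test_that("Pearson correlation handles exact relations and matches the formula", {
  a <- c(1, 3, 7, 9, 12)
  expect_equal(pearson_r(a, 2 * a + 3), 1)
  expect_equal(pearson_r(a, -a), -1)
  set.seed(8)
  b <- a + stats::rnorm(5)
  expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  expect_error(pearson_r(a, rep(2, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the paired t-test matches the reference routine and its null cases", {
  a <- c(4, 7, 2, 9, 5)
  expect_equal(paired_ttest(a, a), list(t = 0, p = 1))
  d <- c(1, -1, 1, -1, 1, -1)
  expect_equal(paired_ttest(d, rep(0, 6))$t, 0)
  expect_equal(paired_ttest(d, rep(0, 6))$p, 1)
  set.seed(99)
  x <- stats::rnorm(10, 10, 2); y <- x + stats::rnorm(10, 0.5, 1)
  got <- paired_ttest(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_error(paired_ttest(a + 2, a), "degenerate")
})

test_that("gold-standard comparison normalizes by the gold value", {
  gold <- c(500, 700, 900)
  expect_equal(exvivo_comparison(1.05 * gold, gold)$mean_pct, 5)
  expect_equal(exvivo_comparison(1.05 * gold, gold)$sd_pct, 0)
  set.seed(5)
  img <- gold * stats::runif(3, 0.9, 1.1)
  ev <- exvivo_comparison(img, gold)
  expect_equal(ev$mean_pct, mean(100 * (img - gold) / gold), tolerance = 1e-12)
  expect_equal(ev$r, pearson_oracle(img, gold), tolerance = 1e-12)
  expect_error(exvivo_comparison(img, c(0, 700, 900)), "positive")
})

test_that("significance stars follow the three conventional thresholds", {
  expect_identical(significance_stars(c(0.5, 0.05, 0.01, 0.001, 1e-6)),
                   c("", "*", "**", "***", "***"))
})

measurements_fixture <- function(perturb = 0) {
  # 4 subjects x 4 conditions x (obs1 rep1, obs1 rep2, obs2)
  set.seed(41)
  base <- tibble::tibble(
    subject = 1:4,
    edv_ul = c(450, 600, 520, 700),
    esv_ul = c(120, 180, 150, 210),
    lvm_mg = c(600, 800, 700, 950))
  base$ef_pct <- 100 * (base$edv_ul - base$esv_ul) / base$edv_ul
  rows <- list()
  for (cond in c("raw", "aniso", "tv", "ornlm"))
    for (m in list(c(1, 1), c(1, 2), c(2, 1))) {
      r <- base
      if (perturb > 0) {
        jig <- function(v) v * (1 + stats::rnorm(4, 0, perturb))
        if (!(m[1] == 1 && m[2] == 1))
          r[c("edv_ul", "esv_ul", "lvm_mg")] <-
            lapply(r[c("edv_ul", "esv_ul", "lvm_mg")], jig)
        r$ef_pct <- 100 * (r$edv_ul - r$esv_ul) / r$edv_ul
      }
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(r, condition = cond, observer = m[1], rep = m[2])
    }
  dplyr::bind_rows(rows)
}

test_that("agreement tables have the full condition-by-parameter structure", {
  fx <- measurements_fixture(perturb = 0.03)
  gold <- tibble::tibble(subject = 1:4, lvm_mg = c(590, 810, 690, 960))
  tb <- build_table(fx, gold = gold)
  expect_identical(nrow(tb$intra), 16L)   # 4 conditions x 4 parameters
  expect_identical(nrow(tb$inter), 16L)
  expect_setequal(unique(tb$intra$parameter), c("EDV", "ESV", "EF", "LVM"))
  expect_identical(nrow(tb$gold), 8L)     # 4 conditions x 2 observers
  # deterministic given the input table
  expect_identical(tb, build_table(fx, gold = gold))
})

test_that("perfect observers produce all-zero agreement rows without stars", {
  fx <- measurements_fixture(perturb = 0)
  tb <- build_table(fx)
  expect_true(all(tb$intra$mean_diff == 0))
  expect_true(all(tb$inter$mean_rel_pct == 0))
  expect_true(all(tb$intra$stars == ""))
  expect_true(all(tb$inter$p == 1))
})

test_that("a missing repeat drops its rows with a warning", {
  fx <- measurements_fixture(perturb = 0.03)
  fx <- dplyr::filter(fx, !(condition == "tv" & observer == 1 & rep == 2))
  expect_warning(tb <- build_table(fx), "tv")
  expect_identical(nrow(tb$intra), 12L)
  expect_identical(nrow(tb$inter), 16L)
})
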