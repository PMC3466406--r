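test_that("preprocessing centers experiments and is scale invariant", {
  d <- data.frame(experiment = rep(c("e1", "e2"), each = 4),
                  treatment = rep(c("control", "HGF"), 4),
                  replicate = rep(1:2, 4),
                  intensity = c(100, 100, 100, 100, 250, 250, 250, 250))
  a <- preprocess_assay(lih_assay(d))
  expect_equal(a$data$value, rep(0, 8)) # equal within experiment -> all 0
  # doubling one experiment's intensities changes nothing after scaling
  d2 <- d
  d2$intensity[d2$experiment == "e1"] <- d2$intensity[d2$experiment == "e1"] * 2
  a2 <- preprocess_assay(lih_assay(d2))
  expect_equal(a2$data$value, a$data$value)
})

test_that("known experiment offsets are eliminated to numerical tolerance", {
  assay <- simulate_assay(c(HGF = 1), n_experiments = 6, n_technical = 3,
                          sd_experiment = 0.8, sd_technical = 0, seed = 21)
  pre <- preprocess_assay(assay)
  mu <- tapply(pre$data$value, pre$data$experiment, mean)
  expect_true(all(abs(mu - mu[[1]]) < 1e-12))
})

test_that("treatment identical to control gives estimate 0 and call 0", {
  d <- expand.grid(experiment = c("e1", "e2", "e3"),
                   treatment = c("control", "x"), replicate = 1:3,
                   stringsAsFactors = FALSE)
  # intensities vary by experiment and replicate but not by treatment
  d$intensity <- 800 + 50 * d$replicate +
    100 * as.integer(factor(d$experiment))
  disc <- discretize_assay(lih_assay(d))
  expect_equal(disc$results$estimate, 0, tolerance = 1e-10)
  expect_equal(disc$results$call, 0L)
  expect_true(disc$results$ci_low <= 0 & disc$results$ci_high >= 0)
})

test_that("discretization is invariant under per-experiment rescaling", {
  assay <- simulate_assay(c(HGF = 1, TGFb = -0.5), seed = 31)
  d2 <- assay$data
  for (e in unique(d2$experiment)) {
    d2$intensity[d2$experiment == e] <-
      d2$intensity[d2$experiment == e] * stats::runif(1, 0.5, 5)
  }
  r1 <- discretize_assay(assay)$results
  r2 <- discretize_assay(lih_assay(d2))$results
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$call, r2$call)
})

test_that("a strong inducer and an inhibitor are called 1 and 0", {
  assay <- simulate_assay(c(HGF = 1, TGFb = -0.6), n_experiments = 4,
                          sd_experiment = 0.2, sd_technical = 0.1, seed = 5)
  disc <- discretize_assay(assay)
  r <- disc$results
  expect_equal(r$call[r$treatment == "HGF"], 1L)
  expect_equal(r$call[r$treatment == "TGFb"], 0L)
  expect_equal(r$estimate[r$treatment == "HGF"], 1, tolerance = 0.25)
  expect_true(all(r$ci_low <= r$estimate & r$estimate <= r$ci_high))
  expect_equal(disc$metadata$df_method, "containment")
})

test_that("variance components are recovered without experiment scaling", {
  sds <- vapply(1:12, function(i) {
    assay <- simulate_assay(c(x = 0.5), n_experiments = 20, n_technical = 3,
                            sd_experiment = 0.2, sd_technical = 0.1,
                            seed = 1000L * i)
    dd <- discretize_assay(assay, scale = FALSE)
    c(dd$metadata$sd_experiment, dd$metadata$sd_technical)
  }, c(0, 0))
  expect_lt(abs(mean(sds[1, ]) - 0.2) / 0.2, 0.3)
  expect_lt(abs(mean(sds[2, ]) - 0.1) / 0.1, 0.3)
})

test_that("the scaled pipeline flags its singular random intercept and falls back", {
  assay <- simulate_assay(c(x = 1), seed = 13)
  disc <- discretize_assay(assay)
  # scaling removes the experiment offsets, so the random-intercept variance
  # sits at the zero boundary and the flagged fixed-effects fallback engages
  expect_true(disc$metadata$singular_fallback)
  expect_match(disc$metadata$model, "fixed-effects")
  disc2 <- discretize_assay(assay, scale = FALSE)
  expect_false(disc2$metadata$singular_fallback)
})

test_that("Dunnett adjustment is monotone and keeps strong calls", {
  assay <- simulate_assay(c(a = 1, b = 0.9, c = 0), n_experiments = 4,
                          seed = 17)
  plain <- discretize_assay(assay, scale = FALSE)
  dun <- discretize_assay(assay, adjust = "dunnett", scale = FALSE)
  expect_true(all(dun$results$p >= plain$results$p - 1e-9))
  expect_equal(dun$results$call[dun$results$treatment %in% c("a", "b")],
               c(1L, 1L))
  expect_equal(dun$metadata$family_size, 3L)
})

test_that("assay validation rejects degenerate designs", {
  d <- data.frame(experiment = "e1", treatment = c("control", "x"),
                  replicate = 1, intensity = c(1, 2))
  expect_error(discretize_assay(lih_assay(d)), ">= 2 experiments")
  d2 <- data.frame(experiment = c("e1", "e1", "e2", "e2"),
                   treatment = c("control", "x", "x", "x"),
                   replicate = 1, intensity = 1:4)
  expect_error(discretize_assay(lih_assay(d2, control = "control")),
               "control")
  expect_error(lih_assay(data.frame(experiment = "e", treatment = "control",
                                    replicate = 1, intensity = -1)),
               "positive")
  expect_error(lih_assay(data.frame(x = 1)), "columns")
})

test_that("fisher upper tail equals direct hypergeometric summation", {
  expect_equal(round(fisher_one_tailed(c(6, 2, 6, 6)), 4), 0.2596)
  expect_equal(round(fisher_one_tailed(c(6, 2, 1, 5)), 4), 0.0513)
  expect_equal(fisher_one_tailed(c(1, 0, 0, 1)), 0.5)
  # oracle: sum of dhyper point probabilities over the upper tail
  hyper_tail <- function(a, b, c, d) {
    m <- a + b; n_ <- c + d; k <- a + c
    sum(stats::dhyper(a:min(m, k), m, n_, k))
  }
  for (seed in 1:40) {
    cnt <- lihnet:::with_seed(seed + 50L, {
      tot <- sample(4:30, 1)
      as.vector(stats::rmultinom(1, tot, rep(1 / 4, 4)))
    })
    p <- fisher_one_tailed(cnt)
    expect_equal(p, hyper_tail(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12, label = sprintf("table seed %d", seed))
    expect_true(p > 0 && p <= 1)
    # transposition symmetry of the enrichment tail
    tab <- matrix(cnt, 2, byrow = TRUE)
    expect_equal(fisher_one_tailed(t(tab)), p, tolerance = 1e-12)
  }
  expect_error(fisher_one_tailed(c(0, 0, 0, 0)), "all-zero")
  expect_error(fisher_one_tailed(c(-1, 1, 1, 1)), "non-negative")
})

test_that("discretization results serialize to TSV and read back from file", {
  assay <- simulate_assay(c(HGF = 1), seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(assay$data, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_assay(p)
  expect_equal(nrow(back$data), nrow(assay$data))
  disc <- discretize_assay(back)
  pr <- withr::local_tempfile(fileext = ".tsv")
  write_discretization_tsv(disc, pr)
  expect_equal(utils::read.delim(pr)$treatment, "HGF")
})
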