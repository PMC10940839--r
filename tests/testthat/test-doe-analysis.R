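test_that("factorial designs cross every factor at every time level", {
  d8 <- build_design(aspiration = c(37, 100), dispension = c(37, 100),
                     needle_depth = c(1, 2))
  expect_equal(nrow(d8), 8)  # the 2^3 full factorial
  expect_equal(length(unique(d8$run_id)), 8)

  d24 <- build_design(aspiration = c(100, 200, 350, 500),
                      dispension = c(100, 200)[1:2],
                      time = c(7, 14, 21), replicates = 1)
  expect_equal(nrow(d24), 4 * 2 * 3)
  counts <- table(d24$aspiration, d24$dispension, d24$day)
  expect_true(all(counts == 1))  # balanced within platform

  expect_error(build_design(aspiration = 100, dispension = 50),
               "two or more levels")
  expect_error(build_design(aspiration = numeric(0), dispension = c(1, 2)),
               "at least one level")
})

test_that("a pure additive time effect loads only on the time term", {
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100),
                         time = c(7, 14, 21), replicates = 2)
  response <- 5 + 2 * match(design$day, c(7, 14, 21)) +
    rnorm(nrow(design), sd = 1e-8)
  tab <- fit_anova(design, response)
  expect_lt(tab$p_value[tab$term == "time"], 1e-6)
  for (term in c("aspiration", "dispension", "aspiration:dispension")) {
    expect_lt(tab$sum_sq[tab$term == term], 1e-9)
  }
})

test_that("the ANOVA table matches hand-computed sums of squares", {
  # 8 runs: 2 aspiration x 2 dispension, 2 replicates, no time
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100),
                         replicates = 2)
  y <- c(4.1, 9.0, 5.2, 12.3, 3.8, 10.1, 5.9, 11.2)
  tab <- fit_anova(design, y)
  # independent oracle: explicit balanced two-way ANOVA arithmetic
  a <- factor(design$aspiration); b <- factor(design$dispension)
  gm <- mean(y)
  ss_a <- sum(tapply(y, a, length) * (tapply(y, a, mean) - gm)^2)
  ss_b <- sum(tapply(y, b, length) * (tapply(y, b, mean) - gm)^2)
  cellm <- tapply(y, interaction(a, b), mean)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  ss_ab <- 0
  for (ai in levels(a)) for (bi in levels(b)) {
    ss_ab <- ss_ab + 2 * (cellm[paste(ai, bi, sep = ".")] - am[ai] -
                            bm[bi] + gm)^2
  }
  ss_res <- sum((y - cellm[interaction(a, b)])^2)
  expect_equal(tab$sum_sq[tab$term == "aspiration"], unname(ss_a))
  expect_equal(tab$sum_sq[tab$term == "dispension"], unname(ss_b))
  expect_equal(tab$sum_sq[tab$term == "aspiration:dispension"],
               unname(ss_ab))
  expect_equal(tab$sum_sq[tab$term == "Residuals"], unname(ss_res))
  expect_equal(sum(tab$df), length(y) - 1)
  f_a <- (ss_a / 1) / (ss_res / 4)
  expect_equal(tab$statistic[tab$term == "aspiration"], unname(f_a))
  expect_equal(tab$p_value[tab$term == "aspiration"],
               unname(1 - pf(f_a, 1, 4)))
})

test_that("the SS decomposition is exact and order-stable on balanced designs", {
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100),
                         time = c(7, 14, 21), replicates = 2)
  set.seed(31)
  y <- rnorm(nrow(design), 10, 2)
  tab <- fit_anova(design, y)
  expect_equal(sum(tab$sum_sq), sum((y - mean(y))^2), tolerance = 1e-9)
  perm <- sample(nrow(design))
  tab2 <- fit_anova(design[perm, ], y[perm])
  expect_equal(tab2$sum_sq, tab$sum_sq, tolerance = 1e-9)
})

test_that("degenerate responses and saturated models are rejected", {
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100))
  expect_error(fit_anova(design, rep(5, nrow(design))), "degenerate")
  expect_error(fit_anova(design, rnorm(nrow(design))), "degrees of freedom")
  expect_error(fit_anova(design, rnorm(3)), "length")
})

test_that("unbalanced designs trigger a warning", {
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100),
                         replicates = 2)
  design <- design[-1, ]
  expect_warning(fit_anova(design, rnorm(nrow(design), 1:7)), "unbalanced")
})

test_that("effect summaries reproduce trivial level means", {
  design <- build_design(aspiration = c(100, 500), dispension = c(37, 100),
                         replicates = 2)
  const <- effect_summaries(design, rep(3.5, 8))
  expect_true(all(const$main$mean == 3.5))
  expect_true(all(const$main$sd == 0))
  y <- ifelse(design$aspiration == 100, 0, 10)
  es <- effect_summaries(design, y)
  asp <- es$main[es$main$factor == "aspiration", ]
  expect_equal(asp$mean[asp$level == "100"], 0)
  expect_equal(asp$mean[asp$level == "500"], 10)
  inter <- es$interaction[es$interaction$factor_a == "aspiration", ]
  expect_true(all(inter$mean[inter$level_a == "500"] == 10))
})

test_that("simulated experiments recover the sign of an injected speed effect", {
  layout <- make_layout("A800", pixel_size = 8)
  model <- displacement_model(base_escape_prob = 0.01,
                              aspiration_coeff = 0.004)
  design <- build_design(aspiration = c(100, 500), dispension = 100,
                         time = c(7, 14, 21))
  hits <- 0
  for (s in 1:100) {
    resp <- simulate_doe(design, layout, model, seed = s)
    m <- tapply(resp, design$aspiration, mean)
    if (m["500"] > m["100"]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
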