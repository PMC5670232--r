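# Statistical core: BH-FDR, signed-rank, Kruskal-Wallis, Spearman, and the
# mixed-effects ANOVA contract. Brute-force enumeration oracles live here.

# step-up oracle: enumerate the BH rejection set directly
bh_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(n) / n * alpha)
  reject <- rep(FALSE, n)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# exact signed-rank two-sided p by enumerating all 2^n sign patterns
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

test_that("BH-FDR matches the step-up oracle and the worked example", {
  p <- c(0.001, 0.02, 0.9)
  res <- bh_fdr(p, alpha = 0.05)
  # step-up: 0.02 <= (2/3) * 0.05, so the first two are rejected
  expect_equal(res$reject, c(TRUE, TRUE, FALSE))
  expect_equal(res$q, c(0.003, 0.03, 0.9))
  expect_equal(res$reject, bh_oracle(p, 0.05))
  expect_false(any(bh_fdr(rep(1, 5), 0.05)$reject))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(50)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    p <- round(runif(n), 3)
    a <- runif(1, 0.01, 0.2)
    expect_equal(bh_fdr(p, a)$reject, bh_oracle(p, a))
  }
})

test_that("BH keeps the realized FDR at or below alpha under the null", {
  set.seed(51)
  fdr <- vapply(1:100, function(i) {
    p <- runif(1000)
    mean(bh_fdr(p, 0.05)$reject)
  }, numeric(1))
  expect_lte(mean(fdr), 0.05)
})

test_that("signed-rank exact path matches full enumeration", {
  # all-positive differences, n = 6: p = 2/64
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p, 2 / 64)
  expect_equal(r$statistic, 21)
  set.seed(52)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 5 || any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p, signed_rank_oracle(d),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "zero")
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0, 1)), "at least 5")
})

test_that("signed-rank normal path is calibrated and signed correctly", {
  set.seed(53)
  ps <- vapply(1:500, function(i) wilcoxon_signed_rank(rnorm(40))$p,
               numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  up <- wilcoxon_signed_rank(rnorm(40, mean = 2))
  expect_gt(up$z, 0)
  down <- wilcoxon_signed_rank(rnorm(40, mean = -2))
  expect_lt(down$z, 0)
  # paired form equals the one-sample form on differences
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcoxon_signed_rank(x - y)$p)
})

test_that("Kruskal-Wallis handles ties, degeneracy, and has power", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$p, 1, tolerance = 0.3)
  deg <- kruskal_wallis(list(rep(2, 5), rep(2, 5)))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  # matches kruskal.test (the reference) with ties present
  set.seed(54)
  vals <- round(rnorm(30), 1)
  g <- rep(1:3, each = 10)
  expect_equal(kruskal_wallis(vals, g)$statistic,
               unname(kruskal.test(vals, factor(g))$statistic))
  # power: 3 groups shifted by 2 sd
  ps <- vapply(1:20, function(i) {
    kruskal_wallis(list(rnorm(20), rnorm(20, 2), rnorm(20, 4)))$p
  }, numeric(1))
  expect_true(all(ps < 0.01))
  # calibration under identical distributions
  ps0 <- vapply(1:300, function(i)
    kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))$p, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps0, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Spearman handles monotone transforms and rejects bad input", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, x)$estimate, 1)
  expect_equal(spearman_cor(x, -x^2)$estimate, -1)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 5")
  set.seed(55)
  ps <- vapply(1:500, function(i)
    spearman_cor(rnorm(30), rnorm(30))$p, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

# summary-level cohort for the mixed model: per electrode x category medians
anova_cohort <- function(n_pat = 12, n_el = 5, interaction_db = 0.25,
                         sd_el = 0.1, sd_obs = 0.15, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pat), function(p) {
    purrr::map_dfr(seq_len(n_el), function(e) {
      grp <- if (e %% 2 == 1) "face_selective" else "place_selective"
      pe <- rnorm(1, 0, sd_el)
      purrr::map_dfr(c("face", "place"), function(cat) {
        eff <- if ((grp == "face_selective") == (cat == "face"))
          interaction_db else -interaction_db
        tibble::tibble(patient = p, electrode = paste(p, e, sep = "_"),
                       group = grp, category = cat,
                       y = pe + eff + rnorm(1, 0, sd_obs))
      })
    })
  })
}

test_that("mixed ANOVA detects a group x category interaction", {
  hits <- vapply(1:10, function(r) {
    d <- anova_cohort(seed = 100 + r)
    m <- mixed_anova(d, "y", c("group", "category"))
    tab <- tidy(m)
    tab$p[tab$effect == "group:category"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("mixed ANOVA interaction p is calibrated under the null", {
  ps <- vapply(1:30, function(r) {
    d <- anova_cohort(interaction_db = 0, seed = 300 + r)
    tab <- tidy(mixed_anova(d, "y", c("group", "category"),
                            df_method = "satterthwaite"))
    tab$p[tab$effect == "group:category"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixed ANOVA reduces to ordinary ANOVA as random variance vanishes", {
  # balanced design (Type I = Type III) and enough electrodes that the
  # boundary estimate of the vanishing random-intercept variance is tiny
  rel <- vapply(1:5, function(s) {
    d <- anova_cohort(n_pat = 20, n_el = 8, sd_el = 1e-6, sd_obs = 0.3,
                      seed = s)
    m <- suppressMessages(suppressWarnings(
      mixed_anova(d, "y", c("group", "category"))))
    tab <- tidy(m)
    ref_f <- summary(stats::aov(y ~ group * category,
                                data = d))[[1]][["F value"]][3]
    got_f <- tab$F[tab$effect == "group:category"]
    abs(got_f - ref_f) / ref_f
  }, numeric(1))
  # the boundary variance estimate is zero in most draws; the typical fit
  # coincides with the ordinary two-way ANOVA
  expect_lt(median(rel), 0.05)
  d1 <- anova_cohort(seed = 1)
  expect_error(
    mixed_anova(d1[d1$patient == 1 & d1$electrode == "1_1", ],
                "y", c("group", "category")),
    "unidentifiable")
})

test_that("recall-order table feeds the three-way model contract", {
  s <- small_session()
  tab <- s |>
    (\(ss) recall_order_analysis(ss$hfb_ratio, ss$sched$events, ss$profiles,
                                 mask = ss$mask))()
  tab <- dplyr::filter(tab, group %in% c("face_selective", "place_selective"))
  tab$patient <- 1L
  tab$electrode <- tab$electrode_id
  m <- mixed_anova(tab, "median_db", c("group", "category", "order"),
                   df_method = "satterthwaite")
  expect_true(all(c("group:category", "order") %in% tidy(m)$effect))
  # injected preferred-category shift drives the interaction
  expect_lt(tidy(m)$p[tidy(m)$effect == "group:category"], 0.05)
})
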