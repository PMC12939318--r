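make_expr <- function(values, condition, group = rep("g1", ncol(values)),
                      qvalues = NULL) {
  expression_matrix(values, condition, group, qvalues = qvalues)
}

test_that("cellline_de averages replicates and divides KO by WT", {
  vals <- rbind(g1 = c(2, 2, 4, 4), g2 = c(5, 5, 5, 5), g3 = c(0, 0, 3, 3))
  colnames(vals) <- paste0("s", 1:4)
  expr <- make_expr(vals, c("WT", "WT", "KO", "KO"))
  de <- cellline_de(expr, "g1")
  expect_equal(de$fc[de$gene == "g1"], 2)
  expect_equal(de$fc[de$gene == "g2"], 1)
  # WT mean zero: fold change undefined, flagged rather than zero
  expect_true(is.na(de$fc[de$gene == "g3"]))
  expect_false(de$fc_defined[de$gene == "g3"])
  expect_error(cellline_de(expr, "nope"), "group")
})

test_that("cellline_de requires both conditions in the group", {
  vals <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expr <- make_expr(vals, c("WT", "WT"))
  expect_error(cellline_de(expr, "g1"), "WT and .* KO")
})

test_that("eexp calls follow the q-value and fold-change rules", {
  de <- structure(data.frame(
    gene = c("up", "down", "ns", "small", "bigup"),
    fc = c(2.0, 0.5, 3.0, 1.2, 3.0),
    q = c(0.01, 0.01, 0.20, 0.01, 0.01),
    fc_defined = TRUE), mode = "linear", class = c("de_result", "data.frame"))
  e1 <- eexp_from_de(de, fc_threshold = 1)
  expect_equal(unclass(e1)[c("up", "down", "ns", "small")],
               c(up = 1L, down = -1L, ns = 0L, small = 1L))
  # biological threshold overrides significance
  e15 <- eexp_from_de(de, fc_threshold = 1.5)
  expect_equal(e15[["small"]], 0L)
  # thresholds are inclusive
  e3 <- eexp_from_de(de, fc_threshold = 3)
  expect_equal(e3[["bigup"]], 1L)
  expect_equal(e3[["up"]], 0L)
  expect_error(eexp_from_de(de, fc_threshold = 0.5), ">= 1")
})

test_that("q-value exactly at the cut-off is not significant", {
  de <- structure(data.frame(gene = "g", fc = 2, q = 0.05, fc_defined = TRUE),
                  mode = "linear", class = c("de_result", "data.frame"))
  expect_equal(eexp_from_de(de)[["g"]], 0L)
})

test_that("log10 mode calls the sign of the log fold change", {
  de <- structure(data.frame(
    gene = c("up", "down", "ns"),
    log10_fc = c(0.3, -0.3, 1.0),
    q = c(0.01, 0.01, 0.5),
    fc_defined = TRUE), mode = "log10", class = c("de_result", "data.frame"))
  e <- eexp_from_de(de)
  expect_equal(unclass(e)[names(e)], c(up = 1L, down = -1L, ns = 0L))
  # at T = 2 the cut is log10(2) ~ 0.301, which |0.3| fails
  e2 <- eexp_from_de(de, fc_threshold = 2)
  expect_equal(unclass(e2)[names(e2)], c(up = 0L, down = 0L, ns = 0L))
})

test_that("undefined fold changes land in the missing set", {
  de <- structure(data.frame(gene = c("a", "b"), fc = c(NA, 2),
                             q = c(0.01, 0.01), fc_defined = c(FALSE, TRUE)),
                  mode = "linear", class = c("de_result", "data.frame"))
  e <- eexp_from_de(de)
  expect_equal(attr(e, "missing"), "a")
  expect_equal(names(e), "b")
})

test_that("raising the threshold never creates new calls", {
  set.seed(33)
  for (i in 1:20) {
    de <- structure(data.frame(
      gene = paste0("g", 1:50),
      fc = rlnorm(50, 0, 1),
      q = runif(50),
      fc_defined = TRUE), mode = "linear", class = c("de_result", "data.frame"))
    prev <- NULL
    for (thr in c(1, 1.5, 2, 3)) {
      e <- eexp_from_de(de, fc_threshold = thr)
      nz <- names(e)[e != 0L]
      if (!is.null(prev)) expect_true(all(nz %in% prev))
      prev <- nz
    }
  }
})

test_that("binomial point probability matches the closed form", {
  expect_equal(binom_point_p(0, 1), 2 / 3)
  expect_equal(binom_point_p(4, 4, 0.4), 0.4^4)
  # independent closed-form oracle
  pp <- function(k, n, p) choose(n, k) * p^k * (1 - p)^(n - k)
  for (n in c(5, 17, 28)) {
    ks <- 0:n
    expect_equal(vapply(ks, binom_point_p, numeric(1), n = n), pp(ks, n, 1 / 3))
    expect_equal(sum(vapply(ks, binom_point_p, numeric(1), n = n)), 1)
  }
  # symmetry at p0 = 1/2
  expect_equal(binom_point_p(3, 10, 0.5), binom_point_p(7, 10, 0.5))
  # upper tail is a sum of point probabilities
  expect_equal(binom_point_p(5, 8, 1 / 3, upper_tail = TRUE),
               sum(vapply(5:8, binom_point_p, numeric(1), n = 8)))
  expect_error(binom_point_p(5, 4), "n >= k")
})

test_that("score_predictions classifies errors and excludes the criterion", {
  ev <- structure(setNames(c(0L, 0L, 1L, -1L), c("a", "b", "c", "SORL1")),
                  excluded = "SORL1", class = "emod_vector")
  ee <- structure(setNames(c(0L, 1L, -1L, -1L), c("a", "b", "c", "SORL1")),
                  missing = character(0), class = "eexp_vector")
  rep <- score_predictions(ev, ee, "SORL1")
  expect_equal(rep$n_evaluated, 3L)
  expect_equal(unname(rep$n_by_error), c(1L, 1L, 1L))
  expect_equal(rep$rate, 100 / 3)
  expect_equal(rep$p_value, binom_point_p(1, 3))
  expect_true("SORL1" %in% rep$excluded)
})

test_that("a perfect prediction vector scores 100 percent", {
  genes <- paste0("g", 1:10)
  v <- setNames(sample(-1:1, 10, replace = TRUE), genes)
  ev <- structure(c(v, SORL1 = -1L), excluded = character(0),
                  class = "emod_vector")
  ee <- structure(c(v, SORL1 = -1L), missing = character(0),
                  class = "eexp_vector")
  rep <- score_predictions(ev, ee, "SORL1")
  expect_equal(rep$rate, 100)
  expect_equal(rep$n_evaluated, 10L)
})

test_that("directionality check demands a down-regulated criterion", {
  ev <- structure(c(a = 0L, SORL1 = -1L), excluded = "SORL1",
                  class = "emod_vector")
  bad <- structure(c(a = 0L, SORL1 = 1L), missing = character(0),
                   class = "eexp_vector")
  expect_error(score_predictions(ev, bad, "SORL1"), "directionality")
  absent <- structure(c(a = 0L), missing = character(0),
                      class = "eexp_vector")
  expect_error(score_predictions(ev, absent, "SORL1"), "not present")
  expect_silent(score_predictions(ev, absent, "SORL1",
                                  check_direction = FALSE))
})

test_that("missing genes are excluded from the denominator", {
  ev <- structure(setNames(rep(0L, 4), c("a", "b", "c", "SORL1")),
                  excluded = "SORL1", class = "emod_vector")
  ee <- structure(setNames(c(0L, -1L), c("a", "SORL1")),
                  missing = c("b", "c"), class = "eexp_vector")
  rep <- score_predictions(ev, ee, "SORL1")
  expect_equal(rep$n_evaluated, 1L)
  expect_true(all(c("b", "c") %in% rep$excluded))
})

test_that("knockdown correlation matches the direct t formula", {
  # perfectly linear
  expect_equal(knockdown_correlation(1:5, 11:15)$r, 1)
  expect_equal(knockdown_correlation(1:5, 15:11)$r, -1)
  x <- c(0.95, 0.52, 0.40, 0.61, 0.33)
  y <- c(35.5, 44.8, 50.0, 37.9, 53.6)
  res <- knockdown_correlation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r)
  expect_equal(res$r_squared, r^2)
  t_stat <- r * sqrt(3 / (1 - r^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_stat), 3))
  # cross-check against the standard test
  expect_equal(res$p_value, cor.test(x, y)$p.value)
  expect_error(knockdown_correlation(1:3, 1:4), "lengths")
  expect_error(knockdown_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("cohort splits cover all patients at the stated threshold", {
  m <- matrix(c(1, 2, 3, 4), ncol = 1,
              dimnames = list(paste0("P", 1:4), "SORL1"))
  s <- split_cohort(m, "SORL1", "median")
  expect_setequal(s$high, c("P3", "P4"))
  expect_setequal(s$low, c("P1", "P2"))
  m2 <- matrix(c(0, 0, 0, 10), ncol = 1,
               dimnames = list(paste0("P", 1:4), "SORL1"))
  s2 <- split_cohort(m2, "SORL1", "mean")
  expect_equal(s2$high, "P4")
  expect_length(s2$low, 3)
  # quartile thresholds use linear interpolation (spreadsheet default)
  m3 <- matrix(1:8, ncol = 1, dimnames = list(paste0("P", 1:8), "SORL1"))
  s3 <- split_cohort(m3, "SORL1", "upper_quartile")
  expect_equal(s3$threshold, quantile(1:8, 0.75, names = FALSE))
  expect_setequal(s3$high, c("P7", "P8"))
  # partition invariant
  expect_length(intersect(s3$high, s3$low), 0)
  expect_setequal(c(s3$high, s3$low), paste0("P", 1:8))
  const <- matrix(rep(1, 4), ncol = 1,
                  dimnames = list(paste0("P", 1:4), "SORL1"))
  expect_error(split_cohort(const, "SORL1", "mean"), "degenerate")
  expect_error(split_cohort(m, "GENE2", "mean"), "focal gene")
})

test_that("cohort_de orients log10 fold changes as Low over High", {
  pts <- paste0("P", 1:8)
  high <- pts[1:4]; low <- pts[5:8]
  m <- cbind(flat = rep(5, 8),
             tenfold = c(rep(10, 4), rep(100, 4)),
             SORL1 = c(rep(100, 4), rep(10, 4)))
  rownames(m) <- pts
  m <- m * matrix(exp(rnorm(24, 0, 1e-9)), 8)  # break exact ties
  de <- cohort_de(m, high, low)
  expect_equal(de$log10_fc[de$gene == "flat"], 0, tolerance = 1e-6)
  expect_equal(de$log10_fc[de$gene == "tenfold"], 1, tolerance = 1e-6)
  expect_equal(de$log10_fc[de$gene == "SORL1"], -1, tolerance = 1e-6)
  expect_error(cohort_de(m, high, c(high[1], low)), "overlap")
})

test_that("cohort_de recovers a planted association after a median split", {
  genes <- c("SORL1", paste0("g", 1:6))
  sim <- gen_cohort(genes, "SORL1",
                    assoc_sign = setNames(c(1, 1, 1, -1, -1, 0), paste0("g", 1:6)),
                    effect_size = 1, n_patients = 80, seed = 42)
  s <- split_cohort(sim$cohort, "SORL1", "median")
  de <- cohort_de(sim$cohort, s$high, s$low)
  ee <- eexp_from_de(de)
  # positively associated genes drop in the Low group; the focal gene is
  # negative by construction
  expect_equal(ee[["SORL1"]], -1L)
  expect_equal(unname(unclass(ee)[paste0("g", 1:5)]),
               c(-1L, -1L, -1L, 1L, 1L))
})
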