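# Index construction: orientation, Rankit, exponential rank transform,
# domain combination, deciles, diagnostics, and the pipeline-level
# invariances (monotone transforms, cancellation resistance).

test_that("orient_values applies the sign rule", {
  expect_equal(orient_values(c(1, 5, 10), "flip"), c(-1, -5, -10))
  expect_equal(orient_values(c(0.3, 7), "keep"), c(0.3, 7))
  expect_equal(orient_values(c(0, 1e4), "flip"), c(0, -1e4))
  # after flipping, the nearest-to-hazard zone is largest (least healthy)
  expect_equal(which.max(orient_values(c(1, 5, 10), "flip")), 1L)
})

test_that("rankit matches the (r - 0.5)/n plotting position", {
  expect_equal(rankit(5), 0)                        # n = 1 -> qnorm(0.5)
  sc <- sort(rankit(c(10, 1, 4)))
  expect_equal(sc, qnorm(c(1, 3, 5) / 6))
  expect_equal(sc[3], 0.967421566101701, tolerance = 1e-12)
  # high-precision oracle across several n
  for (n in c(2, 5, 17, 101)) {
    set.seed(n)
    v <- rnorm(n)
    expect_equal(rankit(v), oracle_qnorm((rank(v) - 0.5) / n), tolerance = 1e-10)
  }
  # antisymmetry: the score set of distinct values equals its own negation
  set.seed(9)
  v <- runif(31)
  expect_equal(sort(rankit(v)), sort(-rankit(v)), tolerance = 1e-12)
  expect_lt(abs(mean(rankit(v))), 1e-6)
  # ties get average ranks
  expect_equal(rankit(c(1, 1, 2)), qnorm(c(1.5, 1.5, 3) / 3 - 0.5 / 3 + c(0, 0, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # idempotence under re-application (rank invariance)
  expect_equal(rankit(rankit(v)), rankit(v))
  expect_error(rankit(c(1, NA, 2)), "non-finite")
})

test_that("exp_transform matches the closed form and its limits", {
  expect_equal(exp_transform(1), 100, tolerance = 1e-12)
  expect_equal(exp_transform(0.5), 15.6467900726028918, tolerance = 1e-12)
  expect_lt(exp_transform(1e-9), 1e-6)
  expect_error(exp_transform(0), "0, 1")
  expect_error(exp_transform(1.1), "0, 1")
  # strict monotonicity and range on a dense grid
  grid <- seq(1e-4, 1, length.out = 1e4)
  x <- exp_transform(grid)
  expect_true(all(diff(x) > 0))
  expect_true(all(x > 0 & x <= 100))
})

test_that("domain_score is the equal-weight mean with cancellation identities", {
  set.seed(2)
  col <- rnorm(20)
  expect_equal(domain_score(matrix(rep(col, 5), ncol = 5)), col)
  expect_equal(domain_score(cbind(col, -col)), rep(0, 20))
  m <- matrix(rnorm(100), 20, 5)
  expect_equal(domain_score(m), apply(m, 1, function(r) sum(r) / 5))
})

test_that("build_index ranks, scores and deciles per the polarity convention", {
  # all-worst zone: X = (100, 100, 100) -> index 100
  d1 <- data.frame(zone_code = "Z1", retail_X = 100, health_X = 100, physical_X = 100)
  idx1 <- build_index(d1)
  expect_equal(idx1$index_score, 100)
  # N zones -> exactly N/10 per decile when 10 | N
  set.seed(5)
  n <- 100
  d <- data.frame(zone_code = sprintf("Z%03d", 1:n),
                  retail_X = runif(n, 0, 100), health_X = runif(n, 0, 100),
                  physical_X = runif(n, 0, 100))
  idx <- build_index(d)
  expect_equal(sort(idx$index_rank), 1:n)
  expect_true(all(table(idx$index_decile) == 10))
  # rank 1 = lowest score = healthiest; decile 1 holds the lowest scores
  expect_equal(idx$zone_code[idx$index_rank == 1], idx$zone_code[which.min(idx$index_score)])
  expect_lt(max(idx$index_score[idx$index_decile == 1]),
            min(idx$index_score[idx$index_decile == 10]))
  expect_error(build_index(d[, -2]), "retail_X")
})

test_that("a single zone degenerates to R = 1 and index 100", {
  specs <- indicator_specs()
  tab <- data.frame(zone_code = "Z1", as.list(setNames(runif(14, 1, 5), specs$name)))
  fit <- ahah(tab)
  expect_equal(fit$domains$retail_R, 1)
  expect_equal(fit$domains$retail_X, 100)
  expect_equal(fit$index$index_score, 100)
  expect_equal(fit$index$index_decile, 1L)
})

test_that("strictly monotone unit changes leave the whole index unchanged", {
  reg <- tiny_region()
  tab <- measure_region(reg)$table
  fit <- ahah(tab)
  tab2 <- tab
  for (nm in indicator_specs()$name[indicator_specs()$unit == "km"]) {
    tab2[[nm]] <- tab2[[nm]] * 0.621371   # km -> miles
  }
  fit2 <- ahah(tab2)
  expect_equal(fit2$domains[, -1], fit$domains[, -1], tolerance = 1e-12)
  expect_equal(fit2$index, fit$index, tolerance = 1e-12)
})

test_that("the exponential index resists cancellation between domains", {
  # nine zones; zone M mid-ranked everywhere, zone B best in two domains and
  # worst in the third
  n <- 9
  ranks_M <- c(5, 5, 5); ranks_B <- c(1, 1, 9)
  exp_index <- function(r) mean(exp_transform(r / n))
  lin_index <- function(r) mean(100 * r / n)     # linear rank averaging
  gap_M <- exp_index(ranks_M) - lin_index(ranks_M)
  gap_B <- exp_index(ranks_B) - lin_index(ranks_B)
  expect_gt(gap_B, gap_M)
})

test_that("ahah() reproduces its components through the object methods", {
  z <- local({
    set.seed(31)
    codes <- sprintf("Z%02d", 1:20)
    specs <- indicator_specs()
    tab <- data.frame(zone_code = codes)
    for (nm in specs$name) tab[[nm]] <- round(runif(20, 1, 50), 6)
    tab
  })
  fit <- ahah(z)
  expect_s3_class(fit, "ahah")
  expect_equal(fit$n, 20L)
  # domain score = equal-weight mean of that domain's rankit columns
  specs <- indicator_specs()
  rcols <- specs$name[specs$domain == "retail"]
  expect_equal(fit$domains$retail_std,
               rowMeans(fit$rankit_scores[, rcols]), ignore_attr = TRUE)
  # index = mean of the three X columns
  expect_equal(fit$index$index_score,
               rowMeans(as.matrix(fit$domains[, c("retail_X", "health_X", "physical_X")])),
               ignore_attr = TRUE)
  # R = rank / N, distinct, in (0, 1]
  expect_equal(fit$domains$health_R, fit$domains$health_rank / 20)
  expect_equal(sort(fit$domains$health_rank), 1:20)
  # as.data.frame carries Table-4 columns
  df <- as.data.frame(fit)
  expect_true(all(c("index_score", "retail_X", "physical_decile",
                    "fastfood", "so2_decile") %in% names(df)))
  expect_output(print(fit), "50 zones|20 zones")
  expect_output(print(summary(fit)), "decile")
})

test_that("diagnostics report correlations with undefined-variance markers", {
  z <- local({
    set.seed(8)
    codes <- sprintf("Z%02d", 1:25)
    specs <- indicator_specs()
    tab <- data.frame(zone_code = codes)
    for (nm in specs$name) tab[[nm]] <- round(runif(25, 1, 50), 6)
    tab
  })
  d <- ahah_diagnostics(z)
  expect_equal(unname(diag(d$indicator_cor)), rep(1, 14))
  expect_equal(d$indicator_cor["no2", "pm10"], cor(z$no2, z$pm10))
  # a column against its negation
  z2 <- z; z2$pm10 <- -z2$no2
  d2 <- ahah_diagnostics(z2)
  expect_equal(d2$indicator_cor["no2", "pm10"], -1)
  # zero variance -> NA marker, not NaN
  z3 <- z; z3$so2 <- 5
  d3 <- ahah_diagnostics(z3)
  expect_true(all(is.na(d3$indicator_cor["so2", ])))
  expect_false(any(is.nan(d3$indicator_cor)))
  # spearman option
  ds <- ahah_diagnostics(z, method = "spearman")
  expect_equal(ds$indicator_cor["gp", "pubs"],
               cor(z$gp, z$pubs, method = "spearman"))
})
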