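test_that("CT-PFT pairing keeps the nearest record inside the window", {
  metrics <- data.frame(subject_id = c("a", "b", "c"),
                        pectoralis_volume_cc = c(100, 110, 120),
                        ct_date = as.Date("2022-06-01"))
  pft <- data.frame(
    subject_id = c("a", "a", "b", "c"),
    test_date = as.Date("2022-06-01") + c(10, 40, 91, -30),
    FVC = c(3.1, 3.2, 3.3, 3.4))
  expect_message(paired <- pair_ct_with_pft(metrics, pft, 90L), "dropped")
  # subject b: PFT 91 days away with window 90 -> dropped
  expect_setequal(paired$subject_id, c("a", "c"))
  # subject a: records at 10 and 40 days -> the 10-day one
  expect_equal(paired$FVC[paired$subject_id == "a"], 3.1)
  expect_equal(paired$pairing_gap_days[paired$subject_id == "a"], 10)

  none <- suppressMessages(pair_ct_with_pft(metrics, pft, 5L))
  expect_equal(nrow(none), 0)
  expect_error(build_correlation_table(none), "no paired")

  dup <- rbind(metrics, metrics[1, ])
  expect_error(pair_ct_with_pft(dup, pft), "duplicate")
})

test_that("spearman_rho reproduces hand-computed and oracle values", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  # d = (1-3, 2-1, 3-2): sum d^2 = 6; 1 - 6*6/(3*8) = -0.5
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(5, 1, 4, 2)),
               oracle_spearman(c(1, 2, 2, 3), c(5, 1, 4, 2)),
               tolerance = 1e-12)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("rho honours its invariants on random vectors", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(1:10, n, TRUE)   # heavy ties
    y <- rnorm(n)
    r <- suppressWarnings(spearman_rho(x, y))
    if (is.na(r)) next
    expect_equal(r, oracle_spearman(x, y), tolerance = 1e-12)
    expect_lte(abs(r), 1)
    expect_equal(spearman_rho(x + 0L, x + 0L), 1)
    expect_equal(suppressWarnings(spearman_rho(y, -y)), -1)
    # invariance under strictly monotone transforms
    expect_equal(r, suppressWarnings(spearman_rho(exp(x / 4), y)),
                 tolerance = 1e-12)
    expect_equal(r, suppressWarnings(spearman_rho(3 * x + 2, exp(y))),
                 tolerance = 1e-12)
  }
})

test_that("the correlation table is exact on constructed cohorts", {
  set.seed(92)
  n <- 40
  metrics <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        pectoralis_volume_cc = sort(runif(n, 50, 400)),
                        intercostal_density_hu = rnorm(n, 30, 5),
                        ct_date = as.Date("2022-01-01") + seq_len(n))
  pft <- data.frame(subject_id = metrics$subject_id,
                    test_date = metrics$ct_date + 5,
                    FVC = 1 + 0.01 * metrics$pectoralis_volume_cc,
                    DLCO = rnorm(n, 15, 2))
  paired <- pair_ct_with_pft(metrics, pft)
  tab <- build_correlation_table(paired)
  expect_equal(tab$pectoralis_volume_cc[tab$pft == "FVC"], 1)
  expect_true(all(abs(unlist(tab[-1])) <= 1, na.rm = TRUE))
  expect_equal(attr(tab, "n")$pectoralis_volume_cc,
               rep(n, length(tab$pft)))
  # permutation invariance of subject order
  perm <- paired[sample(nrow(paired)), ]
  tab2 <- build_correlation_table(perm)
  expect_equal(as.data.frame(tab2), as.data.frame(tab), tolerance = 1e-12)
})

test_that("PFT CSV reader validates its schema", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "a", test_date = "2022-01-01",
                       FVC = 3.2), f, row.names = FALSE)
  df <- read_pft(f)
  expect_s3_class(df$test_date, "Date")
  write.csv(data.frame(x = 1), f, row.names = FALSE)
  expect_error(read_pft(f), "subject_id")
})
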