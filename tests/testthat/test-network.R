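test_that("load_ipd types a minimal table and rejects schema violations", {
  df <- data.frame(study = "s1", trt = c("PBO", "A"), age = c(50, 60),
                   male = c(0, 1),
                   out_cat = c("<PASI75", "PASI100"),
                   stringsAsFactors = FALSE)
  ipd <- load_ipd(df, c("age", "male"), pasi4)
  expect_length(ipd, 1)
  expect_equal(ipd$s1$n, 2)
  expect_equal(sort(ipd$s1$treatments), c("A", "PBO"))
  expect_equal(ipd$s1$data$y, c(1L, 4L))

  bad <- df; bad$out_cat[2] <- "PASI80"
  expect_error(load_ipd(bad, c("age", "male"), pasi4), "PASI80.*row 2")

  bad2 <- df; bad2$age[1] <- NA
  expect_error(load_ipd(bad2, c("age", "male"), pasi4), "missing.*age.*row 1")

  one_arm <- df; one_arm$trt <- "PBO"
  expect_error(load_ipd(one_arm, c("age", "male"), pasi4),
               "fewer than 2 distinct treatments")
})

test_that("load_agd validates counts and summaries", {
  base <- data.frame(study = "g1", trt = "A", n = 100,
                     cat1 = 40, cat2 = 30, cat3 = 20, cat4 = 10,
                     age_mean = 45, age_sd = 8, male_prop = 0.5)
  agd <- load_agd(base, c("age", "male"), pasi4)
  expect_length(agd, 1)
  expect_equal(agd$g1$covariate_types, c(age = "continuous", male = "binary"))

  bad <- base; bad$cat4 <- 20
  expect_error(load_agd(bad, c("age", "male"), pasi4), "do not sum to n")
  bad <- base; bad$cat1 <- -1; bad$cat2 <- 71
  expect_error(load_agd(bad, c("age", "male"), pasi4), "negative")
  bad <- base; bad$age_sd <- 0
  expect_error(load_agd(bad, c("age", "male"), pasi4), "sd <= 0")
  bad <- base; bad$age_mean <- NULL; bad$age_sd <- NULL
  expect_error(load_agd(bad, c("age", "male"), pasi4), "no summary columns")
})

test_that("psoriasis-like fixture loads round-trip with expected shape", {
  sim <- psoriasis_like_network(seed = 5, n_ipd = 40, n_agd = 40)
  net <- sim$network
  expect_length(net$ipd, 4)
  expect_length(net$agd, 5)
  for (s in net$ipd) expect_length(s$covariates, 5)
  expect_equal(nrow(net$treatments), 7)
})

test_that("assemble_network validates connectivity, classes and duplicates", {
  ipd <- load_ipd(tiny_ipd_df(), c("age", "male"), pasi4)
  net <- assemble_network(ipd, list(), c(PBO = "placebo", A = "active"),
                          pasi4, "PBO")
  expect_s3_class(net, "mlnmr_network")
  expect_equal(nrow(net$treatments), 2)
  expect_equal(net$treatments$id[1], "PBO")

  # two studies sharing no treatment -> disconnected
  df2 <- tiny_ipd_df(study = "s2", seed = 12)
  df2$trt <- sub("PBO", "C", sub("^A$", "D", df2$trt))
  ipd2 <- load_ipd(df2, c("age", "male"), pasi4)
  expect_error(
    assemble_network(c(ipd, ipd2),
                     list(), c(PBO = "p", A = "a", C = "c", D = "d"),
                     pasi4, "PBO"),
    "disconnected")

  expect_error(
    assemble_network(c(ipd, load_ipd(tiny_ipd_df(), c("age", "male"), pasi4)),
                     list(), c(PBO = "p", A = "a"), pasi4, "PBO"),
    "duplicate")
  expect_error(assemble_network(ipd, list(), c(PBO = "p"), pasi4, "PBO"),
               "without a class")
})

test_that("connectivity decision matches a union-find oracle on random graphs", {
  set.seed(42)
  for (rep in 1:30) {
    K <- sample(3:7, 1)
    trts <- paste0("t", seq_len(K))
    n_studies <- sample(2:5, 1)
    rosters <- lapply(seq_len(n_studies), function(i)
      sample(trts, sample(2:min(3, K), 1)))
    present <- unique(unlist(rosters))
    oracle <- uf_connected(present, rosters)
    comps <- mlnmr:::treatment_components(present, rosters)
    expect_equal(length(comps) == 1L, oracle)
  }
})

test_that("inclusive counts are the tail partial sums and always monotone", {
  expect_equal(inclusive_counts(c(40, 30, 20, 10)), c(60, 30, 10))
  expect_equal(inclusive_counts(c(100, 0, 0, 0)), c(0, 0, 0))
  expect_error(inclusive_counts(c(-1, 5)), "negative")
  set.seed(1)
  for (i in 1:50) {
    cnt <- as.numeric(rmultinom(1, rpois(1, 50) + 1, runif(4)))
    inc <- inclusive_counts(cnt)
    expect_true(all(diff(inc) <= 0))
    expect_equal(inc[1], sum(cnt[-1]))
  }
})

test_that("write_network / read_network round-trips a mixed network", {
  sim <- small_mixed_network(seed = 3, n_ipd = 30, n_agd = 40, n_points = 8)
  net <- sim$network
  dir <- withr::local_tempdir()
  write_network(net, dir)
  net2 <- read_network(dir)
  expect_equal(net2$treatments, net$treatments)
  expect_equal(net2$outcome$labels, net$outcome$labels)
  expect_equal(names(net2$ipd), names(net$ipd))
  expect_equal(names(net2$agd), names(net$agd))
  for (s in names(net$ipd))
    expect_equal(net2$ipd[[s]]$data, net$ipd[[s]]$data, tolerance = 1e-12)
  for (s in names(net$agd))
    expect_equal(net2$agd[[s]]$arms, net$agd[[s]]$arms, tolerance = 1e-12)
})
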