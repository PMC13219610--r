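test_that("CSV round trip is the identity on random valid tables", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(0:20, 1)
    p <- sample(2:6, 1)
    X <- matrix(round(rnorm(n * p) * 10^sample(-3:3, 1), 9), n, p,
                dimnames = list(NULL, paste0("d", seq_len(p))))
    has_y <- i %% 2 == 0
    tab <- compound_table(sprintf("C%03d", seq_len(n)), X,
                          if (has_y) runif(n, 1, 5) else NULL)
    path <- tempfile(fileext = ".csv")
    write_compound_table(tab, path)
    back <- read_compound_table(path)
    expect_identical(back$ids, tab$ids)
    expect_equal(back$X, tab$X, tolerance = 1e-12)
    if (has_y) expect_equal(back$y, tab$y, tolerance = 1e-12)
    else expect_null(back$y)
  }
})

test_that("reading deduplicates exact duplicate ids and is idempotent", {
  df <- data.frame(compound_id = c("a", "b", "b", "c"),
                   LogP = c(1, 2, 2, 3), MW = c(10, 20, 20, 30),
                   pIGC50 = c(1.1, 2.2, 2.2, 3.3))
  path <- make_csv(df)
  expect_message(tab <- read_compound_table(path), "collapsed 1")
  expect_equal(nrow(tab$X), 3)
  expect_equal(attr(tab, "dedup_count"), 1L)

  # idempotent: a clean re-read of the deduplicated table changes nothing
  path2 <- tempfile(fileext = ".csv")
  write_compound_table(tab, path2)
  tab2 <- read_compound_table(path2)
  expect_equal(attr(tab2, "dedup_count"), 0L)
  expect_equal(tab2$X, tab$X)

  # conflicting values under one id are an error, not silently merged
  df$MW[3] <- 99
  expect_error(read_compound_table(make_csv(df)), "conflicting")
})

test_that("validation errors name the offending row and column", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,LogP,MW", "a,1.0,10", "b,,20", "c,3.0,30"), path)
  expect_error(read_compound_table(path), "row 2, column LogP")
  writeLines(c("compound_id,LogP,MW", "a,1.0,10", "b,xx,20"), path)
  expect_error(read_compound_table(path), "row 2, column LogP")
  expect_error(read_compound_table(tempfile()), "not found")
})

test_that("empty tables round trip as header-only CSVs", {
  tab <- compound_table(character(0),
                        matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("LogP", "MW"))))
  path <- tempfile(fileext = ".csv")
  write_compound_table(tab, path)
  back <- read_compound_table(path)
  expect_equal(nrow(back$X), 0)
  expect_equal(colnames(back$X), c("LogP", "MW"))
})

test_that("summarize_table matches hand arithmetic and its own variance", {
  tab <- compound_table(c("a", "b", "c"),
                        cbind(x = c(1, 2, 3), cns = c(1, 1, 1)))
  s <- summarize_table(tab)
  expect_equal(s$mean[s$variable == "x"], 2)
  expect_equal(s$sd[s$variable == "x"], 1)
  expect_equal(s$median[s$variable == "x"], 2)
  expect_equal(s$sd[s$variable == "cns"], 0)
  expect_equal(s$variance[s$variable == "cns"], 0)

  set.seed(1)
  big <- compound_table(sprintf("c%02d", 1:50),
                        matrix(rnorm(100), 50, 2,
                               dimnames = list(NULL, c("u", "v"))),
                        runif(50, 1, 5))
  sb <- summarize_table(big)
  expect_equal(sb$variance, sb$sd^2, tolerance = 1e-9)
  expect_true("pIGC50" %in% sb$variable)

  one <- compound_table("a", cbind(x = 1))
  expect_error(summarize_table(one), "n >= 2")
})

test_that("descriptor specs enforce their invariants", {
  expect_error(descriptor_spec("x", "continuous", 1, 0), "lower")
  expect_error(descriptor_spec("x", "discrete", 0.5, 3), "integers")
  expect_error(descriptor_spec("x", "continuous", 0, 1, sd = 2, variance = 9),
               "inconsistent")
  expect_error(descriptor_spec("x", "continuous", 0, 1,
                               monotone_direction = 2), "monotone_direction")
  dirs <- constraint_map(descriptor_specs())
  expect_equal(dirs[c("LogP", "MW", "nDB")], c(LogP = 1L, MW = 1L, nDB = 1L))
  expect_equal(dirs[["nROH"]], -1L)
  expect_true(all(dirs[c("A", "B", "GATS1p", "NRB")] == 0L))
})

test_that("compound_table rejects structural violations", {
  X <- cbind(a = c(1, 2), b = c(3, 4))
  expect_error(compound_table(c("x", "x"), X), "duplicate")
  expect_error(compound_table(c("x", "y"), cbind(c(1, NA), c(3, 4))),
               "column names")
  Xna <- X; Xna[2, 1] <- NA
  expect_error(compound_table(c("x", "y"), Xna), "missing value at row 2")
  sp <- list(a = descriptor_spec("a", "discrete", 0, 5),
             b = descriptor_spec("b", "continuous", 0, 10))
  expect_error(compound_table(c("x", "y"), cbind(a = c(1.5, 2), b = c(1, 2)),
                              specs = sp), "non-integers")
  expect_error(compound_table(c("x", "y"), cbind(a = c(7, 2), b = c(1, 2)),
                              specs = sp), "outside")
})
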