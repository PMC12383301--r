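test_that("comma and point dialects parse to identical traces", {
  vals <- list(A1 = c(0.0, 0.1, 12.5, 30.25, 44),
               B7 = c(1, 2.5, 10, 20, 35.75))
  tms <- 0:4
  p_point <- write_export(tms, vals, "point")
  p_comma <- write_export(tms, vals, "comma",
                          comment = "# exported with decimal commas")
  tr_point <- read_confluence_export(p_point)
  tr_comma <- read_confluence_export(p_comma)
  expect_equal(names(tr_point), c("A1", "B7"))
  expect_equal(tr_comma$A1$values, c(0.0, 0.1, 12.5, 30.25, 44))
  for (w in names(tr_point)) {
    expect_equal(tr_point[[w]]$values, tr_comma[[w]]$values)
    expect_equal(tr_point[[w]]$times, tr_comma[[w]]$times)
  }
  # forcing the wrong dialect on a comma file must fail, not mis-parse
  expect_error(read_confluence_export(p_comma, dialect = "point"))
})

test_that("a 49-point hourly single-well export reads as one full trace", {
  p <- write_export(0:48, list(C3 = seq(5, 53, length.out = 49)))
  tr <- read_confluence_export(p)
  expect_length(tr, 1)
  expect_length(tr$C3$values, 49)
  expect_equal(tr$C3$well_id, "C3")
})

test_that("malformed exports produce named, specific errors", {
  p <- write_export(0:3, list(A1 = c(1, 2, 3, 4)))
  txt <- readLines(p)
  txt[3] <- "1,oops"
  writeLines(txt, p)
  expect_error(read_confluence_export(p), "oops.*row.*column|row.*column")

  p2 <- write_export(c(0, 1, 1, 2), list(A1 = c(1, 2, 3, 4)))
  expect_error(read_confluence_export(p2), "increasing")

  p3 <- write_export(0:3, list(A1 = c(1, 2, 105, 4)))
  expect_error(read_confluence_export(p3), "\\[0,100\\]")
})

test_that("pre-treatment rows are dropped and short gaps interpolated", {
  p <- write_export(-2:4, list(A1 = c(9, 9, 10, 12, 14, 16, 18)))
  expect_warning(tr <- read_confluence_export(p), "pre-treatment")
  expect_equal(tr$A1$times, 0:4)
  expect_equal(tr$A1$values, c(10, 12, 14, 16, 18))

  # two consecutive missing points interpolate linearly
  p2 <- write_export(0:5, list(A1 = c(10, NA, NA, 16, 18, 20)))
  tr2 <- read_confluence_export(p2)
  expect_equal(tr2$A1$values, c(10, 12, 14, 16, 18, 20))

  # three consecutive missing points are an error
  p3 <- write_export(0:5, list(A1 = c(10, NA, NA, NA, 18, 20)))
  expect_error(read_confluence_export(p3), "gap of 3")
})

test_that("trace invariants reject bad grids and ranges", {
  expect_error(confluence_trace("A1", c(0, 1, 2.5), c(1, 2, 3)), "uniform")
  expect_error(confluence_trace("A1", 0, 1), ">= 2")
  expect_error(confluence_trace("A1", 0:2, c(1, -2, 3)), "\\[0,100\\]")
  expect_error(death_trace("A1", 0:2, c(2, 1.5, 3)), "tolerance")
  # 0.2-point dips are within the smoothing tolerance
  expect_silent(death_trace("A1", 0:2, c(2, 1.85, 3)))
})

test_that("plate map validation matches treated groups to controls", {
  pm <- plate_map(basic_map())
  expect_s3_class(pm, "stip_plate_map")

  treated_only <- basic_map()[1:3, ]
  expect_error(plate_map(treated_only), "no matched control")

  dup <- basic_map(); dup$well[2] <- "A1"
  expect_error(plate_map(dup), "duplicate")

  # 8 lines x 2 conditions x 3 reps = 48 wells -> 16 groups, 8 matched pairs
  big <- do.call(rbind, lapply(1:8, function(i) {
    m <- basic_map(line = paste0("L", i))
    m$well <- paste0(LETTERS[i], 1:6)
    m
  }))
  pm2 <- plate_map(big)
  grp <- unique(pm2[, c("cell_line", "condition")])
  expect_equal(nrow(grp), 16)
  expect_equal(sum(grp$condition == "treated"), 8)
})

test_that("cytokine reader canonicalizes analytes and validates values", {
  df <- data.frame(sample_id = 1:4, cell_line = "X", condition = "treated",
                   analyte = c("IL6", "il-10", "IFN-g", "TNF-alpha"),
                   concentration_pg_ml = c(10, 20, 30, 40),
                   below_llod = FALSE)
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  out <- read_cytokine_table(p)
  expect_setequal(out$analyte, c("IL-6", "IL-10", "IFN-gamma", "TNF-alpha"))

  df$concentration_pg_ml[1] <- -5
  write.csv(df, p, row.names = FALSE)
  expect_error(read_cytokine_table(p), "negative")
})

test_that("result writer round-trips metrics and handles empty results", {
  out <- tempfile()
  paths <- write_results(out)
  expect_true(all(file.exists(paths)))
  expect_equal(jsonlite::read_json(file.path(out, "calls.json")),
               structure(list(), names = character()))

  metrics <- data.frame(cell_line = c("A", "B"), condition = "treated",
                        production_batch = "B1",
                        auc = c(1234.567890123, 2.000001),
                        delta_relative = c(0.123456789, -0.5))
  write_results(out, metrics = metrics)
  back <- read.csv(file.path(out, "metrics.csv"))
  expect_equal(back$auc, metrics$auc, tolerance = 1e-6)
  expect_equal(back$delta_relative, metrics$delta_relative, tolerance = 1e-6)
})
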