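# The seven-column positional table schema, row validation, and CSV
# round-tripping.

write_raw_csv <- function(rows, path, header = "name,ID,SMILES,Doses max,Activity,FUB,CLint") {
  writeLines(c(header, rows), path)
}

test_that("a one-row file binds fields by position", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv('drugA,CHEMBL1,CCO,500,1,0.8,10', f)
  tab <- read_compound_table(f)
  expect_s3_class(tab, "compound_table")
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$name, "drugA")
  expect_identical(tab$chembl_id, "CHEMBL1")
  expect_identical(tab$smiles, "CCO")
  expect_identical(tab$dose_max, 500)
  expect_identical(tab$activity, 1L)
  expect_identical(tab$fub, 0.8)
  expect_identical(tab$clint, 10)
})

test_that("header text is ignored: binding is positional", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv('drugA,CHEMBL1,CCO,500,1,0.8,10', f,
                header = "colA,colB,colC,colD,colE,colF,colG")
  tab <- read_compound_table(f)
  expect_identical(tab$dose_max, 500)
  expect_identical(tab$fub, 0.8)
})

test_that("out-of-range rows are rejected with the row named", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(c('ok,ID1,CCO,500,1,0.8,10',
                  'badfub,ID2,CCO,500,1,1.5,10',
                  'badsmiles,ID3,xx$$,500,0,0.5,10',
                  'badclint,ID4,CCO,500,0,0.5,-3'), f)
  expect_warning(tab <- read_compound_table(f), "row 2")
  expect_identical(nrow(tab), 1L)
  rej <- attr(tab, "rejected")
  expect_identical(rej$row, c(2L, 3L, 4L))
  expect_match(rej$reason[1], "FUB")
  expect_match(rej$reason[2], "SMILES")
  expect_match(rej$reason[3], "CLint")
})

test_that("blank, NA and NaN cells become absent dose/activity", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(c('a,I1,CCO,,,0.5,10',
                  'b,I2,CCO,NA,na,0.5,10',
                  'c,I3,CCO,NaN,NAN,0.5,10'), f)
  tab <- read_compound_table(f)
  expect_identical(nrow(tab), 3L)
  expect_true(all(is.na(tab$dose_max)))
  expect_true(all(is.na(tab$activity)))
})

test_that("structural errors are reported: missing file, too few columns, extras", {
  expect_error(read_compound_table("no/such/file.csv"), "not found")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "x,CCO,1"), f)
  expect_error(read_compound_table(f), ">= 7 columns")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv('a,I1,CCO,500,1,0.5,10,extra1,extra2', f2,
                header = "n,i,s,d,a,f,c,x1,x2")
  expect_warning(tab <- read_compound_table(f2), "extra column")
  expect_identical(ncol(tab), 7L)
})

test_that("a generated table round-trips through the CSV schema", {
  tab <- small_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_compound_csv(tab, f)
  back <- read_compound_table(f)
  expect_identical(nrow(back), nrow(tab))
  expect_identical(back$name, tab$name)
  expect_identical(back$smiles, tab$smiles)
  expect_equal(back$fub, tab$fub, tolerance = 1e-12)
  expect_equal(back$clint, tab$clint, tolerance = 1e-12)
  expect_equal(back$dose_max, tab$dose_max, tolerance = 1e-12)
  expect_identical(back$activity, tab$activity)
})

test_that("the XLSX input route parses the same schema", {
  # build a genuine xlsx with openpyxl (text-only repo: generated on the fly)
  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_compound_csv(small_table()[1:5, ], f_csv)
  script <- sprintf(paste0(
    "import csv, openpyxl\n",
    "wb = openpyxl.Workbook(); ws = wb.active\n",
    "for row in csv.reader(open('%s')):\n",
    "    ws.append(row)\n",
    "wb.save('%s')\n"), f_csv, f_xlsx)
  status <- system2("python", "-", input = script, stdout = FALSE,
                    stderr = FALSE)
  expect_identical(status, 0L)
  tab <- read_compound_table(f_xlsx)
  expect_identical(nrow(tab), 5L)
  expect_equal(tab$fub, small_table()$fub[1:5], tolerance = 1e-10)
  expect_identical(tab$smiles, small_table()$smiles[1:5])
})

test_that("prediction CSV has the documented schema and round-trips numerics", {
  tab <- small_table()[1:4, ]
  cfg <- rule_config(selected = c("BSEP", "P-gp"), rule = "OR", k = 1)
  res <- predict_batch(tab, oracle_panel(fixture_spec(25L, 101L)), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_prediction_csv(res, f)
  out <- utils::read.csv(f)
  expect_identical(nrow(out), 4L)
  expect_true(all(c("name", "smiles", "dose_BSEP", "dose_P_gp",
                    "predicted_activity", "score") %in% names(out)))
  df <- as.data.frame(res)
  # >= 10 significant digits survive the round trip
  expect_equal(out$dose_BSEP, df$dose_BSEP, tolerance = 1e-10)
  expect_equal(out$score, df$score, tolerance = 1e-10)
  expect_identical(out$predicted_activity, df$predicted_activity)
})

test_that("empty prediction sets are refused", {
  expect_error(write_prediction_csv(data.frame(), tempfile()), "no prediction")
})
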