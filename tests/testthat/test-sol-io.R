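test_that("written files carry the fixed-width conventions", {
  set.seed(1)
  p <- random_profile(1)
  p$layers$slll[1] <- 0.188
  p$layers$sdul[1] <- max(p$layers$sdul[1], 0.2)
  p$layers$ssat[1] <- max(p$layers$ssat[1], 0.3)
  path <- withr::local_tempfile(fileext = ".SOL")
  write_sol(p, path)
  lines <- readLines(path)
  layer1 <- lines[grep("^@  SLB", lines) + 1]
  expect_match(layer1, " 0.188", fixed = TRUE) # SLLL at 3 decimals
  expect_match(layer1, "  -99", fixed = TRUE)  # SLCF sentinel, literal
  # no trailing whitespace anywhere, LF endings
  expect_false(any(grepl("[ \t]$", lines)))
  raw <- readBin(path, "raw", file.size(path))
  expect_false(any(raw == charToRaw("\r")))
})

test_that("the -99 sentinel appears only in SLCF and SLHB", {
  set.seed(2)
  p <- random_profile(2)
  path <- withr::local_tempfile(fileext = ".SOL")
  write_sol(p, path)
  q <- read_sol(path)[[1]]
  for (col in c("slcf", "slhb")) {
    expect_true(all(q$layers[[col]] == -99))
  }
  others <- setdiff(names(q$layers), c("slcf", "slhb", "slmh"))
  for (col in others) {
    expect_true(all(q$layers[[col]] != -99), label = col)
  }
})

test_that("write then read round-trips at printed precision", {
  set.seed(3)
  path <- withr::local_tempfile(fileext = ".SOL")
  profiles <- lapply(1:50, random_profile)
  write_sol(profiles, path)
  back <- read_sol(path)
  expect_length(back, 50)
  for (i in seq_along(profiles)) {
    expect_profile_roundtrip_equal(profiles[[i]],
      back[[profiles[[i]]$profile_id]])
  }
})

test_that("every emitted file is parseable by the module's own reader", {
  dir <- withr::local_tempdir()
  generate_template_set(dir, seed = 5)
  for (f in list.files(dir, full.names = TRUE)) {
    expect_length(read_sol(f), 1)
  }
  # a combined 27-template file parses into 27 keys
  combined <- withr::local_tempfile(fileext = ".SOL")
  write_sol(default_templates(), combined)
  expect_length(read_sol(combined), 27)
})

test_that("malformed input raises located parse errors", {
  set.seed(4)
  p <- random_profile(4)
  path <- withr::local_tempfile(fileext = ".SOL")
  write_sol(p, path)
  lines <- readLines(path)

  # truncated final layer line
  trunc <- lines
  trunc[length(trunc)] <- substr(trunc[length(trunc)], 1, 20)
  path2 <- withr::local_tempfile(fileext = ".SOL")
  writeLines(trunc, path2)
  expect_error(read_sol(path2), "line")

  # non-numeric field names its column
  bad <- lines
  i <- grep("^@  SLB", bad) + 1
  bad[i] <- sub("0\\.", "x.", bad[i])
  path3 <- withr::local_tempfile(fileext = ".SOL")
  writeLines(bad, path3)
  expect_error(read_sol(path3), "non-numeric")

  # malformed profile header
  hdr <- lines
  hdr[grep("^\\*TP", hdr)] <- "*BROKEN"
  path4 <- withr::local_tempfile(fileext = ".SOL")
  writeLines(hdr, path4)
  expect_error(read_sol(path4), "malformed|sections")
})

test_that("field overflow is reported with profile and field name", {
  set.seed(5)
  p <- random_profile(5)
  p$layers$scec[1] <- 12345678
  path <- withr::local_tempfile(fileext = ".SOL")
  expect_error(write_sol(p, path), "SCEC")
})

test_that("profile invariants are enforced at construction", {
  set.seed(6)
  p <- random_profile(6)
  bad_layers <- p$layers
  bad_layers$sdul[2] <- bad_layers$slll[2] - 0.01
  expect_error(new_soil_profile("BADPROF", "TEST", "L", 200, "d",
    p$site, p$surface, bad_layers), "SLLL < SDUL < SSAT")
  bad_layers2 <- p$layers
  bad_layers2$slb[3] <- bad_layers2$slb[2]
  expect_error(new_soil_profile("BADPROF", "TEST", "L", 200, "d",
    p$site, p$surface, bad_layers2), "strictly increasing")
  expect_error(new_soil_profile("TOOLONGPROFILE", "TEST", "L", 200, "d",
    p$site, p$surface, p$layers), "10 characters")
})
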