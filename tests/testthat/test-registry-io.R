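writeLinesTmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("frequency tables are read with delimiter sniffing and checks", {
  f <- writeLinesTmp(c("category\tfrequency", "a\t0.6", "b\t0.4"))
  tab <- readFrequencyTable(f)
  expect_s4_class(tab, "FrequencyTable")
  rec <- tableRecords(tab)
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$frequency), 1)
  expect_equal(rec$category[1], "a")   # descending frequency order
  # comma dialect
  fc <- writeLinesTmp(c("category,frequency", "a,0.6", "b,0.4"))
  expect_equal(tableRecords(readFrequencyTable(fc))$frequency,
               c(0.6, 0.4))
  # counts-only tables derive frequencies
  fk <- writeLinesTmp(c("category\tcount", "a\t6", "b\t4"))
  expect_equal(tableRecords(readFrequencyTable(fk))$frequency, c(0.6, 0.4))
})

test_that("near-unit sums renormalize and bad tables fail loudly", {
  f <- writeLinesTmp(c("category\tfrequency", "a\t0.595", "b\t0.4"))
  expect_message(tab <- readFrequencyTable(f), "renormalizing")
  expect_equal(sum(tableRecords(tab)$frequency), 1, tolerance = 1e-12)
  f2 <- writeLinesTmp(c("category\tfrequency", "a\t0.5", "b\t0.4"))
  expect_error(readFrequencyTable(f2), "renormalization band")
  dup <- writeLinesTmp(c("category\tfrequency", "a\t0.6", "a\t0.4"))
  expect_error(readFrequencyTable(dup), "line 3")
  noCat <- writeLinesTmp(c("name\tfrequency", "a\t1"))
  expect_error(readFrequencyTable(noCat), "category")
  bad <- writeLinesTmp(c("category\tfrequency", "a\t0.6", "b\tx"))
  expect_error(readFrequencyTable(bad), "non-numeric")
})

test_that("write-read round trips are byte-stable", {
  rec <- data.frame(category = c("b", "a", "c"),
                    frequency = c(0.2, 0.5, 0.3))
  tab <- FrequencyTable(rec, population = "toy")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeFrequencyTable(tab, f1)
  writeFrequencyTable(readFrequencyTable(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("haplotype strings parse and serialize losslessly", {
  h <- c("A*01:01~C*07:01~B*08:01~DRB3*01:01~DRB1*03:01~DQB1*02:01",
         "A*02:01~C*04:01~B*35:01~DRB4*01:01~DRB1*04:01~DQB1*03:02")
  m <- parseHaplotype(h)
  expect_equal(dim(m), c(2, 6))
  expect_equal(colnames(m), c("A", "C", "B", "DRBX", "DRB1", "DQB1"))
  expect_identical(haplotypeString(m), h)
  expect_error(parseHaplotype("A*01:01~B*08:01"), "malformed")
  expect_error(parseHaplotype("a~~b~c~d~e"), "malformed")
})

test_that("allele marginalization sums haplotype frequencies per locus", {
  rec <- data.frame(
    category = c("A*01:01~C*07:01~B*08:01~DRB3*01:01~DRB1*03:01~DQB1*02:01",
                 "A*01:01~C*04:01~B*35:01~DRB4*01:01~DRB1*04:01~DQB1*03:02",
                 "A*02:01~C*04:01~B*35:01~DRB4*01:01~DRB1*04:01~DQB1*03:02"),
    frequency = c(0.06, 0.04, 0.90))
  tabs <- allelesFromHaplotypes(FrequencyTable(rec))
  a <- tableRecords(tabs$A)
  expect_equal(a$frequency[a$category == "A*01:01"], 0.10)
  expect_equal(a$frequency[a$category == "A*02:01"], 0.90)
  expect_equal(tabs$A@kind, "allele")
  # every locus conserves mass
  for (t in tabs) expect_equal(sum(tableRecords(t)$frequency), 1,
                               tolerance = 1e-9)
  # single haplotype: every locus is one allele at frequency 1
  solo <- allelesFromHaplotypes(
    FrequencyTable(data.frame(category = rec$category[1], frequency = 1)))
  for (t in solo) expect_equal(tableRecords(t)$frequency, 1)
})

test_that("marginals match a brute-force group-by on random tables", {
  set.seed(31)
  alleles <- lapply(c("A", "C", "B", "DRB3", "DRB1", "DQB1"), function(l)
    paste0(l, "*", sprintf("%02d:01", 1:6)))
  cats <- unique(vapply(1:80, function(i)
    paste(vapply(alleles, sample, character(1), size = 1), collapse = "~"),
    character(1)))
  w <- stats::runif(length(cats))
  tab <- FrequencyTable(data.frame(category = cats, frequency = w / sum(w)))
  tabs <- allelesFromHaplotypes(tab)
  fields <- do.call(rbind, strsplit(cats, "~", fixed = TRUE))
  rec <- tableRecords(tab)
  recFields <- do.call(rbind, strsplit(rec$category, "~", fixed = TRUE))
  for (j in 1:6) {
    expected <- tapply(rec$frequency, recFields[, j], sum)
    got <- tableRecords(tabs[[j]])
    expect_equal(got$frequency,
                 as.numeric(expected[got$category]), tolerance = 1e-12)
  }
})

test_that("frequency tables convert to counts with the rounding policy", {
  tab <- FrequencyTable(data.frame(category = c("a", "b"),
                                   frequency = c(0.5, 0.5)))
  s <- countsFromFrequencies(tab, 10)
  expect_equal(unname(categoryCounts(s)[order(names(categoryCounts(s)))]),
               c(5, 5))
  tiny <- FrequencyTable(data.frame(category = c("a", "b"),
                                    frequency = c(0.9999, 1e-4)))
  expect_message(s2 <- countsFromFrequencies(tiny, 100), "dropped")
  expect_equal(nUnique(s2), 1)
  expect_lte(totalDraws(s2), 100 + 2)
  expect_error(countsFromFrequencies(tiny, 0.5), ">= 1")
  # explicit counts win over frequency scaling
  withCounts <- FrequencyTable(data.frame(category = c("a", "b"),
                                          frequency = c(0.6, 0.4),
                                          count = c(12, 8)))
  expect_equal(totalDraws(countsFromFrequencies(withCounts, 5)), 20)
})
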