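# Chemistry-path tests; the backend is Open Babel (obabel + ChemmineOB).

write_smi <- function(lines) {
  f <- withr::local_tempfile(fileext = ".smi", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("SMILES files are read in order with rejects reported", {
  f <- write_smi(c("CCO eth", "c1ccccc1 bz"))
  r <- read_compounds(f)
  expect_equal(r$id, c("eth", "bz"))
  expect_equal(nrow(rejects(r)), 0L)

  f2 <- write_smi(c("CCO a", "C1CC b", "c1ccccc1 c"))  # unmatched ring bond
  r2 <- read_compounds(f2)
  expect_equal(r2$id, c("a", "c"))
  expect_equal(rejects(r2)$id, "b")
  expect_match(rejects(r2)$reason, "unparsable")

  f3 <- write_smi(character())
  expect_error(read_compounds(f3), "empty")
  expect_error(read_compounds("/nonexistent/file.smi"), "no such file")
})

test_that("standardization collapses stereo, salts and charges to one key", {
  recs <- fip:::compound_records(
    c("l_ala", "ala", "acet_na", "acet", "ethanol", "ethanol2", "benzene"),
    c("C[C@H](N)C(=O)O", "CC(N)C(=O)O",       # stereoisomer pair
      "CC(=O)[O-].[Na+]", "CC(=O)O",          # salt vs parent
      "CCO", "OCC",                           # same molecule, atom order
      "c1ccccc1"))
  std <- standardize_compounds(recs)
  expect_equal(nrow(std), 7L)
  expect_true(all(nchar(std$inchikey) == 27L))
  key <- function(id) std$inchikey[std$id == id]
  expect_identical(key("l_ala"), key("ala"))
  expect_identical(key("acet_na"), key("acet"))
  expect_identical(key("ethanol"), key("ethanol2"))
  # idempotence: standardizing the standardized records changes nothing
  again <- standardize_compounds(std)
  expect_identical(again$inchikey, std$inchikey)
  expect_identical(again$smiles, std$smiles)
  # aromatic benzene passes through structurally unchanged
  expect_identical(std$smiles[std$id == "benzene"], "c1ccccc1")
})

test_that("deduplication keeps first occurrences and counts duplicates", {
  recs <- standardize_compounds(
    fip:::compound_records(c("a", "b", "c"), c("CCO", "OCC", "CCN")))
  ded <- deduplicate_compounds(recs)
  expect_equal(ded$id, c("a", "c"))
  expect_identical(attr(ded, "duplicates"), 1L)
  distinct <- deduplicate_compounds(
    standardize_compounds(fip:::compound_records(c("x", "y"), c("CCO", "CCN"))))
  expect_equal(nrow(distinct), 2L)
  expect_identical(attr(distinct, "duplicates"), 0L)
  # concatenating a set with itself returns the original unique set
  twice <- fip:::compound_records(rep(recs$id, 2), rep(recs$smiles, 2),
                                  rep(recs$inchikey, 2))
  expect_equal(deduplicate_compounds(twice)$inchikey, ded$inchikey)
  expect_error(deduplicate_compounds(fip:::compound_records("a", "CCO")),
               "standardized")
})

test_that("encoding yields correct widths and is deterministic", {
  recs <- standardize_compounds(fip:::compound_records(
    c("eth", "asp"), c("CCO", "CC(=O)Oc1ccccc1C(=O)O")))
  m <- encode_compounds(recs, fingerprint_spec("maccs"))
  expect_identical(ncol(m$bits), 166L)
  e4 <- encode_compounds(recs, fingerprint_spec("ecfp", radius = 2))
  expect_identical(ncol(e4$bits), 1024L)
  expect_gt(sum(e4$bits[1, ]), 0)  # popcount positive for ethanol
  e6 <- encode_compounds(recs, fingerprint_spec("ecfp", radius = 3))
  expect_gte(sum(e6$bits[2, ]), sum(e4$bits[2, ]))  # larger neighborhoods
  # determinism: identical standardized structures -> identical vectors
  m2 <- encode_compounds(recs, fingerprint_spec("maccs"))
  expect_identical(m2$bits, m$bits)
  dup <- standardize_compounds(fip:::compound_records(c("x", "y"),
                                                      c("CCO", "OCC")))
  md <- encode_compounds(dup, fingerprint_spec("maccs"))
  expect_identical(md$bits[1, ], md$bits[2, ])
  expect_error(encode_compounds(recs, fingerprint_spec("pubchemkey")),
               "not supported")
})

test_that("the bundled 40-compound fixture survives the whole pipeline", {
  f <- system.file("extdata", "druglike40.smi", package = "fip")
  x <- featurize_file(f, fingerprint_spec("ecfp", radius = 2))
  expect_identical(nrow(x$bits), 40L)
  expect_identical(ncol(x$bits), 1024L)
  expect_identical(nrow(attr(x, "rejects")), 0L)
  expect_true(all(rowSums(x$bits) > 0))
})

test_that("FPS files round-trip bitwise and reject malformed input", {
  set.seed(14)
  x <- rand_fpset(10, 37)  # length not divisible by 8 exercises padding
  f <- withr::local_tempfile(fileext = ".fps")
  write_fps(x, f)
  back <- read_fps(f)
  expect_identical(back$bits, x$bits)
  expect_identical(format(back$spec), format(x$spec))

  # empty set -> valid header-only file
  empty <- fpset(matrix(integer(), 0, 8), fingerprint_spec("custom", length = 8),
                 ids = character())
  write_fps(empty, f)
  expect_identical(nrow(read_fps(f)$bits), 0L)

  # header/record length mismatch is an error
  lines <- c("#FPS1", "#num_bits=16", "#type=custom-16", "abcdef\tid1")
  writeLines(lines, f)
  expect_error(read_fps(f), "length mismatch")
  writeLines(c("#FPS1", "#type=custom-16"), f)
  expect_error(read_fps(f), "num_bits")
})

test_that("sdf input reaches the same records as smi input", {
  smi <- write_smi(c("CCO eth", "CCN amine"))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  system2(fip:::obabel_path(), c(smi, "-osdf", "-e"), stdout = sdf,
          stderr = FALSE)
  r_smi <- standardize_compounds(read_compounds(smi))
  r_sdf <- standardize_compounds(read_compounds(sdf))
  expect_setequal(r_sdf$inchikey, r_smi$inchikey)
})
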