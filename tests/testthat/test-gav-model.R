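test_that("packaged table holds the printed group rows bit-exactly", {
  tab <- builtin_gav_table()
  expect_equal(nrow(tab$values), 41)
  expect_equal(unname(tab$intercept), c(272.69, -153.46, 168.44))
  expect_equal(unname(gav_lookup(tab, "CO-(O)(CO)")),
               c(9.79, -28.16, -79.72))
  expect_equal(unname(gav_lookup(tab, "correction m-")),
               c(-1.91, -1.91, 14.90))
  expect_equal(unname(gav_lookup(tab, "rsc")), c(-20.22, -20.22, 4.19))
  expect_equal(unname(gav_lookup(tab, "N-(CO)_2_(C_B)")),
               c(30.65, -66.09, 38.44))
  # known collinearity aliases stay distinct labels with equal triples
  expect_equal(unname(gav_lookup(tab, "O-(C)(C_B)")),
               unname(gav_lookup(tab, "C-(H)3(O)")))
})

test_that("label canonicalization normalizes spelling and ligand order", {
  expect_equal(canonical_label("CO-(O)(C_B)"), "CO-(C_B)(O)")
  expect_equal(canonical_label("C_B-(H)(C_B)_2_"), "C_B-(H)(C_B)2")
  expect_equal(canonical_label("C_B-(C_B)(H)(C_B)"), "C_B-(H)(C_B)2")
  expect_equal(canonical_label("C-(C)(H)2(C_B)"), "C-(H)2(C_B)(C)")
  expect_equal(canonical_label("rsc"), "rsc")
  expect_equal(canonical_label("CH_3(qua)"), "CH3(qua)")
  expect_equal(canonical_label(canonical_label("CO-(O)(CO)")),
               canonical_label("CO-(O)(CO)"))  # idempotent
  expect_error(canonical_label("Q-(H)"), "malformed")
})

test_that("estimation sums intercept plus count-weighted group values", {
  tab <- builtin_gav_table()
  expect_equal(gav_estimate(group_vector(), tab, "S"), 272.69)
  expect_equal(gav_estimate(group_vector(), tab, "dfS"), -153.46)
  expect_equal(gav_estimate(group_vector(), tab, "dfG"), 168.44)
  benzene <- group_vector(c("C_B-(H)(C_B)2" = 6))
  expect_equal(gav_estimate(benzene, tab, "S"), 272.69 + 6 * 2.38)
  expect_equal(gav_estimate(benzene, tab, "dfG"), 168.44 - 6 * 8.79)
})

test_that("estimation is linear in group vectors and order-invariant", {
  tab <- builtin_gav_table()
  gv1 <- group_vector(c("C_B-(H)(C_B)2" = 4, "CO-(O)(C_B)" = 1))
  gv2 <- group_vector(c("O-(H)(CO)" = 1, "C_B-(H)(C_B)2" = 2))
  for (p in c("S", "dfS", "dfG")) {
    expect_equal(gav_estimate(gv1 + gv2, tab, p),
                 gav_estimate(gv1, tab, p) + gav_estimate(gv2, tab, p) -
                   unname(tab$intercept[p]))
  }
  perm <- group_vector(c("CO-(O)(C_B)" = 1, "C_B-(H)(C_B)2" = 4))
  expect_equal(gav_estimate(perm, tab, "S"), gav_estimate(gv1, tab, "S"))
})

test_that("unknown labels error naming every missing label", {
  tab <- builtin_gav_table()
  gv <- group_vector(c("C_B-(H)(C_B)2" = 1, "O-(C_B)2" = 1, "N-(H)2(C)" = 1))
  err <- tryCatch(gav_estimate(gv, tab, "S"), error = conditionMessage)
  expect_match(err, "O-\\(C_B\\)2")
  expect_match(err, "N-\\(H\\)2\\(C\\)")
})

test_that("group vectors imply the right elemental formulas", {
  expect_formula_equal(
    formula_from_groups(group_vector(c("C_B-(H)(C_B)2" = 6))), "C6H6")
  expect_formula_equal(formula_from_groups(dita_group_vector()),
                       "C25H12N2O10")
  expect_formula_equal(formula_from_groups(group_vector()), "")
  # correction labels carry no atoms
  with_corr <- dita_group_vector() +
    group_vector(corrections = c("correction o-" = 2, "correction m-" = 1))
  expect_formula_equal(formula_from_groups(with_corr), "C25H12N2O10")
})

test_that("parameter tables round-trip through JSON", {
  tab <- builtin_gav_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_gav_table(tab, path)
  back <- load_gav_table(path)
  expect_equal(back$values, tab$values)
  expect_equal(back$intercept, tab$intercept)
  expect_error(suppressWarnings(
    load_gav_table(withr::local_tempfile(fileext = ".json"))))
})

test_that("table loading rejects schema violations and duplicates", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(groups = list("C-(H)3(C)" = list(S = 1))),
                       path, auto_unbox = TRUE)
  expect_error(load_gav_table(path), "intercept")
  jsonlite::write_json(
    list(groups = list("CO-(O)(C_B)" = list(S = 1, dfS = 1, dfG = 1),
                       "CO-(C_B)(O)" = list(S = 2, dfS = 2, dfG = 2)),
         intercept = list(S = 0, dfS = 0, dfG = 0)),
    path, auto_unbox = TRUE)
  expect_error(load_gav_table(path), "duplicate")
})
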