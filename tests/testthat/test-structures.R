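test_that("parsing the Spaink nomenclature recovers backbone, acyl and flags", {
  s <- parseStructure("V (C18:1, NMe, S)")
  expect_equal(s@backbone, 5L)
  expect_equal(c(s@acylCarbons, s@acylUnsat), c(18L, 1L))
  expect_true(s@nMethyl)
  expect_true(s@sulfate)
  expect_false(s@carbamoyl)
  expect_false(s@hexose)

  s <- parseStructure("IV-Hex (C18:1)")
  expect_equal(s@backbone, 4L)
  expect_true(s@hexose)
  expect_false(s@nMethyl)

  s <- parseStructure("V (C18:1, Cb) dNAc", deacetylPosition = 3)
  expect_true(s@carbamoyl)
  expect_equal(s@deacetylated, 3L)

  # substituent order in the input is irrelevant
  expect_equal(structureLabel(parseStructure("V (C18:1, S, NMe)")),
               structureLabel(parseStructure("V (C18:1, NMe, S)")))
})

test_that("malformed names are rejected with informative errors", {
  expect_error(parseStructure("IIII (C18:1)"), "Roman")
  expect_error(parseStructure("V (C18:1, Foo)"), "Foo")
  expect_error(parseStructure("V (C18:1, NMe, NMe)"), "duplicated")
  expect_error(parseStructure("V (C18:1) dNAc"), "deacetylPosition")
  expect_error(parseStructure("V (C18:1)", deacetylPosition = 3), "dNAc")
  expect_error(parseStructure("not a structure"), "parse")
  # dNAc cannot sit on the acylated residue or outside the backbone
  expect_error(parseStructure("V (C18:1) dNAc", deacetylPosition = 1), "acyl")
  expect_error(parseStructure("V (C18:1) dNAc", deacetylPosition = 6), "out of")
})

test_that("format/parse round trip is the identity over the whole inventory", {
  inv <- testInventory()
  expect_equal(nrow(inv), 36L)
  structures <- inventoryStructures(inv)
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    txt <- formatStructure(s)
    pos <- if (is.na(s@deacetylated)) NA_integer_ else s@deacetylated
    expect_equal(structureLabel(parseStructure(txt, pos)), structureLabel(s))
  }
  expect_equal(formatStructure(LCOStructure(3, c(16, 0))), "III (C16:0)")
  expect_equal(formatStructure(LCOStructure(4, c(18, 1), hexose = TRUE)),
               "IV-Hex (C18:1)")
})

test_that("composition rules give the expected formulas", {
  # frozen from residue-wise summation: 5 GlcNAc (C8H15NO6) - 4 H2O,
  # then acetyl C2H3O swapped for oleoyl C18H33O
  expect_equal(formulaString(elementalFormula(parseStructure("V (C18:1)"))),
               "C56H97N5O26")
  # 3 GlcNAc - 2 H2O, acetyl swapped for palmitoyl C16H31O
  expect_equal(formulaString(elementalFormula(parseStructure("III (C16:0)"))),
               "C38H69N3O16")
})

test_that("substituent deltas are exactly NMe +CH2, S +SO3, Cb +CHNO, Hex +C6H10O5, dNAc -C2H2O", {
  base <- parseStructure("V (C18:1)")
  fb <- elementalFormula(base)
  expect_true(elementalFormula(parseStructure("V (C18:1, NMe)")) ==
                fb + ElementalFormula(C = 1, H = 2))
  expect_true(elementalFormula(parseStructure("V (C18:1, S)")) ==
                fb + ElementalFormula(S = 1, O = 3))
  expect_true(elementalFormula(parseStructure("V (C18:1, Cb)")) ==
                fb + ElementalFormula(C = 1, H = 1, N = 1, O = 1))
  expect_true(elementalFormula(parseStructure("V-Hex (C18:1)")) ==
                fb + ElementalFormula(C = 6, H = 10, O = 5))
  expect_true(elementalFormula(parseStructure("V (C18:1) dNAc", 3)) ==
                fb - ElementalFormula(C = 2, H = 2, O = 1))
  # the full combination equals the sum of the independent deltas
  expect_true(elementalFormula(parseStructure("V (C18:1, NMe, S)")) ==
                fb + ElementalFormula(C = 1, H = 2) + ElementalFormula(S = 1, O = 3))
})

test_that("one unsaturation removes H2 and one backbone residue adds C8H13NO5", {
  expect_true(elementalFormula(parseStructure("IV (C18:0)")) ==
                elementalFormula(parseStructure("IV (C18:1)")) +
                ElementalFormula(H = 2))
  inv <- testInventory()
  structures <- inventoryStructures(inv)
  anhydro <- ElementalFormula(C = 8, H = 13, N = 1, O = 5)
  labels <- vapply(structures, structureLabel, character(1))
  for (s in structures) {
    if (s@backbone >= 3L && is.na(s@deacetylated)) {
      twin <- s
      twin@backbone <- s@backbone + 1L
      if (structureLabel(twin) %in% labels)
        expect_true(elementalFormula(twin) == elementalFormula(s) + anhydro)
    }
  }
  # positional dNAc isomers share one formula by construction
  expect_true(elementalFormula(parseStructure("V (C18:1, NMe) dNAc", 3)) ==
                elementalFormula(parseStructure("V (C18:1, NMe) dNAc", 4)))
})

test_that("formula arithmetic validates its operands", {
  expect_error(ElementalFormula(C = -1), "nonnegative")
  expect_error(ElementalFormula(Zz = 1), "unknown element")
  expect_error(ElementalFormula(H = 1) - ElementalFormula(H = 2), "underflow")
  expect_equal(formulaString(parseFormula("H14C6O6")), "C6H14O6")
  expect_equal(formulaString(ElementalFormula()), "")
  expect_true(parseFormula("CH4") * 2 == parseFormula("C2H8"))
})
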