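toy_nexus <- function(path) {
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=4;",
    "FORMAT SYMBOLS=\"0 1 2\" MISSING=? GAP=-;",
    "MATRIX",
    "taxA 0102",
    "taxB 01{01}?",
    "taxC -112",
    ";",
    "END;",
    "BEGIN ASSUMPTIONS;",
    "TYPESET * default = ord: 2 4;",
    "END;"), path)
  path
}

test_that("NEXUS parsing fills taxa, cells, polymorphisms and ordered flags", {
  path <- withr::local_tempfile(fileext = ".nex")
  m <- read_matrix(toy_nexus(path))
  expect_equal(dim(m), c(3, 4))
  expect_equal(m$taxa, c("taxA", "taxB", "taxC"))
  expect_equal(unname(m$cells["taxB", 3]), "{01}")
  expect_equal(unname(m$cells["taxB", 4]), "?")
  expect_equal(unname(m$cells["taxC", 1]), "-")
  expect_equal(m$ordered, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(m$symbols, c("0", "1", "2"))
})

test_that("matrices round-trip through both dialects", {
  path <- withr::local_tempfile(fileext = ".nex")
  m <- read_matrix(toy_nexus(path))
  out_nex <- withr::local_tempfile(fileext = ".nex")
  write_matrix(m, out_nex, "nexus")
  m_nex <- read_matrix(out_nex)
  expect_equal(m_nex$cells, m$cells)
  expect_equal(m_nex$ordered, m$ordered)

  out_tnt <- withr::local_tempfile(fileext = ".tnt")
  write_matrix(m, out_tnt, "tnt")
  m_tnt <- read_matrix(out_tnt)
  expect_equal(unname(m_tnt$cells), unname(m$cells))
  expect_equal(m_tnt$ordered, m$ordered)
  expect_equal(m_tnt$taxa, m$taxa)
})

test_that("ragged rows are rejected", {
  path <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=3;", "MATRIX",
               "taxA 010", "taxB 01", ";", "END;"), path)
  expect_error(read_matrix(path), "ragged")
})

test_that("the seven new characters carry the published codings", {
  defs <- new_characters_table3()
  expect_equal(vapply(defs, `[[`, integer(1), "index"),
               c(32L, 33L, 62L, 64L, 87L, 88L, 92L))
  sc <- function(i) unname(defs[[i]]$scores)
  expect_equal(sc(7), c("0", "1", "1", "1"))       # processus epipterygoideus
  expect_equal(sc(3), c("0", "-", "-", "1"))       # epipterygoid/trigeminal
  expect_equal(sc(6), c("1", "0", "1", "0"))       # opisthotic participation
})

test_that("insertion shifts columns per the dual numbering and preserves cells", {
  base <- synthetic_base_matrix()
  ins <- insert_characters(base)
  m <- ins$matrix
  expect_equal(dim(m), c(154, 263))
  expect_equal(unname(ins$index_map[74]), 78)
  expect_equal(unname(ins$index_map[18]), 18)
  expect_equal(unname(ins$index_map[250]), 257)
  # every original cell survives under the map
  expect_identical(m$cells[, ins$index_map], base$cells)
  # non-study taxa are missing on the new columns
  expect_true(all(m$cells["taxon_001", c(32, 33, 62, 64, 87, 88, 92)] == "?"))
  expect_equal(unname(m$cells["Desmatochelys_lowii", 92]), "0")
  expect_error(insert_characters(m), "already inserted")
})

test_that("small insertions preserve cells on toy matrices too", {
  toy <- character_matrix(matrix(c("0", "1", "1", "0", "0", "1"), 2,
                                 dimnames = list(c("tA", "tB"), NULL)))
  ins <- insert_characters(toy, list(list(index = 2L, label = "new_one",
                                          ordered = TRUE,
                                          scores = c(tA = "1"))))
  expect_equal(dim(ins$matrix), c(2, 4))
  expect_identical(ins$matrix$cells[, ins$index_map], toy$cells)
  expect_equal(unname(ins$matrix$cells[, 2]), c("1", "?"))
  expect_true(ins$matrix$ordered[2])
})

test_that("the recoding patch applies exactly once, guarded by old states", {
  m <- insert_characters(synthetic_base_matrix())$matrix
  patch <- dlowii_recoding_patch()
  expect_equal(nrow(patch), 10)
  before <- m$cells["Desmatochelys_lowii", patch$index]
  expect_equal(unname(before), patch$old)
  m2 <- apply_recoding_patch(m)
  expect_equal(unname(m2$cells["Desmatochelys_lowii", patch$index]), patch$new)
  expect_equal(unname(m2$cells["Desmatochelys_lowii", 18]), "0")
  expect_equal(unname(m2$cells["Desmatochelys_lowii", 105]), "2")
  # everything else untouched
  untouched <- setdiff(seq_len(263), patch$index)
  expect_identical(m2$cells[, untouched], m$cells[, untouched])
  # double application refuses and changes nothing
  expect_error(apply_recoding_patch(m2), "expected-state mismatch")
})

test_that("ordered flags and taxon deactivation follow the study settings", {
  expect_length(ordered_characters(), 37)
  m <- insert_characters(synthetic_base_matrix())$matrix
  m <- set_ordered(m)
  expect_true(m$ordered[7])
  expect_false(m$ordered[1])
  expect_equal(sum(m$ordered), 37)
  expect_error(set_ordered(m, 999), "out of range")

  drop <- setdiff(m$taxa, c("Odontochelys_semitestacea", "Desmatochelys_lowii",
                            "Eretmochelys_imbricata", "Dermochelys_coriacea",
                            "Chelydra_serpentina"))[1:81]
  m2 <- deactivate_taxa(m, drop)
  expect_equal(sum(m2$active), 73)
  expect_equal(length(m2$taxa), 154)
  expect_equal(length(active_matrix(m2)$taxa), 73)
  expect_error(deactivate_taxa(m, "no_such_taxon"), "unknown taxon")
  expect_equal(sum(deactivate_taxa(m, character(0))$active), 154)
})
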