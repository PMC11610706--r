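test_that("reference topology validates its invariants", {
  ref <- g4_reference()
  expect_s3_class(ref, "g4_reference")
  chars <- strsplit(ref$sequence, "")[[1]]
  expect_true(all(chars[unlist(ref$tetrad_layers)] == "G"))
  expect_error(g4_reference("GGGTGGGTTGGGTGGG"), "17-character")
  expect_error(g4_reference("GGGTGGGTTGGGTGGGX"), "A, C, G, T")
  # a non-G at a tetrad position is an invalid reference
  expect_error(g4_reference("AGGTGGGTTGGGTGGGA"), "must carry G")
})

test_that("enumeration yields 496 unique sequences from 499 raw records", {
  lib <- enumerate_library()
  raw <- enumerate_library(dedup = FALSE)
  expect_equal(nrow(lib), 496L)
  expect_equal(nrow(raw), 499L)
  expect_equal(sum(duplicated(raw$sequence)), 3L)
  expect_false(any(duplicated(lib$sequence)))
  expect_equal(sum(raw$sublibrary == "tetrad"), 256L)
  for (sl in c("loop_17_3", "loop_17_4", "loop_17_10"))
    expect_equal(sum(raw$sublibrary == sl), 81L)
})

test_that("the three duplicates are the reference-loop members of the loop libraries", {
  # independent construction of the expected duplicate strings
  ref <- "GGGTGGGTTGGGTGGGA"
  v17_4 <- ref; substr(v17_4, 2, 2) <- "A"
  v17_10 <- ref; substr(v17_10, 11, 11) <- "A"
  raw <- enumerate_library(dedup = FALSE)
  for (s in c(ref, v17_4, v17_10))
    expect_equal(sum(raw$sequence == s), 2L)
  # merged records keep all sub-library tags and the tetrad id as canonical
  lib <- enumerate_library()
  merged <- lib[grepl(",", lib$sublibrary), ]
  expect_equal(nrow(merged), 3L)
  expect_true(all(grepl("^tet_", merged$seq_id)))
  expect_true(all(grepl("^tetrad,", merged$sublibrary)))
})

test_that("annotation fills mutational-signature fields with 1-based positions", {
  ref <- g4_reference()
  a <- annotate_sequences(ref$sequence)
  expect_equal(a$n_tetrad_mutations, 0L)
  expect_equal(a$tetrad_pattern, "GGGG")
  expect_equal(a$mutated_tetrad_positions, "")

  one <- ref$sequence; substr(one, 2, 2) <- "A"
  a1 <- annotate_sequences(one)
  expect_equal(a1$n_tetrad_mutations, 1L)
  expect_equal(a1$mutated_tetrad_positions, "2")
  expect_equal(a1$tetrad_pattern, "AGGG")

  all4 <- ref$sequence
  for (p in c(2, 6, 11, 15)) substr(all4, p, p) <- "A"
  expect_equal(annotate_sequences(all4)$n_tetrad_mutations, 4L)

  expect_error(annotate_sequences("GGGT"), "length must be 17")
  expect_error(annotate_sequences("GGGTGGGTTGGGTGGGZ"), "alphabet")
})

test_that("mutation-count partition matches the library design", {
  lib <- enumerate_library()
  counts <- vapply(list(0, 1, 2, c(3, 4)), function(k)
    count_by_tetrad_mutations(lib, k), numeric(1))
  expect_equal(counts, c(81, 172, 54, 189))
  expect_equal(sum(counts), 496)
  # closed form for two mutations within the tetrad sub-library:
  # choose(4,2) position pairs x 3^2 non-G substitutions
  expect_equal(counts[3], choose(4, 2) * 3^2)
})

test_that("IUPAC tetrad pattern matching selects the documented sets", {
  lib <- enumerate_library()
  expect_equal(nrow(match_tetrad_pattern(lib, c("NAAA", "AAAN"))), 7L)
  expect_equal(nrow(match_tetrad_pattern(lib, "GGGG")),
               count_by_tetrad_mutations(lib, 0))
  tet <- lib[grepl("tetrad", lib$sublibrary), ]
  expect_equal(nrow(match_tetrad_pattern(tet, "YYYY")), 2L^4)
  expect_error(match_tetrad_pattern(lib, "GGQ G"), "pattern error")
  expect_error(match_tetrad_pattern(lib, "GGG"), "4 characters")
})

test_that("rule classifier follows the three mutational rules", {
  lib <- assign_rule_class(enumerate_library())

  # both halves intact <=> Class 17.3 (biconditional)
  expect_true(all(lib$class[lib$tetrad_pattern == "GGGG"] == "17.3"))
  expect_true(all(lib$tetrad_pattern[lib$class == "17.3"] == "GGGG"))

  # first half intact only -> 17.63; second half intact only -> 17.4 family
  expect_equal(unique(lib$class[lib$tetrad_pattern == "GGAG"]), "17.63")
  fam <- c("17.4", "17.4s26", "17.4+17.4s26")
  expect_true(all(lib$class[lib$tetrad_pattern == "AGGG"] %in% fam))

  # near-complete replacement signatures
  expect_true(all(lib$class[lib$tetrad_pattern == "AAAA"] == "17.180"))
  expect_equal(sum(lib$class == "17.180"), 7L)
  expect_equal(sum(lib$class == "17.28"), 8L)

  # totality and determinism
  expect_false(any(is.na(lib$class)))
  expect_identical(assign_rule_class(enumerate_library())$class, lib$class)
})

test_that("17.4 loop library splits by adenosine count at positions 4, 8, 9", {
  lib <- assign_rule_class(enumerate_library())
  l4 <- lib[grepl("loop_17_4", lib$sublibrary), ]
  expect_equal(nrow(l4), 81L)
  expect_true(all(l4$class[l4$n_loop_adenosines_489 <= 1] == "17.4s26"))
  expect_true(all(l4$class[l4$n_loop_adenosines_489 >= 2] == "17.4"))
  # overlap bands carry the mixed class as recorded alternative
  mid <- l4[l4$n_loop_adenosines_489 %in% 1:2, ]
  expect_true(all(mid$ambiguous_alternatives == "17.4+17.4s26"))
})

test_that("HGGH/TGGT ambiguity is recorded, not dropped", {
  lib <- assign_rule_class(enumerate_library())
  hggh <- lib[lib$class == "17.28", ]
  expect_true(all(hggh$ambiguous_alternatives == "17.36"))
  expect_true(all(lib$class[lib$tetrad_pattern == "TGGT"] == "17.36"))
  # config switch keeps TGGT with the HGGH group
  lib2 <- assign_rule_class(enumerate_library(), tggt_to_17_36 = FALSE)
  expect_true(all(lib2$class[lib2$tetrad_pattern == "TGGT"] == "17.28"))
  expect_equal(sum(lib2$class == "17.28"), 9L)
})

test_that("remaining heavily mutated sequences fall into the catch-alls", {
  lib <- assign_rule_class(enumerate_library())
  rest <- lib[!lib$class %in% c("17.3", "17.63", "17.4", "17.4s26",
                                "17.4+17.4s26", "17.49", "17.28", "17.36",
                                "17.180", "17.154"), ]
  expect_true(all(rest$class %in% c("no_pattern", "no_G4_signals")))
  expect_true(all(rest$n_tetrad_mutations[rest$class == "no_G4_signals"] >= 3))
  expect_true(all(lib$class %in% g4_class_labels()))
})
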