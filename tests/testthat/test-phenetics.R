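pol <- similarity_policy()

test_that("segment similarity follows the two-category depth rule", {
  expect_true(segments_similar(list(spatial = "c", depth = "if"),
                               list(spatial = "c", depth = "im"), pol))
  expect_false(segments_similar(list(spatial = "c", depth = "if"),
                                list(spatial = "c", depth = "is"), pol))
  expect_false(segments_similar(list(spatial = "p", depth = "s"),
                                list(spatial = "o", depth = "s"), pol))
  expect_true(segments_similar(list(spatial = "p", depth = "?"),
                               list(spatial = "p", depth = "is"), pol))
  strict <- similarity_policy(unknown_depth = "exclude_pair")
  expect_true(is.na(segments_similar(list(spatial = "p", depth = "?"),
                                     list(spatial = "p", depth = "is"),
                                     strict)))
})

test_that("whole-contact comparison handles statuses and segment counts", {
  mk <- function(status, sp = character(), d = character()) {
    canonicalize_contact("frontal", "parietal",
                         data.frame(spatial = sp, depth = d), status = status)
  }
  p_im <- mk("present", "p", "im")
  expect_equal(contacts_similar(p_im, p_im, pol), "similar")
  expect_equal(contacts_similar(p_im, mk("absent"), pol), "dissimilar")
  expect_equal(contacts_similar(mk("absent"), mk("absent"), pol),
               "not_comparable")
  expect_equal(contacts_similar(mk("absent"), mk("absent"),
                                similarity_policy(both_absent = "count_similar")),
               "similar")
  expect_equal(contacts_similar(p_im, mk("unknown"), pol), "not_comparable")
  two <- mk("present", c("p", "o"), c("s", "s"))
  one <- mk("present", "p", "s")
  expect_equal(contacts_similar(two, one, pol), "dissimilar")
  other_pair <- canonicalize_contact("jugal", "maxilla",
                                     data.frame(spatial = "p", depth = "s"))
  expect_error(contacts_similar(p_im, other_pair, pol), "different bone pairs")
})

test_that("multiset mode ignores segment order, sequence mode does not", {
  a <- canonicalize_contact("frontal", "parietal",
                            data.frame(spatial = c("p", "o"),
                                       depth = c("s", "im")))
  b <- canonicalize_contact("frontal", "parietal",
                            data.frame(spatial = c("o", "p"),
                                       depth = c("im", "s")))
  expect_equal(contacts_similar(a, b, pol), "dissimilar")
  expect_equal(contacts_similar(a, b, similarity_policy(multi_segment = "multiset")),
               "similar")
})

test_that("pairwise similarity: identity, constructed fraction, exclusions", {
  rows <- rbind(
    segment_row("tA", "frontal", "parietal", 1, "p", "s"),
    segment_row("tA", "frontal", "prefrontal", 1, "o", "im"),
    segment_row("tA", "jugal", "maxilla", 1, "c", "if"),
    segment_row("tA", "maxilla", "premaxilla", 1, "t", "im"),
    segment_row("tA", "nasal", "prefrontal", 1, "p", "s"),
    segment_row("tB", "frontal", "parietal", 1, "p", "if"),
    segment_row("tB", "frontal", "prefrontal", 1, "o", "im"),
    segment_row("tB", "jugal", "maxilla", 1, "c", "im"),
    segment_row("tB", "maxilla", "premaxilla", 1, "o", "im"),
    segment_row("tB", "nasal", "prefrontal", 1, "o", "s"))
  tab <- contact_table(rows)
  # self-similarity is exact
  expect_equal(pairwise_similarity(tab, "tA", "tA", pol)$percent, 100)
  # 4 comparable pairs (nasal excluded), 3 similar: 75%
  res <- pairwise_similarity(tab, "tA", "tB", pol)
  expect_equal(res$n_compared, 4)
  expect_equal(res$n_similar, 3)
  expect_equal(res$percent, 75)
  # symmetric
  expect_equal(pairwise_similarity(tab, "tB", "tA", pol), res)
})

test_that("degenerate comparisons raise, never silently zero", {
  rows <- rbind(status_row("tA", "frontal", "parietal", "unknown"),
                status_row("tB", "frontal", "parietal", "unknown"))
  tab <- contact_table(rows)
  expect_error(pairwise_similarity(tab, "tA", "tB", pol), "no comparable")
  sm <- similarity_matrix(tab)
  expect_true(length(sm$degenerate) == 1)
  expect_true(is.na(sm$percent["tA", "tB"]))
})

test_that("similarity matrix is symmetric, bounded, 100 for identical taxa", {
  set.seed(11)
  rows <- random_contact_rows(8, taxa = c("tA", "tB", "tC"))
  tab <- contact_table(rows)
  sm <- similarity_matrix(tab, pol)
  expect_true(isSymmetric(sm$percent))
  off <- sm$percent[!is.na(sm$percent)]
  expect_true(all(off >= 0 & off <= 100))
  expect_true(all(sm$n_similar[!is.na(sm$n_similar)] <=
                    sm$n_compared[!is.na(sm$n_compared)]))

  dup <- rows[rows$taxon == "tA", ]
  dup$taxon <- "tD"
  tab2 <- contact_table(rbind(rows[rows$taxon == "tA", ], dup))
  sm2 <- similarity_matrix(tab2, pol)
  expect_equal(unname(sm2$percent["tA", "tD"]), 100)
})

test_that("the statistic matches an independent enumeration on small tables", {
  set.seed(23)
  for (i in 1:40) {
    rows <- random_contact_rows(sample(3:6, 1))
    tab <- contact_table(rows)
    for (p in list(pol,
                   similarity_policy(both_absent = "count_similar"),
                   similarity_policy(unknown_depth = "exclude_pair"),
                   similarity_policy(multi_segment = "multiset"))) {
      want <- oracle_similarity(rows, "tA", "tB", p)
      if (want$n_compared == 0) {
        expect_error(pairwise_similarity(tab, "tA", "tB", p))
      } else {
        got <- pairwise_similarity(tab, "tA", "tB", p)
        expect_equal(got$n_compared, want$n_compared)
        expect_equal(got$n_similar, want$n_similar)
        expect_equal(got$percent, want$percent)
      }
    }
  }
})

test_that("raising the depth threshold never lowers similarity", {
  set.seed(31)
  for (i in 1:20) {
    rows <- random_contact_rows(6)
    tab <- contact_table(rows)
    pcts <- vapply(1:4, function(th) {
      p <- similarity_policy(depth_threshold = th)
      tryCatch(pairwise_similarity(tab, "tA", "tB", p)$percent,
               error = function(e) NA_real_)
    }, numeric(1))
    pcts <- pcts[!is.na(pcts)]
    expect_true(all(diff(pcts) >= 0))
  }
})

test_that("excluding a bone never increases the denominator", {
  set.seed(41)
  rows <- random_contact_rows(10)
  tab <- contact_table(rows)
  base <- pairwise_similarity(tab, "tA", "tB",
                              similarity_policy(excluded_bones = character()))
  for (b in unique(c(rows$bone_a, rows$bone_b))) {
    res <- tryCatch(
      pairwise_similarity(tab, "tA", "tB",
                          similarity_policy(excluded_bones = b)),
      error = function(e) list(n_compared = 0))
    expect_lte(res$n_compared, base$n_compared)
  }
})

test_that("rank report sorts by similarity with alphabetical tie-break", {
  rows <- rbind(
    segment_row("tA", "frontal", "parietal", 1, "p", "s"),
    segment_row("tB", "frontal", "parietal", 1, "p", "s"),
    segment_row("tC", "frontal", "parietal", 1, "p", "s"))
  sm <- similarity_matrix(contact_table(rows))
  r <- rank_report(sm, "tB")
  expect_equal(r$taxon, c("tA", "tC"))   # all 100%, alphabetical
  expect_equal(r$percent, c(100, 100))
  expect_error(rank_report(sm, "nope"), "unknown focal")
  two <- similarity_matrix(contact_table(rows[rows$taxon != "tC", ]))
  expect_equal(nrow(rank_report(two, "tA")), 1)
})
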