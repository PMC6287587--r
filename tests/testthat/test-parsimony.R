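test_that("single-character lengths match simple hand cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(char_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(char_length(tr, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_equal(char_length(ape::read.tree(text = "(A,B);"),
                           c(A = "0", B = "2"), ordered = TRUE), 2L)
  expect_equal(char_length(ape::read.tree(text = "(A,B);"),
                           c(A = "0", B = "2"), ordered = FALSE), 1L)
  # missing and polymorphic leaves never force changes
  expect_equal(char_length(tr, c(A = "0", B = "?", C = "0", D = "0")), 0L)
  expect_equal(char_length(tr, c(A = "{01}", B = "1", C = "1", D = "1")), 0L)
  expect_error(char_length(tr, c(A = "0", B = "0", C = "1")), "cover")
})

test_that("lengths equal the exhaustive internal-assignment oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    col <- random_column(tr$tip.label, n_states = sample(3:4, 1))
    for (ord in c(FALSE, TRUE)) {
      expect_equal(char_length(tr, col, ordered = ord),
                   oracle_char_length(tr, col, ordered = ord),
                   info = paste("case", i, "ordered", ord))
    }
  }
})

test_that("unordered lengths agree with phangorn's Fitch on clean columns", {
  set.seed(202)
  for (i in 1:10) {
    n <- 6
    tr <- ape::rtree(n)
    col <- vapply(1:n, function(j) sample(c("0", "1", "2"), 1), character(1))
    names(col) <- tr$tip.label
    pd <- phangorn::phyDat(matrix(col, ncol = 1,
                                  dimnames = list(names(col), NULL)),
                           type = "USER", levels = c("0", "1", "2"))
    expect_equal(char_length(tr, col),
                 as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("length is invariant to rooting and leaf order", {
  set.seed(303)
  tr <- ape::rtree(7)
  col <- random_column(tr$tip.label)
  base <- char_length(tr, col)
  expect_equal(char_length(ape::unroot(tr), col), base)
  for (og in tr$tip.label[1:3]) {
    expect_equal(char_length(ape::root(ape::unroot(tr), og,
                                       resolve.root = TRUE), col), base)
  }
  perm <- sample(names(col))
  expect_equal(char_length(tr, col[perm]), base)
})

test_that("tree_length reports hand-computed CI and RI", {
  # 5 taxa; char 1 clean (m=1, s=1); char 2 homoplastic on this tree:
  # states A,B=0 C,D=1 E=... choose tree ((A,C),(B,D),E) forcing extra steps
  tr <- ape::read.tree(text = "((A,C),(B,D),E);")
  m <- character_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
                              C = c("1", "0"), D = c("1", "1"),
                              E = c("0", "0")))
  rep <- tree_length(tr, m)
  # char1: A,B,E=0, C,D=1 on ((A,C),(B,D),E): s=2, m=1, g(star)=2
  # char2: B,D=1 others 0: s=1, m=1, g=2
  expect_equal(rep$steps, c(2L, 1L))
  expect_equal(rep$min_steps, c(1L, 1L))
  expect_equal(rep$star_steps, c(2L, 2L))
  expect_equal(rep$L, 3L)
  expect_equal(rep$CI, 2 / 3)
  expect_equal(rep$RI, (4 - 3) / (4 - 2))
})

test_that("degenerate and perfect matrices give the stated indices", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  const <- character_matrix(rbind(A = "0", B = "0", C = "0", D = "0"))
  rep <- tree_length(tr, const)
  expect_equal(rep$L, 0L)
  expect_true(is.na(rep$CI) && is.na(rep$RI))

  clean <- character_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
                                  C = c("1", "0"), D = c("1", "1")))
  tr2 <- ape::read.tree(text = "((A,B),(C,D));")
  rep2 <- tree_length(tr2, clean)
  expect_equal(rep2$CI, 1)
})

test_that("sum(m) <= L <= sum(g) across random trees and matrices", {
  set.seed(404)
  for (i in 1:15) {
    tr <- ape::rtree(6)
    cells <- replicate(8, random_column(tr$tip.label))
    m <- character_matrix(cells, taxa = tr$tip.label,
                          ordered = sample(c(TRUE, FALSE), 8, replace = TRUE))
    rep <- tree_length(tr, m)
    expect_lte(sum(rep$min_steps), rep$L)
    expect_lte(rep$L, sum(rep$star_steps))
    if (!is.na(rep$CI)) expect_true(rep$CI >= 0 && rep$CI <= 1)
    if (!is.na(rep$RI)) expect_true(rep$RI >= 0 && rep$RI <= 1)
  }
})

test_that("a missing-only taxon never changes the optimal length", {
  set.seed(505)
  tr <- random_tree(6, 42)
  m <- simulate_character_matrix(tr, n_chars = 10, seed = 7)
  base <- exhaustive_search(m)
  cells2 <- rbind(m$cells, ghost = rep("?", ncol(m$cells)))
  m2 <- character_matrix(cells2, taxa = c(m$taxa, "ghost"))
  expect_equal(exhaustive_search(m2)$length, base$length)
})

test_that("exhaustive search enumerates and finds the global optimum set", {
  m3 <- character_matrix(rbind(A = "0", B = "1", C = "0"))
  expect_equal(length(exhaustive_search(m3)$trees), 1)

  m4 <- character_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  res <- exhaustive_search(m4)
  expect_equal(res$length, 1L)
  expect_equal(length(res$trees), 1)
  expect_equal(oracle_splits(res$trees[[1]]), "A|B")

  big <- character_matrix(matrix("0", 10, 1,
                                 dimnames = list(paste0("t", 1:10), NULL)))
  expect_error(exhaustive_search(big), "limited to 9")
})

test_that("heuristic search is seed-deterministic and recovers clean signal", {
  tr <- random_tree(7, 55)
  m <- simulate_character_matrix(tr, n_chars = 30, rate = 0.15, seed = 9)
  h1 <- heuristic_search(m, n_replicates = 5, seed = 3)
  h2 <- heuristic_search(m, n_replicates = 5, seed = 3)
  expect_identical(h1$newicks, h2$newicks)
  ex <- exhaustive_search(m)
  expect_equal(h1$length, ex$length)

  # zero-homoplasy matrix: search recovers the generating topology at sum(m)
  clean <- character_matrix(rbind(
    A = c("0", "0", "0"), B = c("1", "0", "0"),
    C = c("1", "1", "0"), D = c("1", "1", "1"), E = c("1", "1", "1")))
  res <- heuristic_search(clean, n_replicates = 3, seed = 1)
  rep <- tree_length(res$trees[[1]], clean)
  expect_equal(rep$L, sum(rep$min_steps))
  expect_equal(rep$CI, 1)
})

test_that("constraint checking uses backbone display semantics", {
  cons <- ape::read.tree(text = "((A,B),C);")
  expect_true(satisfies_constraint(ape::read.tree(text = "((A,B),C);"), cons))
  expect_false(satisfies_constraint(
    ape::read.tree(text = "(((A,C),B),(D,E));"),
    ape::read.tree(text = "(((A,B),C),(D,E));")))
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_true(satisfies_constraint(ape::read.tree(text = "(((A,C),B),D);"),
                                   star))
  # floaters attach anywhere
  cons2 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(satisfies_constraint(
    ape::read.tree(text = "(((A,X),B),((C,Y),D));"), cons2))
  expect_false(satisfies_constraint(
    ape::read.tree(text = "(((A,C),B),((X,Y),D));"), cons2))
})

test_that("constrained search only emits constraint-compatible trees", {
  set.seed(606)
  tr <- random_tree(7, 77)
  m <- simulate_character_matrix(tr, n_chars = 15, seed = 13)
  cons <- ape::read.tree(text = paste0("((", tr$tip.label[1], ",",
                                       tr$tip.label[2], "),(",
                                       tr$tip.label[3], ",",
                                       tr$tip.label[4], "));"))
  res <- heuristic_search(m, n_replicates = 4, seed = 5, constraint = cons)
  for (t in res$trees) expect_true(satisfies_constraint(t, cons))
  # constrained optimum can never beat the unconstrained one
  expect_gte(res$length, heuristic_search(m, n_replicates = 4, seed = 5)$length)
  bad <- ape::read.tree(text = "(zz1,zz2,zz3);")
  expect_error(heuristic_search(m, 2, 1, constraint = bad), "not in matrix")
})

test_that("heuristic matches the exhaustive optimum on simulated data", {
  # quick version; the acceptance suite runs 50 replicates at 8 taxa
  hits <- vapply(1:10, function(i) {
    tr <- random_tree(7, 800 + i)
    m <- simulate_character_matrix(tr, n_chars = 12, seed = 900 + i)
    heuristic_search(m, n_replicates = 5, seed = i)$length ==
      exhaustive_search(m)$length
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  expect_equal(oracle_splits(strict_consensus(list(t1, t1))),
               oracle_splits(t1))

  t2 <- ape::read.tree(text = "((A,C),((B,D),(E,F)));")
  cons <- strict_consensus(list(t1, t2))
  expect_equal(oracle_splits(cons), intersect(oracle_splits(t1),
                                              oracle_splits(t2)))

  # trees sharing nothing give the star tree
  t3 <- ape::read.tree(text = "((A,D),((B,F),(C,E)));")
  t4 <- ape::read.tree(text = "((A,E),((B,C),(D,F)));")
  star <- strict_consensus(list(t1, t3, t4))
  expect_equal(length(oracle_splits(star)), 0)

  # several trees differing only in one clade's resolution collapse it
  ta <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  tb <- ape::read.tree(text = "(((A,C),B),((D,E),F));")
  tc <- ape::read.tree(text = "(((B,C),A),((D,E),F));")
  cons2 <- strict_consensus(list(ta, tb, tc))
  expect_setequal(oracle_splits(cons2),
                  c("A|B|C", "A|B|C|F"))
  expect_error(strict_consensus(list(t1, ape::rtree(4))), "leaf sets")
})

test_that("strict consensus agrees with ape's consensus", {
  set.seed(707)
  for (i in 1:5) {
    trees <- lapply(1:4, function(j) ape::rtree(7, tip.label = paste0("t", 1:7)))
    ours <- strict_consensus(trees)
    apes <- ape::consensus(trees, p = 1, rooted = FALSE)
    expect_setequal(oracle_splits(ours), oracle_splits(apes))
  }
})

test_that("pruning removes leaves and suppresses degree-2 nodes", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  p <- prune_taxa(tr, "C")
  expect_setequal(p$tip.label, c("A", "B", "D", "E"))
  expect_equal(oracle_splits(p), "A|B")
  expect_identical(prune_taxa(tr, character(0)), tr)
  expect_error(prune_taxa(tr, c("A", "B", "C")), "fewer than 3")
  expect_error(prune_taxa(tr, "nope"), "not leaves")

  # pruning commutes with restriction: induced splits survive
  set.seed(808)
  big <- ape::rtree(8, tip.label = paste0("t", 1:8))
  keep <- paste0("t", 1:5)
  pruned <- prune_taxa(big, setdiff(big$tip.label, keep))
  restricted <- lapply(oracle_splits(big), function(k) {
    side <- intersect(strsplit(k, "|", fixed = TRUE)[[1]], keep)
    other <- setdiff(keep, side)
    if (length(side) < 2 || length(other) < 2) return(NA_character_)
    a <- paste(sort(side), collapse = "|"); b <- paste(sort(other), collapse = "|")
    if (a < b) a else b
  })
  restricted <- unique(stats::na.omit(unlist(restricted)))
  expect_setequal(oracle_splits(pruned), restricted)
})
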