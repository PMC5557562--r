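# Dataset construction: loading, window extraction, identity filtering,
# splitting and balanced subsets.

test_that("FASTA + site table loading validates sites and drops fragments", {
  fa <- tempfile(fileext = ".fa")
  st <- tempfile(fileext = ".tsv")
  writeLines(c(">p1 test protein", paste0("AAAR", strrep("A", 26)),
               ">p2", strrep("GARG", 10)), fa)
  writeLines(c("protein_id\tposition", "p1\t4", "p2\t3", "p2\t7"), st)
  prot <- read_annotated_proteins(fa, st)
  expect_length(prot, 2L)
  expect_equal(prot[[1]]$methylated_positions, 4L)
  expect_equal(prot[[2]]$methylated_positions, c(3L, 7L))

  # site on a non-R residue is a hard error naming protein and position
  writeLines(c("protein_id\tposition", "p1\t3"), st)
  expect_error(read_annotated_proteins(fa, st), "position 3 of p1 is not R")

  # unknown FASTA id is a hard error
  writeLines(c("protein_id\tposition", "nope\t4"), st)
  expect_error(read_annotated_proteins(fa, st), "nope")

  # proteins shorter than 30 aa are dropped with a warning
  writeLines(c(">short", "AAARAAAAAAAAAAAAAAAAAAAAAAAAA"), fa)  # 29 aa
  writeLines(c("protein_id\tposition", "short\t4"), st)
  expect_warning(res <- read_annotated_proteins(fa, st), "30 aa")
  expect_length(res, 0L)
})

test_that("window extraction is one window per R, X-padded, correctly labeled", {
  # R at position 1 and interior/terminal arginines
  p <- tiny_protein(paste0("RAA", strrep("A", 24), "GRG"), sites = 29L)
  w <- extract_windows(p, 7)
  chars <- strsplit(p[[1]]$sequence, "")[[1]]
  expect_equal(nrow(w), sum(chars == "R"))
  expect_equal(w$peptide[w$center_position == 1], "XXXRAAA")
  expect_equal(w$label[w$center_position == 29], "positive")
  expect_true(all(substring(w$peptide, 4, 4) == "R"))
  # right-terminal padding
  expect_equal(w$peptide[w$center_position == 29], "AAGRGXX")
  expect_error(extract_windows(p, 8), "odd")
})

test_that("windows with nonstandard residues are dropped with a warning", {
  p <- tiny_protein(paste0("ABARAAA", strrep("A", 23)), sites = 4L)
  expect_warning(w <- extract_windows(p, 7), "nonstandard")
  expect_false(any(grepl("B", w$peptide)))
})

test_that("window identity matches its definition and X matches nothing", {
  expect_equal(window_identity("AAAA", "AAAT"), 0.75)
  expect_equal(window_identity("AAAX", "AAAA"), 0.75)
  expect_equal(window_identity("XAAX", "XAAA"), 0.5)  # X-X is not a match
  expect_equal(window_identity("RGRG", "RGRG"), 1.0)
  expect_error(window_identity("AA", "AAA"), "length")
})

test_that("greedy redundancy reduction retains no pair above threshold", {
  # spec's 3-window case: id(w1,w2) >= t, others below
  w1 <- "AAARAAA"; w2 <- "AAARAAG"; w3 <- "GGSRSGG"
  expect_gte(window_identity(w1, w2), 0.4)
  expect_lt(window_identity(w1, w3), 0.4)
  expect_lt(window_identity(w2, w3), 0.4)
  red <- reduce_redundancy(ws_from_peptides(c(w1, w2, w3)), 0.4)
  expect_equal(red$peptide, c(w1, w3))

  # identical windows collapse to one
  red2 <- reduce_redundancy(ws_from_peptides(c(w1, w1)), 0.4)
  expect_equal(nrow(red2), 1L)

  # all-dissimilar sets are untouched
  dis <- ws_from_peptides(c("AAARAAA", "GGGRGGG", "SSSRSSS"))
  expect_equal(nrow(reduce_redundancy(dis, 0.9)), 3L)

  expect_error(reduce_redundancy(dis, 0), "threshold")
  expect_error(reduce_redundancy(dis, 1.2), "threshold")
})

test_that("redundancy reduction agrees with the brute-force greedy oracle", {
  set.seed(11)
  for (rep in 1:40) {
    peps <- random_windows(sample(2:12, 1), 7)
    t <- sample(c(0.3, 0.4, 0.6), 1)
    got <- reduce_redundancy(ws_from_peptides(peps), t)$peptide
    expect_identical(got, peps[oracle_greedy_reduce(peps, t)])
    # exhaustive pairwise check on the retained set
    if (length(got) > 1) {
      for (i in 1:(length(got) - 1)) for (j in (i + 1):length(got)) {
        expect_lt(window_identity(got[i], got[j]), t)
      }
    }
  }
})

test_that("negative derivation removes everything similar to a positive", {
  pos <- ws_from_peptides(c("AAARAAA", "GGGRGGG"), "positive")
  unl <- ws_from_peptides(c("AAARAAA",    # identical to a positive
                            "SSSRSSS",    # dissimilar
                            "AAARGGG"))   # 0.57 identity to first positive
  neg <- derive_negatives(unl, pos, 0.4)
  expect_equal(neg$peptide, "SSSRSSS")
  expect_true(all(neg$label == "negative"))

  # exhaustive cross-check on random sets
  set.seed(12)
  for (rep in 1:20) {
    p <- ws_from_peptides(random_windows(5, 7), "positive")
    u <- ws_from_peptides(random_windows(12, 7))
    neg <- derive_negatives(u, p, 0.4)
    manual <- vapply(u$peptide, function(a) {
      all(vapply(p$peptide, function(b) window_identity(a, b) < 0.4, TRUE))
    }, TRUE)
    expect_identical(neg$peptide, u$peptide[manual])
  }
  expect_error(derive_negatives(ws_from_peptides(random_windows(3, 9)), pos),
               "length")
})

test_that("4:1 split gives round(n/5) tests, equal negative test, reproducibly", {
  set.seed(3)
  pos <- ws_from_peptides(random_windows(100, 7), "positive")
  neg <- ws_from_peptides(random_windows(500, 7), "negative")
  s1 <- split_dataset(pos, neg, seed = 1)
  expect_equal(nrow(s1$test_pos), 20L)
  expect_equal(nrow(s1$train_pos), 80L)
  expect_equal(nrow(s1$test_neg), 20L)
  expect_equal(nrow(s1$train_neg), 480L)
  # disjoint and exhaustive
  expect_setequal(c(s1$train_pos$protein_id, s1$test_pos$protein_id),
                  pos$protein_id)
  expect_length(intersect(s1$train_pos$protein_id, s1$test_pos$protein_id), 0L)
  # determinism
  s2 <- split_dataset(pos, neg, seed = 1)
  expect_identical(s1, s2)
  s3 <- split_dataset(pos, neg, seed = 2)
  expect_false(identical(s1$test_pos$peptide, s3$test_pos$peptide))
  # precondition: too few negatives
  tiny_neg <- ws_from_peptides(random_windows(1, 7), "negative")
  expect_error(split_dataset(ws_from_peptides(random_windows(5, 7), "positive"),
                             tiny_neg, seed = 1), "too few negatives")
})

test_that("negative subsets are balanced, within-subset unique, seeded", {
  set.seed(4)
  pool <- ws_from_peptides(random_windows(400, 7), "negative")
  subs <- make_negative_subsets(pool, 80, k = 5, seed = 7)
  expect_length(subs, 5L)
  for (s in subs) {
    expect_equal(nrow(s), 80L)
    expect_false(any(duplicated(s$protein_id)))  # without replacement
  }
  expect_identical(subs, make_negative_subsets(pool, 80, k = 5, seed = 7))
  # degenerate pool == subset size: identical subsets, message
  small <- ws_from_peptides(random_windows(80, 7), "negative")
  expect_message(deg <- make_negative_subsets(small, 80, k = 3, seed = 1),
                 "identical")
  expect_identical(deg[[1]], deg[[2]])
  expect_error(make_negative_subsets(small, 81, k = 5, seed = 1), "smaller")
})

test_that("window sets round-trip through TSV", {
  w <- ws_from_peptides(random_windows(10, 7))
  path <- tempfile(fileext = ".tsv")
  write_window_set(w, path)
  expect_identical(read_window_set(path), w)
})
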