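test_that("canonicalisation rotates to the anchor and fixes orientation", {
  expect_equal(gene_order(c("cox1", "trnK", "cox2"))$tokens,
               c("cox1", "trnK", "cox2"))
  expect_equal(gene_order(c("trnK", "cox2", "cox1"))$tokens,
               c("cox1", "trnK", "cox2"))
  # minus-strand anchor: reflect (reverse + flip signs), then re-rotate
  expect_equal(gene_order(c("-cox1", "-cox2", "trnK"))$tokens,
               c("cox1", "-trnK", "cox2"))
})

test_that("canonicalisation is idempotent and rotation/reflection invariant", {
  with_seed(11, {
    for (rep in 1:40) {
      n <- sample(4:10, 1)
      go <- random_order(n)
      expect_equal(canonicalize_gene_order(go)$tokens, go$tokens)
      # arbitrary rotation of the raw representation
      k <- sample(n, 1)
      rot <- gene_order(go$tokens[c(k:n, seq_len(k - 1))], canonical = FALSE)
      expect_equal(canonicalize_gene_order(rot)$tokens, go$tokens)
      # reflection = reading the other strand
      refl <- gene_order(rev(ifelse(startsWith(go$tokens, "-"),
                                    sub("^-", "", go$tokens),
                                    paste0("-", go$tokens))),
                         canonical = FALSE)
      expect_equal(canonicalize_gene_order(refl)$tokens, go$tokens)
    }
  })
})

test_that("extract_gene_order sorts, maps strands and canonicalises", {
  feats <- data.frame(
    token = c("cox2", "cox1", "trnK"), kind = c("PCG", "PCG", "tRNA"),
    strand = c(1L, 1L, 1L), start = c(1000L, 0L, 900L),
    end = c(1600L, 800L, 960L), spans_origin = FALSE,
    raw_name = c("cox2", "cox1", "trnK"))
  rec <- mitogenome_record("toy", strrep("A", 2000), feats)
  expect_equal(extract_gene_order(rec)$tokens, c("cox1", "trnK", "cox2"))
  # PCG-only restriction drops the tRNA
  expect_equal(extract_gene_order(rec, "PCG")$tokens, c("cox1", "cox2"))
})

test_that("restriction removes unshared genes and collapses duplicates", {
  o1 <- gene_order(c("a", "b", "c", "d"), "t1")
  o2 <- gene_order(c("a", "c", "d"), "t2")
  res <- suppressMessages(restrict_to_shared_genes(list(t1 = o1, t2 = o2)))
  expect_equal(res$t1$tokens, c("a", "c", "d"))
  expect_equal(res$t2$tokens, c("a", "c", "d"))
  expect_true("b" %in% attr(res, "deletions")$token)

  o3 <- gene_order(c("a", "b", "b", "c"), "t3", canonical = FALSE)
  o4 <- gene_order(c("a", "b", "c"), "t4")
  res2 <- suppressMessages(restrict_to_shared_genes(list(t3 = o3, t4 = o4)))
  expect_equal(res2$t3$tokens, c("a", "b", "c"))
  expect_equal(res2$t4$tokens, c("a", "b", "c"))

  # all genes shared: identity
  res3 <- suppressMessages(restrict_to_shared_genes(list(t4 = o4, t5 = o4)))
  expect_equal(res3$t4$tokens, o4$tokens)

  expect_error(restrict_to_shared_genes(list(
    gene_order(c("a", "b", "x", "y")), gene_order(c("a", "b", "p", "q")))),
    "fewer than 3")
})

test_that("pattern clustering partitions by exact canonical equality", {
  orders <- list(
    t1 = gene_order(c("a", "b", "c"), "t1"),
    t2 = gene_order(c("b", "c", "a"), "t2"),   # rotation of t1
    t3 = gene_order(c("a", "c", "b"), "t3"))
  pats <- cluster_patterns(orders, reference = NULL)
  expect_equal(sort(pats$count), c(1L, 2L))
  expect_equal(sum(pats$count), 3L)

  same <- cluster_patterns(list(x = orders$t1, y = orders$t2), reference = NULL)
  expect_equal(nrow(same), 1L)
  expect_equal(same$count, 2L)

  distinct <- cluster_patterns(list(x = orders$t1, z = orders$t3),
                               reference = NULL)
  expect_equal(nrow(distinct), 2L)
})

test_that("the ground-pattern cluster is labelled Gr, others by prefix", {
  gp <- ground_pattern()
  derived <- apply_event(gp, event_r(5, 8))
  orders <- list(A = gp, B = gp, C = derived)
  orders <- lapply(orders, function(g) g)
  pm <- c(A = "An", B = "An", C = "An")
  pats <- cluster_patterns(orders, prefix_map = pm)
  expect_setequal(pats$pattern_id, c("Gr", "An1"))
  expect_equal(pats$count[pats$pattern_id == "Gr"], 2L)
})

test_that("breakpoint distance matches hand-enumerated adjacency sets", {
  a <- gene_order(c("a", "b", "c", "d", "e"))
  expect_equal(breakpoint_distance(a, a), 0)
  expect_equal(breakpoint_distance(
    a, gene_order(c("a", "c", "b", "d", "e"))), 3)
  expect_equal(breakpoint_distance(
    a, gene_order(c("a", "-c", "-b", "d", "e"))), 2)
  expect_error(breakpoint_distance(a, gene_order(c("a", "b", "c"))),
               "restrict_to_shared_genes")
})

test_that("breakpoint distance is a metric on random orders", {
  with_seed(21, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      base <- sort(letters[1:n])
      mk <- function() {
        toks <- sample(base)
        sg <- sample(c("", "-"), n, replace = TRUE)
        gene_order(paste0(sg, toks))
      }
      x <- mk(); y <- mk(); z <- mk()
      dxy <- breakpoint_distance(x, y)
      expect_equal(dxy, breakpoint_distance(y, x))
      expect_equal(breakpoint_distance(x, x), 0)
      if (dxy == 0) expect_true(go_equal(x, y))
      expect_lte(dxy, breakpoint_distance(x, z) + breakpoint_distance(z, y))
    }
  })
})

test_that("one reversal shifts breakpoints by 2, one transposition by 3", {
  with_seed(31, {
    for (rep in 1:20) {
      n <- sample(6:10, 1)
      go <- random_order(n)
      i <- sample(2:(n - 1), 1)
      len <- sample(1:(n - i), 1)
      ev_r <- event_r(i, i + len - 1)
      expect_lte(breakpoint_distance(go, apply_event(go, ev_r)), 2)
      seg <- i:(i + len - 1)
      after <- sample(setdiff(seq_len(n), c(seg, max(i - 1, 1))), 1)
      ev_t <- event_T(i, i + len - 1, after)
      expect_lte(breakpoint_distance(go, apply_event(go, ev_t)), 3)
    }
  })
})

test_that("amiga is the pattern-sharing fraction", {
  orders <- list(
    t1 = gene_order(c("a", "b", "c")), t2 = gene_order(c("b", "c", "a")),
    t3 = gene_order(c("a", "c", "b")), t4 = gene_order(c("-b", "-a", "c")))
  pats <- cluster_patterns(orders, reference = NULL)
  am <- amiga(pats)
  expect_equal(sort(unique(unname(am))), c(0.25, 0.5))
  expect_equal(unname(am[c("t1", "t2")]), c(0.5, 0.5))
  # all identical -> all 1; all distinct over n=5 -> all 0.2
  same <- cluster_patterns(list(a = orders$t1, b = orders$t1, c = orders$t1),
                           reference = NULL)
  expect_true(all(amiga(same) == 1))
  # weighted identity: mean amiga equals sum(size^2)/n^2
  expect_equal(mean(am), sum(pats$count^2) / length(orders)^2)
})
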