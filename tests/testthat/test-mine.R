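test_that("weighted density matches hand-derived values", {
  net <- weighted_network(c("u"), c("v"), 0.37)
  expect_equal(weighted_density(c("u", "v"), net), 1)

  tri <- weighted_network(c("a", "a", "b"), c("b", "c", "c"),
                          c(0.5, 0.5, 1.0))
  expect_equal(weighted_density(c("a", "b", "c"), tri), (2 * 2.0) / (1.0 * 6))

  # complete graph, equal weights -> density 1
  k4 <- t(combn(c("a", "b", "c", "d"), 2))
  net4 <- weighted_network(k4[, 1], k4[, 2], rep(0.3, 6))
  expect_equal(weighted_density(c("a", "b", "c", "d"), net4), 1)

  # degenerate inputs cohere to 0
  expect_equal(weighted_density("a", tri), 0)
  expect_equal(weighted_density(character(0), tri), 0)
  disj <- weighted_network(c("a", "c"), c("b", "d"), c(1, 1))
  expect_equal(weighted_density(c("a", "d"), disj), 0)
})

test_that("weighted density and matching score agree with brute force on
           every subset / pair of small random instances", {
  set.seed(202)
  ids <- sprintf("N%02d", 1:8)
  for (rep in 1:10) {
    fix <- random_network(8, p = 0.45)
    subsets <- unlist(lapply(2:8, function(k) {
      combn(ids, k, simplify = FALSE)
    }), recursive = FALSE)
    for (s in subsets) {
      expect_equal(weighted_density(s, fix$network),
                   oracle_weighted_density(fix$edges, s))
    }
  }
  pool <- letters[1:10]
  for (rep in 1:100) {
    a <- sample(pool, sample(1:6, 1))
    b <- sample(pool, sample(1:6, 1))
    expect_equal(matching_score(a, b), oracle_matching_score(a, b))
    expect_identical(matching_score(a, b), matching_score(b, a))
  }
})

test_that("sub-network weighted degree sums edges into the target set", {
  f <- fig4_fixture()
  expect_equal(swd("D", f$ns, f$network), 0.7)
  expect_equal(swd("D", setdiff(f$ccs, "D"), f$network), 0.2)
  expect_equal(swd("D", character(0), f$network), 0)
  iso <- weighted_network("x", "y", 1)
  expect_equal(swd("zz", c("x", "y"), iso), 0)
  # u itself in the target set contributes nothing
  expect_equal(swd("D", c("D", "E"), f$network), 0.3)
})

test_that("growth accepts the seed's whole neighborhood at WDT 0", {
  star <- weighted_network(rep("s", 4), c("a", "b", "c", "d"),
                           c(0.4, 0.4, 0.4, 0.4))
  cand <- grow_candidate("s", star, mine_params(wdt = 0))
  expect_setequal(cand$members, c("s", "a", "b", "c", "d"))
  expect_equal(cand$seed, "s")
  expect_error(grow_candidate("nope", star), "not in the network")
})

test_that("at WDT 1 only the heaviest first neighbor joins the seed", {
  star <- weighted_network(rep("s", 3), c("x", "y", "z"), c(0.9, 0.5, 0.3))
  cand <- grow_candidate("s", star, mine_params(wdt = 1))
  expect_setequal(cand$members, c("s", "x"))
  expect_equal(cand$wd, 1)
})

test_that("growth follows the hand-traced greedy insertion", {
  # seed s; neighbors by weight: a (1.0), b (0.8), c (0.6), d (0.1); a-b 0.9
  net <- weighted_network(c("s", "s", "s", "s", "a"),
                          c("a", "b", "c", "d", "b"),
                          c(1.0, 0.8, 0.6, 0.1, 0.9))
  cand <- grow_candidate("s", net, mine_params(wdt = 0.5))
  # {s,a}: WD 1; +b: 5.4/6 = 0.9; +c: 6.6/12 = 0.55; +d: 6.8/20 = 0.34 < 0.5
  expect_setequal(cand$members, c("s", "a", "b", "c"))
  expect_equal(cand$wd, 6.6 / 12)
})

test_that("replaying the insertion log never accepts a step below WDT", {
  set.seed(303)
  for (rep in 1:10) {
    fix <- random_network(12, p = 0.3)
    wdt <- sample(c(0.05, 0.3, 0.6), 1)
    for (seed in network_proteins(fix$network)) {
      cand <- grow_candidate(seed, fix$network, mine_params(wdt = wdt))
      inc <- network_neighbors(fix$network, seed)
      order_in <- names(inc)[order(-inc, names(inc))]
      ccs <- seed
      for (v in order_in) {
        if (v %in% cand$members) {
          ccs <- c(ccs, v)
          expect_gte(oracle_weighted_density(fix$edges, ccs), wdt)
        }
      }
      expect_setequal(ccs, cand$members)
    }
  }
})

test_that("coupling-based pruning removes the worked example's node D only", {
  f <- fig4_fixture()
  pruned <- prune_coupling(f$candidate, f$network)
  expect_setequal(pruned$members, c("A", "B", "C"))
  expect_equal(pruned$seed, "A")
})

test_that("pruning keeps isolated candidates and ties intact", {
  # candidate with no outside edges is unchanged
  tri <- weighted_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
  cand <- candidate_complex(c("a", "b", "c"), "a", tri)
  expect_setequal(prune_coupling(cand, tri)$members, c("a", "b", "c"))

  # swd inside == swd outside -> retained (strict inequality)
  net <- weighted_network(c("s", "s", "b"), c("a", "b", "x"),
                          c(0.5, 0.5, 0.5))
  cand2 <- candidate_complex(c("s", "a", "b"), "s", net)
  expect_setequal(prune_coupling(cand2, net)$members, c("s", "a", "b"))

  # the seed is never removed even under high coupling
  net3 <- weighted_network(c("s", "s", "x"), c("a", "x", "a"),
                           c(0.1, 0.9, 0.9))
  cand3 <- candidate_complex(c("s", "a"), "s", net3)
  expect_true("s" %in% prune_coupling(cand3, net3)$members)
})

test_that("pruning iterates to a fixed point with NS recomputed", {
  # chain of weak members: removing the outermost exposes the next
  net <- weighted_network(
    a = c("s", "s", "a", "b", "c", "c"),
    b = c("a", "b", "b", "c", "x", "y"),
    weight = c(1.0, 1.0, 1.0, 0.3, 0.4, 0.4)
  )
  cand <- candidate_complex(c("s", "a", "b", "c"), "s", net)
  pruned <- prune_coupling(cand, net)
  # c: inside 0.3 < outside 0.8 -> removed; then b: inside 2.0 > 0.3 stays
  expect_setequal(pruned$members, c("s", "a", "b"))
})

test_that("matching score handles the documented cases", {
  expect_equal(matching_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(matching_score(c("a", "b"), c("x", "y")), 0)
  expect_equal(matching_score(c("a", "b"), c("b", "c")), 0.25)
  expect_error(matching_score(character(0), "a"), "empty")
})

fake_complex <- function(members, wd, relation = "PPIN") {
  list(members = sort(members), seed = members[1], relation = relation,
       wd = wd)
}

test_that("redundancy filtering discards by size, then density, then name", {
  a <- fake_complex(c("a", "b", "c", "d", "e"), 0.6)
  b <- fake_complex(c("a", "b", "c", "d"), 0.9)
  kept <- redundancy_filter(structure(list(a, b), class = "complex_set"), 0.8)
  expect_length(kept, 1L)  # MS = 16/20 = 0.8 >= 0.8
  expect_setequal(kept[[1]]$members, a$members)  # smaller one discarded

  # strictly below the threshold both survive
  kept2 <- redundancy_filter(structure(list(a, b), class = "complex_set"),
                             0.81)
  expect_length(kept2, 2L)

  # identical complexes collapse to one
  kept3 <- redundancy_filter(structure(list(a, a), class = "complex_set"), 0.8)
  expect_length(kept3, 1L)

  # equal size: lower-density member goes
  c1 <- fake_complex(c("a", "b", "c", "d"), 0.9)
  c2 <- fake_complex(c("a", "b", "c", "x"), 0.4)
  kept4 <- redundancy_filter(structure(list(c2, c1), class = "complex_set"),
                             0.5)
  expect_length(kept4, 1L)
  expect_setequal(kept4[[1]]$members, c1$members)
})

test_that("two disjoint triangles are detected as exactly two complexes", {
  net <- weighted_network(c("a", "a", "b", "x", "x", "y"),
                          c("b", "c", "c", "y", "z", "z"),
                          rep(0.5, 6))
  sc <- mine_complexes(net, mine_params(wdt = 0.05))
  expect_length(sc, 2L)
  got <- lapply(sc, function(x) x$members)
  expect_setequal(got, list(c("a", "b", "c"), c("x", "y", "z")))
})

test_that("an empty network yields an empty complex set", {
  empty <- weighted_network(character(0), character(0), numeric(0))
  sc <- mine_complexes(list(empty), mine_params())
  expect_length(sc, 0L)
  expect_s3_class(sc, "complex_set")
})

test_that("detection is deterministic and independent of edge-list order", {
  set.seed(404)
  fix <- random_network(20, p = 0.25)
  e <- fix$edges
  perm <- sample(nrow(e))
  net_shuffled <- weighted_network(e$a[perm], e$b[perm], e$weight[perm])
  p <- mine_params(wdt = 0.05)
  sc1 <- mine_complexes(fix$network, p)
  sc2 <- mine_complexes(fix$network, p)
  sc3 <- mine_complexes(net_shuffled, p)
  expect_identical(as.data.frame(sc1), as.data.frame(sc2))
  expect_identical(as.data.frame(sc1), as.data.frame(sc3))
})

test_that("output complexes satisfy the structural guarantees", {
  set.seed(505)
  for (rep in 1:5) {
    fix <- random_network(15, p = 0.3)
    params <- mine_params(wdt = 0.05, min_size = 3)
    sc <- mine_complexes(fix$network, params)
    for (cand in sc) {
      expect_gte(length(cand$members), params$min_size)
      expect_gt(cand$wd, 0)
      expect_equal(cand$wd, weighted_density(cand$members, fix$network))
      expect_true(cand$seed %in% cand$members)
    }
    # pairwise overlap below the redundancy threshold
    if (length(sc) > 1) {
      for (i in seq_len(length(sc) - 1)) {
        for (j in seq(i + 1, length(sc))) {
          expect_lt(matching_score(sc[[i]]$members, sc[[j]]$members),
                    params$overlap_threshold)
        }
      }
    }
    # output sorted by size desc, density desc, member tuple
    df <- as.data.frame(sc)
    key <- order(-df$size, -df$weighted_density, df$members)
    expect_equal(key, seq_len(nrow(df)))
  }
})

test_that("the global complex set suppresses subsets across networks", {
  big <- weighted_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1),
                          relation = "PPIN")
  # second network would find {a, b} which is a subset of {a, b, c}
  small <- weighted_network("a", "b", 1, relation = "BPN")
  sc <- mine_complexes(list(big, small), mine_params(wdt = 0.05))
  expect_length(sc, 1L)
  expect_setequal(sc[[1]]$members, c("a", "b", "c"))
  expect_equal(sc[[1]]$relation, "PPIN")
})

test_that("parameter validation rejects out-of-range thresholds", {
  expect_error(mine_params(wdt = 1.5), "\\[0, 1\\]")
  expect_error(mine_params(wdt = -0.1), "\\[0, 1\\]")
  expect_error(mine_params(overlap_threshold = 2), "\\[0, 1\\]")
  expect_error(mine_params(min_size = 0), ">= 1")
})
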