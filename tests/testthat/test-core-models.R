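test_that("validate_model flags family/structure violations by name", {
  # OT node with two parents
  ot_bad <- restriction_dag("OT", c("A", "B", "C"),
                            parents = list(C = c("A", "B")),
                            relation = c(C = "AND"),
                            param = c(A = .5, B = .5, C = .5),
                            validate = FALSE)
  v <- validate_model(ot_bad)
  expect_true(any(grepl("'C'", v) & grepl("parent", v)))

  # CBN with an OR relation
  cbn_bad <- restriction_dag("CBN", c("A", "B", "C"),
                             parents = list(C = c("A", "B")),
                             relation = c(C = "OR"),
                             param = c(A = 1, B = 1, C = 1),
                             validate = FALSE)
  expect_true(any(grepl("OR", validate_model(cbn_bad))))

  # valid MHN with arbitrary finite theta
  expect_length(validate_model(mhn_model(matrix(rnorm(9), 3, 3))), 0L)

  # cycle detection
  cyc <- restriction_dag("CBN", c("A", "B"),
                         parents = list(A = "B", B = "A"),
                         param = c(A = 1, B = 1), validate = FALSE)
  expect_true(any(grepl("cycle", validate_model(cyc))))

  # parameter domains: untimed probabilities must lie in (0,1)
  pbad <- restriction_dag("OT", c("A"), param = c(A = 1.2), validate = FALSE)
  expect_true(any(grepl("probability", validate_model(pbad))))
  rbad <- restriction_dag("CBN", c("A"), param = c(A = -1), validate = FALSE)
  expect_true(any(grepl("rate", validate_model(rbad))))
})

test_that("dependency_satisfied implements AND / OR / XOR / root semantics", {
  mk <- function(rel) restriction_dag("HESBCN", c("A", "B", "C"),
                                      parents = list(C = c("A", "B")),
                                      relation = c(C = rel),
                                      param = c(A = 1, B = 1, C = 1))
  and <- mk("AND"); or <- mk("OR"); xor <- mk("XOR")
  expect_false(dependency_satisfied(and, "C", "A"))
  expect_true(dependency_satisfied(and, "C", c("A", "B")))
  expect_true(dependency_satisfied(or, "C", "A"))
  expect_false(dependency_satisfied(or, "C", character(0)))
  expect_true(dependency_satisfied(xor, "C", "A"))
  expect_false(dependency_satisfied(xor, "C", c("A", "B")))
  # root children are always gainable
  expect_true(dependency_satisfied(and, "A", character(0)))
  expect_error(dependency_satisfied(and, "Z", "A"), "mismatch")
})

test_that("reachable_genotypes matches hand enumeration on worked examples", {
  # CBN AND example: 5 of 8 genotypes
  reach <- reachable_genotypes(cbn_and_example())
  expect_setequal(reach, c(0L, 1L, 2L, 3L, 7L))

  # OT chain root -> A -> B: {B} alone inaccessible
  ot <- restriction_dag("OT", c("A", "B"), parents = list(B = "A"),
                        param = c(A = .8, B = .5))
  expect_setequal(reachable_genotypes(ot), c(0L, 1L, 3L))

  # MHN has no restrictions: all 8 genotypes
  expect_length(reachable_genotypes(mhn_model(matrix(rnorm(9), 3, 3))), 8L)
})

test_that("every reachable genotype has a one-event predecessor in the set", {
  for (k in 1:20) {
    fam <- c("OT", "CBN", "OncoBN", "HESBCN", "MHN")[(k %% 5) + 1L]
    m <- random_any_model(fam, n = 2L + (k %% 4L), seed = 400 + k)
    reach <- reachable_genotypes(m)
    expect_true(0L %in% reach)
    for (g in setdiff(reach, 0L)) {
      preds <- vapply(seq_along(m$events), function(i) {
        b <- bitwShiftL(1L, i - 1L)
        bitwAnd(g, b) != 0L && bitwAnd(g, bitwNot(b)) %in% reach
      }, logical(1))
      expect_true(any(preds))
    }
  }
})

test_that("BFS reachability equals the static predicate for monotone relations", {
  # SINGLE/AND/OR relations are monotone: a genotype is reachable iff every
  # event's dependency holds within the genotype itself.
  for (k in 1:30) {
    fam <- c("OT", "CBN", "OncoBN")[(k %% 3) + 1L]
    m <- random_dag_model(fam, n = 2L + (k %% 4L), seed = 900 + k,
                          oncobn_form = if (k %% 2) "conjunctive" else "disjunctive")
    expect_identical(sort(reachable_genotypes(m)), static_reachable_masks(m))
  }
})

test_that("XOR reachability is path dependent and BFS is authoritative", {
  xor <- hesbcn_xor_example()
  reach <- reachable_genotypes(xor)
  # {A, B, C} is reachable via A -> C -> B even though C's XOR constraint
  # is violated statically within {A, B, C}
  expect_true(7L %in% reach)
  expect_false(7L %in% static_reachable_masks(xor))
  # but C cannot be gained from {A, B}
  expect_false(dependency_satisfied(xor, "C", c("A", "B")))
})

test_that("genotype labels and masks round-trip in canonical order", {
  ev <- c("A", "B", "C")
  expect_identical(genotype_label(0L, ev), "WT")
  expect_identical(genotype_label(5L, ev), "A, C")
  expect_identical(genotype_mask(c("A", "C"), ev), 5L)
  d <- genotype_distribution(ev, c(7L, 0L, 1L), c(.2, .5, .3))
  expect_identical(d$genotype, c("WT", "A", "A, B, C"))
  expect_error(genotype_mask("Z", ev), "unknown event")
})
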