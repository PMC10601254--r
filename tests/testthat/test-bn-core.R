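test_that("fit_cpt applies the additive-smoothing formula", {
  # parentless child, counts 30/70, no smoothing -> empirical frequencies
  d <- counts_to_df(list("0" = 30, "1" = 70), "x")
  cpt <- fit_cpt(d, "x", smoothing = 0)
  expect_equal(as.vector(cpt$prob), c(0.3, 0.7))

  # binary child, binary parent, counts (p=0: 2 vs 0; p=1: 1 vs 1),
  # smoothing 1 -> p=0 row (3/4, 1/4)
  d2 <- counts_to_df(list("0|0" = 2, "1|0" = 1, "1|1" = 1), c("pa", "ch"))
  cpt2 <- fit_cpt(d2, "ch", "pa", smoothing = 1)
  expect_equal(unname(cpt2$prob[, "0"]), c(3 / 4, 1 / 4))
  expect_equal(unname(cpt2$prob[, "1"]), c(2 / 4, 2 / 4))

  # unseen parent combination under smoothing 1 -> uniform
  d3 <- data.frame(pa = factor(c("0", "0"), levels = c("0", "1")),
                   ch = factor(c("0", "1")))
  cpt3 <- fit_cpt(d3, "ch", "pa", smoothing = 1)
  expect_equal(unname(cpt3$prob[, "1"]), c(0.5, 0.5))

  # unseen parent combination with smoothing 0 -> uniform by convention
  cpt4 <- fit_cpt(d3, "ch", "pa", smoothing = 0)
  expect_equal(unname(cpt4$prob[, "1"]), c(0.5, 0.5))
  expect_error(fit_cpt(d3, "ch", "pa", smoothing = -1), "smoothing")
})

test_that("joint_probability factorizes over the DAG", {
  one <- bn_net(list(make_cpt("X", c("0", "1"), prob = c(0.4, 0.6))))
  expect_equal(joint_probability(one, list(X = "0")), 0.4)

  net <- chain_network()
  # chain A -> B: P(A=1) * P(B=0 | A=1) (C marginalised out by summation)
  expect_equal(
    joint_probability(net, list(A = "1", B = "0", C = "0")) +
      joint_probability(net, list(A = "1", B = "0", C = "1")),
    0.3 * 0.2, tolerance = 1e-12)

  # normalization over all full assignments
  jt <- oracle_joint_table(net)
  total <- sum(vapply(seq_len(nrow(jt)), function(r) {
    joint_probability(net, as.list(jt[r, c("A", "B", "C")]))
  }, 0))
  expect_equal(total, 1, tolerance = 1e-9)

  expect_error(joint_probability(net, list(A = "1", B = "0")), "C")
})

test_that("mutual information matches direct formula evaluation", {
  # identical balanced binary variables -> 1 bit
  d <- counts_to_df(list("0|0" = 50, "1|1" = 50), c("x", "y"))
  expect_equal(mutual_information(d, "x", "y"), 1)

  # independence by construction (product counts) -> 0
  d0 <- counts_to_df(list("0|0" = 12, "0|1" = 36, "1|0" = 8, "1|1" = 24),
                     c("x", "y"))
  expect_equal(mutual_information(d0, "x", "y"), 0, tolerance = 1e-12)

  # arbitrary 2x2 counts vs brute-force summation
  d1 <- counts_to_df(list("0|0" = 4, "0|1" = 1, "1|0" = 1, "1|1" = 4),
                     c("x", "y"))
  expect_equal(mutual_information(d1, "x", "y"),
               oracle_mi(matrix(c(4, 1, 1, 4), 2)), tolerance = 1e-12)
  expect_error(mutual_information(d1[0, ], "x", "y"), "empty")
})

test_that("conditional mutual information matches the triple summation", {
  # xi independent of xj within each class -> 0
  d0 <- counts_to_df(list(
    "0|0|0" = 9, "0|1|0" = 3, "1|0|0" = 3, "1|1|0" = 1,
    "0|0|1" = 2, "0|1|1" = 4, "1|0|1" = 2, "1|1|1" = 4),
    c("xi", "xj", "c"))
  expect_equal(conditional_mutual_information(d0, "xi", "xj", "c"), 0,
               tolerance = 1e-12)

  # xi identical to xj, balanced within each class -> 1 bit
  d1 <- counts_to_df(list("0|0|0" = 10, "1|1|0" = 10,
                          "0|0|1" = 25, "1|1|1" = 25), c("xi", "xj", "c"))
  expect_equal(conditional_mutual_information(d1, "xi", "xj", "c"), 1)

  # arbitrary 2x2x2 cube vs brute-force oracle
  cnt <- array(c(5, 2, 1, 7, 3, 6, 4, 2), c(2, 2, 2))
  keys <- expand.grid(xi = 0:1, xj = 0:1, c = 0:1)
  lst <- stats::setNames(as.list(as.vector(cnt)),
                         apply(keys, 1, paste, collapse = "|"))
  d2 <- counts_to_df(lst, c("xi", "xj", "c"))
  expect_equal(conditional_mutual_information(d2, "xi", "xj", "c"),
               oracle_cmi(cnt), tolerance = 1e-12)
})

test_that("MI and CMI are non-negative and symmetric in the feature pair", {
  set.seed(42)
  for (i in 1:10) {
    d <- data.frame(x = factor(sample(0:2, 60, replace = TRUE)),
                    y = factor(sample(0:1, 60, replace = TRUE)),
                    c = factor(sample(0:1, 60, replace = TRUE)))
    expect_gte(mutual_information(d, "x", "y"), 0)
    expect_equal(mutual_information(d, "x", "y"),
                 mutual_information(d, "y", "x"), tolerance = 1e-12)
    expect_gte(conditional_mutual_information(d, "x", "y", "c"), 0)
    expect_equal(conditional_mutual_information(d, "x", "y", "c"),
                 conditional_mutual_information(d, "y", "x", "c"),
                 tolerance = 1e-12)
  }
})

test_that("class_posterior equals the enumeration oracle", {
  # symmetric model -> uniform posterior
  sym <- manual_classifier(
    "Y", c("0", "1"), "X", list(X = "Y"),
    list(make_cpt("Y", c("0", "1"), prob = c(0.5, 0.5)),
         make_cpt("X", c("0", "1"), "Y", list(Y = c("0", "1")),
                  prob = c(0.7, 0.3, 0.7, 0.3))))
  expect_equal(unname(class_posterior(sym, list(X = "0"))), c(0.5, 0.5))

  # hand-set 2-attribute naive Bayes vs brute-force Bayes table
  set.seed(7)
  nb <- random_classifier(2, "nb")
  for (x1 in c("0", "1")) for (x2 in c("0", "1")) {
    ev <- list(X1 = x1, X2 = x2)
    expect_equal(class_posterior(nb, ev), oracle_posterior(nb, ev),
                 tolerance = 1e-9)
  }

  # 3-attribute tree-augmented model, all 8 evidence patterns
  tan <- random_classifier(3, "tan")
  grid <- expand.grid(X1 = c("0", "1"), X2 = c("0", "1"), X3 = c("0", "1"),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    ev <- as.list(grid[r, ])
    expect_equal(class_posterior(tan, ev), oracle_posterior(tan, ev),
                 tolerance = 1e-9)
  }

  expect_error(class_posterior(nb, list(X1 = "0")), "X2")
})

test_that("markov_blanket applies parents + children + co-parents", {
  iso <- bn_dag(c("A", "B"), list(B = character(0)))
  expect_length(markov_blanket(iso, "A"), 0)

  v <- bn_dag(c("A", "B", "C"), list(C = c("A", "B")))
  expect_setequal(markov_blanket(v, "A"), c("B", "C"))

  chain <- bn_dag(c("A", "B", "C"), list(B = "A", C = "B"))
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  expect_error(markov_blanket(chain, "Z"), "unknown")
})

test_that("query_cpt returns stored rows and validates the parent set", {
  net <- chain_network()
  expect_equal(unname(query_cpt(net, "A")), c(0.7, 0.3))
  expect_equal(unname(query_cpt(net, "B", list(A = "1"))), c(0.2, 0.8))

  # round-trip with fit_cpt
  d <- counts_to_df(list("0|0" = 2, "1|0" = 1, "1|1" = 1), c("pa", "ch"))
  cpt <- fit_cpt(d, "ch", "pa", smoothing = 1)
  m <- bn_net(list(fit_cpt(d, "pa", smoothing = 1), cpt))
  expect_equal(unname(query_cpt(m, "ch", list(pa = "0"))), c(3 / 4, 1 / 4))

  expect_error(query_cpt(net, "B", list(C = "1")), "exactly")
  expect_error(query_cpt(net, "B", list(A = "9")), "unknown state")

  # a fitted classifier row sums to 1 (jaundice given outcome + fluid)
  cohort <- sample_cohort(default_ground_truth(), 500, seed = 21)
  fit <- bnc(np ~ ., cohort, method = "tan")
  pa <- fit$dag$parents[["nnj"]]
  row <- query_cpt(fit, "nnj",
                   stats::setNames(as.list(rep("1", length(pa))), pa))
  expect_equal(sum(row), 1, tolerance = 1e-9)
})
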