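test_that("naive Bayes posterior matches a hand Bayes-rule computation", {
  # one binary attribute, hand-countable table, smoothing 0
  d <- counts_to_df(list("0|0" = 30, "1|0" = 10, "0|1" = 20, "1|1" = 40),
                    c("x", "y"))
  fit <- bnc(y ~ x, d, method = "nb", smoothing = 0)
  # P(y=0)=0.4, P(y=1)=0.6; P(x=0|y=0)=30/40, P(x=0|y=1)=20/60
  post0 <- 0.4 * (30 / 40) / (0.4 * (30 / 40) + 0.6 * (20 / 60))
  expect_equal(unname(class_posterior(fit, list(x = "0"))),
               c(post0, 1 - post0), tolerance = 1e-12)
  expect_identical(as.character(predict(fit, data.frame(x = "0"))), "0")

  # constant attributes are uninformative: posterior equals the class prior
  dc <- data.frame(y = factor(c(0, 0, 0, 1, 1)),
                   x = factor(rep("a", 5)), z = factor(rep("b", 5)))
  fitc <- bnc(y ~ x + z, dc, method = "nb", smoothing = 1)
  expect_equal(unname(class_posterior(fitc, list(x = "a", z = "b"))),
               unname(fitc$class_prior), tolerance = 1e-12)
})

test_that("formula interface validates inputs", {
  d <- sample_cohort(default_ground_truth(), 100, seed = 1)
  expect_error(bnc(np ~ np + ptb, d, method = "nb"), "class variable")
  expect_error(bnc(np ~ ptb, d, method = "tan"), "two attributes")
  expect_error(bnc(np ~ ptb + prom, d, method = "kdb", k = 5), "k must")
  expect_error(bnc(np ~ nope, d, method = "nb"), "unknown attribute")
})

test_that("structural contracts hold for all three variants", {
  d <- sample_cohort(default_ground_truth(), 600, seed = 9)
  attrs <- setdiff(names(d), "np")

  fit_nb <- bnc(np ~ ., d, method = "nb")
  for (a in attrs) expect_identical(fit_nb$dag$parents[[a]], "np")

  fit_tan <- bnc(np ~ ., d, method = "tan")
  n_aa <- 0L
  for (a in attrs) {
    pa <- fit_tan$dag$parents[[a]]
    expect_true("np" %in% pa)
    expect_lte(length(pa), 2)
    n_aa <- n_aa + length(setdiff(pa, "np"))
  }
  expect_identical(n_aa, length(attrs) - 1L) # spanning tree: n - 1 edges
  expect_true(is_acyclic(fit_tan$dag))

  for (k in c(0, 2, 3)) {
    fit_k <- bnc(np ~ ., d, method = "kdb", k = k)
    ord <- setdiff(fit_k$dag$nodes, "np")
    for (i in seq_along(ord)) {
      pa <- setdiff(fit_k$dag$parents[[ord[i]]], "np")
      expect_identical(length(pa), as.integer(min(i - 1, k)))
      expect_true(all(pa %in% ord[seq_len(i - 1)]))
    }
    n_arcs <- sum(lengths(fit_k$dag$parents)) - length(attrs)
    expect_identical(n_arcs, as.integer(count_dependencies(length(attrs), k)))
    expect_true(is_acyclic(fit_k$dag))
  }
})

test_that("kdb with k = 0 is structurally identical to naive Bayes", {
  d <- sample_cohort(default_ground_truth(), 500, seed = 13)
  fit_nb <- bnc(np ~ ., d, method = "nb")
  fit_k0 <- bnc(np ~ ., d, method = "kdb", k = 0)
  test <- sample_cohort(default_ground_truth(), 200, seed = 14)
  expect_equal(predict(fit_nb, test, type = "posterior"),
               predict(fit_k0, test, type = "posterior"), tolerance = 1e-12)
})

test_that("two-attribute TAN uses the single possible edge", {
  d <- sample_cohort(default_ground_truth(), 300, seed = 2)
  fit <- bnc(np ~ ptb + prom, d, method = "tan")
  aa <- c(setdiff(fit$dag$parents$ptb, "np"),
          setdiff(fit$dag$parents$prom, "np"))
  expect_identical(aa, "ptb") # root is one of them, edge joins the pair
})

test_that("greedy spanning tree maximises total weight (brute force)", {
  set.seed(77)
  for (n in c(4, 5)) {
    for (rep in 1:10) {
      w <- matrix(0, n, n, dimnames = list(paste0("X", 1:n), paste0("X", 1:n)))
      w[upper.tri(w)] <- runif(n * (n - 1) / 2)
      w <- w + t(w)
      tree <- pneumonet:::mwst_kruskal(w)
      ora <- oracle_mwst(w)
      expect_equal(sum(w[tree]), ora$weight, tolerance = 1e-12)
      tree_sorted <- tree[order(tree[, 1], tree[, 2]), , drop = FALSE]
      expect_identical(unname(tree_sorted), unname(ora$edges))
    }
  }
})

test_that("TAN recovers a generating tree skeleton from data", {
  # ground truth: class-augmented chain X1 -> X2 -> X3 with strong links
  bin <- c("0", "1")
  pl <- stats::plogis
  gt <- bn_net(list(
    make_cpt("Y", bin, prob = c(0.5, 0.5)),
    make_cpt("X1", bin, "Y", list(Y = bin), prob = c(0.8, 0.2, 0.3, 0.7)),
    make_cpt("X2", bin, c("Y", "X1"), list(Y = bin, X1 = bin),
             prob = as.vector(rbind(1 - pl(c(-1.5, -0.7, 1.0, 1.8)),
                                    pl(c(-1.5, -0.7, 1.0, 1.8))))),
    make_cpt("X3", bin, c("Y", "X2"), list(Y = bin, X2 = bin),
             prob = as.vector(rbind(1 - pl(c(-1.6, -0.9, 0.9, 1.6)),
                                    pl(c(-1.6, -0.9, 0.9, 1.6)))))
  ))
  d <- sample_cohort(gt, 5000, seed = 3)
  fit <- bnc(Y ~ X1 + X2 + X3, d, method = "tan")
  skel <- lapply(c("X1", "X2", "X3"), function(a) {
    setdiff(fit$dag$parents[[a]], "Y")
  })
  edges <- sort(unname(unlist(Map(function(a, pa) {
    if (length(pa)) paste(sort(c(a, pa)), collapse = "-")
  }, c("X1", "X2", "X3"), skel))))
  expect_identical(edges, c("X1-X2", "X2-X3"))
})

test_that("kdb parent selection follows the MI / CMI ranking by hand", {
  # three attributes engineered so the rankings are unambiguous:
  # a1 nearly determines y; a2 depends on y and strongly on a1; a3 weakly on y
  d <- counts_to_df(list(
    "0|0|0|0" = 20, "1|0|0|0" = 2, "0|1|1|0" = 3, "1|1|1|0" = 22,
    "0|0|1|1" = 3, "1|0|0|1" = 1, "0|1|0|0" = 2, "1|1|1|1" = 9,
    "0|0|0|1" = 6, "1|1|0|1" = 4), c("y", "a1", "a2", "a3"))
  mi <- vapply(c("a1", "a2", "a3"), function(a) {
    mutual_information(d, a, "y")
  }, 0)
  ord <- names(sort(mi, decreasing = TRUE))
  fit <- bnc(y ~ a1 + a2 + a3, d, method = "kdb", k = 1)
  # hand-executed rule: first attribute gets no attribute parent; each later
  # one gets the single earlier attribute with the highest CMI
  expect_identical(setdiff(fit$dag$parents[[ord[1]]], "y"), character(0))
  cmi21 <- conditional_mutual_information(d, ord[2], ord[1], "y")
  expect_identical(setdiff(fit$dag$parents[[ord[2]]], "y"), ord[1])
  cmi3 <- vapply(ord[1:2], function(a) {
    conditional_mutual_information(d, ord[3], a, "y")
  }, 0)
  expect_identical(setdiff(fit$dag$parents[[ord[3]]], "y"),
                   names(which.max(cmi3)))
})

test_that("count_dependencies evaluates the closed form", {
  expect_identical(count_dependencies(17, 2), 31L)
  expect_identical(count_dependencies(16, 2), 29L)
  expect_identical(count_dependencies(10, 1), 9L) # TAN's n - 1
  expect_identical(count_dependencies(10, 0), 0L)
  expect_identical(count_dependencies(5, 4), 10L) # saturated: n(n-1)/2
  expect_error(count_dependencies(5, 5), "k must")
  expect_error(count_dependencies(5, -1), "k must")
})

test_that("prediction is the posterior argmax with first-level tie-break", {
  sym <- manual_classifier(
    "Y", c("0", "1"), "X", list(X = "Y"),
    list(make_cpt("Y", c("0", "1"), prob = c(0.5, 0.5)),
         make_cpt("X", c("0", "1"), "Y", list(Y = c("0", "1")),
                  prob = c(0.7, 0.3, 0.7, 0.3))))
  expect_identical(as.character(predict(sym, data.frame(X = "0"))), "0")

  set.seed(11)
  for (method in c("nb", "tan", "kdb")) {
    m <- random_classifier(4, method, k = 2)
    grid <- expand.grid(X1 = c("0", "1"), X2 = c("0", "1"), X3 = c("0", "1"),
                        X4 = c("0", "1"), stringsAsFactors = FALSE)
    pred <- predict(m, grid)
    post <- predict(m, grid, type = "posterior")
    for (r in seq_len(nrow(grid))) {
      ora <- oracle_posterior(m, as.list(grid[r, ]))
      expect_equal(unname(post[r, ]), unname(ora), tolerance = 1e-9)
      expect_identical(as.character(pred[r]), names(ora)[which.max(ora)])
    }
  }
  expect_error(predict(sym, data.frame(Z = "0")), "X")
})

test_that("richer structures never fit worse in training log-likelihood", {
  # unsmoothed fits on a complete table: NB <= TAN and KDB(k) <= KDB(k+1)
  net <- kdb2_ground_truth()
  d <- sample_cohort(net, 4000, seed = 19)
  # complete the table: append one record per joint state so no parent
  # configuration is unobserved (the nesting argument needs finite terms)
  grid <- do.call(expand.grid, c(net$levels, stringsAsFactors = FALSE))
  grid <- data.frame(lapply(stats::setNames(names(grid), names(grid)),
                            function(v) factor(grid[[v]], net$levels[[v]])))
  d <- rbind(d, grid[, names(d)])
  stopifnot(nrow(unique(d)) == 2^6)
  ll <- function(method, k = 2) {
    as.numeric(logLik(bnc(Y ~ ., d, method = method, k = k, smoothing = 0),
                      d))
  }
  expect_lte(ll("nb"), ll("tan") + 1e-9)
  expect_lte(ll("kdb", 0), ll("kdb", 1) + 1e-9)
  expect_lte(ll("kdb", 1), ll("kdb", 2) + 1e-9)
  expect_lte(ll("kdb", 2), ll("kdb", 3) + 1e-9)
})

test_that("joint probabilities of fitted classifiers are normalized", {
  d <- sample_cohort(chain_network(), 400, seed = 23)
  names(d) <- c("A", "B", "C")
  for (method in c("nb", "tan", "kdb")) {
    fit <- bnc(A ~ B + C, d, method = method, k = 1)
    grid <- expand.grid(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"),
                        stringsAsFactors = FALSE)
    total <- sum(vapply(seq_len(nrow(grid)), function(r) {
      joint_probability(fit, as.list(grid[r, ]))
    }, 0))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("classifier JSON serialization round-trips predictions", {
  d <- sample_cohort(default_ground_truth(), 300, seed = 31)
  fit <- bnc(np ~ ., d, method = "kdb", k = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_bnc_json(fit, f)
  back <- read_bnc_json(f)
  test <- sample_cohort(default_ground_truth(), 100, seed = 32)
  expect_equal(predict(back, test, type = "posterior"),
               predict(fit, test, type = "posterior"), tolerance = 1e-12)
  expect_identical(back$dag$parents, fit$dag$parents)
  expect_identical(back$method, "kdb")
})
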