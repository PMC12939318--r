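test_that("a single positive edge is a strong activator and nothing else", {
  net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
  dm <- dependency_matrix(net)
  expect_equal(dm["A", "B"], "STRONG_ACTIVATOR")
  expect_equal(dm["B", "A"], "NO_EFFECT")
  expect_equal(dm["A", "A"], "NO_EFFECT")
})

test_that("opposite-sign parallel paths are ambivalent", {
  net <- signed_network(data.frame(source = c("A", "A"), target = c("B", "B"),
                                   sign = c(1, -1)))
  expect_equal(dependency_matrix(net)["A", "B"], "AMBIVALENT")
})

test_that("negative feedback demotes strong to weak along touched paths", {
  dm <- dependency_matrix(feedback_net())
  # the only A->C path is positive and runs through the negative loop B->C-|B
  expect_equal(dm["A", "C"], "WEAK_ACTIVATOR")
  # B depends on itself only through the negative circuit
  expect_equal(dm["B", "B"], "WEAK_INHIBITOR")
  expect_equal(dm["A", "A"], "NO_EFFECT")
})

test_that("negative self-edges make a node its own weak inhibitor", {
  net <- signed_network(data.frame(source = c("A", "A"), target = c("A", "B"),
                                   sign = c(-1, 1)))
  dm <- dependency_matrix(net)
  expect_equal(dm["A", "A"], "WEAK_INHIBITOR")
  # the A->B path touches A, which lies on the negative loop
  expect_equal(dm["A", "B"], "WEAK_ACTIVATOR")
})

test_that("diagonal entries come from circuits, not the identity", {
  # positive two-cycle with no negative loop anywhere: self-dependency is
  # a strong activation
  net <- signed_network(data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = c(1, 1)))
  dm <- dependency_matrix(net)
  expect_equal(dm["A", "A"], "STRONG_ACTIVATOR")
  expect_equal(dm["B", "B"], "STRONG_ACTIVATOR")
})

test_that("inhibitor chains classify by path-sign product", {
  # A -| B -| C: the A->C path is positive
  net <- chain_net(c(-1, -1))
  dm <- dependency_matrix(net)
  expect_equal(dm["A", "C"], "STRONG_ACTIVATOR")
  expect_equal(dm["A", "B"], "STRONG_INHIBITOR")
  expect_equal(dm["B", "C"], "STRONG_INHIBITOR")
})

test_that("edge-sign flip swaps activator and inhibitor classes on chains", {
  for (signs in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    dm <- dependency_matrix(chain_net(signs))
    dm_flip <- dependency_matrix(chain_net(-signs))
    # odd-length paths flip class; A->B and B->C are single edges
    swap <- c(STRONG_ACTIVATOR = "STRONG_INHIBITOR",
              STRONG_INHIBITOR = "STRONG_ACTIVATOR")
    expect_equal(dm_flip["A", "B"], unname(swap[dm["A", "B"]]))
    expect_equal(dm_flip["B", "C"], unname(swap[dm["B", "C"]]))
    # the even-length A->C path keeps its class
    expect_equal(dm_flip["A", "C"], dm["A", "C"])
  }
})

test_that("DAGs admit no weak classes and an all-NO_EFFECT diagonal", {
  set.seed(21)
  for (i in 1:20) {
    n <- 7
    # random DAG: edges only from lower to higher index
    pairs <- expand.grid(s = 1:n, t = 1:n)
    pairs <- pairs[pairs$s < pairs$t, ]
    sel <- pairs[sample(nrow(pairs), 10), ]
    net <- signed_network(data.frame(source = paste0("V", sel$s),
                                     target = paste0("V", sel$t),
                                     sign = sample(c(1L, -1L), 10, replace = TRUE)),
                          nodes = paste0("V", 1:n))
    dm <- dependency_matrix(net)
    expect_true(all(diag(unclass(dm)) == "NO_EFFECT"))
    expect_false(any(dm %in% c("WEAK_ACTIVATOR", "WEAK_INHIBITOR")))
  }
})

test_that("pruned search matches the literal-enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    net <- random_net(sample(3:8, 1), sample(4:14, 1))
    expect_identical(unclass(dependency_matrix(net)),
                     unclass(dependency_matrix_bruteforce(net)))
  }
})

test_that("the oracle refuses networks beyond its guard", {
  net <- gen_network(n_nodes = 15, n_edges = 25, seed = 2)
  expect_error(dependency_matrix_bruteforce(net), "max_nodes")
  expect_silent(dependency_matrix_bruteforce(net, max_nodes = 15))
})

test_that("class counts are exhaustive and sum to n squared", {
  net <- feedback_net()
  counts <- class_counts(dependency_matrix(net))
  expect_named(counts, dependency_classes())
  expect_equal(sum(counts), length(net$nodes)^2)
  lone <- signed_network(data.frame(source = character(), target = character(),
                                    sign = integer()), nodes = "A")
  expect_equal(class_counts(dependency_matrix(lone))[["NO_EFFECT"]], 1L)
})

test_that("dm_delta counts changes over the common node set", {
  net <- feedback_net()
  dm <- dependency_matrix(net)
  # identical matrices: no changes
  d0 <- dm_delta(dm, dm)
  expect_equal(d0$n_changed, 0L)
  expect_equal(sum(d0$transitions), length(net$nodes)^2)
  expect_equal(nrow(d0$strong_changes), 0L)
  # knocking out C removes the negative loop: B->C paths vanish, A->B
  # becomes untouched by any loop
  ko <- knockout(net, "C")
  dko <- dependency_matrix(ko)
  d1 <- dm_delta(dm, dko)
  expect_equal(nrow(d1$pairs), 4L)  # 2 x 2 common pairs
  expect_equal(sum(d1$transitions), 4L)
  expect_equal(d1$pairs$after[d1$pairs$source == "A" & d1$pairs$target == "B"],
               "STRONG_ACTIVATOR")
  sc <- d1$strong_changes
  expect_true(any(sc$source == "A" & sc$target == "B" &
                    sc$before == "WEAK_ACTIVATOR" &
                    sc$after == "STRONG_ACTIVATOR"))
  # nodes absent from the base matrix are an error
  expect_error(dm_delta(dko, dm), "absent")
})

test_that("transition matrix tallies every (before, after) pair", {
  net <- gen_network(n_nodes = 8, n_edges = 18, seed = 13)
  dm <- dependency_matrix(net)
  v <- net$nodes[[2]]
  d <- dm_delta(dm, dependency_matrix(knockout(net, v)))
  expect_equal(sum(d$transitions), 49L)
  expect_equal(sum(d$transitions) - sum(diag(d$transitions)), d$n_changed)
  # strong-change list is exactly the changed pairs ending strong
  ends_strong <- d$pairs$after %in% c("STRONG_ACTIVATOR", "STRONG_INHIBITOR") &
    d$pairs$before != d$pairs$after
  expect_equal(nrow(d$strong_changes), sum(ends_strong))
})

test_that("ko_scenario_report reproduces per-node knockouts", {
  net <- feedback_net()
  rep <- ko_scenario_report(net, c("B", "C"))
  expect_named(rep$scenarios, c("B", "C"))
  expect_equal(sum(rep$full), 9L)
  expect_equal(sum(rep$scenarios$B$counts), 4L)
  direct <- dependency_matrix(knockout(net, "B"))
  expect_equal(rep$scenarios$B$counts, class_counts(direct))
  # deleting an isolated node from an edgeless network: all NO_EFFECT
  bare <- signed_network(data.frame(source = character(), target = character(),
                                    sign = integer()), nodes = c("A", "B"))
  r2 <- ko_scenario_report(bare, "B")
  expect_equal(r2$scenarios$B$counts[["NO_EFFECT"]], 1L)
})

test_that("depmat TSV output labels rows as acting nodes", {
  net <- feedback_net()
  dm <- dependency_matrix(net)
  f <- tempfile()
  write_depmat(dm, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(tab$node, net$nodes)
  expect_equal(tab[tab$node == "A", "C"], "WA")
})
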