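# build a sort outcome directly from a stream and per-droplet labels
events_from_labels <- function(stream, labels, triggered) {
  data.frame(droplet_id = stream$droplet_id, label = labels,
             triggered = triggered)
}

test_that("a perfect classifier with feasible deflection sorts perfectly", {
  st <- quick_stream(300, lam = 0.5, seed = 12)
  truth <- stream_true_class(st)
  ev <- events_from_labels(st, truth, truth == "single")
  out <- virtual_sort(st, ev)
  expect_equal(out$metrics$purity_pct, 100)
  expect_equal(out$metrics$recovery_pct, 100)
  # counts conserved
  expect_equal(out$metrics$counts$target_outlet +
                 out$metrics$counts$waste_outlet, nrow(st))
})

test_that("metrics equal brute-force per-droplet tallies with random confusion", {
  set.seed(51)
  n <- 1e4
  st <- sample_stream(encapsulation_params(lam = 0.5, arrival = "regular"),
                      n, seed = 52)
  truth <- stream_true_class(st)
  conf <- matrix(c(0.92, 0.06, 0.02,
                   0.05, 0.90, 0.05,
                   0.02, 0.28, 0.70), 3, 3, byrow = TRUE,
                 dimnames = list(c("empty", "single", "multi"),
                                 c("empty", "single", "multi")))
  labels <- vapply(truth, function(tc) {
    sample(colnames(conf), 1, prob = conf[tc, ])
  }, "")
  ev <- events_from_labels(st, labels, labels == "single")
  out <- virtual_sort(st, ev)
  m <- out$metrics
  # brute-force counting oracle
  in_t <- labels == "single"
  expect_equal(m$counts$target_outlet, sum(in_t))
  expect_equal(m$purity_pct, 100 * sum(in_t & truth == "single") / sum(in_t))
  expect_equal(m$recovery_pct,
               100 * sum(in_t & truth == "single") / sum(truth == "single"))
  expect_equal(m$enrichment_fold,
               (sum(in_t & truth == "single") / sum(in_t)) /
                 (sum(truth == "single") / n))
  # closed-form composition algebra: expected purity from the confusion
  # matrix and the Poisson class mix
  p_cls <- c(empty = poisson_pmf(0, 0.5), single = poisson_pmf(1, 0.5),
             multi = multi_cell_probability(0.5))
  sel <- conf[, "single"]
  purity_cf <- 100 * p_cls[["single"]] * sel[["single"]] /
    sum(p_cls * sel)
  se <- 100 * sqrt(purity_cf / 100 * (1 - purity_cf / 100) / sum(in_t))
  expect_lt(abs(m$purity_pct - purity_cf), 4 * se)
})

test_that("compositions normalize and enrichment is post over pre", {
  st <- quick_stream(500, lam = 1, seed = 13)
  truth <- stream_true_class(st)
  ev <- events_from_labels(st, truth, truth %in% c("single", "multi"))
  out <- virtual_sort(st, ev)
  m <- sort_metrics(out, target_class = "single")
  expect_equal(sum(m$pre_composition_pct), 100, tolerance = 1e-9)
  expect_equal(sum(m$post_composition_pct), 100, tolerance = 1e-9)
  expect_equal(m$enrichment_fold * m$pre_composition_pct[["single"]],
               m$post_composition_pct[["single"]], tolerance = 1e-9)
})

test_that("deflection infeasibility sends droplets to waste", {
  st <- quick_stream(100, lam = 0.5, seed = 14)
  truth <- stream_true_class(st)
  ev <- events_from_labels(st, truth, truth == "single")
  out <- virtual_sort(st, ev, deflectable = FALSE)
  expect_equal(out$metrics$counts$target_outlet, 0)
  expect_true(is.na(out$metrics$purity_pct))
})

test_that("unmatched event ids raise", {
  st <- quick_stream(10, lam = 0.5, seed = 15)
  ev <- data.frame(droplet_id = c(1, 99), label = c("single", "single"),
                   triggered = c(TRUE, TRUE))
  expect_error(virtual_sort(st, ev), "unmatched")
})

test_that("printed-composition arithmetic reproduces the headline folds", {
  expect_equal(round(enrichment_fold(5.2, 81.7)), 16)
  expect_equal(enrichment_fold(10, 10), 1)
  expect_equal(round(throughput_fold(c(28948, 19875), c(30, 180) * 60)), 9)
  expect_equal(throughput_fold(c(100, 100), c(60, 60)), 1)
})

test_that("throughput comparison matches theory and simulation", {
  tc <- throughput_comparison(c(0.5, 0.05), c(30, 180) * 60, 200,
                              seed = 61)
  expect_lt(tc$rate_hz[2], 10)
  expect_equal(tc$rate_hz[1], 200 * poisson_pmf(1, 0.5), tolerance = 1e-12)
  # simulated counts near expectation (binomial 4-sigma band)
  for (i in 1:2) {
    p1 <- poisson_pmf(1, tc$lam[i])
    n <- 200 * tc$duration_s[i]
    expect_lt(abs(tc$simulated_count[i] - tc$expected_count[i]),
              4 * sqrt(n * p1 * (1 - p1)))
  }
  fold <- attr(tc, "fold_vs_last")
  expect_equal(fold[2], 1)
  expect_gt(fold[1], 4)
})

test_that("gate sweep exposes the purity-recovery trade-off", {
  set.seed(71)
  n <- c(empty = 1200, single = 600, multi = 200)
  amp <- c(rnorm(n[1], 0.21, 0.012), rnorm(n[2], 0.31, 0.015),
           rnorm(n[3], 0.46, 0.02))
  truth <- rep(names(n), n)
  grid <- seq(0.15, 0.55, by = 0.02)
  tr <- gate_tradeoff(amp, truth, grid, grid)
  # widest gate: recovery 100%, purity equals the accepted single share
  wide <- tr[tr$lower_uA == 0.15 & tr$upper_uA == 0.55, ]
  expect_equal(wide$recovery_pct, 100, tolerance = 0.5)
  expect_equal(wide$purity_pct, 100 * n[["single"]] / sum(n),
               tolerance = 1)
  # an interior gate reaches both purity and recovery near 90+
  good <- tr[!is.na(tr$purity_pct) & tr$purity_pct > 90 &
               tr$recovery_pct > 90, ]
  expect_gt(nrow(good), 0)
  expect_true(any(tr$pareto))
  # narrowing the gate from both ends cannot increase recovery
  nested <- lapply(seq(0, 4), function(j) {
    tr[abs(tr$lower_uA - (0.23 + 0.02 * j)) < 1e-9 &
         abs(tr$upper_uA - (0.47 - 0.02 * j)) < 1e-9, ]
  })
  recs <- vapply(nested, function(d) d$recovery_pct, 0)
  expect_true(all(diff(recs) <= 1e-9))
  # degenerate single-class input: purity 100 wherever defined
  tr1 <- gate_tradeoff(rnorm(300, 0.3, 0.01), rep("single", 300),
                       c(0.2, 0.28), c(0.32, 0.4))
  expect_true(all(tr1$purity_pct[!is.na(tr1$purity_pct)] == 100))
})
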