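test_that("extract_dwells finds maximal runs with censor flags", {
  p <- make_ideal(c(0, 0, 0.4, 0.4, 0.4, 0))
  d <- extract_dwells(p)
  expect_equal(nrow(d), 3)
  mid <- d[2, ]
  expect_equal(mid$state, 0.4)
  expect_equal(mid$duration, 0.3)
  expect_equal(mid$prev_state, 0)
  expect_equal(mid$next_state, 0)
  expect_false(mid$left_censored || mid$right_censored)
  expect_true(d$left_censored[1])
  expect_true(d$right_censored[3])

  # all-one-state path: single dwell, both flags censored
  d1 <- extract_dwells(make_ideal(rep(0.7, 12)))
  expect_equal(nrow(d1), 1)
  expect_true(d1$left_censored && d1$right_censored)
})

test_that("dwell durations partition each trace exactly", {
  set.seed(3)
  for (i in 1:5) {
    lab <- sample(c(0, 0.4, 0.7), 60, replace = TRUE)
    d <- extract_dwells(make_ideal(lab))
    expect_equal(sum(d$duration), 6.0, tolerance = 1e-12)
    expect_equal(sum(d$n_frames), 60)
  }
})

test_that("dwell multiset matches ground-truth sojourns", {
  sc <- scheme_dncca()
  cond <- experiment_condition(acquisition_frames = 800)
  d <- generate_dataset(sc, cond, quiet_model(), 12, seed = 13)
  paths <- truth_paths(d)
  est <- extract_dwells_all(paths)
  td <- true_dwells(d)
  # interior partially bound dwells agree within frame discretization
  ei <- est[!est$left_censored & !est$right_censored & est$state == 0.4, ]
  ti <- td[!td$censored & td$state == "P", ]
  expect_equal(nrow(ei), nrow(ti))
  expect_lt(abs(mean(ei$duration) - mean(ti$duration)), 0.1)
})

test_that("exponential lifetime fits recover simulated truth", {
  set.seed(7)
  x <- stats::rexp(1000, 1 / 3.6)
  est <- fit_lifetime(x)
  expect_lt(abs(est$tau - 3.6), 2 * est$se)
  expect_equal(est$n_dwells, 1000)

  # histogram least-squares route agrees roughly
  esth <- fit_lifetime(x, method = "histogram")
  expect_lt(abs(esth$tau - 3.6), 0.5)
})

test_that("censoring-aware MLE beats naive fitting under bleaching", {
  # tau = 20 s with bleach mean 70 s: |bias| < 10 percent, and dropping
  # censored dwells underestimates (directional check)
  set.seed(8)
  n <- 4000
  true_d <- stats::rexp(n, 1 / 20)
  bleach <- stats::rexp(n, 1 / 70)
  obs <- pmin(true_d, bleach)
  cens <- bleach < true_d
  dw <- data.frame(molecule_id = "m", state = 0.4, duration = obs,
                   n_frames = pmax(1, round(obs / 0.1)),
                   prev_state = 0, next_state = 0,
                   left_censored = FALSE, right_censored = cens)
  mle <- fit_lifetime(dw)
  naive <- fit_lifetime(dw, include_censored = FALSE)
  expect_lt(abs(mle$tau - 20) / 20, 0.10)
  expect_lt(naive$tau, mle$tau)
  expect_lt(naive$tau, 20)
})

test_that("double-exponential fits report the weighted lifetime", {
  # printed-parameter formula check
  expect_equal(weighted_average_lifetime(3.9, 0.46, 15.7, 0.54),
               10.272, tolerance = 1e-3)

  # degenerate equal mixture collapses to the common lifetime
  set.seed(9)
  x <- stats::rexp(800, 1 / 5)
  est <- fit_lifetime(x, model = "double")
  expect_equal(est$model, "double")
  expect_lt(abs(est$weighted_tau - 5), 0.6)

  # genuine mixture recovers both components
  set.seed(10)
  x2 <- c(stats::rexp(1500, 1 / 2), stats::rexp(1500, 1 / 15))
  est2 <- fit_lifetime(x2, model = "double")
  expect_lt(abs(est2$components[["t1"]] - 2), 0.5)
  expect_lt(abs(est2$components[["t2"]] - 15), 2.5)
  expect_lt(abs(est2$weighted_tau - 8.5), 1.0)
})

test_that("discretization-corrected MLE fixes frame quantization", {
  set.seed(11)
  ft <- 0.1
  x <- stats::rexp(5000, 1 / 0.25)           # tau comparable to frame
  frames <- pmax(1, ceiling(x / ft))          # quantized observation
  naive <- mean(frames * ft)
  est <- fit_lifetime(frames * ft, discrete = TRUE, frame_time = ft)
  expect_gt(naive, 0.27)                      # quantization inflates
  expect_lt(abs(est$tau - 0.25), 0.02)
})

test_that("fret_histogram locates generative peaks", {
  set.seed(12)
  e1 <- stats::rnorm(4000, 0.7, 0.05)
  h1 <- fret_histogram(e1, n_peaks = 1)
  expect_lt(abs(h1$peaks$center - 0.7), 0.01)

  e2 <- c(stats::rnorm(3000, 0.4, 0.05), stats::rnorm(3000, 0.7, 0.05))
  h2 <- fret_histogram(e2, n_peaks = 2)
  expect_equal(h2$peaks$center, c(0.4, 0.7), tolerance = 0.02)
  expect_lt(abs(h2$peaks$weight[1] - 0.5), 0.05)

  # ligand-free data: single peak at zero
  e0 <- stats::rnorm(2000, 0, 0.05)
  h0 <- fret_histogram(e0, n_peaks = 1)
  expect_lt(abs(h0$peaks$center), 0.01)

  expect_error(fret_histogram(numeric(0)), "no valid frames")
})

test_that("transition density reflects scheme reachability", {
  # two-state data: mass only at (0, 0.4) and (0.4, 0)
  d2 <- extract_dwells_all(list(
    make_ideal(c(0, 0, 0.4, 0.4, 0, 0.4, 0, 0))))
  tdp <- transition_density(d2)
  expect_setequal(paste(tdp$transitions$from, tdp$transitions$to),
                  c("0 0.4", "0.4 0"))
  expect_equal(sum(tdp$counts), sum(tdp$transitions$n))

  # single-dwell traces: empty TDP
  tdp0 <- transition_density(extract_dwells_all(list(
    make_ideal(rep(0.7, 10)), make_ideal(rep(0, 10)))))
  expect_equal(sum(tdp0$counts), 0)

  # branched scheme: only neighbouring and direct 0.2<->0.7 transitions
  sc <- scheme_dkt()
  cond <- experiment_condition(acquisition_frames = 500)
  d <- generate_dataset(sc, cond, quiet_model(), 30, seed = 14)
  dd <- extract_dwells_all(truth_paths(d))
  tdpk <- transition_density(dd)
  pairs <- paste(tdpk$transitions$from, tdpk$transitions$to)
  allowed <- c("0 0.2", "0.2 0", "0.2 0.4", "0.4 0.2", "0.4 0.7",
               "0.7 0.4", "0.2 0.7", "0.7 0.2",
               # sub-frame sojourns can bridge non-adjacent levels
               "0 0.4", "0.4 0", "0 0.7", "0.7 0")
  expect_true(all(pairs %in% allowed))
  n_of <- function(a, b) {
    i <- tdpk$transitions$from == a & tdpk$transitions$to == b
    if (any(i)) sum(tdpk$transitions$n[i]) else 0
  }
  expect_gt(n_of(0.2, 0.4) + n_of(0.4, 0.2), n_of(0.2, 0.7))
})

test_that("trace classification follows the three phenotypes", {
  p1 <- make_ideal(c(0, 0.4, 0.7, 0.7, 0.7))        # I
  p2 <- make_ideal(c(0, 0.7, 0.7, 0.4, 0.7))        # II
  p3 <- make_ideal(c(0, 0.4, 0.4, 0, 0))            # III
  p0 <- make_ideal(rep(0, 6))                       # never bound
  cl <- classify_traces(list(p1, p2, p3, p0))
  expect_equal(cl$n_bound, 3)
  expect_equal(unname(cl$fractions), rep(1 / 3, 3))
  expect_equal(sum(cl$fractions), 1)

  # invariant to trace ordering
  cl2 <- classify_traces(list(p3, p0, p2, p1))
  expect_equal(cl2$fractions, cl$fractions)

  expect_error(classify_traces(list(p0)), "no bound traces")
})

test_that("post-synchronized histograms align at first binding", {
  # deterministic noiseless single trace equals its indicator path
  lab <- c(rep(0, 10), rep(0.4, 3), rep(0.7, 17))
  f <- make_fret(lab)
  p <- make_ideal(lab)
  ps <- postsynchronized_histogram(list(f), list(p), n_frames_out = 20,
                                   fret_bins = 0.1)
  expect_equal(ps$n_traces, 1)
  # first three synced frames in the 0.4 bin, rest in 0.7
  bin_of <- function(v) findInterval(v, ps$fret_breaks,
                                     rightmost.closed = TRUE)
  expect_equal(which(ps$density[1, ] > 0), bin_of(0.4))
  expect_equal(which(ps$density[5, ] > 0), bin_of(0.7))

  # dNCCA-like traces never enter the 0.7 band
  labs2 <- list(c(rep(0, 5), rep(0.4, 20), rep(0, 5)),
                c(rep(0, 12), rep(0.4, 18)))
  ps2 <- postsynchronized_histogram(lapply(labs2, make_fret),
                                    lapply(labs2, make_ideal),
                                    n_frames_out = 15, fret_bins = 0.1)
  high <- ps2$fret_breaks[-length(ps2$fret_breaks)] >= 0.55
  expect_equal(sum(ps2$counts[, high]), 0)

  # no qualifying trace errors
  expect_error(postsynchronized_histogram(
    list(make_fret(rep(0, 10))), list(make_ideal(rep(0, 10)))),
    "no trace")
})

test_that("fast docking reaches the 0.7 band right after binding", {
  sc <- scheme_wt()   # k2 = 10: mean 0.4 sojourn ~ 1 frame
  cond <- experiment_condition(acquisition_frames = 400)
  d <- generate_dataset(sc, cond, quiet_model(), 40, seed = 15)
  paths <- truth_paths(d)
  frets <- lapply(d$traces, function(tr) {
    nbl <- min(400, floor(tr$truth$bleach$donor / 0.1))
    make_fret(tr$truth$frame_fret[seq_len(max(nbl, 1))],
              molecule_id = tr$molecule_id)
  })
  ps <- postsynchronized_histogram(frets, paths, n_frames_out = 10,
                                   fret_bins = 0.1)
  high <- ps$fret_breaks[-length(ps$fret_breaks)] >= 0.55
  # by the third frame after synchronization most mass is fully bound
  expect_gt(sum(ps$density[3, high]), 0.6)
})

test_that("merge_dwell_levels pools bound conformations", {
  p <- make_ideal(c(0, 0.2, 0.4, 0.2, 0.7, 0.4, 0))
  d <- extract_dwells(p)
  m <- merge_dwell_levels(d, c(0.2, 0.4), 0.2)
  expect_equal(m$state, c(0, 0.2, 0.7, 0.2, 0))
  expect_equal(m$duration[2], 0.3)     # three pooled frames
  expect_equal(m$next_state[2], 0.7)
  expect_equal(sum(m$duration), sum(d$duration))
})
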