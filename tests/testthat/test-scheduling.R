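test_that("generate_jobs produces the K_Q x K_D x M farm with routing", {
  reg <- method_registry()   # usm sequential; tm, rmsd parallel
  doms <- dummy_domains(34L, len = 20L)
  jobs <- generate_jobs(doms, doms, reg)
  expect_equal(sum(jobs$routing == "parallel"), 2L * 34L * 34L)   # 2312
  expect_equal(sum(jobs$routing == "sequential"), 34L * 34L)      # 1156
  # self-pairs included
  expect_true(any(jobs$query_id == jobs$db_id))

  one <- generate_jobs(dummy_domains(1L), dummy_domains(1L), reg)
  expect_equal(nrow(one), 3L)

  mm <- generate_jobs(dummy_domains(2L), dummy_domains(3L), reg)
  expect_equal(sum(mm$routing == "parallel"), 12L)
  expect_equal(mm$attr_sum, rep(200L, 18L))
  expect_equal(mm$attr_product, rep(1e4, 18L))
})

test_that("partition_random deals equal-count partitions deterministically", {
  reg <- method_registry(default = FALSE)
  register_method(reg, "m", "distance", "parallel", function(q, d, ctx) 0)
  jobs <- generate_jobs(dummy_domains(47L), dummy_domains(2L), reg)
  expect_equal(nrow(jobs), 94L)
  parts <- partition_random(jobs, 47L, seed = 5L)
  expect_equal(lengths(parts), rep(2L, 47L))
  expect_identical(parts, partition_random(jobs, 47L, seed = 5L))
  expect_false(identical(parts, partition_random(jobs, 47L, seed = 6L)))
  expect_equal(sort(unlist(parts)), seq_len(94L))   # conservation

  tiny <- partition_random(jobs[1:3, ], 5L, seed = 1L)
  expect_equal(sum(lengths(tiny) == 0L), 2L)
  expect_true(max(lengths(tiny)) - min(lengths(tiny)) <= 1L)
})

test_that("greedy LPT matches the hand-worked example and stays within its bound", {
  mkjobs <- function(w) {
    df <- do.call(rbind, lapply(seq_along(w), function(i)
      psc_job(sprintf("q%02d", i), "d", "m", "parallel", 1L, 1L)))
    class(df) <- c("JobList", "data.frame")
    df
  }
  j5 <- mkjobs(1:5)
  parts <- partition_greedy_lpt(j5, 2L, attribute = c(5, 4, 3, 2, 1))
  sums <- vapply(parts, function(ix) sum(c(5, 4, 3, 2, 1)[ix]), numeric(1))
  expect_setequal(sums, c(8, 7))
  expect_equal(max(sums), brute_force_makespan(c(5, 4, 3, 2, 1), 2L))

  eq <- partition_greedy_lpt(mkjobs(rep(2, 8)), 4L, attribute = rep(2, 8))
  expect_equal(vapply(eq, length, integer(1)), rep(2L, 4L))

  single <- partition_greedy_lpt(mkjobs(3), 3L, attribute = 3)
  expect_equal(sum(lengths(single) > 0L), 1L)

  # LPT guarantee on random instances: makespan <= (4/3 - 1/(3N)) * OPT
  set.seed(99)
  for (rep in 1:25) {
    n_jobs <- sample(3:12, 1L); n_w <- sample(2:4, 1L)
    w <- sample(1:50, n_jobs, replace = TRUE)
    parts <- partition_greedy_lpt(mkjobs(w), n_w, attribute = as.numeric(w))
    expect_equal(sort(unlist(parts)), seq_len(n_jobs))   # conservation
    ms <- max(vapply(parts, function(ix) sum(w[ix]), numeric(1)))
    expect_lte(ms, (4 / 3 - 1 / (3 * n_w)) * brute_force_makespan(w, n_w) + 1e-9)
  }
})

test_that("sort_jobs_desc is a stable descending sort", {
  df <- do.call(rbind, lapply(1:3, function(i)
    psc_job(paste0("q", i), "d", "m", "parallel", c(3L, 9L, 1L)[i], 0L)))
  class(df) <- c("JobList", "data.frame")
  sorted <- sort_jobs_desc(df, "sum")
  expect_equal(sorted$attr_sum, c(9L, 3L, 1L))
  resorted <- sort_jobs_desc(sorted, "sum")
  expect_equal(resorted$query_id, sorted$query_id)   # idempotent

  eqdf <- do.call(rbind, lapply(c("z", "a", "m"), function(q)
    psc_job(q, "d", "m", "parallel", 5L, 5L)))
  class(eqdf) <- c("JobList", "data.frame")
  expect_equal(sort_jobs_desc(eqdf, "sum")$query_id, c("z", "a", "m"))  # stability
})

test_that("dispatch_round_robin simulates next-free dispatch", {
  sch <- dispatch_round_robin(4L, 2L, costs = c(4, 3, 2, 1))
  expect_equal(sch$finish_times, c(5, 5))
  expect_equal(sch$makespan, brute_force_makespan(c(4, 3, 2, 1), 2L))
  expect_equal(sch$speedup, 2)
  expect_equal(sch$efficiency, 1)

  one <- dispatch_round_robin(5L, 1L, costs = c(1, 2, 3, 4, 5))
  expect_equal(one$makespan, 15)
  expect_equal(one$speedup, 1)

  bal <- dispatch_round_robin(8L, 4L, costs = rep(2, 8))
  expect_equal(bal$idle, rep(0, 4L))

  expect_error(dispatch_round_robin(4L, 2L, costs = c(1, 2)), "cost count")
})

test_that("simulate_partition_schedule computes makespan / speedup / efficiency", {
  costs <- c(5, 2, 1, 4, 3)
  sch <- simulate_partition_schedule(list(c(1L, 2L, 3L), c(4L, 5L)), costs)
  expect_equal(sch$finish_times, c(8, 7))
  expect_equal(sch$makespan, 8)
  expect_equal(sch$speedup, 15 / 8)
  expect_equal(sch$efficiency, 15 / 16)
  expect_equal(sch$idle, c(0, 1))

  solo <- simulate_partition_schedule(list(seq_len(5L)), costs)
  expect_equal(solo$speedup, 1)
  expect_error(simulate_partition_schedule(list(1:2, 2:3), costs),
               "more than one partition")
})

test_that("execute_parallel is deterministic in the worker count", {
  b <- make_benchmark(n_families = 2L, members_per_family = 3L,
                      n_residues = 30L, seed = 4L)
  reg <- method_registry()
  jobs <- generate_jobs(b$domains, b$domains, reg)
  r1 <- execute_parallel(jobs, reg, domain_store(b$domains), n_workers = 1L)
  r4 <- execute_parallel(jobs, reg, domain_store(b$domains), n_workers = 4L)
  expect_equal(length(r1), nrow(jobs))
  expect_equal(r1, r4)

  # usm-only farm runs entirely in the coordinator
  usm_only <- method_registry(default = FALSE)
  register_method(usm_only, "usm", "distance", "sequential",
    fn = function(q, d, ctx) usm_distance(ctx$cmap(q$id), ctx$cmap(d$id))$value)
  ju <- generate_jobs(b$domains, b$domains, usm_only)
  expect_true(all(ju$routing == "sequential"))
  expect_length(execute_parallel(ju, usm_only, domain_store(b$domains),
                                 n_workers = 4L), nrow(ju))

  # worker failure names the offending job
  boom <- method_registry(default = FALSE)
  register_method(boom, "boom", "distance", "parallel",
    fn = function(q, d, ctx) stop("kaboom"))
  jb <- generate_jobs(b$domains[1:2], b$domains[1:2], boom)
  expect_error(execute_parallel(jb, boom, domain_store(b$domains)),
               "fam01_m01.*boom")
})

test_that("fit_cost_model recovers exact fits and nests residuals", {
  x <- seq(10, 200, by = 10)
  y <- 2 * x^2 + 5
  fit <- fit_cost_model(x, y, "quadratic")
  expect_lte(fit$residual_ss, 1e-6)
  expect_equal(unname(fit$coefficients["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["b"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["c"]), 5, tolerance = 1e-6)
  expect_equal(predict_cost(fit, c(10, 20)), c(205, 805), tolerance = 1e-6)

  set.seed(12)
  for (rep in 1:10) {
    xs <- runif(20, 1, 100)
    ys <- rnorm(20, 3 * xs + xs^1.7, 10)
    expect_lte(fit_cost_model(xs, ys, "quadratic")$residual_ss,
               fit_cost_model(xs, ys, "linear")$residual_ss + 1e-9)
  }

  expect_error(fit_cost_model(rep(5, 10), 1:10, "linear"), "singular")
  expect_error(fit_cost_model(1:2, 1:2, "linear"), "3 observations")
})

test_that("the generating attribute wins model selection on simulated runtimes", {
  doms <- lapply(seq_len(20L), function(i)
    protein_domain(sprintf("p%02d", i), "A",
                   paste(rep("A", 10), collapse = ""),
                   cbind(1:10 * 3.8, 0, 0)))
  # vary the recorded lengths so sum and product decorrelate
  set.seed(31)
  lens <- sample(50:500, 20L)
  reg <- method_registry(default = FALSE)
  register_method(reg, "m", "distance", "parallel", function(q, d, ctx) 0)
  jobs <- generate_jobs(doms, doms, reg)
  jobs$len_q <- lens[match(jobs$query_id, vapply(doms, `[[`, "", "id"))]
  jobs$len_d <- lens[match(jobs$db_id, vapply(doms, `[[`, "", "id"))]
  jobs$attr_sum <- jobs$len_q + jobs$len_d
  jobs$attr_product <- as.numeric(jobs$len_q) * jobs$len_d

  gen <- list(form = "quadratic", attribute = "product",
              coefficients = c(a = 3e-5, b = 0, c = 0.02))
  costs <- simulate_runtimes(jobs, gen, noise_sd = 0.15, seed = 8L)
  rss <- c(product = fit_cost_model(jobs$attr_product, costs, "quadratic")$residual_ss,
           sum = fit_cost_model(jobs$attr_sum, costs, "quadratic")$residual_ss)
  expect_lt(rss[["product"]], rss[["sum"]])

  # noiseless simulated runtimes refit exactly
  clean <- simulate_runtimes(jobs, gen, noise_sd = 0, seed = 1L)
  refit <- fit_cost_model(jobs$attr_product, clean, "quadratic")
  expect_lte(refit$residual_ss, 1e-6)
  expect_equal(unname(refit$coefficients), c(3e-5, 0, 0.02), tolerance = 1e-6)
  expect_identical(simulate_runtimes(jobs, gen, 0.2, seed = 3L),
                   simulate_runtimes(jobs, gen, 0.2, seed = 3L))
})
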