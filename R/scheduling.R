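# Scheduling: the pairwise job farm, partitioning strategies (random,
# greedy LPT, sorted round-robin), schedule simulation and cost-model
# fitting.

#' Construct a single comparison job
#'
#' @param query_id,db_id Domain ids of the pair.
#' @param method Registered method name.
#' @param routing `"sequential"` (run by the coordinator) or `"parallel"`
#'   (run on the worker pool).
#' @param len_q,len_d Domain lengths; `attr_sum` and `attr_product` are the
#'   load-balancing attributes derived from them.
#' @return One-row data frame of class `JobList`.
#' @export
psc_job <- function(query_id, db_id, method, routing, len_q, len_d) {
  routing <- match.arg(routing, c("sequential", "parallel"))
  structure(
    data.frame(query_id = as.character(query_id), db_id = as.character(db_id),
               method = as.character(method), routing = routing,
               len_q = as.integer(len_q), len_d = as.integer(len_d),
               attr_sum = as.integer(len_q) + as.integer(len_d),
               attr_product = as.numeric(len_q) * as.numeric(len_d),
               stringsAsFactors = FALSE),
    class = c("JobList", "data.frame"))
}

#' Generate the pairwise job farm
#'
#' One job per (query, database, method) triple: `K_Q * K_D` jobs for each
#' method, self-pairs included, covering both all-to-all (`Q == D`) and
#' many-to-many comparisons. Methods flagged sequential (the compression
#' distance by default, being orders of magnitude faster) are routed to the
#' coordinating process; the rest form the parallel farm.
#'
#' @param Q,D Lists of [protein_domain()] objects (query and database sets).
#' @param registry A [method_registry()] declaring methods and routing.
#' @return A `JobList` data frame ordered by (method, query, db), parallel
#'   methods first.
#' @export
generate_jobs <- function(Q, D, registry = method_registry()) {
  if (!length(Q) || !length(D)) stop("Q and D must be non-empty")
  if (inherits(Q, "ProteinDomain")) Q <- list(Q)
  if (inherits(D, "ProteinDomain")) D <- list(D)
  qid <- vapply(Q, `[[`, character(1), "id")
  did <- vapply(D, `[[`, character(1), "id")
  qlen <- vapply(Q, `[[`, integer(1), "length")
  dlen <- vapply(D, `[[`, integer(1), "length")
  methods <- c(registry_methods(registry, "parallel"),
               registry_methods(registry, "sequential"))
  out <- do.call(rbind, lapply(methods, function(m) {
    routing <- get_method(registry, m)$routing
    g <- expand.grid(di = seq_along(did), qi = seq_along(qid))
    data.frame(query_id = qid[g$qi], db_id = did[g$di], method = m,
               routing = routing, len_q = qlen[g$qi], len_d = dlen[g$di],
               attr_sum = qlen[g$qi] + dlen[g$di],
               attr_product = as.numeric(qlen[g$qi]) * dlen[g$di],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("JobList", "data.frame")
  out
}

job_tiebreak_order <- function(jobs, primary) {
  order(primary, jobs$query_id, jobs$db_id, jobs$method)
}

#' Random equal-count partitioning
#'
#' Shuffles the job list with the given seed and deals jobs out so that
#' partition sizes differ by at most one. This is the baseline scheme whose
#' per-partition workloads vary widely, leaving cores idle.
#'
#' @param jobs A `JobList`.
#' @param n_parts Number of partitions (>= 1).
#' @param seed RNG seed for the shuffle.
#' @return List of `n_parts` integer vectors of job row indices.
#' @export
partition_random <- function(jobs, n_parts, seed = 1L) {
  stopifnot(n_parts >= 1L)
  n <- nrow(jobs)
  perm <- local_seed(seed, sample.int(n))
  parts <- rep(list(integer(0)), n_parts)
  for (k in seq_len(n)) {
    p <- ((k - 1L) %% n_parts) + 1L
    parts[[p]] <- c(parts[[p]], perm[k])
  }
  parts
}

#' Greedy longest-processing-time partitioning
#'
#' Jobs are sorted in descending order of the chosen length attribute (sum
#' or product of the pair's lengths, the paper-style workload proxies) and
#' each is assigned to the partition with the smallest running total.
#' Sorting ties break by (query_id, db_id, method); running-sum ties go to
#' the lowest partition index, so the result is fully deterministic.
#'
#' @param jobs A `JobList`.
#' @param n_parts Number of partitions (>= 1).
#' @param attribute `"sum"` or `"product"`, or a numeric weight per job.
#' @return List of `n_parts` integer vectors of job row indices.
#' @export
partition_greedy_lpt <- function(jobs, n_parts, attribute = "product") {
  stopifnot(n_parts >= 1L)
  w <- job_weights(jobs, attribute)
  ord <- job_tiebreak_order(jobs, -w)
  parts <- rep(list(integer(0)), n_parts)
  totals <- numeric(n_parts)
  for (i in ord) {
    p <- which.min(totals)   # ties -> lowest index
    parts[[p]] <- c(parts[[p]], i)
    totals[p] <- totals[p] + w[i]
  }
  parts
}

job_weights <- function(jobs, attribute) {
  if (is.numeric(attribute)) {
    if (length(attribute) != nrow(jobs))
      stop("weight count (", length(attribute), ") != job count (", nrow(jobs), ")")
    return(as.numeric(attribute))
  }
  attribute <- match.arg(attribute, c("sum", "product"))
  if (attribute == "sum") as.numeric(jobs$attr_sum) else jobs$attr_product
}

#' Sort jobs by decreasing attribute
#'
#' Stable descending sort on the sum or product of pair lengths; jobs with
#' equal attribute keep their input order. Feeding the sorted list to the
#' dynamic round-robin dispatcher gives the presorted task-farm strategy.
#'
#' @param jobs A `JobList`.
#' @param attribute `"sum"`, `"product"`, or a numeric weight per job.
#' @return The reordered `JobList` (with attribute `"order"` giving the
#'   original row indices).
#' @export
sort_jobs_desc <- function(jobs, attribute = "product") {
  w <- job_weights(jobs, attribute)
  ord <- order(-w)   # stable: ties keep input order
  out <- jobs[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "order") <- ord
  out
}

make_schedule <- function(assignments, finish_times, serial_time) {
  makespan <- max(finish_times)
  n_workers <- length(assignments)
  speedup <- serial_time / makespan
  structure(list(assignments = assignments, finish_times = finish_times,
                 makespan = makespan, serial_time = serial_time,
                 speedup = speedup, efficiency = speedup / n_workers,
                 idle = makespan - finish_times, n_workers = n_workers),
            class = "Schedule")
}

#' @export
print.Schedule <- function(x, ...) {
  cat(sprintf("<Schedule> %d workers, makespan %.4g, speedup %.3f, efficiency %.3f\n",
              x$n_workers, x$makespan, x$speedup, x$efficiency))
  invisible(x)
}

#' Dynamic round-robin dispatch (simulated)
#'
#' Event-driven simulation of the master/worker task farm: each job in list
#' order goes to the worker with the earliest current finish time (ties to
#' the lowest worker index), i.e. the next free worker receives the next
#' job.
#'
#' @param ordered_jobs A `JobList` (typically from [sort_jobs_desc()]), or
#'   an integer job count.
#' @param n_workers Number of workers (>= 1).
#' @param costs Non-negative cost per job, in job-list order.
#' @return A `Schedule`; assignments hold job positions in `ordered_jobs`.
#' @export
dispatch_round_robin <- function(ordered_jobs, n_workers, costs) {
  n <- if (is.numeric(ordered_jobs) && length(ordered_jobs) == 1L) ordered_jobs
       else nrow(ordered_jobs)
  if (length(costs) != n)
    stop("cost count (", length(costs), ") != job count (", n, ")")
  if (any(costs < 0)) stop("costs must be non-negative")
  stopifnot(n_workers >= 1L)
  finish <- numeric(n_workers)
  assignments <- rep(list(integer(0)), n_workers)
  for (k in seq_len(n)) {
    wkr <- which.min(finish)
    assignments[[wkr]] <- c(assignments[[wkr]], k)
    finish[wkr] <- finish[wkr] + costs[k]
  }
  make_schedule(assignments, finish, sum(costs))
}

#' Simulate a static partition schedule
#'
#' Each partition runs on its own worker; a worker's finish time is the sum
#' of its jobs' costs. Reports makespan, speedup over serial execution, and
#' efficiency (speedup / worker count).
#'
#' @param partitions List of integer job-index vectors
#'   (from [partition_random()] or [partition_greedy_lpt()]).
#' @param costs Non-negative cost per job, indexed as in the partitions.
#' @return A `Schedule`.
#' @export
simulate_partition_schedule <- function(partitions, costs) {
  if (any(costs < 0)) stop("costs must be non-negative")
  all_idx <- sort(unlist(partitions))
  if (anyDuplicated(all_idx)) stop("a job appears in more than one partition")
  finish <- vapply(partitions, function(ix) sum(costs[ix]), numeric(1))
  make_schedule(partitions, finish, sum(costs[all_idx]))
}

#' Execute a job farm
#'
#' Sequential-routed jobs run first in the coordinating process; parallel
#' jobs are grouped by pair (so methods sharing an alignment compute it
#' once) and handed to a pool of `n_workers` forked workers with next-free
#' dispatch. Results are deterministic: the returned scores are identical
#' for any `n_workers`.
#'
#' @param jobs A `JobList` from [generate_jobs()].
#' @param registry A [method_registry()].
#' @param store A [domain_store()] over the referenced domains.
#' @param n_workers Worker count (>= 1; 1 means run in-process).
#' @param threshold_angstrom,min_separation Contact-map parameters for
#'   compression-based methods.
#' @return List of [method_score()] objects in job order.
#' @export
execute_parallel <- function(jobs, registry = method_registry(), store,
                             n_workers = 1L, threshold_angstrom = 8.0,
                             min_separation = 2L) {
  stopifnot(n_workers >= 1L)
  ctx <- run_context(store, threshold_angstrom, min_separation)
  res <- vector("list", nrow(jobs))
  for (i in which(jobs$routing == "sequential"))
    res[[i]] <- run_method(jobs[i, ], registry, store, ctx)
  par_idx <- which(jobs$routing == "parallel")
  if (length(par_idx)) {
    key <- paste(jobs$query_id[par_idx], jobs$db_id[par_idx], sep = "\r")
    groups <- split(par_idx, factor(key, levels = unique(key)))
    worker <- function(ix) lapply(ix, function(i)
      tryCatch(run_method(jobs[i, ], registry, store, ctx),
               error = function(e) stop("job (", jobs$query_id[i], ", ",
                                        jobs$db_id[i], ", ", jobs$method[i],
                                        ") failed: ", conditionMessage(e),
                                        call. = FALSE)))
    out <- if (n_workers > 1L && .Platform$OS.type == "unix") {
      o <- parallel::mclapply(groups, worker, mc.cores = n_workers)
      bad <- vapply(o, inherits, logical(1), "try-error")
      if (any(bad)) stop(attr(o[[which(bad)[1L]]], "condition")$message)
      o
    } else lapply(groups, worker)
    for (g in seq_along(groups))
      res[groups[[g]]] <- out[[g]]
  }
  res
}

#' Fit a job cost model
#'
#' Least-squares polynomial fit of observed job times against a length
#' attribute: `linear` fits `a*x + b`, `quadratic` fits `a*x^2 + b*x + c`.
#' Being nested models, the quadratic residual sum of squares never exceeds
#' the linear one on the same data.
#'
#' @param attrs Positive attribute values (sum or product of pair lengths).
#' @param times Observed times, same length.
#' @param form `"linear"` or `"quadratic"`.
#' @param attribute Optional bookkeeping tag (`"sum"` or `"product"`).
#' @return Object of class `CostModel`: `form`, `attribute`, `coefficients`
#'   (highest degree first), `residual_ss`.
#' @export
fit_cost_model <- function(attrs, times, form = c("quadratic", "linear"),
                           attribute = NA_character_) {
  form <- match.arg(form)
  if (length(attrs) != length(times)) stop("attrs and times differ in length")
  if (length(attrs) < 3L) stop("need at least 3 observations")
  if (any(attrs <= 0)) stop("attrs must be positive")
  if (length(unique(attrs)) < 2L)
    stop("singular design: all attribute values equal")
  x <- as.numeric(attrs); y <- as.numeric(times)
  fit <- if (form == "linear") stats::lm(y ~ x) else stats::lm(y ~ I(x^2) + x)
  cf <- stats::coef(fit)
  coefficients <- if (form == "linear")
    c(a = unname(cf["x"]), b = unname(cf["(Intercept)"]))
  else
    c(a = unname(cf["I(x^2)"]), b = unname(cf["x"]), c = unname(cf["(Intercept)"]))
  structure(list(form = form, attribute = attribute,
                 coefficients = coefficients,
                 residual_ss = sum(stats::residuals(fit)^2)),
            class = "CostModel")
}

#' Predict job costs from a cost model
#' @param model A [fit_cost_model()] result (or a list with `form` and
#'   `coefficients`).
#' @param attrs Attribute values.
#' @return Predicted costs.
#' @export
predict_cost <- function(model, attrs) {
  cf <- model$coefficients
  x <- as.numeric(attrs)
  if (model$form == "linear") cf[["a"]] * x + cf[["b"]]
  else cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]]
}
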