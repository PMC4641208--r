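test_that("usm_distance is symmetric, small on self, large on random pairs", {
  maps <- list(
    contact_map(collinear_domain(30L)),
    random_cmap("a", 100L, 200L, seed = 101),
    random_cmap("b", 100L, 200L, seed = 202),
    contact_map(make_family_template(family_spec("h", "helix", 50L, seed = 5)))
  )
  for (cm in maps) {
    if (nrow(cm$contacts) >= 10L)
      expect_lte(usm_distance(cm, cm)$value, 0.15)
  }
  for (i in seq_along(maps)) for (j in seq_along(maps)) {
    expect_identical(usm_distance(maps[[i]], maps[[j]])$value,
                     usm_distance(maps[[j]], maps[[i]])$value)
  }
  # two independent uniformly random maps are near-incompressible together
  expect_gte(usm_distance(maps[[2]], maps[[3]])$value, 0.7)

  s <- usm_distance(maps[[2]], maps[[3]])
  expect_equal(s$kind, "distance")
  cs <- compression_sizes(maps[[2]], maps[[3]])
  expect_true(all(unlist(cs) > 0))
  expect_lte(cs$c_xy, cs$c_x + cs$c_y + 64L)  # concatenation overhead bound
})

test_that("kabsch_superpose recovers rigid transforms and matches the grid oracle", {
  set.seed(21)
  p <- matrix(rnorm(30), 10L)
  fit0 <- kabsch_superpose(p, p)
  expect_equal(fit0$rmsd, 0)
  expect_equal(fit0$rotation, diag(3))
  expect_equal(fit0$translation, c(0, 0, 0))

  q <- rigid_transform(p, angle_deg = 90, axis = c(0, 0, 1), shift = c(5, -2, 1))
  expect_lte(kabsch_superpose(p, q)$rmsd, 1e-6)

  # rmsd invariant under a common rigid transform of both sets
  for (rep in 1:5) {
    a <- matrix(rnorm(18), 6L)
    b <- a + matrix(rnorm(18, sd = 0.3), 6L)
    base <- kabsch_superpose(a, b)$rmsd
    ang <- runif(1, 0, 180); ax <- rnorm(3); sh <- rnorm(3, sd = 10)
    expect_equal(kabsch_superpose(rigid_transform(a, ang, ax, sh),
                                  rigid_transform(b, ang, ax, sh))$rmsd,
                 base, tolerance = 1e-9)
  }

  # brute-force rotation-grid oracle on small noisy instances
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  set.seed(7)
  for (rep in 1:3) {
    qn <- rigid_transform(sq + matrix(rnorm(12, sd = 0.1), 4L),
                          angle_deg = runif(1, 0, 360), axis = rnorm(3))
    expect_equal(kabsch_superpose(sq, qn)$rmsd, grid_search_rmsd(sq, qn),
                 tolerance = 1e-3)
  }
})

test_that("align_sequences matches exhaustive enumeration and frozen cases", {
  id <- align_sequences("ACDE", "ACDE")
  expect_equal(id$pairs, cbind(0:3, 0:3))
  expect_equal(id$score, 4)

  gapped <- align_sequences("ACDE", "ACE")
  expect_equal(gapped$pairs, cbind(c(0L, 1L, 3L), c(0L, 1L, 2L)))
  expect_equal(gapped$score, 2)                     # 3 matches + 1 gap
  expect_equal(gapped$score, enum_align_score("ACDE", "ACE"))

  mm <- align_sequences("A", "G")
  expect_equal(mm$pairs, cbind(0L, 0L))             # mismatch (0) beats 2 gaps
  expect_equal(mm$score, enum_align_score("A", "G"))

  set.seed(33)
  alpha <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    a <- paste(sample(alpha, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), TRUE), collapse = "")
    res <- align_sequences(a, b)
    expect_equal(res$score, enum_align_score(a, b), info = paste(a, b))
    if (nrow(res$pairs) > 1L) {   # strictly increasing in both columns
      expect_true(all(diff(res$pairs[, 1L]) > 0))
      expect_true(all(diff(res$pairs[, 2L]) > 0))
    }
  }
})

test_that("tm_like_compare: identity, rigid invariance, d0 floor, noise monotonicity", {
  tmpl <- make_family_template(family_spec("f", "helix", n_residues = 40L,
                                           seed = 9L))
  self <- tm_like_compare(tmpl, tmpl)
  expect_equal(self$tm_score, 1.0)
  expect_equal(self$rmsd, 0)

  moved <- protein_domain("mv", "A", tmpl$sequence,
                          rigid_transform(tmpl$ca_coords, 123, c(1, 2, 3)))
  rig <- tm_like_compare(tmpl, moved)
  expect_gte(rig$tm_score, 0.999)
  expect_lte(rig$rmsd, 1e-6)

  # d0 formula: L_ref = 21 floors at 0.5 (raw ~0.453)
  t21 <- make_family_template(family_spec("s", "helix", n_residues = 21L,
                                          seed = 2L))
  expect_equal(tm_like_compare(tmpl, t21)$d0, 0.5)
  t40 <- tm_like_compare(t21, tmpl)
  expect_equal(t40$d0, 1.24 * (40 - 15)^(1/3) - 1.8)

  # tm in [0,1] and non-increasing (on average) with growing noise
  sds <- c(0.2, 0.8, 2.0)
  means <- vapply(sds, function(sd) {
    mean(vapply(1:20, function(s) {
      noisy <- sample_family_member(tmpl, noise_sd = sd, indel_rate = 0,
                                    seed = 5000 + s)
      v <- tm_like_compare(tmpl, noisy)$tm_score
      expect_gte(v, 0); expect_lte(v, 1)
      v
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("run_method dispatches via registry and honors the cache contract", {
  doms <- dummy_domains(34L, len = 20L)
  store <- domain_store(doms)
  reg <- method_registry()
  job <- psc_job("d0001", "d0002", "usm", "sequential", 20L, 20L)
  s <- run_method(job, reg, store)
  expect_equal(s$kind, "distance")
  expect_error(run_method(psc_job("d0001", "d0002", "nope", "parallel", 1L, 1L),
                          reg, store), "unknown method")

  tmjob <- psc_job("d0001", "d0001", "tm", "parallel", 20L, 20L)
  expect_equal(run_method(tmjob, reg, store)$value, 1.0)

  # 1156 usm jobs over 34 domains -> exactly 34 domain loads
  usm_only <- method_registry(default = FALSE)
  register_method(usm_only, "usm", "distance", "sequential",
    fn = function(q, d, ctx) usm_distance(ctx$cmap(q$id), ctx$cmap(d$id))$value)
  store2 <- domain_store(doms)
  jobs <- generate_jobs(doms, doms, usm_only)
  expect_equal(nrow(jobs), 1156L)
  res <- execute_parallel(jobs, usm_only, store2)
  expect_length(res, 1156L)
  expect_equal(store2$loads, 34L)
})

test_that("load_external_scores validates the adapter TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tdb_id\tvalue", "a\tb\t0.5", "a\tc\t1.25", "b\tc\t0"),
             path)
  sc <- load_external_scores(path, "tmalign_ext", "similarity")
  expect_length(sc, 3L)
  expect_equal(vapply(sc, `[[`, "", "method"),
               rep("tmalign_ext", 3L))
  expect_equal(vapply(sc, `[[`, 0, "value"), c(0.5, 1.25, 0))
  expect_equal(sc[[1L]]$kind, "similarity")

  writeLines(c("query_id\tdb_id", "a\tb"), path)
  expect_error(load_external_scores(path, "m", "distance"), "value")

  writeLines(c("query_id\tdb_id\tvalue", "a\tb\tnotnum"), path)
  expect_error(load_external_scores(path, "m", "distance"), "non-numeric")

  writeLines(c("query_id\tdb_id\tvalue", "a\tb\t1", "a\tb\t2"), path)
  expect_error(load_external_scores(path, "m", "distance"), "duplicate.*a.*b")
})
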