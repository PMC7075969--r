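test_that("KS statistic matches hand-computed tag placements", {
  top <- ks_statistic(c(1, 2), 10)
  expect_equal(top$a, 0.8)
  expect_equal(top$b, 0.1)
  expect_equal(top$es, 0.8)   # tags at the top: 1 - t/n

  bottom <- ks_statistic(c(9, 10), 10)
  expect_equal(bottom$a, 0)
  expect_equal(bottom$b, 0.9)
  expect_equal(bottom$es, -0.9)

  # a == b tie resolves to the positive branch; both sides exposed
  tie <- ks_statistic(c(3, 7), 10)
  expect_equal(tie$a, 0.3)
  expect_equal(tie$b, 0.3)
  expect_equal(tie$es, 0.3)
  expect_equal(tie$es, ks_oracle(c(3, 7), 10))
})

test_that("KS statistic rejects malformed rank input", {
  expect_error(ks_statistic(c(2, 1), 10), class = "sigconnect_input_error")
  expect_error(ks_statistic(c(3, 3), 10), class = "sigconnect_input_error")
  expect_error(ks_statistic(c(0, 2), 10), class = "sigconnect_input_error")
  expect_error(ks_statistic(c(5, 11), 10), class = "sigconnect_input_error")
  expect_error(ks_statistic(integer(0), 10), class = "sigconnect_input_error")
})

test_that("KS statistic equals the brute-force sup-difference oracle", {
  set.seed(2024)
  for (case in 1:300) {
    n <- sample(2:50, 1)
    t <- sample(seq_len(n), 1)
    v <- sort(sample.int(n, t))
    r <- ks_statistic(v, n)
    expect_equal(r$es, ks_oracle(v, n), tolerance = 0)
    expect_gte(r$a, 0); expect_gte(r$b, 0)
    expect_lte(abs(r$es), 1)
  }
})

test_that("raw scores follow the opposite-sign combination rule", {
  probes <- sprintf("p%02d", 1:10)
  prof <- rank_profile_from_amplitudes(
    stats::setNames(seq(5, -4, length.out = 10), probes), "i1", "cmp", "CL")
  # up tags at top, down tags at bottom: concordant, s = es_up - es_down
  ic <- instance_connectivity(prof, gene_signature(c("p01", "p02"),
                                                   c("p09", "p10")))
  expect_equal(ic$s, ic$ks_up$es - ic$ks_down$es)
  expect_equal(ic$s, 0.8 - (-0.9))

  # both sides crowd the top: same strict sign => null instance
  same <- instance_connectivity(prof, gene_signature(c("p01", "p02"),
                                                     c("p03", "p04")))
  expect_gt(same$ks_up$es, 0)
  expect_gt(same$ks_down$es, 0)
  expect_equal(same$s, 0)

  # one-sided query scores as the es of the present side
  uponly <- instance_connectivity(prof, gene_signature(up = c("p01", "p02")))
  expect_equal(uponly$s, uponly$ks_up$es)

  # no overlap with the universe
  expect_error(instance_connectivity(prof, gene_signature("zz1", "zz2")),
               class = "sigconnect_coverage_error")
})

test_that("swapping up and down tags negates every nonzero raw score", {
  set.seed(77)
  db <- random_db(30, 12, 4, seed = 77)
  probes <- db$probes
  for (rep in 1:10) {
    pick <- sample(probes, 10)
    q <- gene_signature(pick[1:5], pick[6:10])
    qsw <- gene_signature(pick[6:10], pick[1:5])
    r <- run_query(db, q, query_config(n_perm = 200, seed = 5))
    rsw <- run_query(db, qsw, query_config(n_perm = 200, seed = 5))
    expect_equal(rsw$instances$s, -r$instances$s)
    m <- r$results$similarity_mean[order(r$results$group_key)]
    msw <- rsw$results$similarity_mean[order(rsw$results$group_key)]
    expect_equal(msw, -m)
  }
})

test_that("connectivity scaling maps raw scores into [-1, 1] with attained extremes", {
  sc <- scale_scores(c(1.7, -1.7, 0.5, 0))
  expect_equal(sc$factors$p_max, 1.7)
  expect_equal(sc$factors$q_min, -1.7)
  expect_equal(sc$c, c(1, -1, 0.5 / 1.7, 0))

  expect_equal(scale_scores(c(0, 0))$c, c(0, 0))

  set.seed(5)
  for (rep in 1:25) {
    s <- round(rnorm(sample(2:30, 1)), 3)
    sc <- scale_scores(s)
    expect_true(all(abs(sc$c) <= 1))
    if (any(s > 0)) expect_equal(max(sc$c), 1)
    if (any(s < 0)) expect_equal(min(sc$c), -1)
    expect_equal(sc$c * sign(sc$c), abs(sc$c))
    # invariance under positive rescaling
    lambda <- runif(1, 0.1, 10)
    expect_equal(scale_scores(lambda * s)$c, sc$c)
    expect_equal(sign(sc$c), sign(s))
  }
})

test_that("compound aggregation averages member connectivity scores", {
  meta <- data.frame(instance_id = c("a", "b", "c"),
                     compound = "cmp", cell_line = "CL",
                     stringsAsFactors = FALSE)
  sc <- data.frame(instance_id = c("a", "b", "c"),
                   s = c(1.7, -1.7, 0.5), c = c(1, -1, 0.2941))
  agg <- aggregate_compound(sc, meta, query_config())
  expect_equal(agg$similarity_mean, mean(c(1, -1, 0.2941)))
  expect_equal(agg$n_instances, 3L)
  expect_equal(agg$group_key, "cmp:CL")

  one <- aggregate_compound(
    data.frame(instance_id = "a", s = -0.4, c = -0.4),
    meta[1, ], query_config())
  expect_equal(one$similarity_mean, -0.4)
  expect_equal(one$n_instances, 1L)

  withnull <- data.frame(instance_id = c("a", "b", "c"),
                         s = c(0.5, 0, 0), c = c(0.5, 0, 0))
  excl <- aggregate_compound(withnull, meta,
                             query_config(include_null_instances = FALSE))
  expect_equal(excl$similarity_mean, 0.5)
  expect_equal(excl$n_instances, 3L)
  expect_equal(excl$n_nonnull, 1L)
})

test_that("group enrichment is the KS statistic of member positions", {
  expect_equal(set_enrichment(c(1, 2, 3), 100), 0.97)   # 1 - 3/100
  # b branch, dominated by the j = 1 term: 99/100 - 0
  expect_equal(set_enrichment(c(99, 100), 100), -0.99)
  expect_equal(set_enrichment(c(99, 100), 100), ks_oracle(c(99, 100), 100))
  expect_equal(set_enrichment(c(1, 3), 5), 0.4)
  expect_equal(set_enrichment(c(1, 3), 5), ks_oracle(c(1, 3), 5))
})

test_that("permutation p enumerates exactly when affordable and samples otherwise", {
  # N = 5, pairs: exhaustive oracle over all 10 subsets
  all_pairs <- t(combn(5, 2))
  es_all <- apply(all_pairs, 1, function(v) ks_oracle(v, 5))
  obs <- set_enrichment(c(1, 3), 5)
  p_oracle <- mean(es_all >= obs & sign(es_all) == sign(obs))
  expect_equal(p_oracle, 3 / 10)

  cfg_exact <- query_config(n_perm = 100, seed = 1, enumeration_cap = 100)
  expect_equal(permutation_p(obs, 2, 5, cfg_exact), 3 / 10)

  # observed maximal: only the top set itself qualifies
  top_obs <- set_enrichment(c(1, 2), 5)
  expect_equal(permutation_p(top_obs, 2, 5, cfg_exact), 1 / 10)

  # sampling mode converges to the enumerated value
  cfg_samp <- query_config(n_perm = 100000, seed = 42, enumeration_cap = 1)
  p_hat <- permutation_p(obs, 2, 5, cfg_samp)
  se <- sqrt(0.3 * 0.7 / 100000)
  expect_lt(abs(p_hat - 0.3), 3 * se)

  # pseudo-count mode never reports exactly zero in sampling mode
  cfg_pc <- query_config(n_perm = 500, seed = 9, enumeration_cap = 1,
                         pseudo_count = TRUE)
  expect_gt(permutation_p(0.999999, 2, 5, cfg_pc), 0)

  # absolute tail counts both signs
  cfg_abs <- query_config(direction_rule = "absolute", enumeration_cap = 100)
  p_abs <- permutation_p(obs, 2, 5, cfg_abs)
  expect_equal(p_abs, mean(abs(es_all) >= abs(obs)))
  expect_gte(p_abs, permutation_p(obs, 2, 5, cfg_exact))
})

test_that("result ranking orders by p, then |enrichment|, then |mean|, then key", {
  g <- data.frame(group_key = c("a", "b", "c"),
                  similarity_mean = c(0.5, 0.6, 0.7),
                  enrichment = c(0.90, 0.95, 0.99),
                  p_value = c(0.001, 0.001, 0.010))
  r <- rank_results(g)
  expect_equal(r$group_key, c("b", "a", "c"))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(group_key = c("zeta", "alpha"),
                    similarity_mean = 0.2, enrichment = 0.5, p_value = 0.5)
  expect_equal(rank_results(tie)$group_key, c("alpha", "zeta"))

  single <- data.frame(group_key = "only", similarity_mean = 0.1,
                       enrichment = 0.2, p_value = 0.3)
  expect_equal(rank_results(single)$rank, 1L)
})

test_that("run_query drops absent tags with a count and errors on no coverage", {
  db <- toy_db()
  q <- gene_signature(c("p01", "p02", "notaprobe"), c("p09", "p10"))
  expect_message(res <- run_query(db, q, query_config(n_perm = 50, seed = 1)),
                 "1 query tag")
  expect_equal(res$provenance$dropped_up, 1L)
  expect_equal(res$provenance$n_tags_up, 2L)
  expect_error(run_query(db, gene_signature("xx", "yy"), query_config()),
               class = "sigconnect_coverage_error")
})

test_that("query results are deterministic and bounded on a random-permutation database", {
  db <- random_db(40, 24, 8, seed = 123)
  q <- gene_signature(db$probes[1:6], db$probes[7:12])
  cfg <- query_config(n_perm = 2000, seed = 17)
  res <- run_query(db, q, cfg)
  expect_true(all(abs(res$instances$c) <= 1))
  expect_true(all(abs(res$results$enrichment) <= 1))
  expect_true(all(res$results$p_value >= 0 & res$results$p_value <= 1))
  expect_true(all(abs(res$results$similarity_mean) <= 1))

  res2 <- run_query(db, q, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_results(res, f1)
  write_results(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("result tables are written with the documented column order", {
  db <- toy_db()
  res <- run_query(db, gene_signature(c("p01", "p02"), c("p09", "p10")),
                   query_config(n_perm = 50, seed = 1))
  f <- tempfile(fileext = ".tsv")
  fi <- tempfile(fileext = ".tsv")
  write_results(res, f, fi)
  expect_identical(strsplit(readLines(f, n = 1), "\t")[[1]],
                   c("rank", "group_key", "compound", "cell_line",
                     "n_instances", "similarity_mean", "enrichment",
                     "p_value", "n_nonnull"))
  expect_identical(strsplit(readLines(fi, n = 1), "\t")[[1]],
                   c("instance_id", "compound", "cell_line", "ks_up",
                     "ks_down", "s", "c"))
})
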