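test_that("instrument selection uses a strict p-value inequality", {
  rec <- make_records(sprintf("rs%d", 1:5),
                      pvalue = c(1e-9, 1e-7, 4.9e-8, 5e-8, 1e-10))
  kept <- select_instruments(rec, 5e-8)
  expect_identical(kept$snp_id, c("rs1", "rs3", "rs5"))  # order preserved

  none <- make_records(c("rs1", "rs2"), pvalue = 0.5)
  expect_equal(nrow(select_instruments(none)), 0L)
})

test_that("clumping applies the window and strict r2 rules", {
  two <- function(dist, p = c(1e-20, 1e-9)) {
    make_records(c("rsA", "rsB"), pvalue = p, pos = c(1e6L, as.integer(1e6 + dist)))
  }
  ld <- function(r2) ld_info(data.frame(snp_a = "rsA", snp_b = "rsB", r2 = r2))

  # 2 Mb apart: outside the 1 Mb window, both kept despite r2 = 0.9
  expect_equal(nrow(clump(two(2e6), ld(0.9))), 2L)
  # 10 kb apart, r2 = 0.5: only the smaller p-value survives
  res <- clump(two(1e4), ld(0.5))
  expect_identical(res$snp_id, "rsA")
  # r2 exactly at the boundary is kept (strictly-greater rule)
  expect_equal(nrow(clump(two(1e4), ld(0.009))), 2L)
  expect_equal(nrow(clump(two(1e4), ld(0.01))), 2L)
  expect_equal(nrow(clump(two(1e4), ld(0.011))), 1L)
  # unknown in-window pair: error in strict mode, removed in lenient mode
  nold <- ld_info(data.frame(snp_a = character(), snp_b = character(),
                             r2 = numeric()))
  expect_error(clump(two(1e4), nold, strict = TRUE), "rs")
  expect_equal(nrow(clump(two(1e4), nold, strict = FALSE)), 1L)
})

test_that("clumped sets satisfy the pairwise constraint on random instances", {
  for (seed in 1:15) {
    set.seed(seed)
    k <- sample(3:20, 1)
    rec <- make_records(sprintf("rs%02d", 1:k),
                        pvalue = runif(k, 1e-12, 1e-6),
                        chrom = sample(c("1", "2"), k, replace = TRUE),
                        pos = sample.int(3e6, k))
    pairs <- t(combn(rec$snp_id, 2))
    ld <- ld_info(data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                             r2 = runif(nrow(pairs))))
    out <- clump(rec, ld, r2_max = 0.1, window_bp = 1e6)
    expect_true(all(out$snp_id %in% rec$snp_id))
    expect_true(clump_constraint_ok(out, ld, 0.1, 1e6))
    # the best-p SNP always survives greedy clumping
    expect_true(rec$snp_id[which.min(rec$pvalue)] %in% out$snp_id)
  }
})

test_that("proxy substitution applies the r2 gate and max/tie rules", {
  outcome_ids <- c("rsP1", "rsP2", "rsP3")
  tab <- data.frame(snp = "rsX", proxy = c("rsP1", "rsP2"),
                    r2 = c(0.8, 0.95), stringsAsFactors = FALSE)
  res <- substitute_proxies("rsX", tab, outcome_ids)
  expect_identical(res$map$proxy, "rsP2")  # highest r2 wins

  below <- data.frame(snp = "rsX", proxy = "rsP1", r2 = 0.79)
  expect_identical(substitute_proxies("rsX", below, outcome_ids)$dropped, "rsX")

  tie <- data.frame(snp = "rsX", proxy = c("rsP3", "rsP1"), r2 = 0.9)
  expect_identical(substitute_proxies("rsX", tie, outcome_ids)$map$proxy,
                   "rsP1")  # lexicographic tie-break

  expect_identical(substitute_proxies(c("rsX", "rsY"), NULL, outcome_ids)$dropped,
                   c("rsX", "rsY"))
  # proxies absent from the outcome data do not count
  absent <- data.frame(snp = "rsX", proxy = "rsZZ", r2 = 0.99)
  expect_identical(substitute_proxies("rsX", absent, outcome_ids)$dropped, "rsX")
})

rec1 <- function(ea, oa, beta, eaf = NA_real_, id = "rs1") {
  list(snp_id = id, effect_allele = ea, other_allele = oa, beta = beta,
       se = 0.05, eaf = eaf, pvalue = 1e-9)
}

test_that("harmonize_pair handles identity, swap and strand complement", {
  h <- harmonize_pair(rec1("A", "G", 0.1), rec1("A", "G", -0.2))
  expect_equal(h$Y, -0.2)
  expect_identical(h$flag, "unchanged")

  h <- harmonize_pair(rec1("A", "G", 0.1), rec1("G", "A", -0.2, eaf = 0.3))
  expect_equal(h$Y, 0.2)
  expect_equal(h$eaf_out, 0.7)
  expect_identical(h$flag, "allele_flipped")

  # outcome on the opposite strand: T/C is the complement of A/G
  h <- harmonize_pair(rec1("A", "G", 0.1), rec1("T", "C", -0.2))
  expect_equal(h$Y, -0.2)
  expect_identical(h$flag, "unchanged")
  h <- harmonize_pair(rec1("A", "G", 0.1), rec1("C", "T", -0.2))
  expect_equal(h$Y, 0.2)
  expect_identical(h$flag, "allele_flipped")

  d <- harmonize_pair(rec1("A", "G", 0.1), rec1("A", "C", -0.2))
  expect_true(d$dropped)
  expect_identical(d$reason, "incompatible_alleles")
})

test_that("palindromic variants follow the configured policy", {
  ex <- rec1("A", "T", 0.1, eaf = 0.3)
  ot <- rec1("A", "T", -0.2, eaf = 0.25)

  kept <- harmonize_pair(ex, ot, palindromic_mode = "keep")
  expect_identical(kept$flag, "palindromic_kept")
  expect_equal(kept$Y, -0.2)
  swapped <- harmonize_pair(ex, rec1("T", "A", -0.2), palindromic_mode = "keep")
  expect_equal(swapped$Y, 0.2)

  expect_true(harmonize_pair(ex, ot, palindromic_mode = "drop")$dropped)

  # frequency mode: informative same-side frequencies are kept
  expect_false(harmonize_pair(ex, ot, palindromic_mode = "frequency")$dropped)
  # ambiguous window
  amb <- harmonize_pair(rec1("A", "T", 0.1, eaf = 0.5),
                        rec1("A", "T", -0.2, eaf = 0.45),
                        palindromic_mode = "frequency")
  expect_true(amb$dropped)
  # opposite sides of 0.5
  opp <- harmonize_pair(ex, rec1("A", "T", -0.2, eaf = 0.8),
                        palindromic_mode = "frequency")
  expect_true(opp$dropped)
  # missing frequency cannot be resolved
  nof <- harmonize_pair(rec1("A", "T", 0.1), ot, palindromic_mode = "frequency")
  expect_true(nof$dropped)
})

test_that("double allele flip is idempotent", {
  for (seed in 1:10) {
    set.seed(seed)
    beta <- rnorm(1)
    eaf <- runif(1, 0.05, 0.95)
    ex <- rec1("A", "G", 0.1)
    out <- rec1("A", "G", beta, eaf = eaf)
    once <- harmonize_pair(ex, rec1("G", "A", -beta, eaf = 1 - eaf))
    expect_equal(once$Y, beta, tolerance = 1e-15)
    expect_equal(once$eaf_out, eaf, tolerance = 1e-15)
    direct <- harmonize_pair(ex, out)
    expect_equal(once$Y, direct$Y)
  }
})

test_that("build_harmonized_set merges, flags and audits", {
  exposure <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.15))
  outcome <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.05, -0.08, 0.02))
  outcome[2, c("effect_allele", "other_allele")] <- c("G", "A")  # swapped
  h <- build_harmonized_set(exposure, outcome, "gf", "ms")
  expect_equal(length(h$snp_ids), 3L)
  expect_identical(h$flags[h$snp_ids == "rs2"], "allele_flipped")
  expect_equal(h$Y[h$snp_ids == "rs2"], 0.08)
  expect_identical(sort(h$audit$status), rep("kept", 3))

  disjoint <- make_records(c("rs8", "rs9"))
  expect_error(build_harmonized_set(exposure, disjoint, "gf", "ms"),
               "empty harmonized set")
})

test_that("proxies enter harmonization with the proxy_substituted flag", {
  exposure <- make_records(c("rs1", "rs2"), beta = c(0.1, 0.2))
  outcome <- make_records(c("rs1", "rsP"), beta = c(0.05, -0.07))
  proxy <- data.frame(snp = "rs2", proxy = "rsP", r2 = 0.9,
                      proxy_effect_allele = "A", proxy_other_allele = "G",
                      stringsAsFactors = FALSE)
  h <- build_harmonized_set(exposure, outcome, proxy_table = proxy)
  expect_equal(length(h$snp_ids), 2L)
  expect_identical(h$flags[h$snp_ids == "rs2"], "proxy_substituted")
  expect_equal(h$Y[h$snp_ids == "rs2"], -0.07)

  # below the r2 gate the instrument is dropped and audited
  weak <- transform(proxy, r2 = 0.79)
  h2 <- build_harmonized_set(exposure, outcome, proxy_table = weak)
  expect_identical(h2$snp_ids, "rs1")
  expect_identical(h2$audit$detail[h2$audit$snp_id == "rs2"], "no_proxy")
})

test_that("negating both sides of one SNP leaves its Wald ratio unchanged", {
  for (seed in 1:8) {
    h <- rand_hset(6, seed)
    i <- sample(6, 1)
    h2 <- h
    h2$X[i] <- -h2$X[i]
    h2$Y[i] <- -h2$Y[i]
    expect_equal(h2$Y[i] / h2$X[i], h$Y[i] / h$X[i], tolerance = 1e-15)
    expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  }
})
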